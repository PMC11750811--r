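# Independent oracles, written without reference to the package internals.

# Hand-written trio segregation truth table. Autosomal genotypes are coded
# by alternate-allele dosage of a diploid call; male-X genotypes by
# hemizygous dosage for proband/father and diploid dosage for the mother.
oracle_segregation_autosomal <- function(pro, fa, mo) {
  if (pro == 1 && fa == 0 && mo == 0) return("de_novo")
  if (pro == 2 && fa == 1 && mo == 1) return("autosomal_recessive")
  "none"
}

oracle_segregation_male_x <- function(pro, mo, fa) {
  if (pro == 1 && mo == 1 && fa == 0) return("x_linked_recessive")
  if (pro == 1 && mo == 0) return("x_de_novo_flagged")
  "none"
}

# Brute-force evaluator of the 2015 ACMG/AMP combining rules, driven by an
# explicit rule table of minimum counts per strength category.
oracle_combine_acmg <- function(codes) {
  prefix <- sub("[0-9]+$", "", codes)
  cnt <- function(p) sum(prefix == p)
  pvs <- cnt("PVS"); ps <- cnt("PS"); pm <- cnt("PM"); pp <- cnt("PP")
  ba <- cnt("BA"); bs <- cnt("BS"); bp <- cnt("BP")
  meets <- function(rules) {
    any(vapply(rules, function(r) {
      pvs >= r[1] && ps >= r[2] && pm >= r[3] && pp >= r[4]
    }, logical(1)))
  }
  p_rules <- list(c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1), c(1, 0, 0, 2),
                  c(0, 2, 0, 0), c(0, 1, 3, 0), c(0, 1, 2, 2), c(0, 1, 1, 4))
  lp_rules <- list(c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
                   c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4))
  is_p <- meets(p_rules)
  is_lp <- !is_p && meets(lp_rules)
  is_b <- ba >= 1 || bs >= 2
  is_lb <- !is_b && ((bs >= 1 && bp >= 1) || bp >= 2)
  if ((is_p || is_lp) && (is_b || is_lb)) return("vus")
  if (is_p) return("pathogenic")
  if (is_lp) return("likely_pathogenic")
  if (is_b) return("benign")
  if (is_lb) return("likely_benign")
  "vus"
}

# Naive double-loop set intersection size.
oracle_overlap_count <- function(a, b) {
  hits <- character(0)
  for (x in unique(a)) {
    for (y in unique(b)) if (x == y) hits <- c(hits, x)
  }
  length(unique(hits))
}

# Build a one-row trio record for classifier tests.
trio_record <- function(chrom, pro, fa, mo, pro_ploidy = 2L, fa_ploidy = 2L,
                        mo_ploidy = 2L, sex = "male") {
  tibble::tibble(
    chrom = chrom, proband_sex = sex,
    pro_alt = as.integer(pro), pro_ploidy = as.integer(pro_ploidy),
    pro_missing = is.na(pro),
    fa_alt = as.integer(fa), fa_ploidy = as.integer(fa_ploidy),
    fa_missing = is.na(fa),
    mo_alt = as.integer(mo), mo_ploidy = as.integer(mo_ploidy),
    mo_missing = is.na(mo))
}

# Minimal annotation tibble for gate tests.
make_annotation <- function(n = 1, gene = paste0("G", seq_len(n)),
                            effect = "nonsynonymous", af_gnomad = NA_real_,
                            af_exac = NA_real_, af_1000g = NA_real_,
                            cadd = 25, clinvar = NA_character_,
                            verdict = NA_character_,
                            codes = NA_character_, chrom = "1",
                            pos = seq_len(n) * 100L) {
  ann <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
    gene = gene, transcript = "NM_1", hgvs_c = NA_character_,
    hgvs_p = NA_character_, effect = effect,
    af_exac = af_exac, af_1000g = af_1000g, af_gnomad = af_gnomad,
    cadd_phred = cadd, clinvar = clinvar, acmg_verdict = verdict,
    acmg_codes = codes)
  ann$key <- misctrio::variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  ann
}

# Write a small VCF from raw lines (header built here).
write_test_vcf <- function(body_lines, samples, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="QD">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

toy_pedigree <- function(n = 1, sex = "male") {
  sex <- rep_len(sex, n)
  tibble::tibble(
    family_id = sprintf("F%d", seq_len(n)),
    proband_id = sprintf("P%d", seq_len(n)),
    father_id = sprintf("P%dF", seq_len(n)),
    mother_id = sprintf("P%dM", seq_len(n)),
    proband_sex = sex, affected = TRUE)
}
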
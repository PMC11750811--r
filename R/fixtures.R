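FIXTURE_MD5 <- c(
  table1_candidates.tsv = "f628a37be1315521278dde108457282c",
  table2_candidates.tsv = "826e78f4aa0799287d5ab07731b58c10",
  table3_deg.csv = "c80e68131b3c01e24c3b25f261e6caeb",
  misc_gene_panel_synthetic.txt = "8c11252810ee29bb85864bc56a05fa97",
  clinical_synthetic.csv = "04f898daf10dc5b6145c3680a186e256")

fixture_file <- function(name, verify = TRUE) {
  path <- system.file("extdata", name, package = "misctrio", mustWork = TRUE)
  if (verify && name %in% names(FIXTURE_MD5)) {
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(FIXTURE_MD5[[name]]))) {
      abort(sprintf("packaged transcription %s fails its checksum (%s != %s)",
                    name, got, FIXTURE_MD5[[name]]),
            class = "misctrio_integrity_error")
    }
  }
  path
}

# ref/alt alleles implied by an HGVS cDNA string; substitutions keep their
# printed bases, deletions get a synthetic anchored allele pair of the right
# length, anything else falls back to A>G. Positions are synthetic
# throughout — only key consistency between VCF and annotation matters.
parse_hgvs_alleles <- function(hgvs_c) {
  if (is.na(hgvs_c)) return(c("A", "G"))
  m <- regmatches(hgvs_c, regexec("^c\\.([ACGT])[0-9]+([ACGT])$", hgvs_c))[[1]]
  if (length(m) == 3L) return(c(m[2], m[3]))
  m <- regmatches(hgvs_c, regexec("([ACGT])>([ACGT])", hgvs_c))[[1]]
  if (length(m) == 3L) return(c(m[2], m[3]))
  if (grepl("del", hgvs_c)) {
    m <- regmatches(hgvs_c, regexec("c\\.([0-9]+)_([0-9]+)del", hgvs_c))[[1]]
    ndel <- if (length(m) == 3L) as.integer(m[3]) - as.integer(m[2]) + 1L else 1L
    return(c(paste0("A", strrep("C", ndel)), "A"))
  }
  c("A", "G")
}

table1_pedigree <- function() {
  clin <- readr::read_csv(fixture_file("clinical_synthetic.csv"),
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  tibble(family_id = sprintf("FAM%02d", seq_len(nrow(clin))),
         proband_id = clin$proband,
         father_id = paste0(clin$proband, "F"),
         mother_id = paste0(clin$proband, "M"),
         proband_sex = clin$sex,
         affected = TRUE)
}

write_ped_file <- function(ped, path) {
  writeLines(paste(
    rep(ped$family_id, each = 3L),
    as.vector(rbind(ped$proband_id, ped$father_id, ped$mother_id)),
    as.vector(rbind(ped$father_id, "0", "0")),
    as.vector(rbind(ped$mother_id, "0", "0")),
    as.vector(rbind(ifelse(ped$proband_sex == "male", "1", "2"), "1", "2")),
    as.vector(rbind("2", "1", "1")), sep = "\t"), path)
  invisible(path)
}

#' Build the packaged reference fixtures
#'
#' Reconstructs cohort-scale inputs from the plain-text transcriptions of
#' the published candidate tables shipped with the package:
#' \describe{
#'   \item{`"1"`}{a 24-trio cohort (per-trio VCFs + PED + annotation
#'     table) whose genotypes realize each candidate-gene row's printed
#'     inheritance label, plus 200 decoys — 50 failing each of the class,
#'     frequency, CADD and segregation gates;}
#'   \item{`"2"`}{proband-level heterozygous records for every panel
#'     candidate variant with printed AF/CADD/ClinVar/ACMG values, plus
#'     200 decoys failing panel membership, the 1\% frequency gate, the
#'     damaging gate, or heterozygosity (50 each);}
#'   \item{`"3"`}{the differential-expression table;}
#'   \item{`"panel"`}{the packaged synthetic stand-in gene panel;}
#'   \item{`"clinical"`}{the synthetic per-proband clinical summary table.}
#' }
#' Transcription files are verified against stored checksums before use.
#' Candidate-gene rows whose printed gnomAD frequency exceeds the
#' ultra-rare cutoff carry `min(printed, 1e-4)` in the filter column and
#' the printed value in `af_gnomad_printed`.
#'
#' @param table One of `"1"`, `"2"`, `"3"`, `"panel"`, `"clinical"`.
#' @param dir Output directory for generated cohort files (tables 1–2).
#' @param seed Integer seed controlling only decoy placement jitter; all
#'   headline counts are seed-invariant by construction.
#' @return A list (tables 1–2: paths plus in-memory tibbles; otherwise the
#'   parsed object).
#' @export
build_reference_fixture <- function(table = c("1", "2", "3", "panel", "clinical"),
                                dir = tempfile("fixture"), seed = 20260L) {
  table <- match.arg(as.character(table[1L]),
                     c("1", "2", "3", "panel", "clinical"))
  switch(table,
         "1" = build_table1_fixture(dir, seed),
         "2" = build_table2_fixture(seed),
         "3" = read_deg_table(fixture_file("table3_deg.csv")),
         "panel" = read_gene_panel(fixture_file("misc_gene_panel_synthetic.txt"),
                                   name = "misc_panel_synthetic"),
         "clinical" = readr::read_csv(
           fixture_file("clinical_synthetic.csv"),
           col_types = readr::cols(proband = "c", sex = "c", age_years = "d",
                                   ethnicity = "c", .default = "i"),
           progress = FALSE))
}

build_table1_fixture <- function(dir, seed) {
  tab <- readr::read_tsv(fixture_file("table1_candidates.tsv"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ped <- table1_pedigree()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  withr::with_seed(as.integer(seed), {
    # one synthetic locus per distinct printed variant, X for X-linked rows
    uniq <- tab[!duplicated(paste(tab$gene, tab$hgvs_c)), , drop = FALSE]
    uniq$uidx <- seq_len(nrow(uniq))
    uniq$chrom <- ifelse(uniq$inheritance == "x_linked_recessive", "X",
                         as.character((uniq$uidx - 1L) %% 22L + 1L))
    uniq$pos <- 2000000L + uniq$uidx * 10000L +
      sample.int(999L, nrow(uniq), replace = TRUE)
    alleles <- t(vapply(uniq$hgvs_c, parse_hgvs_alleles, character(2)))
    uniq$ref <- alleles[, 1L]
    uniq$alt <- alleles[, 2L]
    loc <- uniq[, c("gene", "hgvs_c", "chrom", "pos", "ref", "alt")]

    rows <- left_join(tab, loc, by = c("gene", "hgvs_c"))
    gts <- t(vapply(rows$inheritance, mode_genotypes, character(3)))
    planted <- tibble(
      proband = rows$proband, gene = rows$gene, chrom = rows$chrom,
      pos = as.integer(rows$pos), ref = rows$ref, alt = rows$alt,
      gt_pro = gts[, 1L], gt_fa = gts[, 2L], gt_mo = gts[, 3L],
      role = "planted", label = rows$inheritance)

    # decoys: 50 per gate, round-robin across the 24 trios
    gates <- c("class", "maf", "cadd", "segregation")
    n_per_gate <- 50L
    d_idx <- seq_len(length(gates) * n_per_gate)
    d_gate <- rep(gates, each = n_per_gate)
    d_pattern <- ifelse(d_gate == "segregation", "inherited_het", "de_novo")
    d_gts <- t(vapply(d_pattern, mode_genotypes, character(3)))
    decoys <- tibble(
      proband = ped$proband_id[(d_idx - 1L) %% nrow(ped) + 1L],
      gene = sprintf("DECOY%s%03d", toupper(substr(d_gate, 1, 3)), d_idx),
      chrom = as.character((d_idx - 1L) %% 22L + 1L),
      pos = 8000000L + d_idx * 10000L +
        sample.int(999L, length(d_idx), replace = TRUE),
      ref = "A", alt = "G",
      gt_pro = d_gts[, 1L], gt_fa = d_gts[, 2L], gt_mo = d_gts[, 3L],
      role = "decoy", label = d_gate)

    sites <- bind_rows(planted, decoys)
    sites$key <- variant_key(sites$chrom, sites$pos, sites$ref, sites$alt)
    sites$info <- PASSING_INFO

    vcf_paths <- character(nrow(ped))
    for (t in seq_len(nrow(ped))) {
      tr <- ped[t, ]
      mine <- sites[sites$proband == tr$proband_id, , drop = FALSE]
      path <- file.path(dir, sprintf("trio_%s.vcf", tr$proband_id))
      write_trio_vcf(mine, tr$proband_id, tr$father_id, tr$mother_id, path)
      vcf_paths[t] <- path
    }
    names(vcf_paths) <- ped$family_id
    ped_path <- write_ped_file(ped, file.path(dir, "cohort.ped"))

    # annotations: printed gnomAD frequencies above the ultra-rare cutoff
    # are preserved as display metadata; the filter column is capped
    printed_af <- numeric_or_na(rows$af_gnomad)
    acmg <- lapply(rows$acmg, parse_acmg_field, lenient = TRUE)
    ann_rows <- tibble(
      chrom = rows$chrom, pos = as.integer(rows$pos), ref = rows$ref,
      alt = rows$alt, gene = rows$gene, transcript = rows$transcript,
      hgvs_c = rows$hgvs_c, hgvs_p = absent_to_na(rows$hgvs_p),
      effect = rows$effect,
      af_exac = NA_real_, af_1000g = NA_real_,
      af_gnomad = pmin(printed_af, 1e-4),
      cadd_phred = numeric_or_na(rows$cadd_phred),
      clinvar = normalize_clinvar(rows$clinvar),
      acmg_verdict = vapply(acmg, `[[`, character(1), "verdict"),
      acmg_codes = vapply(acmg, function(a) {
        if (length(a$codes)) paste(a$codes, collapse = ",") else NA_character_
      }, character(1)),
      af_gnomad_printed = printed_af)
    ann_rows <- ann_rows[!duplicated(variant_key(ann_rows$chrom, ann_rows$pos,
                                                 ann_rows$ref, ann_rows$alt)), ]
    d_ann <- tibble(
      chrom = decoys$chrom, pos = as.integer(decoys$pos), ref = decoys$ref,
      alt = decoys$alt, gene = decoys$gene, transcript = "NM_000000",
      hgvs_c = NA_character_, hgvs_p = NA_character_,
      effect = ifelse(d_gate == "class", "synonymous", "nonsynonymous"),
      af_exac = NA_real_, af_1000g = NA_real_,
      af_gnomad = ifelse(d_gate == "maf", 0.05, 0),
      cadd_phred = ifelse(d_gate == "cadd", 5, 30),
      clinvar = NA_character_, acmg_verdict = NA_character_,
      acmg_codes = NA_character_, af_gnomad_printed = NA_real_)
    ann <- bind_rows(ann_rows, d_ann)
    annotation_path <- file.path(dir, "annotations.tsv")
    write_annotation_table(ann, annotation_path)

    truth <- tibble(key = sites$key, gene = sites$gene,
                    proband_id = sites$proband, role = sites$role,
                    label = sites$label,
                    expect_approach1 = sites$role == "planted")
    truth_path <- file.path(dir, "truth.csv")
    readr::write_csv(truth, truth_path, progress = FALSE)

    list(dir = dir, vcf_paths = vcf_paths, ped_path = ped_path,
         annotation_path = annotation_path, truth_path = truth_path,
         pedigree = ped, annotations = read_annotation_table(annotation_path),
         truth = truth)
  })
}

build_table2_fixture <- function(seed) {
  tab <- readr::read_tsv(fixture_file("table2_candidates.tsv"),
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  panel <- build_reference_fixture("panel")

  withr::with_seed(as.integer(seed), {
    tab$uidx <- seq_len(nrow(tab))
    tab$chrom <- as.character((tab$uidx - 1L) %% 22L + 1L)
    tab$pos <- 3000000L + tab$uidx * 10000L +
      sample.int(999L, nrow(tab), replace = TRUE)
    alleles <- t(vapply(tab$hgvs_c, parse_hgvs_alleles, character(2)))
    tab$ref <- alleles[, 1L]
    tab$alt <- alleles[, 2L]
    tab$key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)

    expanded <- tidyr::separate_rows(tab, "patients", sep = ",")
    expanded$patients <- trimws(expanded$patients)
    planted_rec <- tibble(
      family_id = NA_character_, proband_id = expanded$patients,
      proband_sex = NA_character_,
      chrom = expanded$chrom, pos = as.integer(expanded$pos),
      ref = expanded$ref, alt = expanded$alt, key = expanded$key,
      pro_alt = 1L, pro_ploidy = 2L, pro_missing = FALSE,
      role = "planted", label = "panel_het")

    # decoys: 50 per gate; panel decoys use off-panel genes, the rest use
    # panel genes that carry no printed candidate variant
    gates <- c("panel", "maf", "damaging", "zygosity")
    n_per_gate <- 50L
    spare_panel_genes <- c("TLR3", "TLR6", "IL22RA2", "IFNB1", "IFNA6")
    d_idx <- seq_len(length(gates) * n_per_gate)
    d_gate <- rep(gates, each = n_per_gate)
    probands <- sort(unique(planted_rec$proband_id))
    d_gene <- ifelse(d_gate == "panel",
                     sprintf("OFFPANEL%03d", d_idx),
                     spare_panel_genes[(d_idx - 1L) %% length(spare_panel_genes) + 1L])
    d <- tibble(
      proband_id = probands[(d_idx - 1L) %% length(probands) + 1L],
      gene = d_gene,
      chrom = as.character((d_idx - 1L) %% 22L + 1L),
      pos = 9000000L + d_idx * 10000L +
        sample.int(999L, length(d_idx), replace = TRUE),
      ref = "A", alt = "G",
      pro_alt = ifelse(d_gate == "zygosity", 2L, 1L),
      pro_ploidy = 2L, pro_missing = FALSE,
      af_gnomad = ifelse(d_gate == "maf", 0.05, 0),
      cadd_phred = ifelse(d_gate == "damaging", 10, 30),
      role = "decoy", label = d_gate)
    d$key <- variant_key(d$chrom, d$pos, d$ref, d$alt)
    decoy_rec <- tibble(
      family_id = NA_character_, proband_id = d$proband_id,
      proband_sex = NA_character_, chrom = d$chrom, pos = as.integer(d$pos),
      ref = d$ref, alt = d$alt, key = d$key, pro_alt = d$pro_alt,
      pro_ploidy = d$pro_ploidy, pro_missing = d$pro_missing,
      role = d$role, label = d$label)

    acmg <- lapply(tab$acmg, parse_acmg_field, lenient = TRUE)
    ann <- bind_rows(
      tibble(
        chrom = tab$chrom, pos = as.integer(tab$pos), ref = tab$ref,
        alt = tab$alt, gene = tab$gene, transcript = tab$transcript,
        hgvs_c = tab$hgvs_c, hgvs_p = absent_to_na(tab$hgvs_p),
        effect = tab$effect,
        af_exac = NA_real_, af_1000g = NA_real_,
        af_gnomad = numeric_or_na(tab$af_gnomad),
        cadd_phred = numeric_or_na(tab$cadd_phred),
        clinvar = normalize_clinvar(tab$clinvar),
        acmg_verdict = vapply(acmg, `[[`, character(1), "verdict"),
        acmg_codes = vapply(acmg, function(a) {
          if (length(a$codes)) paste(a$codes, collapse = ",") else NA_character_
        }, character(1)),
        omim_inheritance = tab$omim_inheritance),
      tibble(
        chrom = d$chrom, pos = as.integer(d$pos), ref = d$ref, alt = d$alt,
        gene = d$gene, transcript = "NM_000000", hgvs_c = NA_character_,
        hgvs_p = NA_character_, effect = "nonsynonymous",
        af_exac = NA_real_, af_1000g = NA_real_, af_gnomad = d$af_gnomad,
        cadd_phred = d$cadd_phred, clinvar = NA_character_,
        acmg_verdict = NA_character_, acmg_codes = NA_character_,
        omim_inheritance = NA_character_))
    ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)

    records <- bind_rows(planted_rec, decoy_rec)
    truth <- tibble(key = records$key,
                    proband_id = records$proband_id, role = records$role,
                    label = records$label,
                    expect_approach2 = records$role == "planted")
    list(records = records[, setdiff(names(records), c("role", "label"))],
         annotations = as_tibble(ann), truth = truth, panel = panel)
  })
}
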
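test_that("gate predicates honour inclusive thresholds and missing values", {
  cfg <- approach1_config()
  expect_true(is_functional_class("nonsynonymous", cfg))
  expect_true(is_functional_class("splicing", cfg))
  expect_false(is_functional_class("synonymous", cfg))
  expect_false(is_functional_class("unknown", cfg))
  expect_error(is_functional_class("nonsense"), "invalid effect")

  expect_true(passes_ultra_rare(make_annotation(1, af_gnomad = 3e-5), cfg))
  expect_true(passes_ultra_rare(make_annotation(1, af_gnomad = 1e-4), cfg))
  expect_false(passes_ultra_rare(make_annotation(1, af_gnomad = 2e-3), cfg))
  # absent from every source: unobserved alleles pass by default
  expect_true(passes_ultra_rare(make_annotation(1), cfg))
  strict <- approach1_config(treat_missing_af_as_pass = FALSE)
  expect_false(passes_ultra_rare(make_annotation(1), strict))
  # the maximum over configured sources gates the variant
  both <- make_annotation(1, af_gnomad = 1e-5, af_exac = 0.5)
  expect_false(passes_ultra_rare(both, cfg))
  gnomad_only <- approach1_config(maf_sources = "gnomad")
  expect_true(passes_ultra_rare(both, gnomad_only))

  expect_true(passes_cadd(make_annotation(1, cadd = 20.1), cfg))
  expect_true(passes_cadd(make_annotation(1, cadd = 20), cfg))
  expect_false(passes_cadd(make_annotation(1, cadd = 19.9), cfg))
  expect_false(passes_cadd(make_annotation(1, cadd = NA_real_), cfg))
})

make_cohort_records <- function(n, seed) {
  # random trio records over autosomes and chrX with random genotypes
  set.seed(seed)
  chrom <- sample(c(as.character(1:5), "X"), n, replace = TRUE)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  hemi <- chrom == "X" & sex == "male"
  pro_ploidy <- ifelse(hemi, 1L, 2L)
  fa_ploidy <- ifelse(chrom == "X", 1L, 2L)
  tibble::tibble(
    family_id = sprintf("F%03d", seq_len(n)),
    proband_id = sprintf("P%03d", seq_len(n)),
    proband_sex = sex,
    chrom = chrom, pos = seq_len(n) * 10L,
    ref = "A", alt = "G",
    pro_alt = vapply(pro_ploidy, function(p) sample(0:p, 1), integer(1)),
    pro_ploidy = pro_ploidy, pro_missing = FALSE,
    fa_alt = vapply(fa_ploidy, function(p) sample(0:p, 1), integer(1)),
    fa_ploidy = fa_ploidy, fa_missing = FALSE,
    mo_alt = sample(0:2, n, replace = TRUE),
    mo_ploidy = 2L, mo_missing = FALSE,
    key = misctrio::variant_key(chrom, seq_len(n) * 10L, "A", "G"))
}

test_that("prioritization equals the brute-force per-record filter composition", {
  cfg <- approach1_config()
  for (seed in c(101, 202, 303)) {
    rec <- make_cohort_records(300, seed)
    set.seed(seed + 1)
    ann <- make_annotation(
      300, gene = sprintf("G%03d", 1:300),
      effect = sample(c("nonsynonymous", "synonymous", "stopgain", "unknown"),
                      300, replace = TRUE),
      af_gnomad = sample(c(NA, 0, 5e-5, 1e-4, 0.002), 300, replace = TRUE),
      cadd = sample(c(NA, 5, 19.9, 20, 35), 300, replace = TRUE),
      chrom = rec$chrom, pos = rec$pos)
    got <- prioritize_approach1(rec, ann, cfg)

    expected_keys <- character(0)
    for (i in seq_len(nrow(rec))) {
      a <- ann[ann$key == rec$key[i], ]
      keep <- is_functional_class(a$effect, cfg) &&
        passes_ultra_rare(a, cfg) && passes_cadd(a, cfg) &&
        classify_segregation(rec[i, ], config = cfg) != "none"
      if (keep) expected_keys <- c(expected_keys, rec$key[i])
    }
    expect_setequal(got$key, expected_keys)
    # partition: every retained variant has exactly one inheritance mode
    expect_true(all(got$inheritance_mode %in%
                      c("de_novo", "autosomal_recessive",
                        "x_linked_recessive", "x_de_novo_flagged")))
    s <- summarise_prioritized(got)
    expect_equal(sum(s$modes), s$n_variants)
  }
})

test_that("tightening thresholds never adds retained variants", {
  rec <- make_cohort_records(300, 77)
  set.seed(78)
  ann <- make_annotation(
    300, gene = sprintf("G%03d", 1:300),
    af_gnomad = runif(300, 0, 2e-4),
    cadd = runif(300, 10, 40),
    chrom = rec$chrom, pos = rec$pos)
  base <- prioritize_approach1(rec, ann, approach1_config())
  tighter_maf <- prioritize_approach1(
    rec, ann, approach1_config(maf_threshold = 5e-5))
  higher_cadd <- prioritize_approach1(
    rec, ann, approach1_config(cadd_threshold = 30))
  expect_true(all(tighter_maf$key %in% base$key))
  expect_true(all(higher_cadd$key %in% base$key))
})

test_that("unannotated records are dropped and counted; empty cohorts are not errors", {
  rec <- make_cohort_records(10, 5)
  ann <- make_annotation(1, chrom = "9", pos = 99999L)  # matches nothing
  out <- prioritize_approach1(rec, ann)
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "counters")[["n_unannotated"]], 10L)
  empty <- prioritize_approach1(rec[0, ], ann)
  expect_equal(nrow(empty), 0L)
})

test_that("x_de_novo_flagged variants are reported but excluded from headline totals", {
  rec <- make_cohort_records(2, 9)
  rec$chrom <- "X"; rec$proband_sex <- "male"
  rec$pro_ploidy <- 1L; rec$pro_alt <- 1L
  rec$fa_ploidy <- 1L; rec$fa_alt <- 0L
  rec$mo_ploidy <- 2L; rec$mo_alt <- c(0L, 1L)
  rec$key <- misctrio::variant_key(rec$chrom, rec$pos, rec$ref, rec$alt)
  ann <- make_annotation(2, chrom = "X", pos = rec$pos, cadd = 30)
  out <- prioritize_approach1(rec, ann)
  expect_setequal(out$inheritance_mode,
                  c("x_de_novo_flagged", "x_linked_recessive"))
  s <- summarise_prioritized(out)
  expect_equal(s$n_variants, 1L)
  expect_equal(unname(s$modes["x_linked_recessive"]), 1L)
})
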
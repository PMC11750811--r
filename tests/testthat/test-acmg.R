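test_that("evidence-code parsing canonicalizes, deduplicates, and validates", {
  expect_setequal(parse_evidence_codes("PVS1,PM2"), c("PVS1", "PM2"))
  expect_setequal(parse_evidence_codes(" bs1 , BS2 ,BP4, BP1 "),
                  c("BS1", "BS2", "BP4", "BP1"))
  expect_equal(parse_evidence_codes(""), character(0))
  expect_equal(parse_evidence_codes(NA_character_), character(0))
  expect_setequal(parse_evidence_codes("PM2,PM2,PP3"), c("PM2", "PP3"))
  expect_error(parse_evidence_codes("PB4"), "invalid ACMG")
  expect_error(parse_evidence_codes("PM"), "invalid ACMG")
  # lenient mode repairs transposed prefixes, reporting each correction
  expect_message(codes <- parse_evidence_codes("PB4,PM2", lenient = TRUE),
                 "auto-corrected")
  expect_setequal(codes, c("BP4", "PM2"))
  counts <- acmg_strength_counts(c("BS1", "BS2", "BP4", "BP1"))
  expect_equal(counts[["BS"]], 2L)
  expect_equal(counts[["BP"]], 2L)
})

test_that("combining rules reproduce published verdict examples", {
  expect_equal(combine_acmg(c("PVS1", "PM2")), "likely_pathogenic")
  expect_equal(combine_acmg(c("PVS1", "PP5", "PM2")), "pathogenic")
  expect_equal(combine_acmg("PM2"), "vus")
  expect_equal(combine_acmg("BA1"), "benign")
  expect_equal(combine_acmg(c("BS1", "BS2")), "benign")
  expect_equal(combine_acmg(c("BS2", "BP4")), "likely_benign")
  expect_equal(combine_acmg(character(0)), "vus")
  # contradictory pathogenic + benign evidence collapses to VUS
  expect_equal(combine_acmg(c("PVS1", "PS1", "BA1")), "vus")
})

test_that("combine_acmg matches the brute-force rule evaluator on all code sets of size <= 3", {
  universe <- c("PVS1", "PS1", "PM1", "PP1", "BA1", "BS1", "BP1")
  sets <- list(character(0))
  for (k in 1:3) {
    sets <- c(sets, combn(universe, k, simplify = FALSE))
  }
  for (s in sets) {
    expect_identical(combine_acmg(s), oracle_combine_acmg(s),
                     info = paste(s, collapse = ","))
  }
})

test_that("verdict depends only on the code multiset, and benign evidence never pushes toward pathogenic", {
  set.seed(11)
  pool <- c("PVS1", "PS1", "PS2", "PM1", "PM2", "PP1", "PP3", "BA1", "BS1",
            "BS2", "BP1", "BP4")
  rank <- c(benign = 1, likely_benign = 2, vus = 3, likely_pathogenic = 4,
            pathogenic = 5)
  for (i in 1:100) {
    s <- sample(pool, sample(0:5, 1))
    expect_identical(combine_acmg(s), combine_acmg(rev(s)))
    v0 <- combine_acmg(s)
    extra <- sample(c("BS1", "BS2", "BP1", "BP4", "BA1"), 1)
    v1 <- combine_acmg(unique(c(s, extra)))
    expect_lte(rank[[v1]], rank[[v0]])
  }
})

test_that("verdict audit recomputes from codes and flags divergences", {
  ann <- make_annotation(
    3, gene = c("G1", "G2", "G3"),
    verdict = c("vus", "benign", NA),
    codes = c("PM2,BP4", "BS2,BP6,BP1", NA))
  aud <- audit_verdicts(ann)
  expect_equal(nrow(aud), 2L)
  expect_equal(attr(aud, "n_skipped"), 1L)
  # PM2 + BP4 recomputes to VUS and agrees
  expect_true(aud$agree[aud$gene == "G1"])
  # one strong-benign + one supporting-benign is likely benign, not benign
  expect_equal(aud$recomputed[aud$gene == "G2"], "likely_benign")
  expect_false(aud$agree[aud$gene == "G2"])
  expect_equal(attr(aud, "agreement"), 0.5)
  empty <- audit_verdicts(make_annotation(0))
  expect_equal(nrow(empty), 0L)
})
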
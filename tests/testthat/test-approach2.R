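panel_records <- function(ann, proband = "P1", gt_alt = 1L, ploidy = 2L) {
  gt_alt <- rep_len(as.integer(gt_alt), nrow(ann))
  ploidy <- rep_len(as.integer(ploidy), nrow(ann))
  tibble::tibble(
    family_id = "F1", proband_id = rep_len(proband, nrow(ann)),
    proband_sex = NA_character_,
    chrom = ann$chrom, pos = ann$pos, ref = ann$ref, alt = ann$alt,
    key = ann$key, pro_alt = gt_alt, pro_ploidy = ploidy,
    pro_missing = FALSE)
}

test_that("panel workflow keeps rare damaging heterozygous panel variants (boundaries inclusive)", {
  panel <- gene_panel(c("NOD2", "LY9", "ATM"))
  cfg <- approach2_config()
  ann <- make_annotation(
    6, gene = c("NOD2", "LY9", "ATM", "OFFPANEL", "ATM", "ATM"),
    effect = c("nonsynonymous", "frameshift", "nonsynonymous",
               "nonsynonymous", "synonymous", "nonsynonymous"),
    af_gnomad = c(0.01, 0, 0.02, 0, 0, 0),
    cadd = c(29.9, NA, 30, 30, 30, 10))
  rec <- panel_records(ann)
  out <- prioritize_approach2(rec, ann, panel, cfg)
  # NOD2 at AF exactly 1% is retained; LY9 frameshift without a CADD score
  # is retained through the loss-of-function exemption
  expect_setequal(out$gene, c("NOD2", "LY9"))
  ctr <- attr(out, "counters")
  expect_equal(ctr[["n_panel"]], 1L)
  expect_equal(ctr[["n_maf"]], 1L)
  expect_equal(ctr[["n_class"]], 1L)
  expect_equal(ctr[["n_damaging"]], 1L)
})

test_that("homozygous panel hits are excluded from the retained set but reported separately", {
  panel <- gene_panel("ATM")
  ann <- make_annotation(2, gene = "ATM", cadd = 30, af_gnomad = 0)
  rec <- panel_records(ann, gt_alt = c(1L, 2L))
  out <- prioritize_approach2(rec, ann, panel)
  expect_equal(nrow(out), 1L)
  expect_equal(out$pro_alt, 1L)
  hom <- attr(out, "homozygous_hits")
  expect_equal(nrow(hom), 1L)
  expect_equal(hom$pro_alt, 2L)
  expect_equal(attr(out, "counters")[["n_zygosity"]], 1L)
})

test_that("shrinking the panel never adds outputs, and outputs stay within the panel", {
  set.seed(31)
  genes <- sprintf("PG%02d", 1:20)
  ann <- make_annotation(40, gene = sample(genes, 40, replace = TRUE),
                         af_gnomad = runif(40, 0, 0.02),
                         cadd = runif(40, 10, 40))
  rec <- panel_records(ann, proband = sprintf("P%d", rep(1:4, 10)))
  big <- prioritize_approach2(rec, ann, gene_panel(genes))
  small <- prioritize_approach2(rec, ann, gene_panel(genes[1:5]))
  expect_true(all(small$key %in% big$key))
  expect_true(all(big$gene %in% genes))
  expect_true(all(small$gene %in% genes[1:5]))
  expect_true(all(big$pro_alt == 1L))
})

test_that("ClinVar and ACMG tallies conserve the distinct-variant count", {
  ann <- make_annotation(
    5, gene = sprintf("G%d", 1:5),
    af_gnomad = 0, cadd = 30,
    clinvar = c("pathogenic", "risk_factor", NA, "vus", NA),
    verdict = c("vus", "vus", NA, "benign", "likely_benign"))
  rec <- panel_records(ann, proband = c("P1", "P2", "P3", "P4", "P5"))
  out <- prioritize_approach2(rec, ann, gene_panel(ann$gene))
  tc <- tally_clinvar(out)
  ta <- tally_acmg(out)
  expect_equal(sum(tc$count), 5L)
  expect_equal(sum(ta$count), 5L)
  expect_equal(tc$count[tc$category == "not_reported"], 2L)
  expect_equal(ta$count[ta$category == "unassigned"], 1L)
  expect_equal(ta$count[ta$category == "vus"], 2L)
  empty <- tally_clinvar(out[0, ])
  expect_true(all(empty$count == 0L))
})
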
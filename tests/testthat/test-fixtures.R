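# Build the packaged fixtures once per test run; several blocks share them.
fx1 <- suppressMessages(build_reference_fixture("1", dir = tempfile()))
fx1_ped <- read_pedigree(fx1$ped_path)
fx1_rec <- hard_filter_records(read_trio_cohort(fx1$vcf_paths, fx1_ped))
fx1_a1 <- prioritize_approach1(fx1_rec, fx1$annotations)

fx2 <- suppressMessages(build_reference_fixture("2"))
fx2_a2 <- prioritize_approach2(fx2$records, fx2$annotations, fx2$panel)

test_that("the candidate-gene fixture reproduces the published cohort-level counts", {
  expect_equal(nrow(fx1_ped), 24L)
  s <- summarise_prioritized(fx1_a1)
  expect_equal(s$n_variants, 55L)
  expect_equal(s$n_genes, 53L)
  expect_equal(s$n_probands, 20L)
  expect_equal(unname(s$modes["de_novo"]), 7L)
  expect_equal(unname(s$modes["x_linked_recessive"]), 27L)
  expect_equal(unname(s$modes["autosomal_recessive"]), 21L)
})

test_that("fixture decoys are rejected 50 per gate and recovery is exact", {
  ctr <- attr(fx1_a1, "counters")
  expect_equal(ctr[["n_class"]], 50L)
  expect_equal(ctr[["n_maf"]], 50L)
  expect_equal(ctr[["n_cadd"]], 50L)
  expect_equal(ctr[["n_segregation"]], 50L)
  # precision = recall = 1 against the truth table
  expect_setequal(fx1_a1$key, fx1$truth$key[fx1$truth$expect_approach1])
  # headline counts do not depend on the placement seed
  alt <- suppressMessages(build_reference_fixture("1", dir = tempfile(),
                                              seed = 4242))
  alt_rec <- hard_filter_records(
    read_trio_cohort(alt$vcf_paths, read_pedigree(alt$ped_path)))
  s <- summarise_prioritized(prioritize_approach1(alt_rec, alt$annotations))
  expect_equal(s$n_variants, 55L)
})

test_that("capped fixture frequencies keep the printed gnomAD value as display metadata", {
  ann <- fx1$annotations
  planted <- ann[!startsWith(ann$gene, "DECOY"), ]
  printed <- suppressWarnings(as.numeric(planted$af_gnomad_printed))
  expect_true(all(is.na(planted$af_gnomad) |
                    planted$af_gnomad <= 1e-4))
  over <- !is.na(printed) & printed > 1e-4
  expect_gt(sum(over), 0)  # several rows print AFs above the cutoff
  expect_true(all(planted$af_gnomad[over] == 1e-4))
})

test_that("the candidate-variant fixture reproduces the panel workflow counts and tallies", {
  s <- summarise_prioritized(fx2_a2)
  expect_equal(s$n_variants, 33L)
  expect_equal(s$n_genes, 19L)
  expect_equal(s$n_probands, 19L)
  expect_setequal(unique(fx2_a2$key),
                  fx2$truth$key[fx2$truth$expect_approach2])
  ctr <- attr(fx2_a2, "counters")
  expect_equal(ctr[["n_panel"]], 50L)
  expect_equal(ctr[["n_maf"]], 50L)
  expect_equal(ctr[["n_damaging"]], 50L)
  expect_equal(ctr[["n_zygosity"]], 50L)

  ta <- tally_acmg(fx2_a2)
  expect_equal(ta$count[ta$category == "vus"], 6L)
  expect_equal(ta$count[ta$category == "pathogenic"], 1L)
  expect_equal(ta$members[[which(ta$category == "pathogenic")]],
               "C6:c.2381+2T>C")
  expect_equal(sum(ta$count), 33L)

  tc <- tally_clinvar(fx2_a2)
  expect_equal(tc$members[[which(tc$category == "pathogenic")]],
               "NLRP12:p.R284X")
  expect_equal(tc$members[[which(tc$category == "risk_factor")]],
               "LY9:p.H351fs")
  expect_equal(sum(tc$count), 33L)
})

test_that("differential-expression overlap recovers the published gene sets", {
  deg <- build_reference_fixture("3")
  ov1 <- overlap_genes_with_deg(unique(fx1_a1$gene), deg)
  expect_equal(ov1$count, 3L)
  expect_setequal(ov1$genes, c("DDX60", "TMEM154", "RASSF3"))
  ov2 <- overlap_genes_with_deg(unique(fx2_a2$gene), deg)
  expect_equal(ov2$count, 5L)
  expect_setequal(ov2$genes, c("LY9", "IFIH1", "DOCK8", "DCLRE1C", "LYST"))
})

test_that("recurrent variants and genes are recovered from both fixtures", {
  rec1 <- find_recurrent(fx1_a1)
  expect_true("EGFL6:p.G477W" %in% rec1$recurrent_variants$variant)
  egfl6 <- rec1$recurrent_variants[
    rec1$recurrent_variants$variant == "EGFL6:p.G477W", ]
  expect_equal(egfl6$probands[[1]], c("P3", "P9"))
  # DMD recurs at gene level through two different variants
  expect_true("DMD" %in% rec1$recurrent_genes$gene)
  expect_false("DMD" %in% rec1$recurrent_variants$gene)

  rec2 <- find_recurrent(fx2_a2)
  atm <- rec2$recurrent_variants[
    rec2$recurrent_variants$variant == "ATM:p.P604S", ]
  expect_equal(atm$probands[[1]], c("P13", "P5"))
  ap3b1 <- rec2$recurrent_variants[
    rec2$recurrent_variants$gene == "AP3B1", ]
  expect_equal(ap3b1$probands[[1]], c("P18", "P4"))
})

test_that("the packaged panel and clinical fixtures parse into valid objects", {
  panel <- build_reference_fixture("panel")
  expect_s3_class(panel, "gene_panel")
  expect_true(all(c("NOD2", "TLR3", "IFNA6", "LY9") %in% panel$genes))
  clin <- build_reference_fixture("clinical")
  expect_equal(nrow(clin), 24L)
  expect_equal(sum(clin$sex == "male"), 18L)
})

test_that("ACMG audit over the fixture annotations flags platform divergences without errors", {
  ann <- fx2$annotations
  aud <- audit_verdicts(ann[!is.na(ann$acmg_codes), ])
  expect_equal(nrow(aud), 33L)
  expect_true(attr(aud, "agreement") > 0 && attr(aud, "agreement") <= 1)
  # the published splice-site pathogenic call is reproduced exactly
  c6 <- aud[aud$label == "C6:c.2381+2T>C", ]
  expect_equal(c6$recomputed, "pathogenic")
  expect_true(c6$agree)
})
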
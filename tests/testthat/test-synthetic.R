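read_plan_cohort <- function(gen) {
  ped <- read_pedigree(gen$ped_path)
  hard_filter_records(read_trio_cohort(gen$vcf_paths, ped))
}

test_that("identical plans generate byte-identical cohorts", {
  plan <- synthetic_plan(n_trios = 4, n_decoys_per_gate = 3, seed = 99)
  g1 <- generate_trio_cohort(plan, tempfile())
  g2 <- generate_trio_cohort(plan, tempfile())
  for (f in seq_along(g1$vcf_paths)) {
    expect_identical(readLines(g1$vcf_paths[f]), readLines(g2$vcf_paths[f]))
  }
  expect_identical(readLines(g1$annotation_path),
                   readLines(g2$annotation_path))
  expect_identical(readLines(g1$truth_path), readLines(g2$truth_path))
  # a different seed moves the decoy/plant coordinates
  g3 <- generate_trio_cohort(synthetic_plan(n_trios = 4,
                                            n_decoys_per_gate = 3,
                                            seed = 100), tempfile())
  expect_false(identical(readLines(g1$annotation_path),
                         readLines(g3$annotation_path)))
})

test_that("planted modes are realized exactly and the panel plant is invisible to the trio workflow", {
  plan <- synthetic_plan(n_trios = 4, n_decoys_per_gate = 0, seed = 7)
  gen <- generate_trio_cohort(plan, tempfile())
  rec <- read_plan_cohort(gen)
  a1 <- prioritize_approach1(rec, gen$annotations)
  expect_equal(nrow(a1), 3L)  # de novo + AR + XLR; panel_het inherited
  expect_setequal(a1$inheritance_mode,
                  c("de_novo", "autosomal_recessive", "x_linked_recessive"))
  truth_a1 <- gen$truth[gen$truth$expect_approach1, ]
  expect_setequal(a1$key, truth_a1$key)
  a2 <- prioritize_approach2(rec, gen$annotations,
                             gene_panel(plan$panel_genes))
  expect_setequal(a2$key, gen$truth$key[gen$truth$expect_approach2])
})

test_that("each decoy is rejected by exactly its designated gate", {
  plan <- synthetic_plan(n_trios = 6, n_decoys_per_gate = 5, seed = 3)
  gen <- generate_trio_cohort(plan, tempfile())
  rec <- read_plan_cohort(gen)
  a1 <- prioritize_approach1(rec, gen$annotations)
  ctr <- attr(a1, "counters")
  expect_equal(ctr[["n_class"]], 5L)
  expect_equal(ctr[["n_maf"]], 5L)
  expect_equal(ctr[["n_cadd"]], 5L)
  expect_equal(ctr[["n_segregation"]], 6L)  # 5 decoys + the inherited panel plant
  expect_setequal(a1$key, gen$truth$key[gen$truth$expect_approach1])
})

test_that("plans demanding X-linked plants without male probands are rejected", {
  expect_error(
    synthetic_plan(n_trios = 3, proband_sexes = "female",
                   planted = data.frame(mode = "x_linked_recessive",
                                        gene = "GX")),
    "male proband")
})

test_that("genotype-error injection is seed-reproducible and inert at rate zero", {
  plan <- synthetic_plan(n_trios = 4, n_background_sites = 10, seed = 5)
  gen <- generate_trio_cohort(plan, tempfile())
  rec <- read_plan_cohort(gen)
  expect_identical(inject_genotype_errors(rec, 0, seed = 1), rec)
  c1 <- inject_genotype_errors(rec, 0.05, seed = 42)
  c2 <- inject_genotype_errors(rec, 0.05, seed = 42)
  expect_identical(c1, c2)
  c3 <- inject_genotype_errors(rec, 0.05, seed = 43)
  expect_false(identical(c1, c3))
  # corrupted genotypes stay legal for their ploidy
  expect_true(all(c1$pro_alt <= c1$pro_ploidy, na.rm = TRUE))
  expect_true(all(c1$fa_alt <= c1$fa_ploidy, na.rm = TRUE))
})

test_that("expected spurious-candidate yield is non-decreasing in the corruption rate", {
  plan <- synthetic_plan(n_trios = 6, n_background_sites = 25,
                         planted = data.frame(mode = character(),
                                              gene = character()),
                         seed = 17)
  gen <- generate_trio_cohort(plan, tempfile())
  rec <- read_plan_cohort(gen)
  spurious_total <- function(rate, n_rep = 40) {
    sum(vapply(seq_len(n_rep), function(r) {
      corrupted <- inject_genotype_errors(rec, rate, seed = 1000 + r)
      nrow(prioritize_approach1(corrupted, gen$annotations))
    }, numeric(1)))
  }
  low <- spurious_total(0.005)
  high <- spurious_total(0.02)
  expect_gte(high, low)
  expect_gt(high, 0)
})
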
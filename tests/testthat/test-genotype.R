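test_that("GT tokens parse into normalized allele counts", {
  het <- parse_genotype("0/1", "chr4", "male")
  expect_equal(het[c("allele_count_ref", "allele_count_alt", "ploidy")],
               list(allele_count_ref = 1L, allele_count_alt = 1L, ploidy = 2L))
  expect_false(het$missing)

  hemi <- parse_genotype("1", "chrX", "male")
  expect_equal(hemi$allele_count_alt, 1L)
  expect_equal(hemi$ploidy, 1L)

  expect_true(parse_genotype("./.", "1", "female")$missing)
  expect_true(parse_genotype(".", "chrX", "male")$missing)
  # phased separators are equivalent
  expect_equal(parse_genotype("0|1", "2", "female")$allele_count_alt, 1L)
})

test_that("malformed and out-of-place GT tokens are rejected", {
  expect_error(parse_genotype("0/x", "1", "male"), "non-numeric")
  expect_error(parse_genotype("0/1/1", "1", "male"), "malformed")
  # haploid calls outside male chrX violate the ploidy invariant
  expect_error(parse_genotype("1", "chr7", "male"), "ploidy 1")
  expect_error(parse_genotype("1", "chrX", "female"), "ploidy 1")
})

test_that("segregation classifier matches the hand-written truth table over all trio combinations", {
  cfg <- approach1_config()
  # autosomal: 3 x 3 x 3 diploid dosage combinations
  combos <- expand.grid(pro = 0:2, fa = 0:2, mo = 0:2)
  got <- character(nrow(combos))
  want <- character(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    r <- trio_record("7", combos$pro[i], combos$fa[i], combos$mo[i])
    got[i] <- classify_segregation(r, config = cfg)
    want[i] <- oracle_segregation_autosomal(combos$pro[i], combos$fa[i],
                                            combos$mo[i])
  }
  expect_identical(got, want)
  expect_identical(sum(want == "de_novo"), 1L)
  expect_identical(sum(want == "autosomal_recessive"), 1L)

  # male proband on chrX: 2 x 3 x 2 hemizygous/diploid combinations
  xcombos <- expand.grid(pro = 0:1, mo = 0:2, fa = 0:1)
  for (i in seq_len(nrow(xcombos))) {
    r <- trio_record("X", xcombos$pro[i], xcombos$fa[i], xcombos$mo[i],
                     pro_ploidy = 1L, fa_ploidy = 1L, sex = "male")
    expect_identical(
      classify_segregation(r, config = cfg),
      oracle_segregation_male_x(xcombos$pro[i], xcombos$mo[i], xcombos$fa[i]),
      info = sprintf("male X pro=%d mo=%d fa=%d", xcombos$pro[i],
                     xcombos$mo[i], xcombos$fa[i]))
  }
})

test_that("female probands receive no X-linked call by default", {
  r <- trio_record("X", 2, 1, 1, fa_ploidy = 1L, sex = "female")
  expect_identical(classify_segregation(r), "none")
  cfg <- approach1_config(allow_female_xlr = TRUE)
  expect_identical(classify_segregation(r, config = cfg),
                   "x_linked_recessive")
})

test_that("missing genotypes and Mendelian impossibilities yield none", {
  r <- trio_record("5", 1, NA, 0)
  expect_identical(classify_segregation(r), "none")
  # hom-alt child with a hom-ref parent cannot segregate
  imp <- trio_record("5", 2, 0, 1)
  expect_identical(classify_segregation(imp), "none")
  expect_true(misctrio:::mendelian_inconsistent(
    "5", 2L, 2L, FALSE, 0L, FALSE, 1L, FALSE))
})

test_that("diploid-coded homozygous male X calls collapse to hemizygous dosage", {
  r <- trio_record("X", 2, 0, 1, pro_ploidy = 2L, fa_ploidy = 1L,
                   sex = "male")
  expect_identical(classify_segregation(r), "x_linked_recessive")
})
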
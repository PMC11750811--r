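#!/usr/bin/env Rscript
# Approach 2: candidate-variant screen over the MIS-C gene panel.
# Proband-level records; gates: panel membership -> functional class ->
# MAF <= 1% -> damaging (CADD >= 20 or LoF class) -> heterozygous.
# Tallies retained variants by ClinVar category and ACMG verdict.

suppressPackageStartupMessages(library(misctrio))
dir.create("results", showWarnings = FALSE)

fx <- suppressMessages(build_reference_fixture("2"))
cat(sprintf("panel '%s' with %d genes\n", fx$panel$name,
            length(fx$panel$genes)))
a2 <- prioritize_approach2(fx$records, fx$annotations, fx$panel)
ctr <- attr(a2, "counters")
cat("per-gate drops:\n"); print(ctr)

s <- summarise_prioritized(a2)
cat(sprintf(
  "prioritized %d distinct heterozygous variants in %d genes across %d probands\n",
  s$n_variants, s$n_genes, s$n_probands))

tc <- tally_clinvar(a2)
ta <- tally_acmg(a2)
cat("\nClinVar categories (distinct variants):\n")
print(as.data.frame(tc[tc$count > 0, c("category", "count")]))
cat("\nACMG verdicts (distinct variants):\n")
print(as.data.frame(ta[ta$count > 0, c("category", "count")]))
cat(sprintf("\nACMG pathogenic: %s\n",
            paste(unlist(ta$members[ta$category == "pathogenic"]),
                  collapse = ", ")))
cat(sprintf("ACMG VUS: %s\n",
            paste(unlist(ta$members[ta$category == "vus"]), collapse = ", ")))

readr::write_tsv(
  a2[, c("proband_id", "gene", "hgvs_c", "hgvs_p", "effect", "af_gnomad",
         "cadd_phred", "clinvar", "acmg_verdict", "acmg_codes")],
  "results/approach2_candidates.tsv")
jsonlite::write_json(
  list(summary = s, counters = as.list(ctr),
       clinvar = setNames(as.list(tc$count), tc$category),
       acmg = setNames(as.list(ta$count), ta$category)),
  "results/approach2_summary.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("wrote results/approach2_candidates.tsv and results/approach2_summary.json\n")
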
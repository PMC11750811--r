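Package: misctrio
Title: Trio-Exome Variant Prioritization for MIS-C Monogenic Candidates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dual variant-prioritization workflows for identifying monogenic
    candidates of multisystem inflammatory syndrome in children (MIS-C) from
    family-trio exome data: a genome-wide trio-segregation workflow (ultra-rare
    functional variants, CADD gating, de novo / autosomal-recessive / X-linked
    recessive classification), a gene-panel candidate-variant workflow (rare
    predicted-damaging heterozygous variants in immunity genes), ACMG/AMP
    evidence-code combining and verdict auditing, differential-expression
    overlap, recurrence detection across probands, GATK-style hard-filter QC,
    and a synthetic trio-cohort generator with planted variants and
    single-gate decoys so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    vcfR,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
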
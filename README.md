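# misctrio

Trio-exome variant prioritization for monogenic candidates of multisystem
inflammatory syndrome in children (MIS-C).

MIS-C is a rare post-SARS-CoV-2 hyperinflammatory condition; part of its
risk is hypothesized to be monogenic, through rare inborn errors of
immunity. Sequencing family trios (the affected child and both parents)
lets candidate variants be required to *segregate* — not merely be rare.
`misctrio` implements the two complementary workflows used for this
design, for anyone analysing trio exomes of an inflammatory phenotype:

1. **Candidate-gene workflow** (genome-wide, trio-based): GATK-style hard
   filters → functional class (missense / stop gain–loss / splice /
   frameshift) → ultra-rare MAF ≤ 0.01% (ExAC, 1000 Genomes, gnomAD,
   inclusive) → CADD phred ≥ 20 → trio segregation under *de novo*
   (child 0/1, parents 0/0), autosomal recessive (child 1/1, parents 0/1),
   or X-linked recessive (hemizygous boy, carrier mother) inheritance.
2. **Candidate-variant workflow** (panel-based, proband-only): restrict to
   a curated MIS-C immunity-gene panel, keep rare (MAF ≤ 1%), functional,
   predicted-damaging **heterozygous** variants, with loss-of-function
   classes exempt from the CADD requirement.

Around these sit the canonical 2015 ACMG/AMP evidence-code combiner with a
verdict auditor, differential-expression overlap, cross-proband recurrence
detection, a synthetic trio-cohort generator with planted variants and
single-gate decoys, and packaged plain-text fixtures that rebuild a
24-trio reference cohort so every stage runs without any patient data.

## Worked example

Rebuild the reference 24-trio cohort from the packaged table
transcriptions (genotypes realizing each row's printed inheritance label,
plus 200 decoys that each fail exactly one gate) and run the candidate-gene
workflow:

```r
library(misctrio)

fx  <- build_reference_fixture("1", dir = tempdir())
ped <- read_pedigree(fx$ped_path)
rec <- hard_filter_records(read_trio_cohort(fx$vcf_paths, ped))
a1  <- prioritize_approach1(rec, fx$annotations)
summarise_prioritized(a1)
```

```
$n_records
[1] 60
$n_variants
[1] 55
$n_genes
[1] 53
$n_probands
[1] 20
$modes
            de_novo autosomal_recessive  x_linked_recessive
                  7                  21                  27
```

60 proband×variant records survive all four gates; they collapse to 55
distinct variants in 53 genes (five X-linked variants recur in two boys
each), carried by 20 of the 24 probands: 7 de novo, 21 autosomal
recessive, 27 X-linked recessive. The 200 decoys are rejected 50 per gate
(`attr(a1, "counters")`).

The panel workflow and its tallies:

```r
fx2 <- build_reference_fixture("2")
a2  <- prioritize_approach2(fx2$records, fx2$annotations, fx2$panel)
summarise_prioritized(a2)[c("n_variants", "n_genes", "n_probands")]
#> $n_variants [1] 33   $n_genes [1] 19   $n_probands [1] 19

ta <- tally_acmg(a2)
ta[ta$count > 0, c("category", "count")]
#>   category      count
#> 1 benign            8
#> 2 likely_benign    18
#> 3 vus               6
#> 4 pathogenic        1
```

33 rare predicted-damaging heterozygous panel variants across 19 genes in
19 probands; one is ACMG-pathogenic (a C6 splice-donor variant) and six
are VUS. Intersecting the two prioritized gene sets with the MIS-C
differential-expression table yields 3 genes (DDX60, TMEM154, RASSF3) and
5 genes (LY9, IFIH1, DOCK8, DCLRE1C, LYST) respectively
(`overlap_genes_with_deg()`), and `find_recurrent()` recovers the variants
shared across probands, e.g. `ATM:p.P604S` in P5 and P13.

## Analysis scripts

The numbered drivers under `analysis/` narrate the full study and write
their tables to `results/`:

| script | what it does |
|---|---|
| `01_cohort_summary.R` | cohort demographics and clinical-feature prevalences |
| `02_approach1_candidate_genes.R` | candidate-gene workflow + per-gate drop counters |
| `03_approach2_candidate_variants.R` | panel workflow + ClinVar/ACMG tallies |
| `04_overlap_recurrence_audit.R` | expression overlap, recurrence, ACMG verdict audit |
| `05_simulation_robustness.R` | planted-variant recovery across random plans; spurious de novo rate vs genotype-error rate |

Run any of them from the repository root, e.g.
`Rscript analysis/02_approach1_candidate_genes.R`.

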
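#' Configuration for the gene-panel workflow
#'
#' Defaults mirror the study conditions: rare means a population allele
#' frequency of at most 1\% (inclusive), damaging means a CADD phred of at
#' least 20 with loss-of-function classes (frameshift, in-frame indel,
#' stop gain/loss, splice) exempt from the score requirement — such
#' variants are retained on class alone, as scores are routinely absent
#' for them — and only heterozygous proband genotypes are retained.
#'
#' @param maf_threshold Maximum allele frequency (inclusive).
#' @param maf_sources Frequency sources considered.
#' @param cadd_threshold Minimum CADD phred for non-exempt classes.
#' @param lof_classes_exempt_from_cadd Effect classes retained without a
#'   CADD score.
#' @param functional_classes Effects considered functional.
#' @param require_heterozygous Keep only heterozygous proband calls;
#'   homozygous panel hits are reported separately, not silently dropped.
#' @return A list of class `approach2_config`.
#' @export
approach2_config <- function(maf_threshold = 0.01,
                             maf_sources = c("exac", "kg1000", "gnomad"),
                             cadd_threshold = 20,
                             lof_classes_exempt_from_cadd = c(
                               "frameshift", "nonframeshift", "stopgain",
                               "stoploss", "splicing"),
                             functional_classes = DEFAULT_FUNCTIONAL_CLASSES,
                             require_heterozygous = TRUE) {
  stopifnot(maf_threshold > 0, maf_threshold <= 1, cadd_threshold >= 0)
  maf_sources <- match.arg(maf_sources, names(AF_SOURCE_COLS),
                           several.ok = TRUE)
  structure(list(maf_threshold = maf_threshold, maf_sources = maf_sources,
                 cadd_threshold = cadd_threshold,
                 lof_classes_exempt_from_cadd = lof_classes_exempt_from_cadd,
                 functional_classes = functional_classes,
                 require_heterozygous = require_heterozygous,
                 treat_missing_af_as_pass = TRUE),
            class = "approach2_config")
}

#' Gene-panel candidate-variant prioritization
#'
#' Restricts proband genotype records to a curated gene panel and retains
#' rare (inclusive threshold), functional, predicted-damaging heterozygous
#' variants, carrying the ClinVar category and ACMG verdict/evidence codes
#' along for downstream tallies. Parents are not consulted: this workflow
#' screens probands only, accommodating incomplete penetrance.
#'
#' @param proband_records Tibble of proband calls with `proband_id, chrom,
#'   pos, ref, alt, key, pro_alt, pro_ploidy, pro_missing` (trio records
#'   from [read_trio_vcf()] work as-is).
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @param panel A [gene_panel()]; symbols matched case-insensitively.
#' @param config An [approach2_config()].
#' @return Tibble of prioritized variants, `approach = 2`, sorted by
#'   proband, chromosome, position. Attributes: `counters` (per-gate drop
#'   counts) and `homozygous_hits` (panel variants passing every gate but
#'   zygosity).
#' @export
prioritize_approach2 <- function(proband_records, annotations, panel,
                                 config = approach2_config()) {
  stopifnot(inherits(panel, "gene_panel"))
  counters <- c(n_input = nrow(proband_records), n_unannotated = 0L,
                n_panel = 0L, n_class = 0L, n_maf = 0L, n_damaging = 0L,
                n_zygosity = 0L, n_retained = 0L)
  hom_hits <- empty_prioritized(2L)
  if (nrow(proband_records) == 0L) {
    out <- empty_prioritized(2L)
    attr(out, "counters") <- counters
    attr(out, "homozygous_hits") <- hom_hits
    return(out)
  }
  ann_cols <- c("key", "gene", "transcript", "hgvs_c", "hgvs_p", "effect",
                "af_exac", "af_1000g", "af_gnomad", "cadd_phred", "clinvar",
                "acmg_verdict", "acmg_codes")
  joined <- left_join(proband_records, annotations[, ann_cols], by = "key")
  annotated <- !is.na(joined$effect)
  counters["n_unannotated"] <- sum(!annotated)
  joined <- joined[annotated, , drop = FALSE]

  in_panel <- toupper(joined$gene) %in% panel$genes
  counters["n_panel"] <- sum(!in_panel)
  joined <- joined[in_panel, , drop = FALSE]

  pass_class <- joined$effect %in% config$functional_classes
  counters["n_class"] <- sum(!pass_class)
  joined <- joined[pass_class, , drop = FALSE]

  pass_maf <- passes_ultra_rare(joined, config)
  counters["n_maf"] <- sum(!pass_maf)
  joined <- joined[pass_maf, , drop = FALSE]

  cadd_ok <- !is.na(joined$cadd_phred) &
    joined$cadd_phred >= config$cadd_threshold
  exempt <- joined$effect %in% config$lof_classes_exempt_from_cadd
  pass_damaging <- cadd_ok | exempt
  counters["n_damaging"] <- sum(!pass_damaging)
  joined <- joined[pass_damaging, , drop = FALSE]

  het <- !joined$pro_missing & joined$pro_ploidy == 2L & joined$pro_alt == 1L
  if (config$require_heterozygous) {
    counters["n_zygosity"] <- sum(!het)
    hom <- joined[!joined$pro_missing & joined$pro_alt == joined$pro_ploidy &
                    joined$pro_alt > 0L, , drop = FALSE]
    if (nrow(hom)) {
      hom$inheritance_mode <- NA_character_
      hom$approach <- 2L
      hom_hits <- as_tibble(hom)
    }
    joined <- joined[het, , drop = FALSE]
  }

  joined$inheritance_mode <- NA_character_
  joined$approach <- 2L
  out <- joined[order(joined$proband_id, ord_chrom(joined$chrom),
                      joined$pos), , drop = FALSE]
  counters["n_retained"] <- nrow(out)
  out <- as_tibble(out)
  attr(out, "counters") <- counters
  attr(out, "homozygous_hits") <- hom_hits
  out
}

#' Tally prioritized variants by ClinVar category
#'
#' Counts distinct variants per ClinVar category (a variant recurring in
#' several probands counts once), with variants absent from ClinVar
#' gathered under `"not_reported"`. Bucket counts sum to the number of
#' distinct variants.
#'
#' @param prioritized Prioritized-variant tibble carrying `clinvar`.
#' @return Tibble `category, count, members` (members are `GENE:p.X`
#'   labels).
#' @export
tally_clinvar <- function(prioritized) {
  tally_by(prioritized, "clinvar",
           levels = c(CLINVAR_LEVELS, "not_reported"),
           absent_label = "not_reported")
}

#' Tally prioritized variants by ACMG verdict
#'
#' Counts distinct variants per ingested ACMG verdict; variants with no
#' verdict are counted under `"unassigned"`.
#'
#' @param prioritized Prioritized-variant tibble carrying `acmg_verdict`.
#' @return Tibble `category, count, members`.
#' @export
tally_acmg <- function(prioritized) {
  tally_by(prioritized, "acmg_verdict",
           levels = c(VERDICT_LEVELS, "unassigned"),
           absent_label = "unassigned")
}

tally_by <- function(prioritized, column, levels, absent_label) {
  if (nrow(prioritized) == 0L) {
    return(tibble(category = levels, count = 0L,
                  members = replicate(length(levels), character(0),
                                      simplify = FALSE)))
  }
  uniq <- prioritized[!duplicated(prioritized$key), , drop = FALSE]
  cat <- uniq[[column]]
  cat[is.na(cat)] <- absent_label
  label <- paste0(uniq$gene, ":",
                  ifelse(is.na(uniq$hgvs_p) | uniq$hgvs_p == ".",
                         uniq$hgvs_c, uniq$hgvs_p))
  tibble(
    category = levels,
    count = as.integer(table(factor(cat, levels = levels))),
    members = lapply(levels, function(lv) sort(label[cat == lv])))
}
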
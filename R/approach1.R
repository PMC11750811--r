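DEFAULT_FUNCTIONAL_CLASSES <- c("nonsynonymous", "stopgain", "stoploss",
                                "splicing", "frameshift", "nonframeshift")
AF_SOURCE_COLS <- c(exac = "af_exac", kg1000 = "af_1000g", gnomad = "af_gnomad")

#' Configuration for the genome-wide trio workflow
#'
#' Defaults mirror the study conditions: ultra-rare means a minor allele
#' frequency of at most 0.01\% (`1e-4`) in every configured population
#' source, deleterious means a CADD phred of at least 20, and only
#' protein-altering or splice classes are considered. Variants absent from
#' all frequency databases are treated as rare (unobserved alleles pass),
#' and both parents must carry a called genotype for segregation to be
#' classified.
#'
#' @param maf_threshold Maximum population allele frequency (inclusive).
#' @param maf_sources Which frequency sources gate the filter; subset of
#'   `"exac"`, `"kg1000"`, `"gnomad"`.
#' @param cadd_threshold Minimum CADD phred score (inclusive).
#' @param functional_classes Effects considered functional.
#' @param treat_missing_af_as_pass Pass variants with no AF in the chosen
#'   sources.
#' @param require_both_parents_called Drop records with a missing parental
#'   genotype instead of guessing.
#' @param allow_female_xlr Classify homozygous-alt chrX genotypes in female
#'   probands as X-linked recessive (off by default: every reported
#'   X-linked candidate in this design is a hemizygous male).
#' @return A list of class `approach1_config`.
#' @export
approach1_config <- function(maf_threshold = 1e-4,
                             maf_sources = c("exac", "kg1000", "gnomad"),
                             cadd_threshold = 20,
                             functional_classes = DEFAULT_FUNCTIONAL_CLASSES,
                             treat_missing_af_as_pass = TRUE,
                             require_both_parents_called = TRUE,
                             allow_female_xlr = FALSE) {
  stopifnot(maf_threshold > 0, maf_threshold < 1, cadd_threshold >= 0)
  maf_sources <- match.arg(maf_sources, names(AF_SOURCE_COLS),
                           several.ok = TRUE)
  functional_classes <- match.arg(functional_classes, EFFECT_LEVELS,
                                  several.ok = TRUE)
  structure(list(maf_threshold = maf_threshold, maf_sources = maf_sources,
                 cadd_threshold = cadd_threshold,
                 functional_classes = functional_classes,
                 treat_missing_af_as_pass = treat_missing_af_as_pass,
                 require_both_parents_called = require_both_parents_called,
                 allow_female_xlr = allow_female_xlr),
            class = "approach1_config")
}

#' Functional-class gate
#'
#' @param effect Effect value(s) from an annotation record.
#' @param config An [approach1_config()] (or any list with
#'   `functional_classes`).
#' @return Logical: `TRUE` for protein-altering/splice classes,
#'   `FALSE` for synonymous and unknown.
#' @export
is_functional_class <- function(effect, config = approach1_config()) {
  if (!all(effect %in% EFFECT_LEVELS)) {
    stop_input(sprintf("invalid effect '%s'",
                       effect[!effect %in% EFFECT_LEVELS][1L]))
  }
  effect %in% config$functional_classes
}

#' Ultra-rare allele-frequency gate
#'
#' A variant passes when the largest allele frequency present among the
#' configured sources is at most the threshold (inclusive); with no
#' frequency reported in those sources the result is
#' `config$treat_missing_af_as_pass`.
#'
#' @param annotation One-row annotation record (or data frame; vectorized).
#' @param config An [approach1_config()].
#' @return Logical vector.
#' @export
passes_ultra_rare <- function(annotation, config = approach1_config()) {
  cols <- AF_SOURCE_COLS[config$maf_sources]
  af <- do.call(cbind, lapply(cols, function(cl) {
    v <- annotation[[cl]]
    if (is.null(v)) rep(NA_real_, nrow(as.data.frame(annotation))) else as.numeric(v)
  }))
  max_af <- suppressWarnings(apply(af, 1L, max, na.rm = TRUE))
  none <- !is.finite(max_af)
  out <- max_af <= config$maf_threshold
  out[none] <- config$treat_missing_af_as_pass
  out
}

#' CADD deleteriousness gate
#'
#' Passes only variants with a CADD phred score present and at least the
#' threshold (inclusive); a variant with no score cannot demonstrate
#' deleteriousness and fails.
#'
#' @param annotation One-row annotation record (or data frame; vectorized).
#' @param config An [approach1_config()].
#' @return Logical vector.
#' @export
passes_cadd <- function(annotation, config = approach1_config()) {
  cadd <- as.numeric(annotation[["cadd_phred"]])
  !is.na(cadd) & cadd >= config$cadd_threshold
}

#' Classify trio segregation of a single variant
#'
#' On autosomes: de novo is a heterozygous proband with two homozygous
#' reference parents; autosomal recessive is a homozygous-alternate proband
#' with two heterozygous carrier parents. On chrX with a male proband:
#' X-linked recessive is a hemizygous-alternate proband with a carrier
#' (het) mother and a hemizygous-reference father; a hemizygous-alternate
#' proband with a homozygous-reference mother is flagged
#' `x_de_novo_flagged` (reported, but never counted in headline totals).
#' Female probands receive no X-linked call unless `allow_female_xlr` is
#' set. Any other pattern — including Mendelian-impossible combinations
#' such as a homozygous-alternate proband with a homozygous-reference
#' parent — yields `"none"`; impossible patterns are additionally flagged
#' by [mendelian_inconsistent()]. Missing genotypes yield `"none"` when
#' `require_both_parents_called` is in force.
#'
#' @param record One-row trio record (see [read_trio_vcf()]).
#' @param sex `"male"` or `"female"` proband sex (defaults to the record's
#'   `proband_sex`).
#' @param config An [approach1_config()].
#' @return One of `"de_novo"`, `"autosomal_recessive"`,
#'   `"x_linked_recessive"`, `"x_de_novo_flagged"`, `"none"`.
#' @export
classify_segregation <- function(record, sex = record$proband_sex,
                                 config = approach1_config()) {
  classify_segregation_vec(
    chrom = record$chrom, sex = sex,
    pro_alt = record$pro_alt, pro_ploidy = record$pro_ploidy,
    pro_missing = record$pro_missing,
    fa_alt = record$fa_alt, fa_ploidy = record$fa_ploidy,
    fa_missing = record$fa_missing,
    mo_alt = record$mo_alt, mo_ploidy = record$mo_ploidy,
    mo_missing = record$mo_missing,
    config = config)
}

# Vectorized segregation classifier.
classify_segregation_vec <- function(chrom, sex, pro_alt, pro_ploidy,
                                     pro_missing, fa_alt, fa_ploidy,
                                     fa_missing, mo_alt, mo_ploidy,
                                     mo_missing,
                                     config = approach1_config()) {
  n <- length(pro_alt)
  mode <- rep("none", n)
  any_missing <- pro_missing | fa_missing | mo_missing
  usable <- if (config$require_both_parents_called) !any_missing else
    !pro_missing & !fa_missing & !mo_missing
  x <- is_chrx(chrom)
  male <- sex == "male"

  # collapse diploid-coded homozygous calls on male X to hemizygous dosage
  pro_dose <- pro_alt
  hom_dip <- x & male & pro_ploidy == 2L & !pro_missing &
    pro_alt %in% c(0L, 2L)
  pro_dose[hom_dip] <- pro_alt[hom_dip] / 2L
  pro_hemi <- x & male & (pro_ploidy == 1L | hom_dip)
  fa_dose <- fa_alt
  fa_hom_dip <- x & fa_ploidy == 2L & !fa_missing & fa_alt %in% c(0L, 2L)
  fa_dose[fa_hom_dip] <- fa_alt[fa_hom_dip] / 2L
  fa_hemi <- x & (fa_ploidy == 1L | fa_hom_dip)

  auto <- usable & !x
  mode[auto & pro_alt == 1L & pro_ploidy == 2L &
         fa_alt == 0L & mo_alt == 0L] <- "de_novo"
  mode[auto & pro_alt == 2L & pro_ploidy == 2L &
         fa_alt == 1L & mo_alt == 1L] <- "autosomal_recessive"

  xm <- usable & x & male & pro_hemi
  mode[xm & pro_dose == 1L & mo_alt == 1L & mo_ploidy == 2L &
         fa_hemi & fa_dose == 0L] <- "x_linked_recessive"
  mode[xm & pro_dose == 1L & mo_alt == 0L & mo_ploidy == 2L &
         !mo_missing] <- "x_de_novo_flagged"

  if (isTRUE(config$allow_female_xlr)) {
    xf <- usable & x & !male
    mode[xf & pro_alt == 2L & pro_ploidy == 2L & mo_alt == 1L &
           fa_hemi & fa_dose == 1L] <- "x_linked_recessive"
  }
  mode
}

# Mendelian-impossible trio patterns (used for the inconsistency counter):
# an allele the proband must have inherited is absent from the obligate
# parent, restricted to the unambiguous autosomal cases.
mendelian_inconsistent <- function(chrom, pro_alt, pro_ploidy, pro_missing,
                                   fa_alt, fa_missing, mo_alt, mo_missing) {
  x <- is_chrx(chrom)
  ok <- !(pro_missing | fa_missing | mo_missing) & !x & pro_ploidy == 2L
  inc <- rep(FALSE, length(pro_alt))
  inc[ok & pro_alt == 2L & (fa_alt == 0L | mo_alt == 0L)] <- TRUE
  inc[ok & pro_alt == 0L & (fa_alt == 2L | mo_alt == 2L)] <- TRUE
  inc
}

#' Genome-wide trio prioritization (candidate-gene workflow)
#'
#' Composes the four gates of the candidate-gene workflow over hard-filtered
#' trio records: functional effect class, ultra-rare allele frequency,
#' CADD deleteriousness, and trio segregation under de novo, autosomal
#' recessive, or X-linked recessive inheritance. Records without an
#' annotation are dropped and counted.
#'
#' @param records Trio record tibble (see [read_trio_vcf()]), hard-filter
#'   passing.
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @param config An [approach1_config()].
#' @return A tibble of prioritized variants sorted by proband, chromosome
#'   and position, one inferred `inheritance_mode` each, `approach = 1`.
#'   Attribute `counters` records per-gate drop counts (`n_input,
#'   n_unannotated, n_class, n_maf, n_cadd, n_segregation,
#'   n_mendelian_inconsistent, n_retained`).
#' @export
prioritize_approach1 <- function(records, annotations,
                                 config = approach1_config()) {
  counters <- c(n_input = nrow(records), n_unannotated = 0L, n_class = 0L,
                n_maf = 0L, n_cadd = 0L, n_segregation = 0L,
                n_mendelian_inconsistent = 0L, n_retained = 0L)
  if (nrow(records) == 0L) {
    out <- empty_prioritized(approach = 1L)
    attr(out, "counters") <- counters
    return(out)
  }
  ann_cols <- c("key", "gene", "transcript", "hgvs_c", "hgvs_p", "effect",
                "af_exac", "af_1000g", "af_gnomad", "cadd_phred", "clinvar",
                "acmg_verdict", "acmg_codes")
  joined <- left_join(records, annotations[, ann_cols], by = "key")
  annotated <- !is.na(joined$effect)
  counters["n_unannotated"] <- sum(!annotated)
  joined <- joined[annotated, , drop = FALSE]

  pass_class <- is_functional_class(joined$effect, config)
  counters["n_class"] <- sum(!pass_class)
  joined <- joined[pass_class, , drop = FALSE]

  pass_maf <- passes_ultra_rare(joined, config)
  counters["n_maf"] <- sum(!pass_maf)
  joined <- joined[pass_maf, , drop = FALSE]

  pass_cadd <- passes_cadd(joined, config)
  counters["n_cadd"] <- sum(!pass_cadd)
  joined <- joined[pass_cadd, , drop = FALSE]

  mode <- classify_segregation_vec(
    joined$chrom, joined$proband_sex, joined$pro_alt, joined$pro_ploidy,
    joined$pro_missing, joined$fa_alt, joined$fa_ploidy, joined$fa_missing,
    joined$mo_alt, joined$mo_ploidy, joined$mo_missing, config)
  counters["n_mendelian_inconsistent"] <- sum(mendelian_inconsistent(
    joined$chrom, joined$pro_alt, joined$pro_ploidy, joined$pro_missing,
    joined$fa_alt, joined$fa_missing, joined$mo_alt, joined$mo_missing))
  keep <- mode != "none"
  counters["n_segregation"] <- sum(!keep)
  out <- joined[keep, , drop = FALSE]
  out$inheritance_mode <- mode[keep]
  out$approach <- 1L
  out <- out[order(out$proband_id, ord_chrom(out$chrom), out$pos), ,
             drop = FALSE]
  counters["n_retained"] <- nrow(out)
  out <- as_tibble(out)
  attr(out, "counters") <- counters
  out
}

empty_prioritized <- function(approach) {
  tibble(family_id = character(), proband_id = character(),
         proband_sex = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(), key = character(),
         gene = character(), effect = character(),
         inheritance_mode = character(), approach = integer())
}

HEADLINE_MODES <- c("de_novo", "autosomal_recessive", "x_linked_recessive")

#' Summarise a prioritized-variant table
#'
#' Headline counts follow the distinct-variant convention: a variant
#' recurring in several probands counts once in the variant and mode
#' tallies (and its gene once), while the proband count covers every
#' proband carrying at least one retained variant. Variants flagged
#' `x_de_novo_flagged` are excluded from headline totals.
#'
#' @param prioritized Output of [prioritize_approach1()] or
#'   [prioritize_approach2()].
#' @return A list with `n_records`, `n_variants`, `n_genes`, `n_probands`,
#'   and (for approach 1) the named vector `modes`.
#' @export
summarise_prioritized <- function(prioritized) {
  has_mode <- "inheritance_mode" %in% names(prioritized) &&
    any(!is.na(prioritized$inheritance_mode))
  headline <- if (has_mode) {
    prioritized[prioritized$inheritance_mode %in% HEADLINE_MODES, ,
                drop = FALSE]
  } else prioritized
  uniq <- headline[!duplicated(headline$key), , drop = FALSE]
  out <- list(
    n_records = nrow(headline),
    n_variants = nrow(uniq),
    n_genes = n_distinct(uniq$gene),
    n_probands = n_distinct(headline$proband_id))
  if (has_mode) {
    out$modes <- setNames(
      as.integer(table(factor(uniq$inheritance_mode,
                              levels = HEADLINE_MODES))),
      HEADLINE_MODES)
  }
  out
}
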
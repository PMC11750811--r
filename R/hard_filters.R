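#' GATK-style hard filtering of variant calls
#'
#' Applies the classic short-variant hard-filter thresholds to a call's INFO
#' metrics. SNVs fail on `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `MQRankSum < -12.5` or `ReadPosRankSum < -8.0`; indels fail on `QD < 2.0`,
#' `FS > 200.0` or `ReadPosRankSum < -20.0`. A metric that is absent from the
#' record never triggers a failure (the usual convention for sites where the
#' annotation is undefined), and the reported reason is the first failing
#' metric in the order above.
#'
#' @param record A list or one-row data frame with (some of) the elements
#'   `QD`, `FS`, `MQ`, `MQRankSum`, `ReadPosRankSum`.
#' @param variant_class `"snv"` or `"indel"`.
#' @return A list with `pass` (logical) and `reason` (failing metric name, or
#'   `NA` on pass).
#' @examples
#' apply_hard_filters(list(QD = 1.5), "snv")            # fail on QD
#' apply_hard_filters(list(FS = 250), "indel")          # fail on FS
#' apply_hard_filters(list(QD = 30, FS = 5, MQ = 60), "snv")
#' @export
apply_hard_filters <- function(record, variant_class) {
  if (!variant_class %in% c("snv", "indel")) {
    stop_input(sprintf("unknown variant class '%s'; expected 'snv' or 'indel'",
                       variant_class))
  }
  get1 <- function(nm) {
    v <- record[[nm]]
    if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v[1L])
  }
  reason <- hard_filter_reason(
    qd = get1("QD") %||% NA_real_, fs = get1("FS"), mq = get1("MQ"),
    mqranksum = get1("MQRankSum"), readposranksum = get1("ReadPosRankSum"),
    variant_class = variant_class)
  list(pass = is.na(reason), reason = reason)
}

# Vectorized core: returns the name of the first failing metric, or NA when
# the record passes. Absent (NA) metrics never fail.
hard_filter_reason <- function(qd, fs, mq, mqranksum, readposranksum,
                               variant_class) {
  n <- max(length(qd), length(fs), length(mq), length(mqranksum),
           length(readposranksum), length(variant_class))
  rep_n <- function(x) rep_len(if (length(x)) x else NA_real_, n)
  qd <- rep_n(qd); fs <- rep_n(fs); mq <- rep_n(mq)
  mqranksum <- rep_n(mqranksum); readposranksum <- rep_n(readposranksum)
  variant_class <- rep_len(variant_class, n)
  lt <- function(x, thr) !is.na(x) & x < thr
  gt <- function(x, thr) !is.na(x) & x > thr
  is_snv <- variant_class == "snv"

  reason <- rep(NA_character_, n)
  take <- function(reason, cond, label) {
    ifelse(is.na(reason) & cond, label, reason)
  }
  reason <- take(reason, lt(qd, 2.0), "QD")
  reason <- take(reason, is_snv & gt(fs, 60.0), "FS")
  reason <- take(reason, !is_snv & gt(fs, 200.0), "FS")
  reason <- take(reason, is_snv & lt(mq, 40.0), "MQ")
  reason <- take(reason, is_snv & lt(mqranksum, -12.5), "MQRankSum")
  reason <- take(reason, is_snv & lt(readposranksum, -8.0), "ReadPosRankSum")
  reason <- take(reason, !is_snv & lt(readposranksum, -20.0), "ReadPosRankSum")
  reason
}

#' Hard-filter a table of trio variant records
#'
#' Adds `qc_pass`/`qc_reason` columns to a record table produced by
#' [read_trio_vcf()]. The variant class is inferred from the allele strings:
#' single-base ref and alt is an SNV, anything else an indel.
#'
#' @param records A trio-record tibble (see [read_trio_vcf()]).
#' @param keep_failing Keep failing rows (flagged) instead of dropping them.
#' @return The records tibble with QC columns, failing rows dropped unless
#'   `keep_failing = TRUE`.
#' @export
hard_filter_records <- function(records, keep_failing = FALSE) {
  vclass <- ifelse(nchar(records$ref) == 1L & nchar(records$alt) == 1L,
                   "snv", "indel")
  reason <- hard_filter_reason(records$QD, records$FS, records$MQ,
                               records$MQRankSum, records$ReadPosRankSum,
                               vclass)
  records$qc_pass <- is.na(reason)
  records$qc_reason <- reason
  if (keep_failing) records else records[records$qc_pass, , drop = FALSE]
}
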
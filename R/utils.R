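#' @importFrom rlang %||% abort warn inform hash .data
#' @importFrom dplyr arrange bind_rows distinct filter group_by left_join
#'   mutate n n_distinct pull rename select summarise ungroup across all_of
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd rbinom runif setNames
#' @importFrom utils head
NULL

# Sentinels accepted as "absent" in annotation-style tables. Table exports
# routinely mix en dashes, ASCII dashes and dots for empty cells.
ABSENT_TOKENS <- c("", ".", "-", "–", "—", "NA")

#' Normalize a chromosome name
#'
#' Strips a leading "chr" prefix and upper-cases sex chromosomes so that
#' "chrX", "x" and "X" all compare equal. Variant keys are built on this
#' normalized form.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector of normalized names.
#' @export
norm_chrom <- function(chrom) {
  out <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  toupper(out)
}

is_chrx <- function(chrom) norm_chrom(chrom) == "X"

#' Build an exact-match variant key
#'
#' Variants are keyed by `chrom:pos:ref:alt` with the "chr" prefix stripped
#' and alleles upper-cased. Left-normalization of indels is assumed to have
#' been performed upstream by the caller's annotation tooling.
#'
#' @param chrom,pos,ref,alt Vectors describing the variant.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(norm_chrom(chrom), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

absent_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% ABSENT_TOKENS] <- NA_character_
  x
}

numeric_or_na <- function(x) {
  x <- absent_to_na(x)
  suppressWarnings(as.numeric(x))
}

stop_input <- function(msg, class = "misctrio_input_error") {
  abort(msg, class = class)
}

stop_format <- function(msg) stop_input(msg, class = "misctrio_format_error")

round1 <- function(x) round(x, 1)
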
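#' Parse a VCF GT token into a genotype call
#'
#' Converts a VCF `GT` field into reference/alternate allele counts. Phased
#' (`|`) and unphased (`/`) separators are equivalent here; segregation logic
#' uses allele counts only. A single-allele token on the X chromosome for a
#' male sample is a hemizygous (ploidy 1) call. `"./."`, `".|."` and `"."`
#' yield a missing call.
#'
#' @param gt_text A single GT token, e.g. `"0/1"`, `"1"`, `"./."`.
#' @param chrom Chromosome the call sits on ("chr" prefix tolerated).
#' @param sex `"male"` or `"female"` for the sample.
#' @return A list with `allele_count_ref`, `allele_count_alt`, `ploidy`, and
#'   `missing`.
#' @examples
#' parse_genotype("0/1", "chr4", "male")
#' parse_genotype("1", "chrX", "male")   # hemizygous
#' parse_genotype("./.", "1", "female")  # missing
#' @export
parse_genotype <- function(gt_text, chrom, sex) {
  stopifnot(length(gt_text) == 1L)
  sex <- match.arg(sex, c("male", "female"))
  tok <- strsplit(as.character(gt_text), "[/|]")[[1]]
  if (length(tok) == 0L || length(tok) > 2L) {
    stop_format(sprintf("malformed GT token '%s': expected 1 or 2 alleles",
                        gt_text))
  }
  if (all(tok == ".")) {
    return(list(allele_count_ref = NA_integer_, allele_count_alt = NA_integer_,
                ploidy = length(tok), missing = TRUE))
  }
  if (any(tok == ".")) {
    # half-missing diploid calls are treated as missing outright
    return(list(allele_count_ref = NA_integer_, allele_count_alt = NA_integer_,
                ploidy = length(tok), missing = TRUE))
  }
  if (!all(grepl("^[0-9]+$", tok))) {
    stop_format(sprintf("malformed GT token '%s': non-numeric allele index",
                        gt_text))
  }
  idx <- as.integer(tok)
  ploidy <- length(idx)
  if (ploidy == 1L && !(is_chrx(chrom) && sex == "male")) {
    stop_format(sprintf(
      "haploid GT token '%s' on %s for a %s sample; ploidy 1 is only valid on chrX for males",
      gt_text, chrom, sex))
  }
  list(allele_count_ref = sum(idx == 0L),
       allele_count_alt = sum(idx != 0L),
       ploidy = ploidy,
       missing = FALSE)
}

# Vectorized GT parsing used by the VCF reader. `gt` is a character vector of
# GT tokens already recoded against a single alternate allele (indices other
# than the focal alternate count as reference). Returns a tibble with columns
# alt, ploidy, missing.
parse_gt_vec <- function(gt, chrom, sex) {
  gt <- sub(":.*$", "", as.character(gt))
  gt[is.na(gt)] <- "."
  parts <- strsplit(gt, "[/|]")
  nall <- lengths(parts)
  bad <- nall == 0L | nall > 2L
  if (any(bad)) {
    stop_format(sprintf("malformed GT token '%s'", gt[which(bad)[1L]]))
  }
  flat <- unlist(parts, use.names = FALSE)
  if (!all(grepl("^([0-9]+|\\.)$", flat))) {
    offending <- gt[vapply(parts, function(p) {
      !all(grepl("^([0-9]+|\\.)$", p))
    }, logical(1))][1L]
    stop_format(sprintf("malformed GT token '%s': non-numeric allele index",
                        offending))
  }
  missing <- vapply(parts, function(p) any(p == "."), logical(1))
  alt <- integer(length(gt))
  alt[!missing] <- vapply(parts[!missing],
                          function(p) sum(as.integer(p) != 0L), integer(1))
  alt[missing] <- NA_integer_
  haploid_bad <- nall == 1L & !missing & !(is_chrx(chrom) & sex == "male")
  if (any(haploid_bad)) {
    stop_format(sprintf(
      "haploid GT token '%s' outside male chrX", gt[which(haploid_bad)[1L]]))
  }
  tibble(alt = alt, ploidy = nall, missing = missing)
}
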
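INFO_METRICS <- c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")

#' Read trio genotype records from a multi-sample VCF
#'
#' Reads a VCF v4.x file (via \pkg{vcfR}) and emits one record per trio per
#' alternate allele. Multi-allelic sites are split: a site with `ALT=A,T`
#' yields two records at the same position, and genotype allele indices are
#' recoded against the focal alternate (other alternates count as reference).
#' The `QD`, `FS`, `MQ`, `MQRankSum` and `ReadPosRankSum` INFO metrics are
#' carried along for hard filtering when present.
#'
#' @param path Path to the VCF file (plain text or bgzipped).
#' @param pedigree Trio table from [read_pedigree()]. Every trio whose three
#'   sample IDs all appear in the VCF header is read; at least one must.
#' @return A tibble with one row per trio x variant x alternate:
#'   `family_id, proband_id, proband_sex, chrom, pos, ref, alt`, the INFO
#'   metrics, and per-member genotype columns `pro_alt, pro_ploidy,
#'   pro_missing, fa_*, mo_*` (allele counts of the focal alternate).
#' @export
read_trio_vcf <- function(path, pedigree) {
  if (!vcf_has_body(path)) {
    return(empty_trio_records())
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1L]
  have <- pedigree$proband_id %in% samples &
    pedigree$father_id %in% samples & pedigree$mother_id %in% samples
  if (!any(have)) {
    absent <- setdiff(unique(c(pedigree$proband_id, pedigree$father_id,
                               pedigree$mother_id)), samples)
    stop_input(sprintf(
      "no complete trio found in %s; sample IDs absent from the VCF header: %s",
      path, paste(head(absent, 10L), collapse = ", ")))
  }
  trios <- pedigree[have, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1,
                                     dimnames = list(NULL, samples))
  info <- lapply(INFO_METRICS, function(m) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = m)))
  })
  names(info) <- INFO_METRICS

  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt_field <- toupper(fix[, "ALT"])
  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  n_alt <- lengths(alt_list)

  # expand each site once per alternate allele
  site_idx <- rep(seq_along(pos), n_alt)
  alt_rank <- unlist(lapply(n_alt, seq_len), use.names = FALSE)
  alt <- unlist(alt_list, use.names = FALSE)
  if (any(alt == ref[site_idx])) {
    stop_format(sprintf("ALT equals REF at %s:%d",
                        chrom[site_idx][alt == ref[site_idx]][1L],
                        pos[site_idx][alt == ref[site_idx]][1L]))
  }

  recode_gt <- function(tokens, k) {
    # map allele index k -> 1, everything else numeric -> 0, keep "."
    parts <- strsplit(tokens, "[/|]")
    vapply(parts, function(p) {
      p[p != "." & p == as.character(k)] <- "A"   # placeholder
      p[p != "." & p != "A"] <- "0"
      p[p == "A"] <- "1"
      paste(p, collapse = "/")
    }, character(1))
  }

  out <- vector("list", nrow(trios))
  for (i in seq_len(nrow(trios))) {
    tr <- trios[i, ]
    calls <- lapply(
      list(pro = list(id = tr$proband_id, sex = tr$proband_sex),
           fa = list(id = tr$father_id, sex = "male"),
           mo = list(id = tr$mother_id, sex = "female")),
      function(m) {
        raw <- gt[site_idx, m$id]
        raw[is.na(raw)] <- "."
        recoded <- vapply(seq_along(raw), function(j) {
          recode_gt(raw[j], alt_rank[j])
        }, character(1))
        parse_gt_vec(recoded, chrom[site_idx], m$sex)
      })
    out[[i]] <- tibble(
      family_id = tr$family_id, proband_id = tr$proband_id,
      proband_sex = tr$proband_sex,
      chrom = chrom[site_idx], pos = pos[site_idx],
      ref = ref[site_idx], alt = alt,
      QD = info$QD[site_idx], FS = info$FS[site_idx], MQ = info$MQ[site_idx],
      MQRankSum = info$MQRankSum[site_idx],
      ReadPosRankSum = info$ReadPosRankSum[site_idx],
      pro_alt = calls$pro$alt, pro_ploidy = calls$pro$ploidy,
      pro_missing = calls$pro$missing,
      fa_alt = calls$fa$alt, fa_ploidy = calls$fa$ploidy,
      fa_missing = calls$fa$missing,
      mo_alt = calls$mo$alt, mo_ploidy = calls$mo$ploidy,
      mo_missing = calls$mo$missing)
  }
  res <- bind_rows(out)
  res$key <- variant_key(res$chrom, res$pos, res$ref, res$alt)
  res
}

# a VCF with a header but no variant records is legal; detect it cheaply
vcf_has_body <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  repeat {
    lines <- readLines(con, n = 1000L)
    if (length(lines) == 0L) return(FALSE)
    body <- lines[!startsWith(lines, "#")]
    if (length(body)) return(TRUE)
  }
}

empty_trio_records <- function() {
  tibble(family_id = character(), proband_id = character(),
         proband_sex = character(), chrom = character(), pos = integer(),
         ref = character(), alt = character(),
         QD = numeric(), FS = numeric(), MQ = numeric(),
         MQRankSum = numeric(), ReadPosRankSum = numeric(),
         pro_alt = integer(), pro_ploidy = integer(),
         pro_missing = logical(),
         fa_alt = integer(), fa_ploidy = integer(), fa_missing = logical(),
         mo_alt = integer(), mo_ploidy = integer(), mo_missing = logical(),
         key = character())
}

#' Read a cohort of per-trio VCFs
#'
#' @param paths Character vector of VCF paths.
#' @param pedigree Trio table from [read_pedigree()].
#' @return Row-bound records from [read_trio_vcf()] across all files.
#' @export
read_trio_cohort <- function(paths, pedigree) {
  bind_rows(lapply(paths, read_trio_vcf, pedigree = pedigree))
}

# Write a minimal VCF 4.2 for one trio. `sites` is a tibble with chrom, pos,
# ref, alt, info (pre-formatted INFO string) and GT strings gt_pro, gt_fa,
# gt_mo; sample column order is proband, father, mother.
write_trio_vcf <- function(sites, proband_id, father_id, mother_id, path) {
  sites <- sites[order(ord_chrom(sites$chrom), sites$pos), , drop = FALSE]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=misctrio-synthetic",
    '##INFO=<ID=QD,Number=1,Type=Float,Description="Quality by depth">',
    '##INFO=<ID=FS,Number=1,Type=Float,Description="Fisher strand bias">',
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##INFO=<ID=MQRankSum,Number=1,Type=Float,Description="Mapping quality rank sum">',
    '##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description="Read position rank sum">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", proband_id, father_id, mother_id, sep = "\t"))
  body <- if (nrow(sites) == 0L) character(0) else
    paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, "100",
          "PASS", sites$info, "GT", sites$gt_pro, sites$gt_fa,
          sites$gt_mo, sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

# deterministic chromosome ordering for VCF output (1..22, X)
ord_chrom <- function(chrom) {
  ch <- norm_chrom(chrom)
  ord <- suppressWarnings(as.integer(ch))
  ord[ch == "X"] <- 23L
  ord[ch == "Y"] <- 24L
  ord[is.na(ord)] <- 25L
  ord
}
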
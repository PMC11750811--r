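ANNOTATION_COLS <- c("chrom", "pos", "ref", "alt", "gene", "transcript",
                     "hgvs_c", "hgvs_p", "effect", "af_exac", "af_1000g",
                     "af_gnomad", "cadd_phred", "clinvar", "acmg_verdict",
                     "acmg_codes")

EFFECT_LEVELS <- c("nonsynonymous", "stopgain", "stoploss", "splicing",
                   "frameshift", "nonframeshift", "synonymous", "unknown")

CLINVAR_LEVELS <- c("benign", "likely_benign", "vus", "conflicting",
                    "pathogenic", "likely_pathogenic", "risk_factor")

#' Read a per-variant annotation table
#'
#' Reads the tab-separated annotation export consumed by both prioritization
#' workflows. Mandatory columns are `chrom, pos, ref, alt, gene, transcript,
#' hgvs_c, hgvs_p, effect, af_exac, af_1000g, af_gnomad, cadd_phred, clinvar,
#' acmg_verdict, acmg_codes`; extra columns are carried through untouched.
#' Empty cells written as `"-"`, `"."` or an en dash map to absent values; a
#' numeric `"0"` allele frequency is a present value equal to zero. Rows
#' sharing a variant key keep the last occurrence, with a warning.
#'
#' @param path Path to the TSV file.
#' @return A tibble with one row per variant, typed columns, and a `key`
#'   column (`chrom:pos:ref:alt`, normalized).
#' @export
read_annotation_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(ANNOTATION_COLS, names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("annotation table %s is missing mandatory column(s): %s",
                        path, paste(missing_cols, collapse = ", ")))
  }
  out <- df
  out$chrom <- norm_chrom(out$chrom)
  out$pos <- as.integer(out$pos)
  out$ref <- toupper(out$ref)
  out$alt <- toupper(out$alt)
  out$gene <- toupper(trimws(out$gene))
  for (col in c("transcript", "hgvs_c", "hgvs_p")) {
    out[[col]] <- absent_to_na(out[[col]])
  }
  out$effect <- normalize_effect(out$effect)
  for (col in c("af_exac", "af_1000g", "af_gnomad")) {
    out[[col]] <- numeric_or_na(out[[col]])
    bad <- !is.na(out[[col]]) & (out[[col]] < 0 | out[[col]] > 1)
    if (any(bad)) {
      stop_format(sprintf("allele frequency outside [0,1] in column %s", col))
    }
  }
  out$cadd_phred <- numeric_or_na(out$cadd_phred)
  out$clinvar <- normalize_clinvar(out$clinvar)
  out$acmg_verdict <- normalize_verdict(out$acmg_verdict)
  out$acmg_codes <- absent_to_na(out$acmg_codes)
  out$key <- variant_key(out$chrom, out$pos, out$ref, out$alt)
  dup <- duplicated(out$key, fromLast = TRUE)
  if (any(dup)) {
    warn(sprintf("annotation table %s: %d duplicate variant key(s); keeping last occurrence",
                 path, sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  as_tibble(out)
}

#' Write an annotation table
#'
#' Inverse of [read_annotation_table()]: absent values are written as `"."`.
#' Re-reading the written file reproduces the records field-by-field.
#'
#' @param ann Annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(ann, path) {
  out <- ann[, c(ANNOTATION_COLS,
                 setdiff(names(ann), c(ANNOTATION_COLS, "key")))]
  for (col in names(out)) {
    v <- out[[col]]
    v <- as.character(v)
    v[is.na(v)] <- "."
    out[[col]] <- v
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

normalize_effect <- function(x) {
  x <- tolower(gsub("[ _-]", "", absent_to_na(x)))
  map <- c(nonsynonymous = "nonsynonymous", missense = "nonsynonymous",
           stopgain = "stopgain", stoploss = "stoploss",
           splicing = "splicing", splicesite = "splicing",
           frameshift = "frameshift", frameshiftdeletion = "frameshift",
           frameshiftinsertion = "frameshift",
           nonframeshift = "nonframeshift",
           nonframeshiftdeletion = "nonframeshift",
           nonframeshiftinsertion = "nonframeshift",
           synonymous = "synonymous", unknown = "unknown")
  out <- unname(map[x])
  out[is.na(x)] <- "unknown"
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop_format(sprintf("unrecognized effect value '%s'", x[which(bad)[1L]]))
  }
  out
}

normalize_clinvar <- function(x) {
  x <- absent_to_na(x)
  key <- tolower(gsub("[ _-]", "", x))
  map <- c(benign = "benign", likelybenign = "likely_benign",
           "benign/likelybenign" = "likely_benign",
           vus = "vus", uncertainsignificance = "vus",
           uncertain = "vus",
           conflicting = "conflicting", conflictreports = "conflicting",
           conflictingreports = "conflicting",
           pathogenic = "pathogenic", likelypathogenic = "likely_pathogenic",
           riskfactor = "risk_factor")
  out <- unname(map[key])
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    stop_format(sprintf("unrecognized ClinVar category '%s'", x[which(bad)[1L]]))
  }
  out
}

#' Read a 6-column PED pedigree into a trio table
#'
#' Expects the standard whitespace-delimited PED layout (`FamilyID
#' IndividualID PaternalID MaternalID Sex Phenotype`, sex 1=male/2=female,
#' phenotype 2=affected). One affected child with both parental IDs present
#' forms a trio; an affected child with a `"0"` parent is rejected — this
#' workflow requires complete trios.
#'
#' @param path Path to the PED file.
#' @return A tibble with one row per trio: `family_id, proband_id, father_id,
#'   mother_id, proband_sex, affected`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, col.names = c(
    "family_id", "individual_id", "father_id", "mother_id", "sex",
    "phenotype"), colClasses = "character", comment.char = "#")
  kids <- ped[ped$phenotype == "2", , drop = FALSE]
  if (nrow(kids) == 0L) stop_format(sprintf("no affected individuals in %s", path))
  incomplete <- kids$father_id == "0" | kids$mother_id == "0"
  if (any(incomplete)) {
    stop_input(sprintf(
      "incomplete trio(s) for affected individual(s): %s (missing parent)",
      paste(kids$individual_id[incomplete], collapse = ", ")))
  }
  trios <- tibble(
    family_id = kids$family_id,
    proband_id = kids$individual_id,
    father_id = kids$father_id,
    mother_id = kids$mother_id,
    proband_sex = ifelse(kids$sex == "1", "male", "female"),
    affected = TRUE)
  dup_mem <- mapply(function(p, f, m) anyDuplicated(c(p, f, m)) > 0L,
                    trios$proband_id, trios$father_id, trios$mother_id)
  if (any(dup_mem)) {
    stop_format(sprintf("trio members not pairwise distinct for proband %s",
                        trios$proband_id[which(dup_mem)[1L]]))
  }
  trios
}

#' Read a gene panel file
#'
#' One gene symbol per line; `#` starts a comment. Symbols are upper-cased
#' and de-duplicated.
#'
#' @param path Path to the panel file.
#' @param name Panel name (defaults to the file name).
#' @return An object of class `gene_panel`: a list with `name` and the sorted
#'   character vector `genes`.
#' @export
read_gene_panel <- function(path, name = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- toupper(trimws(lines))
  genes <- sort(unique(genes[nzchar(genes)]))
  if (length(genes) == 0L) stop_format(sprintf("gene panel %s is empty", path))
  gene_panel(genes, name = name)
}

#' Construct a gene panel object
#' @param genes Character vector of gene symbols.
#' @param name Panel name.
#' @return A `gene_panel` object.
#' @export
gene_panel <- function(genes, name = "panel") {
  genes <- sort(unique(toupper(trimws(genes))))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop_format("gene panel is empty")
  structure(list(name = name, genes = genes), class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel '%s': %d genes>\n", x$name, length(x$genes)))
  invisible(x)
}

DEG_CELL_TYPES <- c("all_pbmc", "mono_cdc_pdc", "t_cells", "b_cells")

#' Read a differential-expression table
#'
#' CSV with columns `gene, avg_logFC, adj_p, cell_type` (extra columns are
#' kept). Cell-type labels such as "All PBMC" or "Monocytes/cDCs/pDCs" are
#' normalized to `all_pbmc`, `mono_cdc_pdc`, `t_cells`, `b_cells`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of DEG records with upper-cased gene symbols.
#' @export
read_deg_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("gene", "avg_logFC", "adj_p", "cell_type")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop_format(sprintf("DEG table %s is missing column(s): %s", path,
                        paste(missing_cols, collapse = ", ")))
  }
  df$gene <- toupper(trimws(df$gene))
  df$avg_logfc <- as.numeric(df$avg_logFC)
  df$adj_p <- as.numeric(df$adj_p)
  df$avg_logFC <- NULL
  if (any(is.na(df$adj_p)) || any(df$adj_p < 0 | df$adj_p > 1)) {
    stop_format(sprintf("DEG table %s: adjusted p values must lie in [0,1]", path))
  }
  df$cell_type <- normalize_cell_type(df$cell_type)
  as_tibble(df[, c("gene", "avg_logfc", "adj_p", "cell_type",
                   setdiff(names(df), c("gene", "avg_logfc", "adj_p", "cell_type")))])
}

normalize_cell_type <- function(x) {
  key <- tolower(gsub("[^a-z]", "", tolower(x)))
  map <- c(allpbmc = "all_pbmc", pbmc = "all_pbmc",
           monocdcpdc = "mono_cdc_pdc", monocytescdcspdcs = "mono_cdc_pdc",
           tcells = "t_cells", bcells = "b_cells")
  out <- unname(map[key])
  bad <- is.na(out)
  if (any(bad)) {
    stop_format(sprintf("unrecognized cell type '%s'", x[which(bad)[1L]]))
  }
  out
}
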
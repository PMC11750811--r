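#' Intersect prioritized genes with a differential-expression table
#'
#' Returns every DEG record whose gene belongs to the supplied set. The
#' overlap count is the number of distinct genes in the intersection: a
#' gene differentially expressed in several cell types still counts once,
#' though all its per-cell-type records are reported.
#'
#' @param genes Character vector of gene symbols (case-insensitive).
#' @param deg DEG tibble from [read_deg_table()].
#' @return A list with `genes` (sorted distinct overlap genes), `count`,
#'   and `records` (the matching DEG rows, ordered by gene).
#' @export
overlap_genes_with_deg <- function(genes, deg) {
  genes <- unique(toupper(trimws(genes)))
  hit <- deg[deg$gene %in% genes, , drop = FALSE]
  hit <- hit[order(hit$gene), , drop = FALSE]
  list(genes = sort(unique(hit$gene)), count = n_distinct(hit$gene),
       records = as_tibble(hit))
}

# Variant identity used for recurrence: protein change when available,
# otherwise the exact variant key. Two probands sharing a protein change in
# a gene share the variant.
recurrence_id <- function(prioritized) {
  hgvs_p <- prioritized$hgvs_p
  usable <- !is.na(hgvs_p) & hgvs_p != "."
  ifelse(usable, paste0(prioritized$gene, ":", hgvs_p), prioritized$key)
}

#' Detect variants and genes recurring across probands
#'
#' A variant is recurrent when retained in at least two distinct probands;
#' a gene is recurrent when at least two distinct probands carry any
#' retained variant in it (the same variant or different ones). Every
#' recurrent variant's gene therefore appears among the recurrent genes
#' with a superset of its proband list.
#'
#' @param prioritized Prioritized-variant tibble (either workflow, or both
#'   row-bound).
#' @return A list of two tibbles: `recurrent_variants` (`variant, gene,
#'   probands, n_probands`) and `recurrent_genes` (`gene, probands,
#'   n_probands`); `probands` are sorted list-columns.
#' @export
find_recurrent <- function(prioritized) {
  if (nrow(prioritized) == 0L) {
    return(list(
      recurrent_variants = tibble(variant = character(), gene = character(),
                                  probands = list(), n_probands = integer()),
      recurrent_genes = tibble(gene = character(), probands = list(),
                               n_probands = integer())))
  }
  pv <- prioritized
  pv$variant <- recurrence_id(pv)
  var_tab <- pv |>
    group_by(.data$variant, .data$gene) |>
    summarise(probands = list(sort(unique(.data$proband_id))),
              .groups = "drop") |>
    mutate(n_probands = lengths(.data$probands)) |>
    filter(.data$n_probands >= 2L) |>
    arrange(.data$variant)
  gene_tab <- pv |>
    group_by(.data$gene) |>
    summarise(probands = list(sort(unique(.data$proband_id))),
              .groups = "drop") |>
    mutate(n_probands = lengths(.data$probands)) |>
    filter(.data$n_probands >= 2L) |>
    arrange(.data$gene)
  list(recurrent_variants = var_tab, recurrent_genes = gene_tab)
}
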
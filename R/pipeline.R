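#' Run the full dual-prioritization pipeline
#'
#' Thin orchestration over the package's building blocks: read the
#' pedigree and per-trio VCFs, apply hard filters, run the genome-wide
#' trio workflow and the gene-panel workflow, compute the
#' differential-expression overlap for both gene sets, detect recurrent
#' variants/genes, audit ACMG verdicts, and write TSV reports plus a JSON
#' summary and a run manifest. Outputs are deterministic given identical
#' inputs and configuration.
#'
#' @param config A named list (or path to a YAML file parseable by
#'   `yaml::read_yaml`, if available) with input paths `vcf` (vector of
#'   VCF paths, or a directory of `*.vcf`), `ped`, `annotation`, `panel`,
#'   `deg`, and optional threshold overrides `a1_maf_threshold,
#'   a1_cadd_threshold, a2_maf_threshold, a2_cadd_threshold`.
#' @param out_dir Output directory for reports.
#' @return Invisibly, a list with the prioritized tables, overlap,
#'   recurrence, audit, summary and manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop_input(sprintf("config file %s does not exist", config))
    }
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop_input("reading YAML configs requires the 'yaml' package")
    }
    config <- yaml::read_yaml(config)
  }
  needed <- c("vcf", "ped", "annotation", "panel", "deg")
  missing_keys <- setdiff(needed, names(config))
  if (length(missing_keys)) {
    stop_input(sprintf("config is missing input(s): %s",
                       paste(missing_keys, collapse = ", ")))
  }
  vcf_paths <- unlist(config$vcf, use.names = FALSE)
  if (length(vcf_paths) == 1L && dir.exists(vcf_paths)) {
    vcf_paths <- sort(list.files(vcf_paths, pattern = "\\.vcf(\\.gz)?$",
                                 full.names = TRUE))
  }
  inputs <- c(vcf_paths, config$ped, config$annotation, config$panel,
              config$deg)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent)) {
    stop_input(sprintf("missing input file(s): %s",
                       paste(absent, collapse = ", ")))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  a1_cfg <- approach1_config(
    maf_threshold = config$a1_maf_threshold %||% 1e-4,
    cadd_threshold = config$a1_cadd_threshold %||% 20)
  a2_cfg <- approach2_config(
    maf_threshold = config$a2_maf_threshold %||% 0.01,
    cadd_threshold = config$a2_cadd_threshold %||% 20)

  ped <- read_pedigree(config$ped)
  ann <- read_annotation_table(config$annotation)
  panel <- read_gene_panel(config$panel)
  deg <- read_deg_table(config$deg)

  records <- read_trio_cohort(vcf_paths, ped)
  n_raw <- nrow(records)
  records <- hard_filter_records(records)

  a1 <- prioritize_approach1(records, ann, a1_cfg)
  a2 <- prioritize_approach2(records, ann, panel, a2_cfg)
  a1_sum <- summarise_prioritized(a1)
  a2_sum <- summarise_prioritized(a2)
  mode_total <- sum(a1_sum$modes)
  if (mode_total != a1_sum$n_variants) {
    abort(sprintf(
      "invariant violation: inheritance-mode counts (%d) do not sum to the distinct-variant count (%d)",
      mode_total, a1_sum$n_variants), class = "misctrio_invariant_error")
  }

  overlap1 <- overlap_genes_with_deg(unique(a1$gene), deg)
  overlap2 <- overlap_genes_with_deg(unique(a2$gene), deg)
  recur <- find_recurrent(bind_rows(a1, a2))
  audit <- audit_verdicts(ann[!is.na(ann$acmg_codes), , drop = FALSE])

  report_cols <- c("family_id", "proband_id", "chrom", "pos", "ref", "alt",
                   "gene", "transcript", "hgvs_c", "hgvs_p", "effect",
                   "af_exac", "af_1000g", "af_gnomad", "cadd_phred",
                   "clinvar", "acmg_verdict", "acmg_codes",
                   "inheritance_mode", "approach")
  write_report <- function(df, name, cols = report_cols) {
    cols <- intersect(cols, names(df))
    readr::write_tsv(df[, cols, drop = FALSE], file.path(out_dir, name),
                     progress = FALSE)
  }
  write_report(a1, "approach1_report.tsv")
  write_report(a2, "approach2_report.tsv")
  write_report(overlap1$records, "overlap_approach1.tsv",
               c("gene", "avg_logfc", "adj_p", "cell_type"))
  write_report(overlap2$records, "overlap_approach2.tsv",
               c("gene", "avg_logfc", "adj_p", "cell_type"))
  recur_flat <- recur$recurrent_variants
  recur_flat$probands <- vapply(recur_flat$probands, paste, character(1),
                                collapse = ",")
  write_report(recur_flat, "recurrence_report.tsv",
               c("variant", "gene", "probands", "n_probands"))
  write_report(audit, "acmg_audit_report.tsv",
               c("key", "gene", "label", "ingested", "recomputed", "agree"))

  tally_list <- function(t) setNames(as.list(t$count), t$category)
  summary <- list(
    n_trios = nrow(ped),
    n_records_raw = n_raw,
    n_records_qc_pass = nrow(records),
    approach1 = a1_sum,
    approach2 = a2_sum,
    approach1_counters = as.list(attr(a1, "counters")),
    approach2_counters = as.list(attr(a2, "counters")),
    clinvar_tally_approach2 = tally_list(tally_clinvar(a2)),
    acmg_tally_approach2 = tally_list(tally_acmg(a2)),
    deg_overlap = list(approach1 = overlap1$genes, approach2 = overlap2$genes,
                       approach1_count = overlap1$count,
                       approach2_count = overlap2$count),
    n_recurrent_variants = nrow(recur$recurrent_variants),
    n_recurrent_genes = nrow(recur$recurrent_genes),
    acmg_audit_agreement = attr(audit, "agreement"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    tool = "misctrio",
    version = as.character(utils::packageVersion("misctrio")),
    config_hash = rlang::hash(config),
    input_checksums = as.list(tools::md5sum(inputs)),
    thresholds = list(approach1 = unclass(a1_cfg),
                      approach2 = unclass(a2_cfg)),
    drop_counters = list(approach1 = as.list(attr(a1, "counters")),
                         approach2 = as.list(attr(a2, "counters"))))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(approach1 = a1, approach2 = a2, overlap1 = overlap1,
                 overlap2 = overlap2, recurrence = recur, audit = audit,
                 summary = summary, manifest = manifest))
}

#' Summarise cohort demographics and clinical features
#'
#' Computes the cohort-description statistics: sample size, sex counts
#' with percentages (one decimal), age mean and sample (n-1) standard
#' deviation, consanguinity percentage, and the prevalence of each binary
#' clinical feature with its effective denominator (probands with missing
#' values are excluded per feature). Probands present in the pedigree but
#' absent from the clinical table are dropped from feature prevalences
#' with a warning.
#'
#' @param pedigree Trio table from [read_pedigree()].
#' @param clinical Clinical tibble with one row per proband: `proband`,
#'   `sex`, `age_years`, `consanguinity`, and further binary feature
#'   columns (0/1/NA).
#' @return A list with `n`, `sex` (tibble), `age_mean`, `age_sd`,
#'   `age_sd_degenerate`, `consanguinity_pct`, and `features` (tibble
#'   `feature, n_yes, n_known, pct`).
#' @export
summarize_cohort <- function(pedigree, clinical) {
  missing_pro <- setdiff(pedigree$proband_id, clinical$proband)
  if (length(missing_pro)) {
    warn(sprintf("proband(s) missing from the clinical table: %s",
                 paste(missing_pro, collapse = ", ")))
  }
  clin <- clinical[clinical$proband %in% pedigree$proband_id, , drop = FALSE]
  n <- nrow(clin)
  sex_counts <- table(factor(clin$sex, levels = c("male", "female")))
  sex <- tibble(sex = names(sex_counts),
                count = as.integer(sex_counts),
                pct = round1(100 * as.integer(sex_counts) / n))
  age <- as.numeric(clin$age_years)
  degenerate <- sum(!is.na(age)) < 2L
  age_sd <- if (degenerate) 0 else sd(age, na.rm = TRUE)
  feature_cols <- setdiff(names(clin),
                          c("proband", "sex", "age_years", "ethnicity",
                            "consanguinity"))
  features <- bind_rows(lapply(feature_cols, function(col) {
    v <- as.integer(clin[[col]])
    tibble(feature = col, n_yes = sum(v == 1L, na.rm = TRUE),
           n_known = sum(!is.na(v)),
           pct = round1(100 * sum(v == 1L, na.rm = TRUE) / sum(!is.na(v))))
  }))
  cons <- as.integer(clin$consanguinity)
  list(n = n, sex = sex,
       age_mean = mean(age, na.rm = TRUE), age_sd = age_sd,
       age_sd_degenerate = degenerate,
       consanguinity_pct = round1(100 * sum(cons == 1L, na.rm = TRUE) /
                                    sum(!is.na(cons))),
       features = features)
}
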
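PLANT_MODES <- c("de_novo", "autosomal_recessive", "x_linked_recessive",
                 "panel_het")
DECOY_GATES <- c("class", "maf", "cadd", "segregation", "panel", "zygosity")

# toy contig lengths; no reference genome is needed, positions only have to
# be consistent between the VCFs and the annotation table
TOY_CONTIGS <- c(setNames(rep(2e8L, 22L), as.character(1:22)), X = 1.5e8)

#' Specify a synthetic trio cohort
#'
#' A plan names the trios, the variants planted with a known inheritance
#' mode, and the decoys. Each decoy is constructed to fail exactly one
#' gate of the prioritization workflows while passing all others, which
#' makes per-gate drop counters exactly predictable. The default plan
#' mirrors the study design: 24 trios with one planted variant per
#' inheritance mode.
#'
#' @param n_trios Number of trios.
#' @param proband_sexes Proband sexes, recycled to `n_trios`; default
#'   alternates male/female (males first) so X-linked plants always have
#'   an eligible trio.
#' @param planted Data frame with columns `mode` (`de_novo`,
#'   `autosomal_recessive`, `x_linked_recessive`, `panel_het`) and `gene`;
#'   optional `af` (default 0), `cadd` (default 30), `effect` (default
#'   `nonsynonymous`). Default: one plant of each mode.
#' @param n_decoys_per_gate Decoys per gate in `decoy_gates`.
#' @param decoy_gates Subset of `class, maf, cadd, segregation, panel,
#'   zygosity`.
#' @param n_background_sites Homozygous-reference sites per trio whose
#'   annotations pass every gate; genotype-error injection can turn these
#'   into spurious de novo candidates.
#' @param panel_genes Genes considered "on panel" for `panel_het` plants
#'   and panel/zygosity decoys.
#' @param genotype_error_rate Per-call corruption probability recorded in
#'   the plan (applied by [inject_genotype_errors()]).
#' @param seed Integer seed; identical plans generate byte-identical
#'   cohorts.
#' @return A list of class `synthetic_plan`.
#' @export
synthetic_plan <- function(n_trios = 24L,
                           proband_sexes = NULL,
                           planted = NULL,
                           n_decoys_per_gate = 0L,
                           decoy_gates = c("class", "maf", "cadd",
                                           "segregation"),
                           n_background_sites = 0L,
                           panel_genes = c("PANELG1", "PANELG2"),
                           genotype_error_rate = 0,
                           seed = 1L) {
  if (is.null(planted)) {
    planted <- data.frame(
      mode = PLANT_MODES,
      gene = c("GENEDN1", "GENEAR1", "GENEXL1", panel_genes[1L]))
  }
  planted <- as.data.frame(planted)
  if (!all(c("mode", "gene") %in% names(planted))) {
    stop_input("planted must have columns 'mode' and 'gene'")
  }
  if (!all(planted$mode %in% PLANT_MODES)) {
    stop_input(sprintf("unknown plant mode '%s'",
                       setdiff(planted$mode, PLANT_MODES)[1L]))
  }
  if (!all(decoy_gates %in% DECOY_GATES)) {
    stop_input(sprintf("unknown decoy gate '%s'",
                       setdiff(decoy_gates, DECOY_GATES)[1L]))
  }
  if (is.null(planted$af)) planted$af <- rep(0, nrow(planted))
  if (is.null(planted$cadd)) planted$cadd <- rep(30, nrow(planted))
  if (is.null(planted$effect)) {
    planted$effect <- rep("nonsynonymous", nrow(planted))
  }
  if (is.null(proband_sexes)) {
    proband_sexes <- ifelse(seq_len(n_trios) %% 2L == 1L, "male", "female")
  }
  if (!all(proband_sexes %in% c("male", "female"))) {
    stop_input("proband_sexes must be 'male' or 'female'")
  }
  proband_sexes <- rep_len(proband_sexes, n_trios)
  if (any(planted$mode == "x_linked_recessive") &&
      !any(proband_sexes == "male")) {
    stop_input("plan requests X-linked recessive plants but no trio has a male proband")
  }
  bad_panel <- planted$mode == "panel_het" &
    !toupper(planted$gene) %in% toupper(panel_genes)
  if (any(bad_panel)) {
    stop_input(sprintf("panel_het plant gene %s is not in panel_genes",
                       planted$gene[bad_panel][1L]))
  }
  stopifnot(genotype_error_rate >= 0, genotype_error_rate < 1,
            n_trios >= 1L, n_decoys_per_gate >= 0L, n_background_sites >= 0L)
  structure(list(n_trios = as.integer(n_trios),
                 proband_sexes = proband_sexes, planted = planted,
                 n_decoys_per_gate = as.integer(n_decoys_per_gate),
                 decoy_gates = decoy_gates,
                 n_background_sites = as.integer(n_background_sites),
                 panel_genes = toupper(panel_genes),
                 genotype_error_rate = genotype_error_rate,
                 seed = as.integer(seed)),
            class = "synthetic_plan")
}

plan_pedigree <- function(plan) {
  i <- seq_len(plan$n_trios)
  tibble(family_id = sprintf("F%02d", i),
         proband_id = sprintf("S%02dP", i),
         father_id = sprintf("S%02dF", i),
         mother_id = sprintf("S%02dM", i),
         proband_sex = plan$proband_sexes,
         affected = TRUE)
}

# genotype strings per inheritance pattern; X-linked rows use hemizygous
# male encodings
mode_genotypes <- function(mode) {
  switch(mode,
    de_novo = c(pro = "0/1", fa = "0/0", mo = "0/0"),
    autosomal_recessive = c(pro = "1/1", fa = "0/1", mo = "0/1"),
    x_linked_recessive = c(pro = "1", fa = "0", mo = "0/1"),
    panel_het = c(pro = "0/1", fa = "0/1", mo = "0/0"),
    inherited_het = c(pro = "0/1", fa = "0/1", mo = "0/0"),
    hom_planted = c(pro = "1/1", fa = "0/1", mo = "0/1"),
    ref = c(pro = "0/0", fa = "0/0", mo = "0/0"),
    stop_input(sprintf("unknown genotype pattern '%s'", mode)))
}

PASSING_INFO <- "QD=25.0;FS=1.200;MQ=60.00;MQRankSum=0.500;ReadPosRankSum=0.300"

#' Generate a synthetic trio cohort with known ground truth
#'
#' Realizes a [synthetic_plan()] as per-trio VCFs, a PED file, an
#' annotation table and a truth table. Planted genotypes follow each
#' mode's defining trio pattern exactly; each decoy fails only its
#' designated gate. Identical plans (including the seed) produce
#' byte-identical files.
#'
#' @param plan A [synthetic_plan()].
#' @param dir Output directory (created if needed).
#' @return A list with `dir`, `vcf_paths` (named by family), `ped_path`,
#'   `annotation_path`, `truth_path`, and the in-memory `pedigree`,
#'   `annotations`, `truth` tibbles.
#' @export
generate_trio_cohort <- function(plan, dir = tempfile("synthetic_cohort")) {
  stopifnot(inherits(plan, "synthetic_plan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped <- plan_pedigree(plan)
  male_trios <- which(ped$proband_sex == "male")
  if (any(plan$planted$mode == "x_linked_recessive") && !length(male_trios)) {
    stop_input("plan requests X-linked plants but no trio has a male proband")
  }

  withr::with_seed(plan$seed, {
    sites <- list()
    add_site <- function(trio_idx, gene, chrom, effect, af, cadd, pattern,
                         role, label, expect_a1, expect_a2) {
      i <- length(sites) + 1L
      pos <- 1000000L + i * 10000L + sample.int(999L, 1L)
      alleles <- sample(c("A", "C", "G", "T"), 2L)
      gts <- mode_genotypes(pattern)
      sites[[i]] <<- tibble(
        trio_idx = trio_idx, gene = toupper(gene), chrom = chrom,
        pos = pos, ref = alleles[1L], alt = alleles[2L],
        effect = effect, af = af, cadd = cadd,
        gt_pro = gts[["pro"]], gt_fa = gts[["fa"]], gt_mo = gts[["mo"]],
        role = role, label = label,
        expect_a1 = expect_a1, expect_a2 = expect_a2)
    }

    auto_cycle <- as.character(1:22)
    # planted variants, round-robin over eligible trios
    for (j in seq_len(nrow(plan$planted))) {
      p <- plan$planted[j, ]
      if (p$mode == "x_linked_recessive") {
        trio <- male_trios[(j - 1L) %% length(male_trios) + 1L]
        chrom <- "X"
      } else {
        trio <- (j - 1L) %% plan$n_trios + 1L
        chrom <- auto_cycle[(j - 1L) %% 22L + 1L]
      }
      add_site(trio, p$gene, chrom, p$effect, p$af, p$cadd,
               pattern = p$mode, role = "planted", label = p$mode,
               expect_a1 = p$mode %in% HEADLINE_MODES,
               expect_a2 = p$mode == "panel_het")
    }
    # decoys: each fails exactly one gate
    d <- 0L
    for (gate in plan$decoy_gates) {
      for (k in seq_len(plan$n_decoys_per_gate)) {
        d <- d + 1L
        trio <- (d - 1L) %% plan$n_trios + 1L
        gene <- sprintf("DECOY%s%03d", toupper(substr(gate, 1, 3)), d)
        chrom <- auto_cycle[(d - 1L) %% 22L + 1L]
        spec <- switch(gate,
          class = list(effect = "synonymous", af = 0, cadd = 30,
                       pattern = "de_novo"),
          maf = list(effect = "nonsynonymous", af = 0.05, cadd = 30,
                     pattern = "de_novo"),
          cadd = list(effect = "nonsynonymous", af = 0, cadd = 5,
                      pattern = "de_novo"),
          segregation = list(effect = "nonsynonymous", af = 0, cadd = 30,
                             pattern = "inherited_het"),
          panel = list(effect = "nonsynonymous", af = 0, cadd = 30,
                       pattern = "panel_het"),
          zygosity = list(effect = "nonsynonymous", af = 0, cadd = 30,
                          pattern = "hom_planted"))
        if (gate %in% c("zygosity")) {
          gene <- plan$panel_genes[(d - 1L) %% length(plan$panel_genes) + 1L]
        }
        add_site(trio, gene, chrom, spec$effect, spec$af, spec$cadd,
                 spec$pattern, role = "decoy", label = gate,
                 expect_a1 = gate == "zygosity",
                 expect_a2 = FALSE)
      }
    }
    # background hom-ref sites (fodder for genotype-error injection)
    for (t in seq_len(plan$n_trios)) {
      for (k in seq_len(plan$n_background_sites)) {
        add_site(t, sprintf("BGGENE%02d%02d", t, k),
                 auto_cycle[(k - 1L) %% 22L + 1L],
                 "nonsynonymous", 0, 30, "ref", role = "background",
                 label = "ref", expect_a1 = FALSE, expect_a2 = FALSE)
      }
    }

    all_sites <- bind_rows(sites)
    all_sites$key <- variant_key(all_sites$chrom, all_sites$pos,
                                 all_sites$ref, all_sites$alt)

    # a zygosity decoy fed the segregation classifier looks autosomal
    # recessive (hom child, carrier parents); it is rejected by approach 2
    # only. Same for inherited-het panel plants: invisible to approach 1.
    vcf_paths <- character(plan$n_trios)
    for (t in seq_len(plan$n_trios)) {
      tr <- ped[t, ]
      mine <- all_sites[all_sites$trio_idx == t, , drop = FALSE]
      mine$info <- PASSING_INFO
      path <- file.path(dir, sprintf("trio_%s.vcf", tr$family_id))
      write_trio_vcf(mine, tr$proband_id, tr$father_id, tr$mother_id, path)
      vcf_paths[t] <- path
    }
    names(vcf_paths) <- ped$family_id

    ped_path <- file.path(dir, "cohort.ped")
    writeLines(paste(
      rep(ped$family_id, each = 3L),
      as.vector(rbind(ped$proband_id, ped$father_id, ped$mother_id)),
      as.vector(rbind(ped$father_id, "0", "0")),
      as.vector(rbind(ped$mother_id, "0", "0")),
      as.vector(rbind(ifelse(ped$proband_sex == "male", "1", "2"), "1", "2")),
      as.vector(rbind("2", "1", "1")), sep = "\t"), ped_path)

    ann <- tibble(
      chrom = all_sites$chrom, pos = all_sites$pos, ref = all_sites$ref,
      alt = all_sites$alt, gene = all_sites$gene,
      transcript = "NM_000000", hgvs_c = NA_character_,
      hgvs_p = NA_character_, effect = all_sites$effect,
      af_exac = NA_real_, af_1000g = NA_real_, af_gnomad = all_sites$af,
      cadd_phred = all_sites$cadd, clinvar = NA_character_,
      acmg_verdict = NA_character_, acmg_codes = NA_character_)
    annotation_path <- file.path(dir, "annotations.tsv")
    write_annotation_table(ann, annotation_path)

    truth <- tibble(
      key = all_sites$key, gene = all_sites$gene,
      family_id = ped$family_id[all_sites$trio_idx],
      proband_id = ped$proband_id[all_sites$trio_idx],
      role = all_sites$role, label = all_sites$label,
      expect_approach1 = all_sites$expect_a1,
      expect_approach2 = all_sites$expect_a2)
    truth_path <- file.path(dir, "truth.csv")
    readr::write_csv(truth, truth_path, progress = FALSE)

    list(dir = dir, vcf_paths = vcf_paths, ped_path = ped_path,
         annotation_path = annotation_path, truth_path = truth_path,
         pedigree = ped, annotations = read_annotation_table(annotation_path),
         truth = truth)
  })
}

#' Inject random genotype errors into cohort records
#'
#' Flips each non-missing genotype call to a different legal genotype of
#' the same ploidy with the given probability; reproducible under the
#' seed. Useful for measuring how call errors inflate spurious de novo
#' candidates.
#'
#' @param records Trio-record tibble from [read_trio_cohort()].
#' @param rate Per-call corruption probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The corrupted records tibble.
#' @export
inject_genotype_errors <- function(records, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 || nrow(records) == 0L) return(records)
  withr::with_seed(as.integer(seed), {
    for (role in c("pro", "fa", "mo")) {
      alt_col <- paste0(role, "_alt")
      pl_col <- paste0(role, "_ploidy")
      miss_col <- paste0(role, "_missing")
      eligible <- !records[[miss_col]]
      flip <- eligible & (runif(nrow(records)) < rate)
      if (!any(flip)) next
      cur <- records[[alt_col]][flip]
      pl <- records[[pl_col]][flip]
      new <- vapply(seq_along(cur), function(i) {
        legal <- setdiff(0L:pl[i], cur[i])
        if (length(legal) == 1L) legal else sample(legal, 1L)
      }, integer(1))
      records[[alt_col]][flip] <- new
    }
  })
  records
}
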
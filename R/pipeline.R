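# End-to-end orchestration: simulate -> preprocess -> DE -> cluster ->
# gene list -> recluster -> consensus (-> holdout, panels), with a manifest
# recording config, seeds and output hashes.

default_pipeline_config <- function() {
  list(
    seed = NULL,
    sim = list(),
    filter = list(quantile = 0.15, min_age = 25),
    de = list(alpha = 0.05),
    genelist = list(alpha = 0.05, min_datasets = NULL),
    cluster = list(n_starts = 25),
    holdout = FALSE,
    panels = list(enabled = TRUE, file = NULL)
  )
}

validate_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("config must be a list or a YAML path")
  known <- names(default_pipeline_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (is.null(cfg$seed)) abort("config must set `seed` (reproducibility is mandatory)")
  if (!(cfg$filter$quantile > 0 && cfg$filter$quantile < 1)) {
    abort("filter.quantile must lie in (0, 1)")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

# One cohort through filtering, pooled DE, VST + covariate adjustment and
# first-pass clustering on the pooled DE feature set.
analyze_cohort <- function(counts, samples, cfg, seed) {
  samples_f <- filter_subjects(samples, min_age = cfg$filter$min_age)
  counts_f <- counts[, samples_f$sample_id, drop = FALSE]
  counts_f <- filter_low_expression(counts_f, q = cfg$filter$quantile)
  de_pooled <- run_de(counts_f, samples_f, alpha = cfg$de$alpha)
  params <- fit_dispersion_trend(counts_f)
  expr <- vst_transform(counts_f, params)
  expr_adj <- adjust_covariates(expr, samples_f, keep = ~diagnosis)
  cases <- samples_f$sample_id[samples_f$diagnosis == "scz"]
  features <- de_pooled$table$gene[de_pooled$table$de_flag]
  if (length(features) < 2L) {
    abort("analyze_cohort: fewer than 2 pooled DE genes; nothing to cluster on")
  }
  clusters <- cluster_cases(expr_adj[, cases, drop = FALSE], genes = features,
                            seed = seed, n_starts = cfg$cluster$n_starts)
  clusters <- label_subtypes(clusters, counts_f, samples_f, alpha = cfg$de$alpha)
  list(samples = samples_f, counts = counts_f, de_pooled = de_pooled,
       vst_params = params, expr_adj = expr_adj,
       expr_cases = expr_adj[, cases, drop = FALSE], clusters = clusters)
}

# Per-group DE tables (Pooled + consensus groups) and panel statistics for
# one dataset.
panel_stage <- function(cohort, consensus, panels, alpha = 0.05) {
  samples <- cohort$samples
  cons <- tibble::as_tibble(consensus)[, c("subject_id", "consensus")]
  merged <- dplyr::inner_join(dplyr::filter(samples, .data$diagnosis == "scz"),
                              cons, by = "subject_id")
  group_samples <- split(merged$sample_id, merged$consensus)
  de_tables <- list(Pooled = cohort$de_pooled)
  for (grp in c("Type1", "Mix", "Type2")) {
    ids <- group_samples[[grp]]
    if (length(ids) >= 2L) {
      de_tables[[grp]] <- run_de(cohort$counts, samples, case_samples = ids, alpha = alpha)
    }
  }
  expr_l2 <- log2p1_expression(cohort$counts)
  subj_groups <- c(
    setNames(rep("Control", sum(samples$diagnosis == "control")),
             samples$sample_id[samples$diagnosis == "control"]),
    setNames(merged$consensus, merged$sample_id)
  )
  present <- panels[panels$gene %in% rownames(cohort$counts), , drop = FALSE]
  per_panel <- list()
  for (pn in unique(present$panel)) {
    genes <- present$gene[present$panel == pn]
    lfc_tbl <- panel_logfc_table(genes, de_tables)
    per_panel[[pn]] <- list(
      logfc = lfc_tbl,
      abs_lfc_anova = panel_abs_lfc_anova(lfc_tbl),
      gene_anova = purrr::map(setNames(genes, genes),
                              ~ gene_group_anova(expr_l2, .x, subj_groups))
    )
  }
  list(de_tables = de_tables, panels = per_panel, groups = subj_groups)
}

#' Run the full subtype-discovery pipeline on simulated cohorts
#'
#' Orchestrates all stages: cohort simulation, subject/gene filtering,
#' pooled differential expression, VST and covariate adjustment, two-cluster
#' subtype discovery with DE-count labeling, discriminative gene-list
#' derivation, re-clustering on the gene list, cross-cohort consensus
#' classification, optional held-out-cohort agreement, and gene-panel
#' statistics (when panel genes were spiked into the simulation).
#'
#' @param config A list or YAML path. Keys: `seed` (required), `sim`
#'   (arguments to [sim_config()]), `filter` (`quantile`, `min_age`), `de`
#'   (`alpha`), `genelist` (`alpha`, `min_datasets`), `cluster`
#'   (`n_starts`), `holdout` (treat the last simulated cohort as a held-out
#'   validation dataset), `panels` (`enabled`, `file`).
#' @param outdir Optional directory; when given, all stage outputs (counts,
#'   metadata, truth, DE tables, gene list, consensus, summary JSON) are
#'   written there and hashed into the manifest.
#' @return An `scz_pipeline` list: per-cohort results, `gene_list`,
#'   `consensus`, `group_de` (DE of each consensus group vs controls in the
#'   first cohort), `ari` (consensus vs planted labels, Mix excluded),
#'   `holdout_agreement` (if requested), `panel_results`, and `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- validate_pipeline_config(config)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage, start) {
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - start, 2)
  }

  s <- proc.time()[["elapsed"]]
  sim_args <- cfg$sim
  sim_args$seed <- sim_args$seed %||% cfg$seed
  sim <- simulate_cohorts(do.call(sim_config, sim_args))
  tick("simulate", s)

  cohort_ids <- names(sim$counts)
  holdout_id <- NULL
  main_ids <- cohort_ids
  if (isTRUE(cfg$holdout)) {
    if (length(cohort_ids) < 3L) abort("holdout requires at least 3 cohorts")
    holdout_id <- cohort_ids[length(cohort_ids)]
    main_ids <- setdiff(cohort_ids, holdout_id)
  }

  s <- proc.time()[["elapsed"]]
  cohorts <- purrr::imap(sim$counts, function(cnt, id) {
    k <- match(id, cohort_ids)
    analyze_cohort(cnt, dplyr::filter(sim$samples, .data$dataset_id == id),
                   cfg, seed = cfg$seed + 1000L + k)
  })
  tick("per_cohort", s)

  s <- proc.time()[["elapsed"]]
  gl_inputs <- purrr::map(cohorts[main_ids], function(co) {
    list(de_type2 = co$clusters$de_fits$Type2, expr = co$expr_cases,
         clusters = co$clusters)
  })
  gene_list <- derive_gene_list(gl_inputs, alpha = cfg$genelist$alpha,
                                min_datasets = cfg$genelist$min_datasets)
  tick("gene_list", s)

  s <- proc.time()[["elapsed"]]
  cohorts <- purrr::imap(cohorts, function(co, id) {
    k <- match(id, cohort_ids)
    present <- intersect(gene_list$gene, rownames(co$expr_cases))
    if (length(present) < nrow(gene_list)) {
      inform(sprintf("run_pipeline: %s lacks %d gene-list gene(s); clustering on the %d present",
                     id, nrow(gene_list) - length(present), length(present)))
    }
    recl <- recluster_with_list(co$expr_cases, present,
                                seed = cfg$seed + 2000L + k,
                                n_starts = cfg$cluster$n_starts)
    co$clusters_final <- label_subtypes(recl, co$counts, co$samples,
                                        alpha = cfg$de$alpha)
    co
  })
  tick("recluster", s)

  s <- proc.time()[["elapsed"]]
  labels_long <- purrr::map_dfr(cohorts[main_ids],
                                ~ subtype_labels(.x$clusters_final, .x$samples))
  consensus <- consensus_classify(labels_long)
  truth_labels <- sim$truth$labels
  merged <- dplyr::inner_join(tibble::as_tibble(consensus)[, c("subject_id", "consensus")],
                              truth_labels, by = "subject_id")
  core <- dplyr::filter(merged, .data$label != "Mix")
  ari <- adjusted_rand_index(core$consensus, core$label)
  hold_agree <- NULL
  if (!is.null(holdout_id)) {
    hl <- subtype_labels(cohorts[[holdout_id]]$clusters_final,
                         cohorts[[holdout_id]]$samples)
    hold_agree <- holdout_agreement(consensus,
                                    tibble::tibble(subject_id = hl$subject_id,
                                                   label = hl$label))
  }
  tick("consensus", s)

  # DE of each consensus group vs controls in the first main cohort
  # (the per-group DE-count comparison reported for the consistently classified groups)
  s <- proc.time()[["elapsed"]]
  co1 <- cohorts[[main_ids[1L]]]
  cons_map <- dplyr::inner_join(
    dplyr::filter(co1$samples, .data$diagnosis == "scz"),
    tibble::as_tibble(consensus)[, c("subject_id", "consensus")],
    by = "subject_id")
  group_de <- list()
  for (grp in c("Type1", "Mix", "Type2")) {
    ids <- cons_map$sample_id[cons_map$consensus == grp]
    if (length(ids) >= 2L) {
      group_de[[grp]] <- run_de(co1$counts, co1$samples, case_samples = ids,
                                alpha = cfg$de$alpha)
    }
  }
  tick("group_de", s)

  panel_results <- NULL
  if (isTRUE(cfg$panels$enabled)) {
    panels <- load_panels(cfg$panels$file)
    if (any(panels$gene %in% rownames(cohorts[[1L]]$counts))) {
      s <- proc.time()[["elapsed"]]
      panel_results <- panel_stage(cohorts[[main_ids[1L]]], consensus, panels,
                                   alpha = cfg$de$alpha)
      tick("panels", s)
    }
  }

  result <- structure(
    list(config = cfg, truth = sim$truth, samples = sim$samples,
         cohorts = cohorts, main_ids = main_ids, holdout_id = holdout_id,
         gene_list = gene_list, labels = labels_long, consensus = consensus,
         group_de = group_de, ari = ari, holdout_agreement = hold_agree,
         panel_results = panel_results),
    class = "scz_pipeline"
  )

  manifest <- list(
    package_version = as.character(utils::packageVersion("scztype")),
    seed = cfg$seed,
    config = cfg,
    timings = timings,
    total_elapsed = round(proc.time()[["elapsed"]] - t0, 2)
  )
  if (!is.null(outdir)) {
    manifest$files <- write_pipeline_outputs(result, outdir)
  }
  result$manifest <- manifest
  result
}

#' @export
print.scz_pipeline <- function(x, ...) {
  g <- glance(x$consensus)
  cat(sprintf(
    "<scz_pipeline> %d cohort(s)%s | gene list: %d genes | consensus: %d Type1 / %d Type2 / %d Mix | ARI vs truth (Mix excluded): %.3f\n",
    length(x$main_ids),
    if (is.null(x$holdout_id)) "" else sprintf(" (+ holdout %s, agreement %.3f)", x$holdout_id, x$holdout_agreement),
    nrow(x$gene_list), g$n_type1, g$n_type2, g$n_mix, x$ari))
  invisible(x)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  add <- function(p) paths[[length(paths) + 1L]] <<- p
  for (id in names(result$cohorts)) {
    p <- file.path(outdir, paste0("counts_", id, ".tsv"))
    write_counts(result$cohorts[[id]]$counts, p); add(p)
    p <- file.path(outdir, paste0("de_pooled_", id, ".tsv"))
    readr::write_tsv(tidy(result$cohorts[[id]]$de_pooled), p, progress = FALSE); add(p)
    cl <- result$cohorts[[id]]$clusters_final
    p <- file.path(outdir, paste0("clusters_", id, ".tsv"))
    readr::write_tsv(tidy(cl), p, progress = FALSE); add(p)
  }
  p <- file.path(outdir, "samples.csv"); write_samples(result$samples, p); add(p)
  write_truth(result$truth, file.path(outdir, "truth"))
  for (f in list.files(file.path(outdir, "truth"), full.names = TRUE)) add(f)
  p <- file.path(outdir, "gene_list.tsv"); write_gene_list(result$gene_list, p); add(p)
  p <- file.path(outdir, "consensus.tsv")
  readr::write_tsv(tibble::as_tibble(result$consensus), p, progress = FALSE); add(p)
  p <- file.path(outdir, "pairwise_match.csv")
  readr::write_csv(attr(result$consensus, "match"), p, progress = FALSE); add(p)

  g <- glance(result$consensus)
  summary <- list(
    seed = result$config$seed,
    gene_list_size = nrow(result$gene_list),
    consensus = list(n_type1 = g$n_type1, n_type2 = g$n_type2, n_mix = g$n_mix),
    pairwise_match = attr(result$consensus, "match")$match,
    ari_vs_truth = result$ari,
    holdout_agreement = result$holdout_agreement,
    de_counts = purrr::map(result$cohorts[result$main_ids],
                           ~ as.list(.x$clusters_final$de_counts)),
    consensus_group_de = purrr::map(result$group_de, count_de)
  )
  writeLines(yaml::as.yaml(summary), file.path(outdir, "summary.yaml"))
  add(file.path(outdir, "summary.yaml"))
  hashes <- tools::md5sum(unlist(paths))
  tibble::tibble(path = names(hashes), md5 = unname(hashes))
}
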
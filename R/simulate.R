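#' Configuration for the multi-cohort simulator
#'
#' Defines the study conditions the generator emulates: several bulk RNA-seq
#' cohorts drawn from an overlapping pool of postmortem subjects, with
#' negative-binomial counts, a dispersion-mean trend, covariate effects
#' (age, sex, race, RIN), cohort-specific library-prep biases, and planted
#' case subtypes. Type 1 cases carry no expression shift relative to
#' controls; Type 2 cases shift every planted DE gene by its full signed
#' log2 fold change; Mix cases shift by a per-subject attenuation
#' `lambda in mix_attenuation` of the same effects.
#'
#' @param n_genes Number of genes.
#' @param n_controls,n_type1,n_type2,n_mix Per-cohort group sizes.
#' @param n_cohorts Number of cohorts generated from the shared truth.
#' @param shared_fraction Fraction of each cohort's cases drawn from a pool
#'   of subjects present in every cohort (the consortium-style shared subjects).
#' @param n_de_genes Number of planted differentially expressed genes.
#' @param lfc_range Positive ordered pair; planted |log2FC| is uniform on it,
#'   signs random.
#' @param mix_attenuation Pair inside (0,1); per-Mix-subject attenuation of
#'   the planted effects.
#' @param mix_sample_jitter_sd SD of the per-sample (subject-by-cohort)
#'   deviation around a Mix subject's attenuation, truncated to (0, 1).
#'   This is what makes intermediate subjects cluster inconsistently across
#'   cohorts; 0 pins every Mix sample exactly at the subject's lambda.
#' @param a0,a1 Dispersion trend `alpha(mu) = a0 + a1/mu`, i.e. count
#'   variance `mu * (1 + a1) + a0 * mu^2`.
#' @param covariate_effect_sd SD (log2 units) of per-gene covariate
#'   coefficients (age per decade, sex, race levels, RIN per unit).
#' @param cohort_bias_sd SD (log2 units) of the per-gene additive offset each
#'   cohort applies to all of its samples (library-prep bias).
#' @param libsize_sd SD on the natural-log scale of per-sample library size
#'   factors.
#' @param baseline_log2_range Range of per-gene baseline log2 mean counts.
#' @param panel_spike Optional character vector of gene symbols: that many
#'   planted DE genes are renamed to these symbols so shipped gene panels can
#'   be exercised on synthetic data.
#' @param seed Integer seed; mandatory (reproducibility is part of the
#'   contract).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_controls = 100,
                       n_type1 = 40,
                       n_type2 = 30,
                       n_mix = 30,
                       n_cohorts = 3,
                       shared_fraction = 0.65,
                       n_de_genes = 1500,
                       lfc_range = c(0.5, 2.5),
                       mix_attenuation = c(0.3, 0.7),
                       mix_sample_jitter_sd = 0.15,
                       a0 = 0.05,
                       a1 = 1,
                       covariate_effect_sd = 0.1,
                       cohort_bias_sd = 0.2,
                       libsize_sd = 0.2,
                       baseline_log2_range = c(1, 10),
                       panel_spike = NULL,
                       seed = NULL) {
  if (is.null(seed)) abort("sim_config: `seed` is required; simulations must be reproducible.")
  if (n_genes < 1 || n_controls < 1 || n_cohorts < 1 ||
      n_type1 < 0 || n_type2 < 0 || n_mix < 0 ||
      (n_type1 + n_type2 + n_mix) < 1) {
    abort("sim_config: dimensions must be positive (individual case groups may be 0, not all).")
  }
  if (!(shared_fraction > 0 && shared_fraction <= 1)) {
    abort("sim_config: `shared_fraction` must be in (0, 1].")
  }
  if (n_de_genes < 0 || n_de_genes > n_genes) {
    abort("sim_config: `n_de_genes` must lie in [0, n_genes].")
  }
  if (length(lfc_range) != 2L || any(lfc_range <= 0) || diff(lfc_range) < 0) {
    abort("sim_config: `lfc_range` must be a positive ordered pair.")
  }
  if (length(mix_attenuation) != 2L || any(mix_attenuation <= 0) ||
      any(mix_attenuation >= 1) || diff(mix_attenuation) < 0) {
    abort("sim_config: `mix_attenuation` must be an ordered pair inside (0, 1).")
  }
  if (a0 <= 0 || a1 < 0) abort("sim_config: need a0 > 0 and a1 >= 0.")
  if (mix_sample_jitter_sd < 0) abort("sim_config: `mix_sample_jitter_sd` must be nonnegative.")
  if (!is.null(panel_spike)) {
    panel_spike <- as.character(panel_spike)
    if (anyDuplicated(panel_spike)) abort("sim_config: `panel_spike` has duplicates.")
    if (length(panel_spike) > max(n_de_genes, 1L)) {
      abort("sim_config: more `panel_spike` symbols than planted DE genes.")
    }
  }
  structure(
    list(n_genes = as.integer(n_genes), n_controls = as.integer(n_controls),
         n_type1 = as.integer(n_type1), n_type2 = as.integer(n_type2),
         n_mix = as.integer(n_mix), n_cohorts = as.integer(n_cohorts),
         shared_fraction = shared_fraction, n_de_genes = as.integer(n_de_genes),
         lfc_range = lfc_range, mix_attenuation = mix_attenuation,
         mix_sample_jitter_sd = mix_sample_jitter_sd,
         a0 = a0, a1 = a1, covariate_effect_sd = covariate_effect_sd,
         cohort_bias_sd = cohort_bias_sd, libsize_sd = libsize_sd,
         baseline_log2_range = baseline_log2_range,
         panel_spike = panel_spike, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Split a per-cohort group size into shared / cohort-unique parts.
split_shared <- function(n, frac) {
  shared <- round(frac * n)
  c(shared = shared, unique = n - shared)
}

sim_subject_pool <- function(config) {
  lab_sizes <- c(Type1 = config$n_type1, Type2 = config$n_type2, Mix = config$n_mix)
  shared <- purrr::map_int(lab_sizes, ~ as.integer(split_shared(.x, config$shared_fraction)["shared"]))
  subjects <- list()
  idx <- 0L
  for (lab in names(lab_sizes)) {
    if (shared[[lab]] > 0L) {
      ids <- sprintf("SUBJ%04d", idx + seq_len(shared[[lab]]))
      idx <- idx + shared[[lab]]
      subjects[[lab]] <- ids
    } else subjects[[lab]] <- character()
  }
  list(shared = subjects, shared_sizes = shared, label_sizes = lab_sizes)
}

#' Generate synthetic overlapping cohorts with planted subtypes
#'
#' Draws one count matrix per cohort plus a pooled sample table and the
#' ground-truth record. Shared case subjects keep the same subject ID, age,
#' sex, race and planted label in every cohort but their counts are resampled
#' independently (fresh tissue aliquot / library per dataset). Controls and
#' non-shared cases are cohort-specific. Counts are negative binomial with
#' mean `baseline * 2^(covariate effects + cohort bias + effective subtype
#' log2FC) * library size` and dispersion `alpha(mu) = a0 + a1/mu`.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (named list of integer matrices), `samples`
#'   (tibble over all cohorts, including `true_label`), and `truth`
#'   (`sim_truth` list: subject labels, planted DE effects, Mix attenuations,
#'   cohort bias matrix, library size factors).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("gene%05d", seq_len(config$n_genes))
    de_idx <- if (config$n_de_genes > 0) sort(sample.int(config$n_genes, config$n_de_genes)) else integer()
    if (!is.null(config$panel_spike)) {
      genes[de_idx[seq_along(config$panel_spike)]] <- config$panel_spike
    }
    base_log2 <- runif(config$n_genes, config$baseline_log2_range[1], config$baseline_log2_range[2])
    lfc <- numeric(config$n_genes)
    if (length(de_idx)) {
      mag <- runif(length(de_idx), config$lfc_range[1], config$lfc_range[2])
      lfc[de_idx] <- mag * sample(c(-1, 1), length(de_idx), replace = TRUE)
    }
    # per-gene covariate coefficients (log2 units), shared across cohorts
    beta <- matrix(rnorm(config$n_genes * 5L, 0, config$covariate_effect_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, c("age10", "sexM", "raceB", "raceC", "rin")))
    bias <- matrix(rnorm(config$n_genes * config$n_cohorts, 0, config$cohort_bias_sd),
                   nrow = config$n_genes,
                   dimnames = list(genes, paste0("cohort", seq_len(config$n_cohorts))))

    pool <- sim_subject_pool(config)
    shared_ids <- unlist(pool$shared, use.names = FALSE)
    shared_labels <- rep(names(pool$shared), lengths(pool$shared))
    # subject-level covariates fixed across cohorts for shared subjects
    subj_tbl <- tibble::tibble(
      subject_id = shared_ids,
      label = shared_labels,
      age = round(runif(length(shared_ids), 18, 90), 1),
      sex = sample(c("F", "M"), length(shared_ids), replace = TRUE),
      race = sample(c("A", "B", "C"), length(shared_ids), replace = TRUE)
    )
    lambda <- tibble::tibble(
      subject_id = subj_tbl$subject_id[subj_tbl$label == "Mix"],
      lambda = runif(sum(subj_tbl$label == "Mix"),
                     config$mix_attenuation[1], config$mix_attenuation[2])
    )

    counts_list <- list()
    sample_rows <- list()
    libsizes <- list()
    eff_rows <- list()
    uid <- 0L
    for (k in seq_len(config$n_cohorts)) {
      cohort <- sprintf("cohort%d", k)
      # cohort-unique subjects (cases to fill the per-label quota + controls)
      uniq <- list()
      for (lab in names(pool$label_sizes)) {
        n_u <- pool$label_sizes[[lab]] - pool$shared_sizes[[lab]]
        if (n_u > 0L) {
          ids <- sprintf("U%04d", uid + seq_len(n_u)); uid <- uid + n_u
          uniq[[lab]] <- ids
        } else uniq[[lab]] <- character()
      }
      ctl_ids <- sprintf("U%04d", uid + seq_len(config$n_controls))
      uid <- uid + config$n_controls
      uniq_tbl <- tibble::tibble(
        subject_id = c(unlist(uniq, use.names = FALSE), ctl_ids),
        label = c(rep(names(uniq), lengths(uniq)), rep("Control", config$n_controls)),
        age = round(runif(length(c(unlist(uniq), ctl_ids)), 18, 90), 1),
        sex = sample(c("F", "M"), length(c(unlist(uniq), ctl_ids)), replace = TRUE),
        race = sample(c("A", "B", "C"), length(c(unlist(uniq), ctl_ids)), replace = TRUE)
      )
      uniq_lambda <- tibble::tibble(
        subject_id = uniq_tbl$subject_id[uniq_tbl$label == "Mix"],
        lambda = runif(sum(uniq_tbl$label == "Mix"),
                       config$mix_attenuation[1], config$mix_attenuation[2])
      )
      lambda <- dplyr::bind_rows(lambda, uniq_lambda)
      cohort_subjects <- dplyr::bind_rows(subj_tbl, uniq_tbl)
      ns <- nrow(cohort_subjects)
      meta <- dplyr::mutate(
        cohort_subjects,
        sample_id = paste0(.data$subject_id, "_", cohort),
        dataset_id = cohort,
        diagnosis = ifelse(.data$label == "Control", "control", "scz"),
        rin = round(pmin(10, pmax(4, rnorm(ns, 7.5, 1))), 2)
      )
      sf <- exp(rnorm(ns, 0, config$libsize_sd))
      names(sf) <- meta$sample_id

      lam <- setNames(rep(0, ns), meta$subject_id)
      lam[lambda$subject_id[lambda$subject_id %in% names(lam)]] <-
        lambda$lambda[lambda$subject_id %in% names(lam)]
      is_mix <- meta$label == "Mix"
      lam_eff <- unname(lam[meta$subject_id])
      if (config$mix_sample_jitter_sd > 0 && any(is_mix)) {
        lam_eff[is_mix] <- pmin(0.98, pmax(0.02,
          lam_eff[is_mix] + rnorm(sum(is_mix), 0, config$mix_sample_jitter_sd)))
      }
      eff <- dplyr::case_when(
        meta$label == "Type2" ~ 1,
        is_mix ~ lam_eff,
        TRUE ~ 0
      )
      eff_rows[[cohort]] <- tibble::tibble(
        sample_id = meta$sample_id[is_mix],
        subject_id = meta$subject_id[is_mix],
        lambda_eff = lam_eff[is_mix])
      cov_log2 <- beta[, "age10"] %o% ((meta$age - 50) / 10) +
        beta[, "sexM"] %o% as.numeric(meta$sex == "M") +
        beta[, "raceB"] %o% as.numeric(meta$race == "B") +
        beta[, "raceC"] %o% as.numeric(meta$race == "C") +
        beta[, "rin"] %o% (meta$rin - 7.5)
      log2mu <- base_log2 + cov_log2 + bias[, k] + lfc %o% eff
      mu <- sweep(2^log2mu, 2, sf, "*")
      alpha <- config$a0 + config$a1 / mu
      cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / alpha),
                    nrow = config$n_genes,
                    dimnames = list(genes, meta$sample_id))
      storage.mode(cnt) <- "integer"
      counts_list[[cohort]] <- cnt
      sample_rows[[cohort]] <- dplyr::select(
        meta, "sample_id", "subject_id", "dataset_id", "diagnosis",
        "age", "sex", "race", "rin", true_label = "label")
      libsizes[[cohort]] <- tibble::tibble(sample_id = meta$sample_id, factor = unname(sf))
    }

    samples <- dplyr::bind_rows(sample_rows)
    truth <- structure(
      list(
        labels = dplyr::distinct(
          dplyr::filter(samples, .data$true_label != "Control"),
          .data$subject_id, label = .data$true_label),
        de_genes = tibble::tibble(gene = genes[de_idx], lfc = lfc[de_idx]),
        attenuation = lambda,
        sample_attenuation = dplyr::bind_rows(eff_rows),
        cohort_bias = bias,
        libsize = dplyr::bind_rows(libsizes),
        shared_subjects = shared_ids,
        config = config
      ),
      class = "sim_truth"
    )
    list(counts = counts_list, samples = samples, truth = truth)
  })
}

#' Write / read the simulation ground truth
#'
#' The truth record is stored as a directory of TSV files (labels, planted DE
#' effects, Mix attenuations, cohort bias matrix, library size factors,
#' shared-subject list) and round-trips losslessly.
#'
#' @param truth A `sim_truth` object from [simulate_cohorts()].
#' @param path Directory to create/populate.
#' @return `path` (write) or a `sim_truth` (read). The `config` element is not
#'   serialized.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(truth$labels, file.path(path, "labels.tsv"), progress = FALSE)
  readr::write_tsv(truth$de_genes, file.path(path, "de_genes.tsv"), progress = FALSE)
  readr::write_tsv(truth$attenuation, file.path(path, "attenuation.tsv"), progress = FALSE)
  readr::write_tsv(truth$sample_attenuation, file.path(path, "sample_attenuation.tsv"), progress = FALSE)
  readr::write_tsv(tibble::as_tibble(truth$cohort_bias, rownames = "gene"),
                   file.path(path, "cohort_bias.tsv"), progress = FALSE)
  readr::write_tsv(truth$libsize, file.path(path, "libsize.tsv"), progress = FALSE)
  writeLines(truth$shared_subjects, file.path(path, "shared_subjects.txt"))
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  rd <- function(f) readr::read_tsv(file.path(path, f), show_col_types = FALSE, progress = FALSE)
  bias_df <- rd("cohort_bias.tsv")
  bias <- as.matrix(bias_df[, -1L, drop = FALSE])
  rownames(bias) <- bias_df$gene
  att <- rd("attenuation.tsv")
  if (nrow(att) == 0L) att <- tibble::tibble(subject_id = character(), lambda = numeric())
  satt <- rd("sample_attenuation.tsv")
  if (nrow(satt) == 0L) {
    satt <- tibble::tibble(sample_id = character(), subject_id = character(),
                           lambda_eff = numeric())
  }
  de <- rd("de_genes.tsv")
  if (nrow(de) == 0L) de <- tibble::tibble(gene = character(), lfc = numeric())
  structure(
    list(labels = rd("labels.tsv"), de_genes = de, attenuation = att,
         sample_attenuation = satt,
         cohort_bias = bias, libsize = rd("libsize.tsv"),
         shared_subjects = readLines(file.path(path, "shared_subjects.txt")),
         config = NULL),
    class = "sim_truth"
  )
}
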
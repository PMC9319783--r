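# Shared fixture builders. Everything is generated in code; no binary data.

quietly <- function(expr) suppressMessages(expr)

# Small simulated study used across module tests.
tiny_config <- function(seed, ...) {
  args <- utils::modifyList(
    list(n_genes = 400, n_controls = 30, n_type1 = 12, n_type2 = 10, n_mix = 6,
         n_cohorts = 2, n_de_genes = 150, seed = seed),
    list(...))
  do.call(sim_config, args)
}

# Plain NB count matrix with a fixed mean vector (no covariates, unit
# library sizes) — used where tests need counts independent of the
# package's own simulator.
nb_counts <- function(n_genes, n_samples, mu = NULL, a0 = 0.05, a1 = 1, seed = 1) {
  withr::with_seed(seed, {
    mu <- mu %||% 2^stats::runif(n_genes, 3, 10)
    m <- matrix(rep(mu, n_samples), nrow = n_genes)
    alpha <- a0 + a1 / m
    cnt <- matrix(stats::rnbinom(length(m), mu = m, size = 1 / alpha),
                  nrow = n_genes,
                  dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                                  sprintf("s%03d", seq_len(n_samples))))
    storage.mode(cnt) <- "integer"
    cnt
  })
}

# Minimal valid sample table for hand-built fixtures.
mk_samples <- function(sample_id, diagnosis, dataset_id = "d1",
                       subject_id = sample_id, age = 50, sex = "F",
                       race = "A", rin = 7.5) {
  tibble::tibble(sample_id = sample_id, subject_id = subject_id,
                 dataset_id = dataset_id, diagnosis = diagnosis,
                 age = age, sex = sex, race = race, rin = rin)
}

# Long label tibble for consensus tests: one row per subject x dataset.
mk_labels <- function(mat) {
  # mat: subjects x datasets character matrix of Type1/Type2
  tibble::tibble(
    subject_id = rep(rownames(mat), times = ncol(mat)),
    dataset_id = rep(colnames(mat), each = nrow(mat)),
    label = as.vector(mat)
  )
}

`%||%` <- rlang::`%||%`

# Labeled cluster object built directly from known subtype labels.
clusters_from_labels_for_test <- function(sample_ids, subtypes) {
  scztype:::clusters_from_labels(sample_ids, subtypes)
}
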
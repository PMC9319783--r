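#' Read a gene-by-sample count matrix
#'
#' Supports two plain-text formats: TSV (first column gene IDs, header row of
#' sample IDs) and MatrixMarket (`.mtx` plus `genes.txt` / `samples.txt`
#' sidecar files in the same directory). Values must be nonnegative integers
#' and identifiers unique; violations raise an error naming the offender.
#'
#' @param path Path to the `.tsv`/`.txt` file or the `.mtx` file.
#' @param format `"auto"` (by extension), `"tsv"` or `"mtx"`.
#' @return An integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (!file.exists(path)) abort(sprintf("file not found: '%s'", path))
  if (format == "tsv") {
    df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    genes <- as.character(df[[1L]])
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- genes
  } else {
    m <- Matrix::readMM(path)
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.txt")
    sfile <- file.path(dir, "samples.txt")
    if (!file.exists(gfile) || !file.exists(sfile)) {
      abort("MatrixMarket counts need 'genes.txt' and 'samples.txt' alongside the .mtx file")
    }
    mat <- as.matrix(m)
    rownames(mat) <- readLines(gfile)
    colnames(mat) <- readLines(sfile)
  }
  if (any(!is.finite(mat))) abort("counts contain non-finite values")
  if (any(mat != round(mat))) {
    bad <- which(mat != round(mat), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-integer count at gene '%s', sample '%s'",
                  rownames(mat)[bad[1L]], colnames(mat)[bad[2L]]))
  }
  storage.mode(mat) <- "integer"
  check_count_matrix(mat)
  mat
}

#' Write a count matrix
#'
#' Deterministic writers for the two supported formats; row and column order
#' is preserved exactly, so `write_counts()` then [read_counts()] round-trips.
#'
#' @param counts Integer matrix with gene rownames and sample colnames.
#' @param path Output path (`.tsv` or `.mtx`; MatrixMarket also writes
#'   `genes.txt` and `samples.txt` next to it).
#' @param format `"auto"`, `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  check_count_matrix(counts)
  if (format == "tsv") {
    df <- tibble::as_tibble(counts, rownames = "gene")
    readr::write_tsv(df, path, progress = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(rownames(counts), file.path(dir, "genes.txt"))
    writeLines(colnames(counts), file.path(dir, "samples.txt"))
  }
  invisible(path)
}

#' Read / write a sample metadata table
#'
#' CSV with columns `subject_id, sample_id, dataset_id, diagnosis, age, sex,
#' race, rin` (plus optional extras such as `true_label` from the simulator).
#'
#' @param path CSV path.
#' @return A tibble, one row per sample.
#' @export
read_samples <- function(path) {
  tbl <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(), subject_id = readr::col_character(),
      dataset_id = readr::col_character(), diagnosis = readr::col_character(),
      sex = readr::col_character(), race = readr::col_character(),
      age = readr::col_double(), rin = readr::col_double(),
      .default = readr::col_guess()))
  check_sample_table(tbl)
  tbl
}

#' @param samples Sample tibble as returned by [read_samples()] or
#'   [simulate_cohorts()].
#' @rdname read_samples
#' @export
write_samples <- function(samples, path) {
  check_sample_table(samples)
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Subjects present in every cohort
#'
#' Returns the subject IDs shared by all supplied sample tables. Consensus
#' subtyping operates on case subjects that appear in each dataset, so by
#' default only `diagnosis == "scz"` rows are considered.
#'
#' @param tables A list of sample tibbles (or one tibble with several
#'   `dataset_id` values).
#' @param cases_only Restrict to schizophrenia cases (default `TRUE`).
#' @return Character vector of shared subject IDs (sorted).
#' @export
intersect_cohorts <- function(tables, cases_only = TRUE) {
  if (tibble::is_tibble(tables)) {
    tables <- split(tables, tables$dataset_id)
  }
  if (length(tables) == 0L) abort("`tables` is empty.")
  sets <- purrr::map(tables, function(tbl) {
    if (cases_only) tbl <- dplyr::filter(tbl, .data$diagnosis == "scz")
    unique(tbl$subject_id)
  })
  sort(purrr::reduce(sets, intersect))
}

#' Harmonize gene universes across cohorts
#'
#' Restricts every count matrix to the genes present (by exact identifier
#' match) in all of them, preserving the first cohort's gene order. Dropped
#' genes are reported via a message.
#'
#' @param counts_list List of count matrices.
#' @return List of matrices over the common gene set.
#' @export
harmonize_genes <- function(counts_list) {
  if (length(counts_list) == 0L) abort("`counts_list` is empty.")
  common <- purrr::reduce(purrr::map(counts_list, rownames), intersect)
  if (length(common) == 0L) abort("no genes shared across cohorts")
  dropped <- sum(purrr::map_int(counts_list, ~ sum(!rownames(.x) %in% common)))
  if (dropped > 0L) {
    inform(sprintf("harmonize_genes: dropped %d gene rows absent from some cohort", dropped))
  }
  common <- rownames(counts_list[[1L]])[rownames(counts_list[[1L]]) %in% common]
  purrr::map(counts_list, ~ .x[common, , drop = FALSE])
}
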
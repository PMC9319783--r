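# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2L) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# Vectorised Welch two-sample t-test over matrix rows; returns two-sided p.
row_welch_p <- function(x1, x2) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) abort("Welch t-test needs at least 2 samples per group.")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- row_vars(x1); v2 <- row_vars(x2)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * pt(-abs(tt), df)
  # zero variance in both groups: identical -> p 1, different means -> p 0
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b Vectors of labels of equal length.
#' @return A single number in (-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}

check_count_matrix <- function(x, arg = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must have gene rownames and sample colnames.", arg))
  }
  if (anyDuplicated(rownames(x))) {
    dup <- rownames(x)[duplicated(rownames(x))][1L]
    abort(sprintf("duplicate gene identifier: '%s'", dup))
  }
  if (anyDuplicated(colnames(x))) {
    dup <- colnames(x)[duplicated(colnames(x))][1L]
    abort(sprintf("duplicate sample identifier: '%s'", dup))
  }
  if (any(x < 0)) abort(sprintf("`%s` contains negative values.", arg))
  invisible(x)
}

check_sample_table <- function(samples, counts = NULL) {
  required <- c("sample_id", "subject_id", "dataset_id", "diagnosis",
                "age", "sex", "race", "rin")
  missing <- setdiff(required, names(samples))
  if (length(missing)) {
    abort(paste0("sample table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  bad <- setdiff(unique(samples$diagnosis), c("control", "scz"))
  if (length(bad)) {
    abort(paste0("diagnosis must be 'control' or 'scz'; found: ",
                 paste(bad, collapse = ", ")))
  }
  if (!is.null(counts)) {
    lost <- setdiff(colnames(counts), samples$sample_id)
    if (length(lost)) {
      abort(sprintf("%d count column(s) have no sample-table row (first: '%s')",
                    length(lost), lost[1L]))
    }
  }
  invisible(samples)
}
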
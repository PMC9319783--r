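#' Remove genes with low average counts
#'
#' Drops genes whose mean count across samples is strictly below the
#' `q`-quantile of all per-gene mean counts (linear "type 7" interpolation),
#' preserving gene order.
#'
#' @param counts Count matrix (genes x samples).
#' @param q Quantile in (0, 1); default 0.15.
#' @return The filtered count matrix.
#' @export
filter_low_expression <- function(counts, q = 0.15) {
  check_count_matrix(counts)
  if (!(q > 0 && q < 1)) abort("`q` must lie in (0, 1).")
  m <- rowMeans(counts)
  thr <- unname(quantile(m, q, type = 7))
  keep <- m >= thr
  inform(sprintf("filter_low_expression: %d genes in, %d genes out (threshold %.4g)",
                 nrow(counts), sum(keep), thr))
  counts[keep, , drop = FALSE]
}

#' Restrict samples to adults over an age cutoff
#'
#' Keeps samples with `age > min_age` (strictly greater) and a diagnosis of
#' `"control"` or `"scz"`. Rows with a missing age are dropped with a
#' warning.
#'
#' @param samples Sample tibble.
#' @param min_age Years; default 25.
#' @return Filtered sample tibble.
#' @export
filter_subjects <- function(samples, min_age = 25) {
  check_sample_table(samples)
  n_na <- sum(is.na(samples$age))
  if (n_na > 0L) {
    warn(sprintf("filter_subjects: dropping %d sample(s) with missing age", n_na))
  }
  out <- dplyr::filter(samples, !is.na(.data$age), .data$age > min_age,
                       .data$diagnosis %in% c("control", "scz"))
  inform(sprintf("filter_subjects: %d samples in, %d samples out", nrow(samples), nrow(out)))
  out
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes (with all-positive counts) of the
#' ratio of that sample's count to the gene's geometric mean across samples.
#'
#' @param counts Count matrix.
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(counts) {
  check_count_matrix(counts)
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos)) {
    abort("size_factors: no gene has positive counts in every sample; filter low-expression genes first.")
  }
  lc <- log(counts[allpos, , drop = FALSE])
  geo <- rowMeans(lc)
  apply(lc, 2L, function(col) exp(median(col - geo)))
}

#' Dispersion-trend parameters for the VST
#'
#' @param size_factors Positive per-sample scalars.
#' @param a0 Asymptotic dispersion (> 0).
#' @param a1 Extra-Poisson coefficient (>= 0); `alpha(mu) = a0 + a1/mu`.
#' @return A `vst_params` list.
#' @export
vst_params <- function(size_factors, a0, a1) {
  if (any(size_factors <= 0)) abort("size factors must be positive")
  if (a0 <= 0) abort("`a0` must be positive")
  if (a1 < 0) abort("`a1` must be nonnegative")
  structure(list(size_factors = size_factors, a0 = a0, a1 = a1),
            class = "vst_params")
}

#' Fit the dispersion-mean trend from counts
#'
#' Per-gene method-of-moments dispersions (`(var - mu) / mu^2` on
#' size-factor-normalized counts) are regressed on `1/mu` by robust least
#' squares (Huber M-estimation), yielding `alpha(mu) = a0 + a1/mu` with
#' `a0` clamped to at least 1e-8 and `a1` to at least 0.
#'
#' @param counts Count matrix (ideally after [filter_low_expression()]).
#' @param sf Optional precomputed size factors.
#' @return A [vst_params()] object.
#' @export
fit_dispersion_trend <- function(counts, sf = NULL) {
  check_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  norm <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(norm)
  v <- row_vars(norm)
  alpha <- (v - mu) / mu^2
  ok <- is.finite(alpha) & alpha > 0 & mu > 0
  if (sum(ok) < 10L) abort("fit_dispersion_trend: too few genes with positive moment dispersions")
  fit <- MASS::rlm(alpha[ok] ~ I(1 / mu[ok]), maxit = 50)
  a0 <- max(unname(fit$coefficients[1L]), 1e-8)
  a1 <- max(unname(fit$coefficients[2L]), 0)
  vst_params(sf, a0, a1)
}

#' Variance-stabilizing transformation of counts
#'
#' Closed-form VST for negative-binomial counts with dispersion trend
#' `alpha(mu) = a0 + a1/mu`: with `x' = count / size_factor`,
#' `value = log2((1 + a1 + 2*a0*x' + 2*sqrt(a0*x'*(1 + a1 + a0*x'))) / (4*a0))`.
#' The transform is strictly increasing in the normalized count and behaves
#' like `log2(x')` for large counts.
#'
#' @param counts Count matrix.
#' @param params A [vst_params()]; fitted from the data when `NULL`.
#' @return Numeric matrix of transformed expression values.
#' @export
vst_transform <- function(counts, params = NULL) {
  check_count_matrix(counts)
  params <- params %||% fit_dispersion_trend(counts)
  stopifnot(inherits(params, "vst_params"))
  if (length(params$size_factors) != ncol(counts)) {
    abort("vst_transform: size factor length does not match sample count")
  }
  a0 <- params$a0; a1 <- params$a1
  x <- sweep(counts, 2L, params$size_factors, "/")
  log2((1 + a1 + 2 * a0 * x + 2 * sqrt(a0 * x * (1 + a1 + a0 * x))) / (4 * a0))
}

#' Regress nuisance covariates out of an expression matrix
#'
#' Per gene, fits least squares on the combined design `[keep | remove]` and
#' subtracts the fitted contribution of the `remove` covariates only, so that
#' structure captured by `keep` (e.g. diagnosis) is protected. This is the
#' standard batch-removal adjustment applied before clustering.
#'
#' @param expr Expression matrix (genes x samples).
#' @param samples Sample tibble with one row per column of `expr`.
#' @param remove Character vector of covariate columns to remove
#'   (default `c("age", "sex", "race", "rin")`); empty means identity.
#' @param keep One-sided formula of structure to protect (default `~ 1`,
#'   the intercept).
#' @return Adjusted expression matrix of the same shape.
#' @export
adjust_covariates <- function(expr, samples,
                              remove = c("age", "sex", "race", "rin"),
                              keep = ~1) {
  check_sample_table(samples)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) abort("adjust_covariates: expr columns missing from sample table")
  K <- model.matrix(keep, data = samples)
  if (length(remove) == 0L) return(expr)
  miss <- setdiff(remove, names(samples))
  if (length(miss)) abort(paste0("unknown covariate(s): ", paste(miss, collapse = ", ")))
  rform <- stats::as.formula(paste("~", paste(remove, collapse = " + ")))
  R <- model.matrix(rform, data = as.data.frame(samples))[, -1L, drop = FALSE]
  # center removal columns so the intercept keeps the grand level
  R <- scale(R, center = TRUE, scale = FALSE)
  X <- cbind(K, R)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    abort(paste0("adjust_covariates: design is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qx, t(expr))
  rem_idx <- ncol(K) + seq_len(ncol(R))
  adj <- expr - t(R %*% beta[rem_idx, , drop = FALSE])
  dimnames(adj) <- dimnames(expr)
  adj
}
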
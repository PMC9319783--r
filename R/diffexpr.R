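# Precision-weighted per-gene linear modeling with empirical-Bayes moderation.
#
# The stack mirrors the voom/limma approach for bulk RNA-seq: log-CPM
# transform, a lowess mean-variance trend turned into per-observation
# precision weights, weighted least squares per gene, and shrinkage of the
# residual variances toward a pooled prior before forming moderated
# t-statistics.

#' Log2 counts per million
#'
#' `log2((count + prior) / (libsize + 2 * prior) * 1e6)` with library sizes
#' the per-sample column sums (or supplied).
#'
#' @param counts Count matrix.
#' @param prior Prior count added to the numerator; default 0.5.
#' @param lib_sizes Optional per-sample library sizes.
#' @return Matrix of log2-CPM values.
#' @export
logcpm <- function(counts, prior = 0.5, lib_sizes = NULL) {
  check_count_matrix(counts)
  lib_sizes <- lib_sizes %||% colSums(counts)
  if (any(lib_sizes <= 0)) abort("logcpm: library sizes must be positive")
  t(log2(t(counts + prior) / (lib_sizes + 2 * prior) * 1e6))
}

#' Precision weights from the mean-variance trend
#'
#' Fits per-gene OLS on `design`, lowess-smooths the square-root residual
#' standard deviations against per-gene mean log2-CPM, and returns
#' per-observation weights `predicted_sqrt_sd^-4` evaluated at each fitted
#' value. Genes with (near) zero residual SD are floored so weights stay
#' finite.
#'
#' @param E log2-CPM matrix (genes x samples).
#' @param design Numeric design matrix (samples x coefficients).
#' @param span lowess span (default 0.5) with 3 robustness iterations.
#' @return Weight matrix of the same shape as `E`, all entries positive.
#' @export
precision_weights <- function(E, design, span = 0.5) {
  if (nrow(design) != ncol(E)) abort("design rows must match samples")
  if (nrow(design) <= ncol(design)) abort("fewer samples than design columns leaves no residual df")
  fit <- lm.fit(design, t(E))
  df <- nrow(design) - fit$rank
  if (df < 1L) abort("no residual degrees of freedom")
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / df)
  sqrt_sd <- sqrt(pmax(sigma, 1e-4))
  amean <- rowMeans(E)
  lo <- lowess(amean, sqrt_sd, f = span, iter = 3L)
  fitted_logcpm <- t(design %*% fit$coefficients) # genes x samples
  pred <- approx(lo$x, lo$y, xout = fitted_logcpm, rule = 2L, ties = mean)$y
  pred <- pmax(matrix(pred, nrow = nrow(E)), 1e-3)
  w <- pred^-4
  dimnames(w) <- dimnames(E)
  w
}

# Solve trigamma(x) = y by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-8) break
  }
  x
}

#' Moderated per-gene linear model fit
#'
#' Weighted least squares per gene followed by empirical-Bayes moderation of
#' the residual variances: the prior `(d0, s0^2)` is estimated by a
#' closed-form method of moments on the log residual variances, posterior
#' variances are `(d0 * s0^2 + d * s^2) / (d0 + d)`, and moderated
#' t-statistics use `d0 + d` degrees of freedom. With `moderate = FALSE`
#' ordinary t-statistics on `d` df are returned.
#'
#' @param E Expression matrix (genes x samples), e.g. log2-CPM.
#' @param design Numeric design matrix (samples x coefficients), full rank.
#' @param weights Optional positive weight matrix matching `E`; unit weights
#'   when `NULL`.
#' @param coef Column of `design` to test (name or index); defaults to the
#'   second column (the contrast after the intercept).
#' @param alpha Adjusted-p cutoff for the DE flag; default 0.05.
#' @param moderate Apply empirical-Bayes moderation (default `TRUE`).
#' @return An object of class `scz_de_fit`; use [tidy()] for the per-gene
#'   table (gene, log2fc, t, p, padj, mean_expr, de_flag) and [glance()] for
#'   the prior df/variance.
#' @export
fit_moderated <- function(E, design, weights = NULL, coef = 2L,
                          alpha = 0.05, moderate = TRUE) {
  n <- ncol(E); G <- nrow(E)
  if (nrow(design) != n) abort("design rows must match samples")
  p <- ncol(design)
  if (qr(design)$rank < p) abort("design matrix is rank deficient")
  d <- n - p
  if (d < 1L) abort("zero residual degrees of freedom")
  if (is.character(coef)) coef <- match(coef, colnames(design))
  if (is.na(coef) || coef < 1L || coef > p) abort("`coef` not found in design")
  if (is.null(weights)) weights <- matrix(1, G, n)
  if (any(weights <= 0)) abort("weights must be positive")

  beta <- numeric(G); s2 <- numeric(G); vunsc <- numeric(G)
  for (g in seq_len(G)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    Xw <- design * sw
    fit <- .lm.fit(Xw, E[g, ] * sw)
    beta[g] <- fit$coefficients[coef]
    s2[g] <- sum(fit$residuals^2) / d
    xtwx_inv <- chol2inv(chol(crossprod(Xw)))
    vunsc[g] <- xtwx_inv[coef, coef]
  }

  if (moderate) {
    s2_pos <- pmax(s2, 1e-10)
    z <- log(s2_pos)
    evar <- var(z) - trigamma(d / 2)
    if (is.finite(evar) && evar > 0) {
      d0 <- 2 * trigamma_inverse(evar)
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                     digamma(d0 / 2) - log(d0 / 2))
      s2_post <- (d0 * s0_sq + d * s2) / (d0 + d)
      df_total <- d0 + d
    } else {
      d0 <- Inf
      s0_sq <- exp(mean(z) - digamma(d / 2) + log(d / 2))
      s2_post <- rep(s0_sq, G)
      df_total <- Inf
    }
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_post <- s2
    df_total <- d
  }

  tt <- beta / sqrt(s2_post * vunsc)
  pval <- 2 * pt(-abs(tt), df = if (is.finite(df_total)) df_total else Inf)
  padj <- bh_adjust(pval)
  table <- tibble::tibble(
    gene = rownames(E) %||% as.character(seq_len(G)),
    log2fc = beta, t = tt, p = pval, padj = padj,
    mean_expr = rowMeans(E),
    de_flag = padj < alpha
  )
  structure(
    list(table = table, d0 = d0, s0_sq = s0_sq, df_residual = d,
         df_total = df_total, alpha = alpha, coef = colnames(design)[coef] %||% coef,
         moderated = moderate),
    class = "scz_de_fit"
  )
}

#' @export
tidy.scz_de_fit <- function(x, ...) x$table

#' @export
glance.scz_de_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$table), n_de = sum(x$table$de_flag),
                 d0 = x$d0, s0_sq = x$s0_sq, df_residual = x$df_residual,
                 moderated = x$moderated)
}

#' @export
print.scz_de_fit <- function(x, ...) {
  cat(sprintf("<scz_de_fit> %d genes, %d DE at padj < %.3g (prior df %.3g)\n",
              nrow(x$table), sum(x$table$de_flag), x$alpha, x$d0))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up adjusted p-values: sorted ascending, `p * n / rank`, monotonized
#' by a reverse cumulative minimum and capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  n <- length(p)
  if (n == 0L) return(numeric())
  o <- order(p)
  adj <- pmin(1, rev(cummin(rev(p[o] * n / seq_len(n)))))
  out <- numeric(n)
  out[o] <- adj
  out
}

de_table <- function(de) {
  if (inherits(de, "scz_de_fit")) de$table else tibble::as_tibble(de)
}

#' Count differentially expressed genes
#'
#' @param de A `scz_de_fit` or a DE table with `padj` and `log2fc` columns.
#' @param alpha BH-adjusted p cutoff (default 0.05).
#' @return Integer count of genes with `padj < alpha`.
#' @export
count_de <- function(de, alpha = 0.05) {
  tbl <- de_table(de)
  if (nrow(tbl) == 0L) return(0L)
  sum(tbl$padj < alpha)
}

#' @param threshold |log2FC| cutoff (default 1, i.e. a doubling).
#' @rdname count_de
#' @return `count_high_lfc()`: genes with `padj < alpha` and
#'   `|log2fc| > threshold`.
#' @export
count_high_lfc <- function(de, alpha = 0.05, threshold = 1) {
  tbl <- de_table(de)
  if (nrow(tbl) == 0L) return(0L)
  sum(tbl$padj < alpha & abs(tbl$log2fc) > threshold)
}

#' Differential expression of a case group against controls
#'
#' Convenience wrapper running the full stack (log2-CPM, precision weights,
#' moderated fit) for a labeled case group versus reference controls with
#' the standard covariates. Controls are the reference level, so positive
#' `log2fc` means higher expression in the case group.
#'
#' @param counts Count matrix covering at least the involved samples.
#' @param samples Sample tibble.
#' @param case_samples Character vector of case `sample_id`s, or `NULL` to
#'   use every `diagnosis == "scz"` sample.
#' @param covariates Covariate columns entered additively (default
#'   age, sex, race, rin).
#' @param moderate,alpha,prior Passed through to the underlying steps.
#' @return A `scz_de_fit`.
#' @export
run_de <- function(counts, samples, case_samples = NULL,
                   covariates = c("age", "sex", "race", "rin"),
                   moderate = TRUE, alpha = 0.05, prior = 0.5) {
  check_sample_table(samples, counts)
  if (is.null(case_samples)) {
    case_samples <- samples$sample_id[samples$diagnosis == "scz"]
  }
  ctrl <- samples$sample_id[samples$diagnosis == "control"]
  ctrl <- intersect(ctrl, colnames(counts))
  case_samples <- intersect(case_samples, colnames(counts))
  if (length(ctrl) == 0L) abort("run_de: no control samples available")
  if (length(case_samples) == 0L) abort("run_de: empty case group")
  use <- c(ctrl, case_samples)
  sub <- samples[match(use, samples$sample_id), , drop = FALSE]
  sub$group <- factor(ifelse(sub$sample_id %in% case_samples, "case", "control"),
                      levels = c("control", "case"))
  rhs <- paste(c("group", covariates), collapse = " + ")
  design <- model.matrix(stats::as.formula(paste("~", rhs)), data = as.data.frame(sub))
  E <- logcpm(counts[, use, drop = FALSE], prior = prior)
  w <- precision_weights(E, design)
  fit_moderated(E, design, weights = w, coef = "groupcase",
                alpha = alpha, moderate = moderate)
}
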
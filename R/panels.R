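# Neuroinflammation gene panels and the group-comparison statistics
# (per-group logFC tables, |logFC| one-way ANOVA with Tukey HSD, per-gene
# group-expression comparisons on log2(x + 1) normalized counts).

panel_categories <- c("complement", "microglia", "astrocyte",
                      "pro_inflammatory", "bmec", "chemokine", "peripheral")

#' Load gene panels
#'
#' Reads a panel CSV (`panel, category, gene, subgroup`). The shipped default
#' covers the seven neuroinflammation components (complement cascade,
#' microglial and astrocyte activation, pro-inflammatory mediators, brain
#' microvascular endothelium / BBB, chemokines, peripheral immune cells)
#' with gene symbols typed exactly as the source material prints them; a
#' sidecar file (`panel_symbol_notes.csv`) flags probable typos rather than
#' silently correcting them.
#'
#' @param path Panel CSV; default the file shipped with the package.
#' @return An `scz_panels` tibble.
#' @export
load_panels <- function(path = NULL) {
  path <- path %||% system.file("extdata", "neuroinflammation_panels.csv",
                                package = "scztype", mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("panel", "category", "gene")
  missing <- setdiff(need, names(tbl))
  if (length(missing)) abort(paste0("panel file lacks column(s): ", paste(missing, collapse = ", ")))
  if (!"subgroup" %in% names(tbl)) tbl$subgroup <- NA_character_
  bad <- setdiff(unique(tbl$category), panel_categories)
  if (length(bad)) abort(paste0("unknown panel category: ", paste(bad, collapse = ", ")))
  dup <- tbl |> dplyr::count(.data$panel, .data$gene) |> dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate gene '%s' within panel '%s'", dup$gene[1L], dup$panel[1L]))
  }
  if (nrow(tbl) == 0L) abort("panel file is empty")
  structure(tbl, class = c("scz_panels", class(tbl)))
}

#' @param panels An `scz_panels` tibble.
#' @rdname load_panels
#' @export
write_panels <- function(panels, path) {
  readr::write_csv(tibble::as_tibble(panels), path, progress = FALSE)
  invisible(path)
}

#' Per-group log fold changes for a gene panel
#'
#' Collects each panel gene's log2FC and DE flag from the per-group DE tables
#' (typically Pooled, Type1, Mix, Type2 — each versus controls). Panel genes
#' absent from the DE gene universe are reported via the `missing` attribute
#' and a message, never imputed.
#'
#' @param panel Tibble with a `gene` column (one panel, e.g. a filtered
#'   [load_panels()] result) or a character vector of genes.
#' @param de_tables Named list of `scz_de_fit`s or DE tables, one per group.
#' @return Long tibble (`gene`, `group`, `log2fc`, `de_flag`) with attribute
#'   `missing`.
#' @export
panel_logfc_table <- function(panel, de_tables) {
  genes <- if (is.data.frame(panel)) panel$gene else as.character(panel)
  if (is.null(names(de_tables))) abort("`de_tables` must be a named list (one DE table per group)")
  tbls <- purrr::map(de_tables, de_table)
  universe <- unique(unlist(purrr::map(tbls, "gene")))
  missing <- setdiff(genes, universe)
  present <- intersect(genes, universe)
  if (length(present) == 0L) abort("panel_logfc_table: no panel gene present in the DE tables")
  if (length(missing)) {
    inform(paste0("panel_logfc_table: missing from data: ", paste(missing, collapse = ", ")))
  }
  out <- purrr::imap_dfr(tbls, function(tbl, grp) {
    sub <- tbl[match(present, tbl$gene), , drop = FALSE]
    tibble::tibble(gene = present, group = grp,
                   log2fc = sub$log2fc, de_flag = sub$de_flag)
  })
  attr(out, "missing") <- missing
  out
}

#' One-way ANOVA with Tukey-Kramer HSD
#'
#' Computes the one-way ANOVA F statistic (`MS_between / MS_within`) and all
#' pairwise comparisons via the studentized-range distribution:
#' `q_ij = |mean_i - mean_j| / sqrt((MS_within / 2) * (1/n_i + 1/n_j))`,
#' with p-values from `ptukey(q, k, N - k)`. With zero within-group variance,
#' pairs with equal means get p = 1 and unequal means p = 0.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length; at least 2 groups with n >= 2.
#' @return An `scz_anova` list: `f_stat`, `df_between`, `df_within`, `p_f`
#'   (ANOVA p), and `comparisons` (tibble `group_a`, `group_b`, `diff`, `q`,
#'   `p_adj`).
#' @export
anova_tukey <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups[ok])
  ns <- table(groups)
  if (length(ns) < 2L) abort("anova_tukey: need at least 2 groups")
  if (any(ns < 2L)) abort("anova_tukey: every group needs at least 2 observations")
  k <- length(ns)
  N <- length(values)
  means <- tapply(values, groups, mean)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df_b <- k - 1L
  df_w <- N - k
  msw <- ssw / df_w
  f_stat <- if (msw > 0) (ssb / df_b) / msw else if (ssb > 0) Inf else 0
  p_f <- if (is.finite(f_stat)) pf(f_stat, df_b, df_w, lower.tail = FALSE) else 0
  if (!is.finite(f_stat) || (msw == 0 && ssb == 0)) p_f <- if (ssb == 0) 1 else 0

  pairs <- utils::combn(names(ns), 2L, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    d <- means[[pr[1L]]] - means[[pr[2L]]]
    if (msw > 0) {
      se <- sqrt((msw / 2) * (1 / ns[[pr[1L]]] + 1 / ns[[pr[2L]]]))
      q <- abs(d) / se
      p <- ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    } else {
      q <- if (d == 0) 0 else Inf
      p <- if (d == 0) 1 else 0
    }
    tibble::tibble(group_a = pr[1L], group_b = pr[2L], diff = unname(d),
                   q = unname(q), p_adj = unname(p))
  })
  structure(list(f_stat = f_stat, df_between = df_b, df_within = df_w,
                 p_f = p_f, group_means = means, group_sizes = as.vector(ns),
                 comparisons = comparisons),
            class = "scz_anova")
}

#' @export
tidy.scz_anova <- function(x, ...) x$comparisons

#' @export
glance.scz_anova <- function(x, ...) {
  tibble::tibble(f_stat = x$f_stat, df_between = x$df_between,
                 df_within = x$df_within, p_f = x$p_f)
}

#' @export
print.scz_anova <- function(x, ...) {
  cat(sprintf("<scz_anova> F(%d, %d) = %.4g, p = %.3g\n",
              x$df_between, x$df_within, x$f_stat, x$p_f))
  invisible(x)
}

#' Panel-level |log2FC| comparison across SCZ groups
#'
#' Treats the panel's genes as observations within each group and compares
#' absolute log2 fold changes across groups with [anova_tukey()] — the
#' panel-level test of whether one subtype (typically Type 2) shows globally
#' stronger expression shifts on the panel.
#'
#' @param logfc_table Long tibble from [panel_logfc_table()].
#' @return An `scz_anova`.
#' @export
panel_abs_lfc_anova <- function(logfc_table) {
  anova_tukey(abs(logfc_table$log2fc), logfc_table$group)
}

#' log2(x + 1) expression of size-factor-normalized counts
#'
#' The transformation used for the per-gene group boxplot comparisons.
#'
#' @param counts Count matrix.
#' @param sf Optional size factors (computed when `NULL`).
#' @return Matrix of `log2(normalized count + 1)` values.
#' @export
log2p1_expression <- function(counts, sf = NULL) {
  check_count_matrix(counts)
  sf <- sf %||% size_factors(counts)
  log2(sweep(counts, 2L, sf, "/") + 1)
}

#' Per-gene expression comparison across subject groups
#'
#' One-way ANOVA with Tukey HSD on a single gene's transformed expression
#' (e.g. from [log2p1_expression()]) across groups such as Control, Type1,
#' Mix, Type2.
#'
#' @param expr Expression matrix.
#' @param gene Gene identifier (row of `expr`).
#' @param groups Named vector or factor of group labels, names = sample IDs
#'   (samples absent from `expr` are ignored).
#' @return An `scz_anova`.
#' @export
gene_group_anova <- function(expr, gene, groups) {
  if (!gene %in% rownames(expr)) abort(sprintf("gene '%s' not in expression matrix", gene))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(expr)) abort("`groups` must be named by sample or match expr columns")
    names(groups) <- colnames(expr)
  }
  common <- intersect(colnames(expr), names(groups))
  anova_tukey(expr[gene, common], groups[common])
}
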
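# Two-cluster subtype discovery on adjusted expression, the DE-count
# labeling rule, and the cross-dataset discriminative gene list.

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  i <- sample.int(n, 1L)
  centers[1L, ] <- X[i, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1L, prob = prob)
    centers[j, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2))
  }
  centers
}

lloyd_kmeans <- function(X, k, max_iter = 100L) {
  centers <- kmeanspp_init(X, k)
  assign_old <- rep(0L, nrow(X))
  for (it in seq_len(max_iter)) {
    d2 <- sapply(seq_len(k), function(j) {
      rowSums((X - matrix(centers[j, ], nrow(X), ncol(X), byrow = TRUE))^2)
    })
    assign_new <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster with the farthest point
    for (j in seq_len(k)) {
      if (!any(assign_new == j)) {
        far <- which.max(d2[cbind(seq_len(nrow(X)), assign_new)])
        assign_new[far] <- j
      }
    }
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      centers[j, ] <- colMeans(X[assign_new == j, , drop = FALSE])
    }
  }
  d2 <- sapply(seq_len(k), function(j) {
    rowSums((X - matrix(centers[j, ], nrow(X), ncol(X), byrow = TRUE))^2)
  })
  inertia <- sum(d2[cbind(seq_len(nrow(X)), assign_old)])
  list(cluster = assign_old, inertia = inertia, centers = centers)
}

#' K-means clustering of case samples
#'
#' Lloyd's algorithm with k-means++ initialization, best of `n_starts`
#' restarts by within-cluster sum of squares. Feature genes are standardized
#' (mean 0, SD 1 across the clustered samples) before Euclidean distances
#' are computed; constant genes are left at zero. The pipeline is
#' two-cluster by design, so `k` must be 2.
#'
#' @param expr Adjusted expression matrix (genes x samples); columns are the
#'   case samples to cluster.
#' @param genes Feature gene identifiers (default: all rows of `expr`).
#' @param k Number of clusters; only 2 is accepted.
#' @param seed Integer seed (mandatory; clustering must be reproducible).
#' @param n_starts Number of restarts; default 25.
#' @return An `scz_clusters` object: tibble of assignments via [tidy()],
#'   plus inertia, the feature set and the RNG settings.
#' @export
cluster_cases <- function(expr, genes = NULL, k = 2, seed, n_starts = 25) {
  if (k != 2) abort("cluster_cases: the subtype pipeline is two-cluster by design (k = 2).")
  if (missing(seed) || is.null(seed)) abort("cluster_cases: `seed` is required.")
  genes <- genes %||% rownames(expr)
  if (length(genes) == 0L) abort("cluster_cases: empty feature set")
  missing_genes <- setdiff(genes, rownames(expr))
  if (length(missing_genes)) {
    abort(paste0("cluster_cases: feature gene(s) absent from expression matrix: ",
                 paste(head(missing_genes, 5L), collapse = ", "),
                 if (length(missing_genes) > 5L) sprintf(" (+%d more)", length(missing_genes) - 5L) else ""))
  }
  if (ncol(expr) < 2L * k) abort("cluster_cases: need at least 2*k case samples")
  X <- t(expr[genes, , drop = FALSE])
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      res <- lloyd_kmeans(X, k)
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })
  structure(
    list(assignments = tibble::tibble(sample_id = colnames(expr),
                                      cluster = best$cluster),
         inertia = best$inertia, features = genes, k = k,
         seed = as.integer(seed), n_starts = n_starts,
         labels = NULL, de_counts = NULL),
    class = "scz_clusters"
  )
}

#' @export
tidy.scz_clusters <- function(x, ...) {
  out <- x$assignments
  if (!is.null(x$labels)) out$subtype <- unname(x$labels[as.character(out$cluster)])
  out
}

#' @export
glance.scz_clusters <- function(x, ...) {
  tibble::tibble(k = x$k, n_samples = nrow(x$assignments),
                 n_features = length(x$features), inertia = x$inertia,
                 n_starts = x$n_starts, labeled = !is.null(x$labels))
}

#' @export
print.scz_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat(sprintf("<scz_clusters> k=%d, sizes %s, inertia %.4g%s\n", x$k,
              paste(sizes, collapse = "/"), x$inertia,
              if (is.null(x$labels)) "" else
                paste0(", labels: ", paste(names(x$labels), x$labels, sep = "=", collapse = ", "))))
  invisible(x)
}

# Build a labeled cluster object directly from known subtype labels
# (used to run downstream stages against planted truth).
clusters_from_labels <- function(sample_ids, subtypes) {
  stopifnot(length(sample_ids) == length(subtypes),
            all(subtypes %in% c("Type1", "Type2")))
  cl <- ifelse(subtypes == "Type1", 1L, 2L)
  structure(
    list(assignments = tibble::tibble(sample_id = sample_ids, cluster = cl),
         inertia = NA_real_, features = character(), k = 2L,
         seed = NA_integer_, n_starts = 0L,
         labels = c(`1` = "Type1", `2` = "Type2"), de_counts = NULL),
    class = "scz_clusters"
  )
}

#' Label the two clusters as Type 1 / Type 2 by DE-gene count
#'
#' Runs the full differential-expression stack for each cluster against
#' controls; the cluster with fewer significant genes becomes Type 1, the
#' other Type 2 (the defining labeling rule of the subtypes). Ties are broken toward the
#' cluster with smaller mean |log2FC|, with a message.
#'
#' @param clusters An `scz_clusters` from [cluster_cases()].
#' @param counts Count matrix covering the clustered cases and the controls.
#' @param samples Sample tibble.
#' @param covariates Covariates for the DE model.
#' @param alpha DE significance cutoff.
#' @return The `scz_clusters` with `labels`, `de_counts` and per-cluster DE
#'   fits attached.
#' @export
label_subtypes <- function(clusters, counts, samples,
                           covariates = c("age", "sex", "race", "rin"),
                           alpha = 0.05) {
  stopifnot(inherits(clusters, "scz_clusters"))
  fits <- purrr::map(1:2, function(j) {
    ids <- clusters$assignments$sample_id[clusters$assignments$cluster == j]
    run_de(counts, samples, case_samples = ids, covariates = covariates, alpha = alpha)
  })
  n_de <- purrr::map_int(fits, count_de, alpha = alpha)
  if (n_de[1L] != n_de[2L]) {
    type1 <- which.min(n_de)
  } else {
    mean_abs <- purrr::map_dbl(fits, ~ mean(abs(.x$table$log2fc)))
    type1 <- which.min(mean_abs)
    inform(sprintf("label_subtypes: DE-count tie (%d); broke toward smaller mean |log2FC|", n_de[1L]))
  }
  labels <- c("Type2", "Type2"); labels[type1] <- "Type1"
  names(labels) <- c("1", "2")
  clusters$labels <- labels
  clusters$de_counts <- setNames(n_de, labels)
  clusters$de_fits <- setNames(fits, labels)
  clusters
}

#' Subject-level subtype labels from a labeled clustering
#'
#' @param clusters A labeled `scz_clusters`.
#' @param samples Sample tibble (maps sample IDs to subjects and datasets).
#' @return Tibble with `subject_id`, `dataset_id`, `label`.
#' @export
subtype_labels <- function(clusters, samples) {
  stopifnot(inherits(clusters, "scz_clusters"))
  if (is.null(clusters$labels)) abort("clusters are unlabeled; run label_subtypes() first")
  tidy(clusters) |>
    dplyr::left_join(dplyr::select(samples, "sample_id", "subject_id", "dataset_id"),
                     by = "sample_id") |>
    dplyr::select("subject_id", "dataset_id", label = "subtype")
}

#' Derive the discriminative gene list across datasets
#'
#' Per dataset, the candidate set is the intersection of (i) genes flagged DE
#' in Type 2 versus controls and (ii) genes whose adjusted expression differs
#' between Type 1 and Type 2 cases by a Welch t-test at `p < alpha`. The
#' gene list is the intersection of the candidate sets over all datasets
#' (override with `min_datasets` to require membership in at least that many).
#'
#' @param datasets Named list, one element per dataset, each a list with
#'   `de_type2` (fit or DE table for Type 2 vs controls), `expr` (adjusted
#'   expression matrix over case samples), and `clusters` (labeled
#'   `scz_clusters`).
#' @param alpha Welch t-test cutoff (default 0.05).
#' @param min_datasets Required number of contributing datasets (default:
#'   all of them).
#' @return An `scz_gene_list`: tibble with `gene` plus one logical
#'   membership column per dataset; `genes()`-style access via `$gene`.
#' @export
derive_gene_list <- function(datasets, alpha = 0.05, min_datasets = NULL) {
  if (length(datasets) == 0L) abort("derive_gene_list: no datasets supplied")
  if (is.null(names(datasets))) names(datasets) <- paste0("dataset", seq_along(datasets))
  if (length(datasets) == 1L) {
    warn("derive_gene_list: single dataset supplied; returning its candidate set")
  }
  min_datasets <- min_datasets %||% length(datasets)
  candidates <- purrr::imap(datasets, function(d, nm) {
    cl <- tidy(d$clusters)
    if (is.null(cl$subtype) || length(unique(cl$subtype)) < 2L) {
      abort(sprintf("derive_gene_list: dataset '%s' lacks both subtypes", nm))
    }
    t1 <- cl$sample_id[cl$subtype == "Type1"]
    t2 <- cl$sample_id[cl$subtype == "Type2"]
    de_tbl <- de_table(d$de_type2)
    de_genes <- de_tbl$gene[de_tbl$de_flag]
    expr <- d$expr
    pv <- row_welch_p(expr[, t1, drop = FALSE], expr[, t2, drop = FALSE])
    tt_genes <- rownames(expr)[pv < alpha]
    intersect(de_genes, tt_genes)
  })
  universe <- sort(unique(unlist(candidates)))
  member <- purrr::map(candidates, ~ universe %in% .x)
  hits <- Reduce(`+`, member)
  tbl <- tibble::tibble(gene = universe, !!!member)[hits >= min_datasets, , drop = FALSE]
  structure(tbl, class = c("scz_gene_list", class(tbl)),
            alpha = alpha, min_datasets = min_datasets)
}

#' Re-cluster cases restricted to a gene list
#'
#' Identical to [cluster_cases()] with the feature set taken from a derived
#' gene list; genes absent from `expr` raise an error naming them.
#'
#' @param expr Adjusted expression matrix over case samples.
#' @param gene_list An `scz_gene_list` or character vector of genes.
#' @param seed Integer seed.
#' @param n_starts Restarts (default 25).
#' @return An `scz_clusters`.
#' @export
recluster_with_list <- function(expr, gene_list, seed, n_starts = 25) {
  genes <- if (inherits(gene_list, "scz_gene_list")) gene_list$gene else as.character(gene_list)
  cluster_cases(expr, genes = genes, k = 2, seed = seed, n_starts = n_starts)
}

#' Write / read a gene list as TSV
#'
#' @param gene_list An `scz_gene_list`.
#' @param path TSV path.
#' @export
write_gene_list <- function(gene_list, path) {
  readr::write_tsv(tibble::as_tibble(gene_list), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  structure(tbl, class = c("scz_gene_list", class(tbl)))
}
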
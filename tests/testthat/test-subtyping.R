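make_blobs <- function(n_per = 10, n_genes = 40, delta = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    x1 <- matrix(rnorm(n_genes * n_per, 0, sd), n_genes)
    x2 <- matrix(rnorm(n_genes * n_per, delta, sd), n_genes)
    expr <- cbind(x1, x2)
    dimnames(expr) <- list(sprintf("g%03d", seq_len(n_genes)),
                           sprintf("s%03d", seq_len(2 * n_per)))
    expr
  })
}

test_that("well-separated blobs are recovered perfectly for any seed", {
  expr <- make_blobs()
  truth <- rep(1:2, each = 10)
  for (seed in c(1, 7, 99)) {
    cl <- cluster_cases(expr, seed = seed)
    expect_equal(adjusted_rand_index(cl$assignments$cluster, truth), 1)
  }
})

test_that("the clustering matches the exhaustive best two-partition on 6 points", {
  withr::with_seed(4, {
    expr <- matrix(rnorm(12, 0, 2), nrow = 2,
                   dimnames = list(c("g1", "g2"), sprintf("s%d", 1:6)))
  })
  cl <- cluster_cases(expr, seed = 1, n_starts = 50)
  # brute force over all nonempty bipartitions of 6 points, on the same
  # standardized feature matrix the implementation uses
  X <- scale(t(expr))
  inertia_of <- function(part) {
    sum(sapply(unique(part), function(j) {
      xs <- X[part == j, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }))
  }
  best <- Inf
  for (code in 1:(2^5 - 1)) {
    part <- c(1L, as.integer(intToBits(code))[1:5] + 1L)
    if (length(unique(part)) == 2L) best <- min(best, inertia_of(part))
  }
  expect_equal(cl$inertia, best, tolerance = 1e-10)
})

test_that("clustering is deterministic given a seed and k is pinned at 2", {
  expr <- make_blobs(delta = 2, seed = 3)
  a <- cluster_cases(expr, seed = 42)
  b <- cluster_cases(expr, seed = 42)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$inertia, b$inertia)
  expect_error(cluster_cases(expr, k = 3, seed = 1), "k = 2")
  expect_error(cluster_cases(expr, seed = NULL), "seed")
  expect_error(cluster_cases(expr, genes = c("g001", "nope"), seed = 1), "nope")
  expect_error(cluster_cases(expr, genes = character(), seed = 1), "empty feature set")
})

test_that("more restarts never worsen the inertia", {
  expr <- make_blobs(delta = 1.2, sd = 1.5, seed = 9)
  i1 <- cluster_cases(expr, seed = 5, n_starts = 1)$inertia
  i25 <- cluster_cases(expr, seed = 5, n_starts = 25)$inertia
  expect_lte(i25, i1 + 1e-12)
})

test_that("inertia is comparable with the reference k-means implementation", {
  expr <- make_blobs(delta = 1.5, sd = 1.3, seed = 12)
  cl <- cluster_cases(expr, seed = 2, n_starts = 25)
  X <- scale(t(expr))
  km <- withr::with_seed(2, stats::kmeans(X, centers = 2, nstart = 25))
  expect_lt(abs(cl$inertia - km$tot.withinss) / km$tot.withinss, 0.02)
})

test_that("the DE-count rule labels the null cluster Type 1", {
  cfg <- tiny_config(seed = 33, n_cohorts = 1, n_genes = 800, n_de_genes = 300,
                     n_controls = 40, n_type1 = 15, n_type2 = 15, n_mix = 0,
                     lfc_range = c(1, 2.5))
  sim <- quietly(simulate_cohorts(cfg))
  cnt <- quietly(filter_low_expression(sim$counts[[1]]))
  samples <- sim$samples
  expr <- adjust_covariates(vst_transform(cnt), samples, keep = ~diagnosis)
  cases <- samples$sample_id[samples$diagnosis == "scz"]
  cl <- cluster_cases(expr[, cases], seed = 1)
  cl <- quietly(label_subtypes(cl, cnt, samples))
  labeled <- tidy(cl) |>
    dplyr::left_join(samples[, c("sample_id", "true_label")], by = "sample_id")
  # planted-null subjects end up in the cluster labeled Type1
  expect_gt(mean(labeled$subtype[labeled$true_label == "Type1"] == "Type1"), 0.9)
  expect_gt(mean(labeled$subtype[labeled$true_label == "Type2"] == "Type2"), 0.9)
  # labeling guarantees count_de(Type1) <= count_de(Type2)
  expect_lte(cl$de_counts[["Type1"]], cl$de_counts[["Type2"]])

  # label invariance under swapped cluster indices
  swapped <- cl
  swapped$assignments$cluster <- 3L - swapped$assignments$cluster
  swapped$labels <- NULL; swapped$de_counts <- NULL; swapped$de_fits <- NULL
  swapped <- quietly(label_subtypes(swapped, cnt, samples))
  merged <- dplyr::inner_join(tidy(cl), tidy(swapped), by = "sample_id")
  expect_identical(merged$subtype.x, merged$subtype.y)
})

test_that("gene-list derivation intersects candidates across datasets", {
  expr <- make_blobs(n_per = 6, n_genes = 10, seed = 5)
  cl <- clusters_from_labels_for_test(colnames(expr), rep(c("Type1", "Type2"), each = 6))
  mk_de <- function(genes, flags) {
    tibble::tibble(gene = genes, log2fc = 1, t = 1, p = 0.01,
                   padj = ifelse(flags, 0.01, 0.9), mean_expr = 5, de_flag = flags)
  }
  genes <- rownames(expr)
  # dataset A flags g1..g5, dataset B flags g6..g10: disjoint candidates
  dsA <- list(de_type2 = mk_de(genes, genes %in% genes[1:5]), expr = expr, clusters = cl)
  dsB <- list(de_type2 = mk_de(genes, genes %in% genes[6:10]), expr = expr, clusters = cl)
  gl <- derive_gene_list(list(A = dsA, B = dsB))
  expect_identical(nrow(gl), 0L)

  # single dataset: candidate set returned with a warning
  expect_warning(gl1 <- derive_gene_list(list(A = dsA)), "single dataset")
  expect_true(all(gl1$gene %in% genes[1:5]))

  # min_datasets override: union-like behavior at 1
  gl2 <- derive_gene_list(list(A = dsA, B = dsB), min_datasets = 1)
  expect_setequal(gl2$gene, genes)

  # a dataset lacking both subtypes errors
  cl1 <- clusters_from_labels_for_test(colnames(expr), rep("Type1", 12))
  dsC <- list(de_type2 = mk_de(genes, TRUE), expr = expr, clusters = cl1)
  expect_error(derive_gene_list(list(A = dsA, C = dsC)), "lacks both subtypes")
})

test_that("planted discriminative genes are recovered across cohorts", {
  cfg <- tiny_config(seed = 55, n_cohorts = 3, n_genes = 1000, n_de_genes = 100,
                     n_controls = 60, n_type1 = 30, n_type2 = 30, n_mix = 0,
                     lfc_range = c(1, 2.5))
  sim <- quietly(simulate_cohorts(cfg))
  datasets <- purrr::imap(sim$counts, function(cnt, id) {
    samples <- dplyr::filter(sim$samples, .data$dataset_id == id)
    cnt <- quietly(filter_low_expression(cnt))
    expr <- adjust_covariates(vst_transform(cnt), samples, keep = ~diagnosis)
    cases <- samples$sample_id[samples$diagnosis == "scz"]
    truth_lab <- samples$true_label[match(cases, samples$sample_id)]
    cl <- clusters_from_labels_for_test(cases, truth_lab)
    de2 <- quietly(run_de(cnt, samples, case_samples = cases[truth_lab == "Type2"]))
    list(de_type2 = de2, expr = expr[, cases], clusters = cl)
  })
  gl <- derive_gene_list(datasets)
  truth_genes <- sim$truth$de_genes$gene
  recall <- mean(truth_genes %in% gl$gene)
  precision <- mean(gl$gene %in% truth_genes)
  expect_gte(recall, 0.7)
  expect_gte(precision, 0.8)
})

test_that("reclustering with a list equals clustering on the same features", {
  expr <- make_blobs(seed = 8)
  gl <- rownames(expr)[1:20]
  a <- recluster_with_list(expr, gl, seed = 3)
  b <- cluster_cases(expr, genes = gl, seed = 3)
  expect_identical(a$assignments, b$assignments)
  expect_error(recluster_with_list(expr, c("g001", "absent"), seed = 1), "absent")
})

test_that("gene lists round-trip through TSV", {
  tbl <- structure(tibble::tibble(gene = c("gA", "gB"), d1 = c(TRUE, FALSE),
                                  d2 = c(TRUE, TRUE)),
                   class = c("scz_gene_list", class(tibble::tibble())))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(tbl, path)
  back <- read_gene_list(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(tbl))
})
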
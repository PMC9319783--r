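test_that("the shipped panel file covers all seven components and validates", {
  panels <- load_panels()
  expect_setequal(unique(panels$category),
                  c("complement", "microglia", "astrocyte", "pro_inflammatory",
                    "bmec", "chemokine", "peripheral"))
  expect_false(any(duplicated(panels[, c("panel", "gene")])))
  expect_true(all(c("C4A", "SERPINA3", "CX3CR1", "CXCL1", "ICAM1", "S100A8") %in% panels$gene))

  path <- withr::local_tempfile(fileext = ".csv")
  write_panels(panels, path)
  expect_equal(tibble::as_tibble(load_panels(path)), tibble::as_tibble(panels))

  dup <- dplyr::bind_rows(panels, panels[1, ])
  write_panels(dup, path)
  expect_error(load_panels(path), "duplicate gene")
  bad <- dplyr::mutate(panels, category = replace(category, 1, "cytokines"))
  write_panels(bad, path)
  expect_error(load_panels(path), "unknown panel category")
})

test_that("panel logFC tables report missing genes and never impute them", {
  de <- list(
    Type1 = tibble::tibble(gene = c("A", "B"), log2fc = c(0.1, -0.2),
                           p = 0.5, padj = 0.9, de_flag = FALSE),
    Type2 = tibble::tibble(gene = c("A", "B"), log2fc = c(1.5, 2.0),
                           p = 0.001, padj = 0.01, de_flag = TRUE))
  expect_message(tbl <- panel_logfc_table(c("A", "B", "ZZZ"), de), "ZZZ")
  expect_identical(attr(tbl, "missing"), "ZZZ")
  expect_identical(nrow(tbl), 4L)
  expect_false("ZZZ" %in% tbl$gene)
  expect_error(panel_logfc_table("ZZZ", de), "no panel gene")
})

test_that("panel logFC recovers planted group effects from the DE stack", {
  spike <- c("C4A", "C4B", "GFAP", "SERPINA3", "ICAM1", "CXCL1", "CD14", "FTL")
  cfg <- tiny_config(seed = 61, n_cohorts = 1, n_genes = 1000, n_de_genes = 8,
                     lfc_range = c(1.5, 1.5), n_controls = 50, n_type1 = 25,
                     n_type2 = 25, n_mix = 0, panel_spike = spike)
  sim <- quietly(simulate_cohorts(cfg))
  cnt <- sim$counts[[1]]
  samples <- sim$samples
  grab <- function(lab) samples$sample_id[samples$true_label == lab]
  de <- list(Type1 = quietly(run_de(cnt, samples, case_samples = grab("Type1"))),
             Type2 = quietly(run_de(cnt, samples, case_samples = grab("Type2"))))
  tbl <- panel_logfc_table(spike, de)
  t2 <- tbl[tbl$group == "Type2", ]
  t1 <- tbl[tbl$group == "Type1", ]
  # planted signed |log2FC| = 1.5 in Type 2 only
  expect_equal(mean(abs(t2$log2fc)), 1.5, tolerance = 0.2)
  expect_lt(mean(abs(t1$log2fc)), 0.3)
  expect_true(all(t2$de_flag))
  an <- panel_abs_lfc_anova(tbl)
  t2all <- an$comparisons[an$comparisons$group_a == "Type2" | an$comparisons$group_b == "Type2", ]
  expect_true(all(t2all$p_adj < 0.05))
})

test_that("anova_tukey handles degenerate inputs explicitly", {
  same <- anova_tukey(rep(5, 9), rep(c("a", "b", "c"), each = 3))
  expect_equal(same$f_stat, 0)
  expect_equal(same$p_f, 1)
  expect_true(all(same$comparisons$p_adj == 1))

  sep <- anova_tukey(rep(c(1, 2), each = 3), rep(c("a", "b"), each = 3))
  expect_true(is.infinite(sep$f_stat))
  expect_equal(sep$p_f, 0)
  expect_true(all(sep$comparisons$p_adj == 0))

  expect_error(anova_tukey(1:4, rep("a", 4)), "2 groups")
  expect_error(anova_tukey(1:4, c("a", "a", "a", "b")), "at least 2 observations")
})

test_that("with two equal-sized groups Tukey reduces to the pooled t-test", {
  withr::with_seed(20, {
    for (rep in 1:25) {
      x <- rnorm(6); y <- rnorm(6, mean = runif(1, -1, 1))
      res <- anova_tukey(c(x, y), rep(c("x", "y"), each = 6))
      tt <- stats::t.test(x, y, var.equal = TRUE)
      expect_lt(abs(res$comparisons$p_adj - tt$p.value), 1e-6)
    }
  })
})

test_that("F and Tukey p-values match the aov/TukeyHSD oracle", {
  withr::with_seed(30, {
    for (rep in 1:10) {
      v <- rnorm(15, mean = rep(runif(3, 0, 2), each = 5))
      g <- rep(c("g1", "g2", "g3"), each = 5)
      res <- anova_tukey(v, g)
      fit <- stats::aov(v ~ g)
      expect_equal(res$f_stat, summary(fit)[[1]]$`F value`[1], tolerance = 1e-10)
      hsd <- stats::TukeyHSD(fit)$g
      ours <- setNames(res$comparisons$p_adj,
                       paste(res$comparisons$group_a, res$comparisons$group_b, sep = "-"))
      for (pair in rownames(hsd)) {
        parts <- strsplit(pair, "-")[[1]]
        key <- if (paste(parts[1], parts[2], sep = "-") %in% names(ours))
          paste(parts[1], parts[2], sep = "-") else paste(parts[2], parts[1], sep = "-")
        expect_equal(unname(ours[key]), unname(hsd[pair, "p adj"]), tolerance = 1e-8)
      }
    }
  })
})

test_that("Tukey p-values dominate unadjusted pairwise t-tests for k > 2", {
  withr::with_seed(40, {
    for (rep in 1:10) {
      v <- rnorm(20, mean = rep(runif(4, 0, 1), each = 5))
      g <- rep(letters[1:4], each = 5)
      res <- anova_tukey(v, g)
      for (i in seq_len(nrow(res$comparisons))) {
        a <- v[g == res$comparisons$group_a[i]]
        b <- v[g == res$comparisons$group_b[i]]
        expect_gte(res$comparisons$p_adj[i] + 1e-12,
                   stats::t.test(a, b, var.equal = TRUE)$p.value)
      }
    }
  })
})

test_that("anova_tukey is invariant to group order and constant shifts", {
  withr::with_seed(50, {
    v <- rnorm(18, rep(c(0, 0.5, 1.5), each = 6))
    g <- rep(c("a", "b", "c"), each = 6)
    r1 <- anova_tukey(v, g)
    perm <- sample.int(18)
    r2 <- anova_tukey(v[perm], g[perm])
    r3 <- anova_tukey(v + 100, g)
    expect_equal(r1$f_stat, r2$f_stat, tolerance = 1e-12)
    expect_equal(r1$f_stat, r3$f_stat, tolerance = 1e-9)
    expect_equal(dplyr::arrange(r1$comparisons, group_a, group_b)$p_adj,
                 dplyr::arrange(r2$comparisons, group_a, group_b)$p_adj,
                 tolerance = 1e-12)
  })
})

test_that("per-gene group comparisons flag only truly shifted genes", {
  withr::with_seed(60, {
    expr <- matrix(rnorm(2 * 80, mean = 5, sd = 0.4), nrow = 2,
                   dimnames = list(c("hit", "null"), sprintf("s%02d", 1:80)))
    groups <- setNames(rep(c("Control", "Type1", "Mix", "Type2"), each = 20),
                       colnames(expr))
    expr["hit", groups == "Type2"] <- expr["hit", groups == "Type2"] + 1
    hit <- gene_group_anova(expr, "hit", groups)
    t2 <- hit$comparisons[hit$comparisons$group_a == "Type2" |
                            hit$comparisons$group_b == "Type2", ]
    expect_true(all(t2$p_adj < 0.05))
    null <- gene_group_anova(expr, "null", groups)
    expect_gt(null$p_f, 0.01)
    expect_error(gene_group_anova(expr, "absent", groups), "absent")
  })
})
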
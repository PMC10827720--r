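test_that("estimate_mi matches forced-diagonal and closed-form values", {
  # y = x with n = 80 gives B = 4 equal-frequency bins and a diagonal
  # joint: MI = ln 4 exactly (the estimate is clamped at ln B).
  x <- runif(80)
  expect_equal(estimate_mi(x, x), log(4), tolerance = 1e-12)

  set.seed(2024)
  rho <- 0.9
  z <- rnorm(1e4)
  y <- rho * z + sqrt(1 - rho^2) * rnorm(1e4)
  expect_lt(abs(estimate_mi(z, y) - gaussian_mi(rho)), 0.05)
})

test_that("estimate_mi is symmetric and monotone-invariant", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(150); y <- rnorm(150)
    expect_lt(abs(estimate_mi(x, y) - estimate_mi(y, x)), 1e-12)
    # strictly monotone transforms leave ranks, hence MI, unchanged
    expect_identical(estimate_mi(exp(x), y^3 + 5 * y), estimate_mi(x, y))
  }
})

test_that("estimate_mi enforces its preconditions", {
  expect_error(estimate_mi(rep(1, 50), rnorm(50)), "constant")
  expect_error(estimate_mi(rnorm(10), rnorm(10)), "at least 20")
  expect_error(estimate_mi(rnorm(30), rnorm(31)), "equal length")
  expect_error(estimate_mi(c(NA, rnorm(29)), rnorm(30)), "finite")
})

test_that("independent pairs fall below the null's upper tail", {
  set.seed(31)
  x <- rnorm(1000); y <- rnorm(1000)
  null <- replicate(200, estimate_mi(x, sample(y)))
  expect_lt(estimate_mi(x, y), quantile(null, 0.99))
})

test_that("build_null is deterministic and validates n_perm", {
  expr <- cached("null_expr", {
    set.seed(11)
    tiny_expr(matrix(rnorm(50 * 60), 50, 60))
  })
  x <- cached("null_x", { set.seed(12); rnorm(60) })
  cfg <- regulon_config(n_perm = 200, seed = 99)
  n1 <- build_null(x, expr, cfg)
  n2 <- build_null(x, expr, cfg)
  expect_identical(n1$samples, n2$samples)
  expect_error(regulon_config(n_perm = 50), "n_perm")
})

test_that("mi_pvalue is calibrated, monotone and tail-extrapolated", {
  expr <- cached("null_expr", {
    set.seed(11)
    tiny_expr(matrix(rnorm(50 * 60), 50, 60))
  })
  x <- cached("null_x", { set.seed(12); rnorm(60) })
  null <- build_null(x, expr, regulon_config(n_perm = 500, seed = 99))

  expect_gte(mi_pvalue(0, null), 0.5)
  mx <- max(null$samples)
  expect_lt(mi_pvalue(mx + 0.01, null), 1 / null$n_perm)
  # monotone: p(mi1) >= p(mi2) whenever mi1 <= mi2
  grid <- seq(0, mx + 1, length.out = 200)
  p <- mi_pvalue(grid, null)
  expect_true(all(diff(p) <= 0))
  # strictly decreasing in the extrapolated tail
  tail_grid <- seq(mx + 1e-6, mx + 2, length.out = 50)
  expect_true(all(diff(mi_pvalue(tail_grid, null)) < 0))
})

test_that("type-I error of the p <= alpha rule matches alpha", {
  # Rank-based MI on tie-free data has a universal null given n, so one
  # pooled permutation null calibrates independent draws exactly.
  set.seed(55)
  n <- 100   # B = 4: the plug-in statistic is effectively tie-free here
  expr <- tiny_expr(matrix(rnorm(40 * n), 40, n))
  x <- rnorm(n)
  null <- build_null(x, expr, regulon_config(n_perm = 1000, seed = 3))
  p <- replicate(1000, mi_pvalue(
    estimate_mi(x, rnorm(n), correction = "none"), null))
  rate <- mean(p <= 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000) + 0.005)
})

test_that("planted targets are recovered with few false positives", {
  recalls <- fps <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n <- 500
    tf <- rnorm(n)
    true_targets <- sprintf("T%03d", 1:50)
    noise_genes <- sprintf("N%03d", 1:950)
    vals <- rbind(
      t(vapply(1:50, function(i) 0.8 * tf + rnorm(n, 0, 0.5), numeric(n))),
      matrix(rnorm(950 * n), 950, n))
    rownames(vals) <- c(true_targets, noise_genes)
    colnames(vals) <- sprintf("s%d", 1:n)
    expr <- expression_matrix(vals, "gene", log_transformed = TRUE)
    cand <- infer_isoform_targets(tf, expr,
                                  regulon_config(alpha = 1e-6, n_perm = 500,
                                                 seed = s))
    recalls[s] <- mean(true_targets %in% cand$gene_id)
    fps[s] <- sum(cand$gene_id %in% noise_genes)
  }
  expect_gte(mean(recalls), 0.9)
  expect_lte(mean(fps), 2)
})

test_that("target screen honors exclusion and extreme thresholds", {
  set.seed(9)
  expr <- tiny_expr(matrix(rnorm(30 * 100), 30, 100))
  tf <- expr$values[1, ] + rnorm(100, 0, 0.1)
  cfg <- regulon_config(alpha = 1e-6, n_perm = 200, seed = 1)
  cand <- infer_isoform_targets(tf, expr, cfg, exclude = "g1")
  expect_false("g1" %in% cand$gene_id)
  # pure noise at an unreachable alpha -> empty list
  cand0 <- infer_isoform_targets(rnorm(100), expr,
                                 regulon_config(alpha = 1e-130, n_perm = 200,
                                                seed = 2))
  expect_equal(nrow(cand0), 0L)
  expect_error(infer_isoform_targets(rep(1, 100), expr, cfg), "constant")
})

test_that("annotate_mode_weight assigns signed Spearman weights", {
  set.seed(4)
  tf <- rnorm(50)
  vals <- rbind(2 * tf, -tf, tf + rnorm(50, 0, 0.8))
  expr <- tiny_expr(vals, genes = c("up", "down", "noisy"))
  cand <- data.frame(gene_id = c("up", "down", "noisy"),
                     mi = c(1, 1, 0.5), p_value = 0)
  reg <- annotate_mode_weight(tf, expr, cand, tf_id = "TF")
  t <- reg$targets
  expect_equal(t$mode[t$gene_id == "up"], 1)
  expect_equal(t$weight[t$gene_id == "up"], 1)
  expect_equal(t$mode[t$gene_id == "down"], -1)
  expect_equal(t$weight[t$gene_id == "down"], 1)
  expect_true(all(t$weight > 0 & t$weight <= 1))
})

test_that("union_regulons keeps the best entry per gene", {
  mk <- function(genes, weights, mis = rep(0.5, length(genes)))
    regulon("TF", data.frame(gene_id = genes, mode = 1, weight = weights,
                             mi = mis, p_value = 1e-10))
  u <- union_regulons(list(mk(c("g1", "g2"), c(0.5, 0.4)),
                           mk(c("g2", "g3"), c(0.7, 0.6))), "TF")
  expect_setequal(u$targets$gene_id, c("g1", "g2", "g3"))
  expect_equal(u$targets$weight[u$targets$gene_id == "g2"], 0.7)
  # union of one regulon is itself
  one <- mk(c("a", "b"), c(0.3, 0.9))
  expect_equal(union_regulons(list(one), "TF")$targets[
    order(union_regulons(list(one), "TF")$targets$gene_id), ],
    one$targets[order(one$targets$gene_id), ], ignore_attr = TRUE)
  expect_error(regulon("TF", data.frame(gene_id = "TF", mode = 1,
                                        weight = 0.5, mi = 1, p_value = 0)),
               "own TF")
})

test_that("regulon TSV round-trips", {
  reg <- regulon("TFX", data.frame(gene_id = c("a", "b"), mode = c(1, -1),
                                   weight = c(0.25, 1), mi = c(0.9, 0.7),
                                   p_value = c(1e-12, 1e-8)))
  path <- tempfile(fileext = ".tsv")
  write_regulons(reg, path)
  back <- read_regulons(path)[["TFX"]]
  expect_equal(back$targets, reg$targets, tolerance = 1e-12)
})
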
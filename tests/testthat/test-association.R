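test_that("welch_t matches the closed-form Satterthwaite oracle", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 3, 4, 5, 6)
  w <- welch_t(x, y)
  o <- welch_oracle(x, y)
  expect_equal(w$t, o$t, tolerance = 1e-12)
  expect_equal(w$df, o$df, tolerance = 1e-12)
  expect_equal(w$p, o$p, tolerance = 1e-12)

  # identical samples -> t = 0, p = 1
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # antisymmetry
  sw <- welch_t(y, x)
  expect_equal(sw$t, -w$t)
  expect_equal(sw$p, w$p)

  expect_error(welch_t(rep(1, 5), rep(2, 5)), "zero variance")
  expect_error(welch_t(1, c(1, 2)), "n >= 2")
})

test_that("welch reduces to Student t for equal n and equal variances", {
  set.seed(6)
  x <- rnorm(20); y <- rnorm(20)
  y <- (y - mean(y)) / sd(y) * sd(x) + mean(y)   # force equal variance
  w <- welch_t(x, y)
  st <- t.test(x, y, var.equal = TRUE)
  expect_equal(w$t, unname(st$statistic), tolerance = 1e-10)
  expect_equal(w$df, unname(st$parameter), tolerance = 1e-10)
})

test_that("fisher_exact agrees with full enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p, 1)

  tab <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(fisher_exact(tab)$p, fisher_enum_oracle(tab),
               tolerance = 1e-12)

  set.seed(14)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    cells <- as.vector(stats::rmultinom(1, n, runif(4, 0.05, 1)))
    tab <- matrix(cells, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact(tab)$p, fisher_enum_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("fisher_exact is invariant to row/column swaps and reports the sample OR", {
  tab <- matrix(c(12, 3, 5, 9), 2)
  p <- fisher_exact(tab)$p
  expect_equal(fisher_exact(tab[2:1, ])$p, p, tolerance = 1e-12)
  expect_equal(fisher_exact(tab[, 2:1])$p, p, tolerance = 1e-12)
  expect_equal(fisher_exact(tab)$odds_ratio, (12 * 9) / (3 * 5))
  zc <- fisher_exact(matrix(c(8, 0, 2, 10), 2))
  expect_true(zc$zero_cell_corrected)
  expect_equal(zc$odds_ratio, (8.5 * 10.5) / (0.5 * 2.5))
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("p-value adjustment matches hand-computed vectors", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(c(0.01, rep(0.5, 4)), "bonferroni")[1], 0.05)
  expect_equal(adjust_pvalues(rep(0.2, 6), "bh"), rep(0.2, 6))

  set.seed(15)
  p <- runif(40)
  expect_equal(adjust_pvalues(p, "bh"), bh_oracle(p), tolerance = 1e-12)
  expect_true(all(adjust_pvalues(p, "bh") >= p))
  # order invariance: adjust-then-reorder == reorder-then-adjust
  o <- sample(40)
  expect_equal(adjust_pvalues(p, "bh")[o], adjust_pvalues(p[o], "bh"))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("correlate handles monotone, linear and tied data", {
  x <- 1:10
  expect_equal(correlate(x, x^2, "spearman")$r, 1)
  expect_lt(correlate(x, x^2, "pearson")$r, 1)
  expect_equal(correlate(x, -x, "pearson")$r, -1)
  expect_equal(correlate(x, -x, "spearman")$r, -1)

  # tied data against explicit mid-rank computation
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  r_hand <- cor(rank(xt), rank(yt))
  expect_equal(correlate(xt, yt, "spearman")$r, r_hand, tolerance = 1e-12)

  expect_error(correlate(rep(1, 10), 1:10), "variance")
  expect_error(correlate(1:3, 1:3), "n >= 4")
})

test_that("planted feature screen controls FDR with good power", {
  fdrs <- powers <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n_feat <- 500; n_true <- 20
    groups <- factor(rep(c("below", "above"), each = 150),
                     levels = c("below", "above"))
    feats <- matrix(rnorm(n_feat * 300), n_feat, 300)
    feats[1:n_true, groups == "below"] <-
      feats[1:n_true, groups == "below"] + 1          # 1-sd effect
    rownames(feats) <- sprintf("f%03d", 1:n_feat)
    res <- group_feature_screen(feats, groups, test = "welch",
                                correction = "bh")
    called <- res$feature_id[res$significant == 1]
    powers[s] <- mean(sprintf("f%03d", 1:n_true) %in% called)
    fdrs[s] <- if (length(called)) {
      mean(!(called %in% sprintf("f%03d", 1:n_true)))
    } else 0
  }
  expect_lte(mean(fdrs), 0.10)
  expect_gte(mean(powers), 0.8)
})

test_that("feature screen finds nothing without signal", {
  # identical groups: the "above" block duplicates the "below" block, so
  # every feature compares a sample with itself -> nothing significant
  clean <- vapply(1:20, function(s) {
    set.seed(s)
    groups <- factor(rep(c("below", "above"), each = 40),
                     levels = c("below", "above"))
    half <- matrix(rnorm(100 * 40), 100, 40)
    feats <- cbind(half, half)
    sum(group_feature_screen(feats, groups, "welch")$significant) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)

  # label permutation destroys planted signals
  set.seed(99)
  groups <- factor(rep(c("below", "above"), each = 100),
                   levels = c("below", "above"))
  feats <- matrix(rnorm(200 * 200), 200, 200)
  feats[1:20, groups == "below"] <- feats[1:20, groups == "below"] + 1
  counts <- vapply(1:11, function(i) {
    set.seed(i)
    sum(group_feature_screen(feats, sample(groups), "welch")$significant)
  }, numeric(1))
  expect_equal(median(counts), 0)
})

test_that("feature screen rejects mixed feature types", {
  groups <- factor(rep(c("below", "above"), each = 10),
                   levels = c("below", "above"))
  num <- matrix(rnorm(40), 2, 20)
  bin <- matrix(rbinom(40, 1, 0.5), 2, 20)
  expect_error(group_feature_screen(num, groups, "fisher"), "binary")
  expect_error(group_feature_screen(bin, groups, "welch"), "fisher")
})

test_that("binary screen uses Fisher with Bonferroni by default", {
  set.seed(33)
  groups <- factor(rep(c("below", "above"), each = 120),
                   levels = c("below", "above"))
  feats <- rbind(hot = rbinom(240, 1, ifelse(groups == "below", 0.7, 0.2)),
                 cold = rbinom(240, 1, 0.3))
  res <- group_feature_screen(feats, groups, test = "fisher")
  expect_equal(unique(res$method), "fisher+bonferroni")
  expect_equal(res$significant[res$feature_id == "hot"], 1L)
  expect_equal(res$significant[res$feature_id == "cold"], 0L)
  expect_gt(res$effect[res$feature_id == "hot"], 0)  # below-minus-above
})

test_that("drug sensitivity association ranks the planted drug first", {
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    n_lines <- 40
    maa <- setNames(runif(n_lines, 0, 6), sprintf("cl%02d", 1:n_lines))
    ic50 <- matrix(rnorm(11 * n_lines), 11, n_lines,
                   dimnames = list(c("planted", sprintf("null%02d", 1:10)),
                                   names(maa)))
    ic50["planted", ] <- 0.5 * maa + rnorm(n_lines, 0, 0.5)  # sensitive low
    res <- drug_sensitivity_assoc(ic50, maa, threshold = 2.92)
    res$drug[1] == "planted"
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("drug screen skips degenerate drugs with warnings", {
  maa <- setNames(runif(12, 0, 6), sprintf("cl%02d", 1:12))
  ic50 <- rbind(good = rnorm(12), flat = rep(1, 12),
                sparse = c(rnorm(5), rep(NA, 7)))
  colnames(ic50) <- names(maa)
  expect_warning(expect_warning(
    res <- drug_sensitivity_assoc(ic50, maa, threshold = 2.92),
    "constant IC50"), "fewer than")
  expect_equal(res$drug, "good")
  # perfect linear relation -> r = 1
  ic1 <- matrix(maa, 1, dimnames = list("lin", names(maa)))
  expect_equal(drug_sensitivity_assoc(ic1, maa, 2.92)$r, 1)
})
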
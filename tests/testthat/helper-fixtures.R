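# Shared fixtures and independent oracles.  Cohorts are memoized so several
# test files can reuse the same generated data without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

tiny_expr <- function(values, level = "gene", samples = NULL, genes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  # Gaussian test matrices are declared log-scale (negatives allowed there)
  expression_matrix(m, feature_level = level, log_transformed = any(m < 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A moderate synthetic cohort used across activity / MAA / e2e tests.
demo_cohort <- function() {
  cached("demo_cohort", generate_cohort(
    sim_params(n_samples = 400, n_genes = 1000, seed = 101)))
}

demo_gene_expr <- function() {
  cached("demo_gene_expr",
         aggregate_to_gene(demo_cohort()$expression,
                           demo_cohort()$isoform_map, rule = "sum"))
}

true_regulon <- function(cohort, tf) {
  tr <- cohort$truth$regulons
  tr <- tr[tr$tf == tf, , drop = FALSE]
  regulon(tf, data.frame(gene_id = tr$gene_id, mode = tr$mode,
                         weight = tr$weight, mi = 1, p_value = 0,
                         stringsAsFactors = FALSE))
}

## ---- independent oracles ----

# Product-limit estimate by direct accumulation (no survival package).
km_oracle <- function(times, events) {
  ord <- order(times, -events)        # censoring after events at equal times
  times <- times[ord]; events <- events[ord]
  ut <- sort(unique(times[events == 1]))
  surv <- numeric(length(ut)); s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv)
}

# Welch statistic and Satterthwaite df from the closed-form formulas.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-sided Fisher p by full enumeration over all tables with the observed
# margins (probability-mass rule).
fisher_enum_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(a)
    dhyper(a, c1, n - c1, r1), numeric(1))
  p_obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by the definition (sort, scale, cummin).
bh_oracle <- function(p) {
  m <- length(p); o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Closed-form Gaussian mutual information in nats.
gaussian_mi <- function(rho) -0.5 * log(1 - rho^2)
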
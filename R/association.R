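#' Welch two-sample t-test
#'
#' Two-sided Welch statistic with Satterthwaite degrees of freedom — the
#' unequal-variance comparison used for methylation-style group contrasts.
#'
#' @param x,y numeric vectors (each n >= 2; at least one group with
#'   non-zero variance).
#' @return List `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0)
    stop("both groups have zero variance")
  ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value sums hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of
#' the observed table — the probability-mass rule.  The reported odds
#' ratio is the sample cross-product ratio; when a zero cell is present a
#' Haldane-Anscombe 0.5 correction is applied for display only, never for
#' the p-value.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List `odds_ratio`, `p`, `zero_cell_corrected`.
#' @export
fisher_exact <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  zero <- any(tab == 0)
  ctab <- if (zero) tab + 0.5 else tab
  or <- (ctab[1, 1] * ctab[2, 2]) / (ctab[1, 2] * ctab[2, 1])
  list(odds_ratio = unname(or), p = unname(min(p, 1)),
       zero_cell_corrected = zero)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg step-up (with monotonicity enforcement) or
#' Bonferroni.  The convention here: BH for all screens except the
#' mutation-frequency screen, which uses Bonferroni.
#'
#' @param p p-values in \[0, 1\].
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni")[method])
}

#' Correlation with a two-sided p-value
#'
#' @param x,y numeric vectors, n >= 4, non-constant.
#' @param method `"pearson"` or `"spearman"` (mid-ranks for ties; p from
#'   the t approximation).
#' @return List `r`, `p`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 4L) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance input")
  if (method == "spearman") {
    # mid-rank transform then Pearson machinery -> t-approximation p,
    # valid with ties (cor.test's exact path refuses ties)
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  if (abs(r) >= 1) return(list(r = r, p = 0))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

#' Feature screen between the two MAA groups
#'
#' Per-feature comparison of samples below versus above the MAA threshold:
#' numeric features (assumed already on log scale) with the Welch t-test,
#' binary (0/1) features with the Fisher exact test.  Supplying a binary
#' matrix to the Welch path or vice versa is an error — mixed feature
#' types must be screened in separate calls.  Effects are reported as
#' below-minus-above differences (mean difference on the supplied scale
#' for Welch; frequency difference for Fisher).
#'
#' @param features numeric matrix, features x samples.
#' @param groups factor with levels `below`, `above` (one per sample),
#'   e.g. from [dichotomize()].
#' @param test `"welch"` or `"fisher"`.
#' @param correction passed to [adjust_pvalues()]; defaults to BH for
#'   Welch and Bonferroni for Fisher (the mutation-screen convention).
#' @param alpha significance level on the adjusted scale.
#' @return Data frame `feature_id, effect, statistic, p, p_adj,
#'   significant, method`.
#' @export
group_feature_screen <- function(features, groups, test = c("welch", "fisher"),
                                 correction = NULL, alpha = 0.05) {
  test <- match.arg(test)
  if (is.null(correction))
    correction <- if (test == "fisher") "bonferroni" else "bh"
  groups <- factor(as.character(groups), levels = c("below", "above"))
  if (ncol(features) != length(groups)) stop("sample dimension mismatch")
  if (any(is.na(groups))) stop("groups must be 'below'/'above'")
  is_binary <- all(features %in% c(0, 1))
  if (test == "fisher" && !is_binary)
    stop("fisher screen requires a binary 0/1 feature matrix")
  if (test == "welch" && is_binary)
    stop("welch screen on binary features; use test = 'fisher'")
  below <- groups == "below"
  res <- lapply(seq_len(nrow(features)), function(i) {
    x <- features[i, below]
    y <- features[i, !below]
    if (test == "welch") {
      if (stats::var(x) == 0 && stats::var(y) == 0)
        return(data.frame(effect = mean(x) - mean(y), statistic = 0, p = 1))
      w <- welch_t(x, y)
      data.frame(effect = mean(x) - mean(y), statistic = w$t, p = w$p)
    } else {
      tab <- rbind(c(sum(x == 1), sum(x == 0)),
                   c(sum(y == 1), sum(y == 0)))
      if (any(colSums(tab) == 0))  # feature constant in the whole cohort
        return(data.frame(effect = mean(x) - mean(y), statistic = NA_real_,
                          p = 1))
      f <- fisher_exact(tab)
      data.frame(effect = mean(x) - mean(y), statistic = f$odds_ratio,
                 p = f$p)
    }
  })
  out <- do.call(rbind, res)
  out <- data.frame(feature_id = rownames(features) %||%
                      as.character(seq_len(nrow(features))),
                    out, stringsAsFactors = FALSE)
  out$p_adj <- adjust_pvalues(out$p, correction)
  out$significant <- as.integer(out$p_adj < alpha)
  out$method <- paste0(test, "+", correction)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drug-sensitivity association with MAA
#'
#' For each drug, Pearson correlation between ln(IC50) and MAA across cell
#' lines, and the mean IC50 fold change of low-MAA versus high-MAA lines
#' (geometric: `exp(mean ln IC50 low - mean ln IC50 high)`).  Fold change
#' above 1 means low-MAA lines need more drug (are more resistant); below
#' 1 means low-MAA lines are more sensitive.  Drugs with fewer than
#' `min_lines` non-missing observations, or with constant IC50, are
#' skipped with a warning.  P-values (correlation test) are BH-adjusted
#' across retained drugs; rows are sorted by decreasing absolute log fold
#' change.
#'
#' @param ic50 drugs x cell-lines matrix of ln(IC50) (NAs allowed).
#' @param maa named per-cell-line MAA values (names = colnames of `ic50`).
#' @param threshold MAA dichotomization threshold.
#' @param min_lines minimum usable cell lines per drug (default 8).
#' @return Data frame `drug, n, r, fold_change, p, p_adj`.
#' @export
drug_sensitivity_assoc <- function(ic50, maa, threshold, min_lines = 8L) {
  if (is.null(colnames(ic50)) || is.null(names(maa)))
    stop("ic50 columns and maa must be named by cell line")
  lines <- intersect(colnames(ic50), names(maa))
  if (length(lines) == 0L) stop("no shared cell lines")
  rows <- lapply(rownames(ic50), function(drug) {
    v <- ic50[drug, lines]
    ok <- !is.na(v)
    if (sum(ok) < min_lines) {
      warning("drug ", drug, ": fewer than ", min_lines,
              " observations, skipped")
      return(NULL)
    }
    v <- v[ok]; m <- maa[lines][ok]
    if (stats::sd(v) == 0) {
      warning("drug ", drug, ": constant IC50 (zero variance), skipped")
      return(NULL)
    }
    low <- m < threshold
    if (!any(low) || all(low)) {
      warning("drug ", drug, ": all cell lines on one side of threshold, skipped")
      return(NULL)
    }
    ct <- correlate(v, m, method = "pearson")
    data.frame(drug = drug, n = length(v), r = ct$r,
               fold_change = exp(mean(v[low]) - mean(v[!low])),
               p = ct$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no drug with enough data")
  out$p_adj <- adjust_pvalues(out$p, "bh")
  out <- out[order(-abs(log(out$fold_change))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
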
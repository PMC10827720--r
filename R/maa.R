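#' Mean Absolute Activity
#'
#' The balance index between two counterposed regulator activities,
#' \deqn{MAA = \frac{|a_1| + |a_2|}{2}.}
#' High MAA means one regulator strongly prevails over the other (an
#' intact switch); MAA near zero means the two programs balance out and
#' neither drives differentiation.
#'
#' @param a1,a2 finite activity values (NES), vectorized.
#' @return Non-negative MAA values.
#' @export
compute_maa <- function(a1, a2) {
  if (any(!is.finite(a1)) || any(!is.finite(a2)))
    stop("activities must be finite")
  (abs(a1) + abs(a2)) / 2
}

#' Nested log expression ratio between the two regulators
#'
#' \deqn{\log_2\!\big(\log_2 e_1 / \log_2 e_2\big)} on linear-scale
#' expressions.  The ratio is undefined whenever an inner log is not
#' positive (expression <= 1 after any pseudocount); undefined values are
#' returned as `NA` with an attached count, never silently dropped.
#'
#' @param e1,e2 linear-scale expression values (vectorized).
#' @return Ratio values with attribute `n_undefined`.
#' @export
expression_log_ratio <- function(e1, e2) {
  bad <- !(e1 > 1) | !(e2 > 1)
  out <- rep(NA_real_, length(bad))
  ok <- !bad
  out[ok] <- log2(log2(e1[ok]) / log2(e2[ok]))
  if (any(bad))
    warning(sum(bad), " sample(s) with expression <= 1: ratio undefined")
  attr(out, "n_undefined") <- sum(bad)
  out
}

.maa_strata <- c("very_low", "low", "medium", "high", "very_high")

#' Bin MAA values into the five prognostic strata
#'
#' Intervals are closed on the left and open on the right:
#' very low \eqn{[0,1)}, low \eqn{[1,2)}, medium \eqn{[2,3)},
#' high \eqn{[3,4)}, very high \eqn{[4,\infty)}.  The published interval
#' table leaves the point 4 itself formally unassigned ("high" stops below
#' 4, "very high" starts above it); the left-closed convention used for
#' every other boundary is extended to 4 so the strata partition
#' \eqn{[0,\infty)}.
#'
#' @param maa non-negative MAA values.
#' @return Factor with levels `very_low < low < medium < high < very_high`.
#' @export
bin_maa <- function(maa) {
  if (any(!is.finite(maa))) stop("MAA must be finite")
  if (any(maa < 0)) stop("MAA must be non-negative")
  cut(maa, breaks = c(0, 1, 2, 3, 4, Inf), labels = .maa_strata,
      right = FALSE, include.lowest = TRUE, ordered_result = TRUE)
}

#' Dichotomize MAA at a threshold
#'
#' Samples with MAA at or above the threshold are labeled `above`,
#' the rest `below` (ties go to `above`; the tie rule is recorded in the
#' result's attributes).
#'
#' @param maa_values finite numeric vector.
#' @param threshold cut-point (e.g. an [optimal_cutpoint()] result or a
#'   fixed literature value such as 2.92).
#' @return Factor with levels `below`, `above`; attributes `n_below`,
#'   `n_above`, `threshold`, `tie_rule`.
#' @export
dichotomize <- function(maa_values, threshold) {
  if (any(!is.finite(maa_values))) stop("MAA values must be finite")
  g <- factor(ifelse(maa_values >= threshold, "above", "below"),
              levels = c("below", "above"))
  structure(g, n_below = sum(g == "below"), n_above = sum(g == "above"),
            threshold = threshold, tie_rule = "ties_to_above")
}

#' Assemble the per-sample MAA table
#'
#' Combines the two activity columns into MAA, the nested log expression
#' ratio (when linear-scale regulator expressions are supplied), the
#' five-level stratum, and the dichotomized group.
#'
#' @param activity an `ActivityProfile` with exactly two regulator columns.
#' @param threshold dichotomization threshold.
#' @param e1,e2 optional linear-scale expression of the two regulators
#'   (same sample order as `activity`).
#' @return Data frame `sample_id, a1, a2, maa, ratio, stratum, group`.
#' @export
maa_table <- function(activity, threshold, e1 = NULL, e2 = NULL) {
  tf_cols <- setdiff(names(activity), "sample_id")
  if (length(tf_cols) != 2L)
    stop("activity profile must have exactly two regulator columns")
  a1 <- activity[[tf_cols[1L]]]
  a2 <- activity[[tf_cols[2L]]]
  maa <- compute_maa(a1, a2)
  ratio <- if (!is.null(e1) && !is.null(e2)) {
    suppressWarnings(as.numeric(expression_log_ratio(e1, e2)))
  } else NA_real_
  data.frame(sample_id = activity$sample_id, a1 = a1, a2 = a2, maa = maa,
             ratio = ratio, stratum = bin_maa(maa),
             group = dichotomize(maa, threshold),
             stringsAsFactors = FALSE)
}
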
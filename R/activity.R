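#' Rank-based expression signature
#'
#' For each gene, samples are ranked across the cohort (mid-ranks for
#' ties) and mapped through the standard-normal quantile function,
#' \eqn{q_g(s) = \Phi^{-1}(r_{gs}/(n+1))}.  A constant gene row yields all
#' mid-ranks and hence all-zero scores; such rows are counted in a message.
#' The signature is therefore relative to the cohort itself: a sample's
#' score says where it sits among all samples for that gene.
#'
#' @param mat gene-level `ExpressionMatrix` with >= 20 samples.
#' @return Numeric genes-by-samples matrix of signature scores.
#' @export
rank_signature <- function(mat) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$feature_level != "gene")
    stop("signature requires a gene-level matrix")
  n <- ncol(mat$values)
  if (n < 20L) stop("need at least 20 samples")
  constant <- apply(mat$values, 1L, function(r) all(r == r[1L]))
  if (any(constant))
    message(sum(constant), " constant gene row(s) mapped to all-zero scores")
  ranks <- t(apply(mat$values, 1L, rank, ties.method = "average"))
  q <- stats::qnorm(ranks / (n + 1))
  dimnames(q) <- dimnames(mat$values)
  q
}

#' Normalized enrichment score of a regulon on one signature column
#'
#' Weighted, signed average of the regulon targets' signature scores,
#' \deqn{NES = \frac{\sum_g w_g m_g q_g}{\sqrt{\sum_g w_g^2}},}
#' a simplified aREA-style statistic: positive when positively-moded
#' targets are over-ranked in the sample (the regulator is "positively
#' active"), negative when they are under-ranked.  Under independence of
#' regulon and signature, NES is asymptotically standard normal.
#'
#' @param signature_column named numeric vector of signature scores over
#'   genes (one sample).
#' @param regulon a [regulon()].
#' @param min_targets minimum number of regulon targets that must be
#'   present among the signature genes (default 10); below this the score
#'   is unreliable and the call fails rather than silently rescaling.
#' @return NES (scalar).
#' @export
compute_nes <- function(signature_column, regulon, min_targets = 10L) {
  stopifnot(inherits(regulon, "Regulon"))
  hit <- regulon$targets$gene_id %in% names(signature_column)
  if (sum(hit) < min_targets)
    stop(sprintf("only %d of %d regulon targets present in signature (%d missing); need >= %d",
                 sum(hit), nrow(regulon$targets), sum(!hit), min_targets))
  t <- regulon$targets[hit, , drop = FALSE]
  q <- signature_column[t$gene_id]
  sum(t$weight * t$mode * q) / sqrt(sum(t$weight^2))
}

#' Per-sample activity of a set of regulators
#'
#' Computes the rank signature of the cohort and one NES per (sample,
#' regulator).  Deterministic given its inputs; permuting the samples of
#' `mat` permutes the rows of the result identically.
#'
#' @param mat gene-level `ExpressionMatrix`.
#' @param regulons named list of [regulon()] objects.
#' @param min_targets passed to [compute_nes()].
#' @return An `ActivityProfile` data frame: `sample_id` plus one NES
#'   column per regulator.
#' @export
activity_matrix <- function(mat, regulons, min_targets = 10L) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (is.null(names(regulons)))
    names(regulons) <- vapply(regulons, function(r) r$tf_id, character(1L))
  sig <- rank_signature(mat)
  out <- data.frame(sample_id = colnames(sig), stringsAsFactors = FALSE)
  for (tf in names(regulons)) {
    r <- regulons[[tf]]
    hit <- r$targets$gene_id %in% rownames(sig)
    if (sum(hit) < min_targets)
      stop(sprintf("regulon %s: only %d targets present (>= %d required)",
                   tf, sum(hit), min_targets))
    t <- r$targets[hit, , drop = FALSE]
    w <- t$weight * t$mode
    out[[tf]] <- as.numeric(crossprod(sig[t$gene_id, , drop = FALSE], w)) /
      sqrt(sum(t$weight^2))
  }
  class(out) <- c("ActivityProfile", "data.frame")
  out
}

#' Write / read an activity profile as TSV
#' @param activity an `ActivityProfile`.
#' @param path TSV path.
#' @return `path` invisibly; the reader returns the data frame.
#' @export
write_activity <- function(activity, path) {
  utils::write.table(format(as.data.frame(activity), digits = 15, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  class(df) <- c("ActivityProfile", "data.frame")
  df
}
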
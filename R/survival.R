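#' Kaplan-Meier curve
#'
#' Product-limit estimate with Greenwood standard errors, computed with
#' the survival package.  Censoring at a time equal to an event time is
#' handled after the event (the standard convention).
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return A `KMCurve` list: `time`, `surv`, `n_risk`, `n_event`,
#'   `std_err` (Greenwood SE of the survival probability).
#' @export
km_curve <- function(times, events) {
  .check_surv(times, events)
  if (all(times == 0)) stop("all follow-up times are zero")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event,
                 std_err = fit$std.err * fit$surv),   # Greenwood SE of S(t)
            class = "KMCurve")
}

.check_surv <- function(times, events) {
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative")
  if (!all(events %in% c(0, 1)))
    stop("events must be 0/1")
}

#' K-group log-rank test
#'
#' @param times,events survival data.
#' @param groups group labels (K >= 2 non-empty groups).
#' @return List `chisq`, `df` (= K - 1), `p`.
#' @export
logrank_test <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least two non-empty groups")
  if (any(table(groups) == 0L)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Thin, strict wrapper around [survival::coxph()]: Efron ties by default,
#' complete-case handling with a logged count of dropped rows, explicit
#' failure on non-convergence or monotone likelihood (perfect separation)
#' instead of a warning, and a per-covariate table of hazard ratios with
#' Wald 95% confidence intervals — the `HR (95% CI)` schema of clinical
#' survival tables.
#'
#' @param times,events survival data.
#' @param covariates data frame or matrix of covariates (factors allowed
#'   in a data frame; expanded to treatment-coded dummies).
#' @param ties `"efron"` or `"breslow"`.
#' @return A `CoxFit` list: `table` (term, beta, hr, ci_low, ci_high, p),
#'   `loglik`, `n`, `n_events`, `n_dropped`, `ties`, `iter`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_surv(times, events)
  cov_df <- as.data.frame(covariates)
  complete <- stats::complete.cases(cov_df) & is.finite(times) & !is.na(events)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L)
    message(n_dropped, " row(s) with missing covariates dropped from Cox fit")
  cov_df <- cov_df[complete, , drop = FALSE]
  times <- times[complete]; events <- events[complete]
  for (nm in names(cov_df)) {
    v <- cov_df[[nm]]
    if ((is.factor(v) && nlevels(droplevels(v)) < 2L) ||
        (!is.factor(v) && stats::var(as.numeric(v)) == 0))
      stop("constant covariate: ", nm)
  }
  dat <- cbind(data.frame(.time = times, .event = events), cov_df)
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", names(cov_df)),
                                       collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties,
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite|Loglik converged",
                conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15))
    stop("Cox fit failed: monotone likelihood / non-finite estimates")
  z <- stats::qnorm(0.975)
  tab <- data.frame(term = names(beta), beta = unname(beta),
                    hr = exp(unname(beta)),
                    ci_low = exp(unname(beta) - z * se),
                    ci_high = exp(unname(beta) + z * se),
                    se = unname(se),
                    p = 2 * stats::pnorm(-abs(unname(beta) / se)),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, loglik = fit$loglik, n = fit$n,
                 n_events = fit$nevent, n_dropped = n_dropped,
                 ties = ties, iter = fit$iter),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- x$table
  cat(sprintf("  %-20s HR %.2f (%.2f-%.2f)  p = %.3g\n",
              tab$term, tab$hr, tab$ci_low, tab$ci_high, tab$p), sep = "")
  invisible(x)
}

#' Maximally selected cut-point on a biomarker
#'
#' Scans every unique biomarker value between the `q_low` and `q_high`
#' quantiles and returns the threshold maximizing the two-group log-rank
#' statistic (`mode = "logrank"`) or the Wald chi-square of the
#' dichotomized indicator in a one-covariate Cox model
#' (`mode = "cox_scan"`).  Groups are formed as value >= threshold
#' ("above") versus below.  The returned p-value is the unadjusted
#' log-rank p at the selected threshold; because the threshold is chosen
#' to maximize the statistic, this p is optimistically biased — set
#' `permutation_p` to obtain a selection-adjusted permutation p-value.
#'
#' @param maa biomarker values (one per subject; >= 50 subjects).
#' @param times,events survival data.
#' @param q_low,q_high quantile bounds of the candidate grid.
#' @param mode statistic to maximize.
#' @param permutation_p integer number of permutations for an adjusted
#'   p-value, or `NULL` (default) to skip.
#' @return A `CutpointResult` list: `threshold`, `statistic`, `p`,
#'   `n_below`, `n_above`, `mode`, `grid` (candidate thresholds), and
#'   optionally `p_adjusted`.
#' @export
optimal_cutpoint <- function(maa, times, events, q_low = 0.10, q_high = 0.90,
                             mode = c("logrank", "cox_scan"),
                             permutation_p = NULL) {
  mode <- match.arg(mode)
  .check_surv(times, events)
  if (length(maa) < 50L) stop("need at least 50 subjects")
  qs <- stats::quantile(maa, c(q_low, q_high), names = FALSE)
  grid <- sort(unique(maa[maa >= qs[1L] & maa <= qs[2L]]))
  grid <- grid[vapply(grid, function(t) {
    nb <- sum(maa < t); nb > 0L && nb < length(maa)
  }, logical(1L))]
  if (length(grid) == 0L) stop("empty candidate grid")
  stat_at <- function(threshold, marker) {
    g <- marker >= threshold
    if (mode == "logrank") {
      survival::survdiff(survival::Surv(times, events) ~ g)$chisq
    } else {
      fit <- survival::coxph(survival::Surv(times, events) ~ g,
                             ties = "efron")
      (stats::coef(fit) / sqrt(diag(stats::vcov(fit))))^2
    }
  }
  stats_grid <- vapply(grid, stat_at, numeric(1L), marker = maa)
  best <- which.max(stats_grid)
  threshold <- grid[best]
  g <- dichotomize(maa, threshold)
  lr <- logrank_test(times, events, g)
  out <- list(threshold = threshold, statistic = unname(stats_grid[best]),
              p = lr$p, n_below = attr(g, "n_below"),
              n_above = attr(g, "n_above"), mode = mode, grid = grid)
  if (!is.null(permutation_p)) {
    # selection-adjusted p: re-run the full scan on biomarker permutations
    perm_max <- vapply(seq_len(permutation_p), function(i) {
      m <- sample(maa)
      max(vapply(grid, stat_at, numeric(1L), marker = m))
    }, numeric(1L))
    out$p_adjusted <- (sum(perm_max >= out$statistic) + 1) /
      (permutation_p + 1)
  }
  structure(out, class = "CutpointResult")
}

.pool_stage <- function(stage) {
  s <- as.character(stage)
  s[s %in% c("IIIA", "IIIB")] <- "III"
  factor(s, levels = c("I", "II", "III", "IV"))
}

#' Stage-stratified and multivariate prognostic analysis of MAA
#'
#' Reproduces the schema of a clinical survival table: one univariate Cox
#' fit of MAA within each fine-grained stage category (I, II, IIIA, IIIB,
#' IV), plus one multivariate fit with covariates MAA, sex, stage (IIIA
#' and IIIB pooled to III, reference stage I), age and pack-years.  Stages
#' with fewer than `min_events` events are skipped with a warning.  Rows
#' with missing covariates are dropped per model, not globally.
#'
#' @param maa per-sample MAA values aligned with `clinical`.
#' @param clinical a `ClinicalTable`.
#' @param endpoint `"os"` or `"rfs"`.
#' @param min_events minimum events for a per-stage fit (default 10).
#' @return List with `univariate` (named list of `CoxFit` per stage) and
#'   `multivariate` (one `CoxFit`).
#' @export
stage_stratified_analysis <- function(maa, clinical, endpoint = c("os", "rfs"),
                                      min_events = 10L) {
  endpoint <- match.arg(endpoint)
  stopifnot(inherits(clinical, "ClinicalTable"),
            length(maa) == nrow(clinical))
  times <- clinical[[paste0(endpoint, "_time")]]
  events <- clinical[[paste0(endpoint, "_event")]]
  usable <- !is.na(times) & !is.na(events)
  uni <- list()
  for (st in levels(clinical$stage)) {
    idx <- usable & !is.na(clinical$stage) & clinical$stage == st
    if (sum(events[idx], na.rm = TRUE) < min_events) {
      warning("stage ", st, ": fewer than ", min_events,
              " events, univariate fit skipped")
      next
    }
    uni[[st]] <- cox_fit(times[idx], events[idx],
                         data.frame(maa = maa[idx]))
  }
  cov <- data.frame(maa = maa,
                    sex = clinical$sex,
                    stage = .pool_stage(clinical$stage),
                    age = clinical$age,
                    pack_years = clinical$pack_years)
  multi <- cox_fit(times[usable], events[usable],
                   cov[usable, , drop = FALSE])
  list(univariate = uni, multivariate = multi)
}
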
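#' Parameters of the synthetic cohort generator
#'
#' The defaults state the world the analysis assumes: two master
#' regulators with anti-correlated activities, regulons of 111 and 135
#' signed targets, a "polarized corners" activity geometry (most samples
#' driven hard by one regulator, few balanced samples in the middle), a
#' protective per-unit MAA hazard ratio of 0.74 on overall survival,
#' roughly 30% censoring, and binary alteration features whose frequency
#' differs between low- and high-MAA samples (the TP53-like default rates
#' are 75.9% below vs 59.6% above the threshold).
#'
#' @param n_samples cohort size.
#' @param n_genes total genes including the two regulators.
#' @param k1,k2 regulon sizes of TF1 and TF2 (defaults 111 and 135).
#' @param pi_polarized fraction of polarized samples (Beta(5, 1.5) latent
#'   magnitude); the rest are balanced (Beta(1.5, 5)).
#' @param activity_scale scale `c` mapping the latent polarity `d` in
#'   \[-1, 1\] to activity NES units: `A1 = c d`, `A2 = -c d` plus jitter.
#' @param activity_jitter sd of the Gaussian jitter on each activity.
#' @param target_noise_sd sd of target-gene noise on the log2 scale.
#' @param mode_positive_frac fraction of activated (mode +1) targets.
#' @param weight_range uniform range of true target weights.
#' @param hr_per_maa per-MAA-unit hazard ratio on overall survival
#'   (values < 1: high MAA is protective).
#' @param baseline_hazard exponential baseline hazard (events/day).
#' @param censoring_fraction target fraction of censored subjects.
#' @param maa_threshold MAA cut separating the binary-feature rate groups.
#' @param feature_rates named list; each element `c(below=, above=)` of
#'   Bernoulli rates for one binary feature.
#' @param stage_hrs named multiplicative stage effects on the hazard
#'   (all 1 by default: MAA is the only prognostic factor).
#' @param seed integer master seed; all substreams derive from it.
#' @return A `SimParams` list.
#' @export
sim_params <- function(n_samples = 1000L, n_genes = 1000L,
                       k1 = 111L, k2 = 135L,
                       pi_polarized = 0.8, activity_scale = 4,
                       activity_jitter = 0.1, target_noise_sd = 0.25,
                       mode_positive_frac = 0.7, weight_range = c(0.5, 1),
                       hr_per_maa = 0.74, baseline_hazard = 4e-4,
                       censoring_fraction = 0.3, maa_threshold = 2.92,
                       feature_rates = list(
                         TP53 = c(below = 0.759, above = 0.596),
                         RASA1 = c(below = 0.076, above = 0.012),
                         KRAS = c(below = 0.092, above = 0.207)),
                       stage_hrs = c(I = 1, II = 1, IIIA = 1, IIIB = 1,
                                     IV = 1),
                       seed = 1L) {
  if (pi_polarized < 0 || pi_polarized > 1) stop("pi_polarized must be in [0, 1]")
  if (target_noise_sd < 0) stop("target_noise_sd must be >= 0")
  if (hr_per_maa <= 0) stop("hr_per_maa must be positive")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)")
  if (k1 + k2 + 2L > n_genes)
    stop("n_genes must accommodate both regulons plus the two regulators")
  structure(as.list(environment()), class = "SimParams")
}

# Named substream seeds derived deterministically from the master seed, so
# changing e.g. the feature stream never perturbs the expression stream.
.substreams <- function(seed) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max, 6L),
                  c("latent", "expression", "survival", "censoring",
                    "features", "clinical"))
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Builds an isoform-level expression matrix (two designated isoforms per
#' regulator, one isoform per ordinary gene), a clinical table with
#' MAA-dependent exponential survival and tuned uniform censoring, a
#' binary feature table with MAA-group-dependent rates, and a quarantined
#' `truth` list holding every latent quantity used in generation.
#'
#' Construction: a latent polarity `d = s * b` with random sign `s` and
#' Beta-distributed magnitude `b` gives true activities
#' `A1 = c d + jitter`, `A2 = -c d + jitter`.  Regulator log2 expression
#' follows its activity; target gene `g` of regulator `j` has log2
#' expression `mu_g + m_g w_g A_j + noise`; background genes are pure
#' noise.  Event times are exponential with hazard
#' `h0 * HR^MAA_true * stage_hr`; censoring times are Uniform(0, c_max)
#' with `c_max` tuned so the expected censored fraction matches the
#' request.
#'
#' @param params a [sim_params()] list.
#' @return A `SyntheticCohort` list: `expression` (isoform-level
#'   `ExpressionMatrix`), `isoform_map`, `clinical`, `features`
#'   (features x samples 0/1 matrix), `truth`.
#' @export
generate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimParams"))
  p <- params
  ss <- .substreams(p$seed)
  n <- p$n_samples
  samples <- sprintf("S%04d", seq_len(n))

  ## latent polarity and true activities
  set.seed(ss[["latent"]])
  s <- sample(c(-1, 1), n, replace = TRUE)
  polarized <- stats::runif(n) < p$pi_polarized
  b <- ifelse(polarized, stats::rbeta(n, 5, 1.5), stats::rbeta(n, 1.5, 5))
  d <- s * b
  a1 <- p$activity_scale * d + stats::rnorm(n, 0, p$activity_jitter)
  a2 <- -p$activity_scale * d + stats::rnorm(n, 0, p$activity_jitter)
  maa_true <- compute_maa(a1, a2)

  ## expression: regulators, targets, background (log2 scale, then linear)
  set.seed(ss[["expression"]])
  gene_ids <- sprintf("G%04d", seq_len(p$n_genes - 2L))
  t1 <- gene_ids[seq_len(p$k1)]
  t2 <- gene_ids[p$k1 + seq_len(p$k2)]
  background <- gene_ids[-(seq_len(p$k1 + p$k2))]
  truth_reg <- data.frame(
    gene_id = c(t1, t2),
    tf = rep(c("TF1", "TF2"), c(p$k1, p$k2)),
    mode = sample(c(1, -1), p$k1 + p$k2, replace = TRUE,
                  prob = c(p$mode_positive_frac, 1 - p$mode_positive_frac)),
    weight = stats::runif(p$k1 + p$k2, p$weight_range[1L], p$weight_range[2L]),
    stringsAsFactors = FALSE)
  mu <- stats::setNames(stats::runif(length(gene_ids), 3, 9), gene_ids)
  log2x <- matrix(0, nrow = length(gene_ids), ncol = n,
                  dimnames = list(gene_ids, samples))
  act <- rbind(TF1 = a1, TF2 = a2)
  for (i in seq_len(nrow(truth_reg))) {
    g <- truth_reg$gene_id[i]
    log2x[g, ] <- mu[g] + truth_reg$mode[i] * truth_reg$weight[i] *
      act[truth_reg$tf[i], ] + stats::rnorm(n, 0, p$target_noise_sd)
  }
  for (g in background)
    log2x[g, ] <- mu[g] + stats::rnorm(n, 0, 1)
  # regulator expression tracks its activity; split over two isoforms
  tf_log2 <- rbind(TF1 = 6 + a1, TF2 = 6 + a2)
  iso_split <- c(0.6, 0.4)
  iso_rows <- rbind(iso_split[1L] * 2^tf_log2["TF1", ],
                    iso_split[2L] * 2^tf_log2["TF1", ],
                    iso_split[1L] * 2^tf_log2["TF2", ],
                    iso_split[2L] * 2^tf_log2["TF2", ])
  rownames(iso_rows) <- c("TF1.iso1", "TF1.iso2", "TF2.iso1", "TF2.iso2")
  gene_iso <- 2^log2x
  rownames(gene_iso) <- paste0(gene_ids, ".iso1")
  values <- rbind(iso_rows, gene_iso)
  expr <- expression_matrix(values, feature_level = "isoform")
  imap <- isoform_map(
    c(stats::setNames(c("TF1", "TF1", "TF2", "TF2"), rownames(iso_rows)),
      stats::setNames(gene_ids, rownames(gene_iso))),
    regulators = list(TF1 = c("TF1.iso1", "TF1.iso2"),
                      TF2 = c("TF2.iso1", "TF2.iso2")))

  ## clinical covariates
  set.seed(ss[["clinical"]])
  stage <- sample(.stage_levels, n, replace = TRUE,
                  prob = c(0.45, 0.25, 0.15, 0.06, 0.09))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- round(stats::rnorm(n, 66, 8))
  pack_years <- round(stats::rlnorm(n, log(30), 0.6), 1)
  pack_years[stats::runif(n) < 0.2] <- NA_real_

  ## survival: exponential with MAA- (and optionally stage-) scaled hazard
  set.seed(ss[["survival"]])
  hazard <- p$baseline_hazard * p$hr_per_maa^maa_true *
    unname(p$stage_hrs[stage])
  event_time <- stats::rexp(n, rate = hazard)
  rfs_event_time <- stats::rexp(n, rate = hazard * 1.5)

  ## censoring: Uniform(0, cmax), cmax tuned to the requested fraction
  set.seed(ss[["censoring"]])
  cmax <- .tune_censoring(event_time, p$censoring_fraction)
  cens <- stats::runif(n, 0, cmax)
  os_time <- pmin(event_time, cens)
  os_event <- as.numeric(event_time <= cens)
  rfs_time <- pmin(rfs_event_time, cens)
  rfs_event <- as.numeric(rfs_event_time <= cens)

  clinical <- as_clinical_table(data.frame(
    sample_id = samples, os_time = round(os_time, 1),
    os_event = os_event, rfs_time = round(rfs_time, 1),
    rfs_event = rfs_event, stage = stage, sex = sex, age = age,
    pack_years = pack_years, stringsAsFactors = FALSE))

  ## binary features with MAA-group-dependent rates
  set.seed(ss[["features"]])
  above <- maa_true >= p$maa_threshold
  features <- do.call(rbind, lapply(names(p$feature_rates), function(f) {
    r <- p$feature_rates[[f]]
    stats::rbinom(n, 1L, ifelse(above, r[["above"]], r[["below"]]))
  }))
  dimnames(features) <- list(names(p$feature_rates), samples)

  structure(list(expression = expr, isoform_map = imap, clinical = clinical,
                 features = features,
                 truth = list(params = unclass(p), seed = p$seed,
                              substreams = as.list(ss), d = d,
                              a1 = a1, a2 = a2, maa = maa_true,
                              regulons = truth_reg,
                              censoring_max = cmax)),
            class = "SyntheticCohort")
}

# Expected censored fraction for Uniform(0, cmax) censoring given the
# realized event times is mean(min(T/cmax, 1)); solve for cmax.
.tune_censoring <- function(event_time, fraction) {
  if (fraction == 0) return(max(event_time) * 1e6)
  f <- function(cmax) mean(pmin(event_time / cmax, 1)) - fraction
  hi <- max(event_time) / fraction
  if (f(hi) > 0) stop("infeasible censoring fraction")
  stats::uniroot(f, lower = min(event_time[event_time > 0]) * 1e-3,
                 upper = hi, tol = 1e-8)$root
}

#' Write a synthetic cohort to disk
#'
#' Emits the analysis-facing files (`expression.tsv`, `clinical.tsv`,
#' `features.tsv`, `isoform_map.tsv`) and a quarantined `truth.json`
#' carrying the generator parameters, seed and all latent quantities.
#' Analysis files never contain truth fields; keeping the truth in its own
#' file prevents tests from accidentally leaking it into the pipeline.
#'
#' @param cohort a [generate_cohort()] result.
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `out_dir` invisibly.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  stopifnot(inherits(cohort, "SyntheticCohort"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(cohort$expression,
                          file.path(out_dir, "expression.tsv"))
  utils::write.table(as.data.frame(cohort$clinical)[
    , c("sample_id", "os_time", "os_event", "rfs_time", "rfs_event",
        "stage", "sex", "age", "pack_years")],
    file.path(out_dir, "clinical.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(feature_id = rownames(cohort$features),
                                cohort$features, check.names = FALSE),
                     file.path(out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  im <- cohort$isoform_map
  utils::write.table(data.frame(isoform_id = names(im$map),
                                gene_symbol = unname(im$map)),
                     file.path(out_dir, "isoform_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Simulate survival under a per-unit hazard ratio on a marker
#'
#' Standalone helper used for parameter-recovery experiments: exponential
#' event times with hazard `h0 * hr^marker` (or a step model with hazard
#' multiplied by `step_hr` strictly below `step_at`), plus Uniform(0, cmax)
#' censoring tuned to the requested fraction.
#'
#' @param marker numeric marker values (e.g. MAA).
#' @param hr per-unit hazard ratio (ignored when `step_at` is given).
#' @param baseline_hazard exponential baseline hazard.
#' @param censoring_fraction target censored fraction.
#' @param step_at optional threshold for a step (change-point) hazard.
#' @param step_hr hazard multiplier for `marker < step_at`.
#' @return Data frame `time`, `event`.
#' @export
simulate_survival <- function(marker, hr = 0.74, baseline_hazard = 4e-4,
                              censoring_fraction = 0.3, step_at = NULL,
                              step_hr = 2) {
  hazard <- if (is.null(step_at)) {
    baseline_hazard * hr^marker
  } else {
    baseline_hazard * ifelse(marker < step_at, step_hr, 1)
  }
  event_time <- stats::rexp(length(marker), rate = hazard)
  if (censoring_fraction > 0) {
    cmax <- .tune_censoring(event_time, censoring_fraction)
    cens <- stats::runif(length(marker), 0, cmax)
    data.frame(time = pmin(event_time, cens),
               event = as.numeric(event_time <= cens))
  } else {
    data.frame(time = event_time, event = 1)
  }
}
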
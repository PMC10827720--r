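#' Read and validate a pipeline configuration
#'
#' The configuration is a single structured mapping, read from YAML
#' (`.yml`/`.yaml`) or JSON (`.json`).  Exactly one of `input` (paths to
#' expression/clinical/isoform-map files) or `simulate` (a [sim_params()]
#' field set) must be present.  Recognized blocks:
#' \describe{
#'   \item{input}{`expression`, `clinical`, `isoform_map`, optional
#'     `features` — file paths.}
#'   \item{simulate}{any [sim_params()] field.}
#'   \item{regulators}{named list: regulator id -> character vector of
#'     designated isoform ids (required for `input`; the synthetic cohort
#'     carries its own).}
#'   \item{regulon}{any [regulon_config()] field.}
#'   \item{activity}{`min_targets`.}
#'   \item{survival}{`endpoint` (os/rfs), `cutpoint_mode`
#'     (logrank/cox_scan), `threshold` (fixed cut instead of the search),
#'     `q_low`, `q_high`.}
#'   \item{seed}{integer master seed.}
#' }
#'
#' @param path YAML or JSON config path.
#' @return A validated `PipelineConfig` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg configuration list (as parsed from file).
#' @export
validate_pipeline_config <- function(cfg) {
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim)
    stop("config must contain exactly one of 'input' or 'simulate'")
  if (has_input) {
    for (k in c("expression", "clinical", "isoform_map"))
      if (is.null(cfg$input[[k]]))
        stop("config input block lacks '", k, "'")
    if (is.null(cfg$regulators) || length(cfg$regulators) != 2L)
      stop("config must define exactly two regulators with isoform lists")
  }
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$survival <- utils::modifyList(
    list(endpoint = "os", cutpoint_mode = "logrank", threshold = NULL,
         q_low = 0.10, q_high = 0.90),
    cfg$survival %||% list())
  cfg$activity <- utils::modifyList(list(min_targets = 10L),
                                    cfg$activity %||% list())
  cfg$regulon <- cfg$regulon %||% list()
  structure(cfg, class = "PipelineConfig")
}

.stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                  stage, paste0(...)))
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates: data loading (or simulation), gene-level aggregation,
#' per-isoform regulon inference and union, activity inference, MAA
#' computation, cut-point selection (or a fixed threshold),
#' Kaplan-Meier / log-rank analyses of the dichotomized and five-stratum
#' groupings, multivariate and per-stage Cox models, the binary feature
#' screen, and a run manifest.  Every artifact is a TSV or JSON file
#' under `out_dir`.
#'
#' @param config a `PipelineConfig` (see [read_pipeline_config()]) or a
#'   plain list with the same fields.
#' @param out_dir output directory (created; must be empty unless
#'   `force`).
#' @param seed optional override of the config seed.
#' @param threshold optional fixed MAA threshold overriding the cut-point
#'   search (e.g. 2.92 for demonstration runs).
#' @param force overwrite non-empty `out_dir`.
#' @return Invisibly, a list with the principal in-memory results
#'   (`regulons`, `activity`, `maa`, `cutpoint`, `survival`, `screen`).
#' @export
run_all <- function(config, out_dir, seed = NULL, threshold = NULL,
                    force = FALSE) {
  cfg <- if (inherits(config, "PipelineConfig")) config
         else validate_pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(threshold)) cfg$survival$threshold <- threshold
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- load or simulate ----
  if (!is.null(cfg$simulate)) {
    .stage_msg("simulate", "generating synthetic cohort")
    sp <- do.call(sim_params, utils::modifyList(cfg$simulate,
                                                list(seed = cfg$seed)))
    cohort <- .run_stage("simulate", generate_cohort(sp))
    expr_iso <- cohort$expression
    imap <- cohort$isoform_map
    clinical <- cohort$clinical
    features <- cohort$features
    regulators <- imap$regulators
  } else {
    .stage_msg("load", "reading input files")
    expr_iso <- .run_stage("load",
      read_expression_matrix(cfg$input$expression, "isoform"))
    clinical <- .run_stage("load", read_clinical(cfg$input$clinical))
    map_df <- utils::read.delim(cfg$input$isoform_map, sep = "\t",
                                stringsAsFactors = FALSE)
    regulators <- lapply(cfg$regulators, unlist)
    imap <- isoform_map(stats::setNames(map_df$gene_symbol,
                                        map_df$isoform_id), regulators)
    features <- if (!is.null(cfg$input$features)) {
      fm <- utils::read.delim(cfg$input$features, sep = "\t",
                              check.names = FALSE)
      m <- as.matrix(fm[, -1L, drop = FALSE]); rownames(m) <- fm[[1L]]; m
    } else NULL
  }

  ## ---- gene-level aggregation ----
  .stage_msg("aggregate", "isoform -> gene (sum rule)")
  expr_gene <- .run_stage("aggregate",
                          aggregate_to_gene(expr_iso, imap, rule = "sum"))

  ## ---- regulon inference ----
  rcfg <- do.call(regulon_config,
                  utils::modifyList(cfg$regulon, list(seed = cfg$seed)))
  tf_genes <- vapply(names(regulators),
                     function(tf) unname(imap$map[regulators[[tf]][1L]]),
                     character(1L))
  exclude <- unname(tf_genes)
  regulons <- .run_stage("regulon", {
    out <- list()
    for (tf in names(regulators)) {
      per_iso <- list()
      for (iso in regulators[[tf]]) {
        v <- expr_iso$values[iso, ]
        .stage_msg("regulon", tf, " isoform ", iso)
        cand <- infer_isoform_targets(v, expr_gene, rcfg, exclude = exclude)
        if (nrow(cand) > 0L)
          per_iso[[iso]] <- annotate_mode_weight(v, expr_gene, cand,
                                                 tf_id = tf_genes[[tf]])
      }
      if (length(per_iso) == 0L)
        stop("no isoform of ", tf, " yielded targets at alpha = ",
             rcfg$alpha)
      out[[tf]] <- union_regulons(per_iso, tf_id = tf_genes[[tf]])
    }
    out
  })
  for (tf in names(regulons))
    write_regulons(regulons[[tf]],
                   file.path(out_dir, paste0("regulon_", tf, ".tsv")))

  ## ---- activity ----
  .stage_msg("activity", "per-sample NES")
  activity <- .run_stage("activity",
    activity_matrix(expr_gene, regulons,
                    min_targets = cfg$activity$min_targets))
  write_activity(activity, file.path(out_dir, "activity.tsv"))

  ## ---- MAA + cut-point ----
  .stage_msg("maa", "balance index and threshold")
  tf_expr <- lapply(names(regulators), function(tf)
    colSums(expr_iso$values[regulators[[tf]], , drop = FALSE]))
  clin_idx <- match(activity$sample_id, clinical$sample_id)
  os_ok <- !is.na(clin_idx) & clinical$has_survival[clin_idx]
  maa_vals <- compute_maa(activity[[2L]], activity[[3L]])
  cutpoint <- NULL
  thr <- cfg$survival$threshold
  if (is.null(thr)) {
    cutpoint <- .run_stage("cutpoint", optimal_cutpoint(
      maa_vals[os_ok], clinical$os_time[clin_idx[os_ok]],
      clinical$os_event[clin_idx[os_ok]],
      q_low = cfg$survival$q_low, q_high = cfg$survival$q_high,
      mode = cfg$survival$cutpoint_mode))
    thr <- cutpoint$threshold
  }
  maa <- .run_stage("maa", maa_table(activity, threshold = thr,
                                     e1 = tf_expr[[1L]], e2 = tf_expr[[2L]]))
  utils::write.table(format(maa, digits = 15, trim = TRUE),
                     file.path(out_dir, "maa.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## ---- survival analyses ----
  .stage_msg("survive", "KM / log-rank / Cox")
  surv_out <- .run_stage("survive", {
    tm <- clinical$os_time[clin_idx[os_ok]]
    ev <- clinical$os_event[clin_idx[os_ok]]
    grp <- maa$group[os_ok]
    strat <- droplevels(maa$stratum[os_ok])
    km <- lapply(split(seq_along(tm), grp), function(i) {
      k <- km_curve(tm[i], ev[i])
      data.frame(time = k$time, surv = k$surv, n_risk = k$n_risk)
    })
    multi <- tryCatch(
      stage_stratified_analysis(maa$maa[os_ok],
                                clinical[clin_idx[os_ok], , drop = FALSE]),
      error = function(e) {
        warning("stage-stratified analysis skipped: ", conditionMessage(e))
        NULL
      })
    list(
      threshold = thr,
      threshold_mode = if (is.null(cutpoint)) "fixed" else cutpoint$mode,
      tie_rule = "ties_to_above",
      km_curves = km,
      dichotomized = c(logrank_test(tm, ev, grp),
                       list(n_below = sum(grp == "below"),
                            n_above = sum(grp == "above"))),
      strata = if (nlevels(strat) >= 2L) logrank_test(tm, ev, strat)
               else NULL,
      univariate_maa = cox_fit(tm, ev, data.frame(maa = maa$maa[os_ok])),
      stage_stratified = multi)
  })
  km_dir <- file.path(out_dir, "km")
  dir.create(km_dir, showWarnings = FALSE)
  for (gname in names(surv_out$km_curves))
    utils::write.table(surv_out$km_curves[[gname]],
                       file.path(km_dir, paste0("km_", gname, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  surv_json <- .serialize_surv(surv_out)
  surv_json$km_curves <- NULL
  jsonlite::write_json(surv_json, file.path(out_dir, "survival.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## ---- feature screen ----
  screen <- NULL
  if (!is.null(features)) {
    .stage_msg("compare", "binary feature screen (Fisher + Bonferroni)")
    common <- intersect(colnames(features), maa$sample_id)
    screen <- .run_stage("compare", group_feature_screen(
      features[, common, drop = FALSE],
      maa$group[match(common, maa$sample_id)], test = "fisher"))
    utils::write.table(screen, file.path(out_dir, "feature_screen.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## ---- manifest ----
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(config_hash = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("maabalance")),
                   r_version = R.version.string,
                   artifacts = dir(out_dir))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(regulons = regulons, activity = activity, maa = maa,
                 cutpoint = cutpoint, survival = surv_out,
                 screen = screen))
}

.serialize_cox <- function(fit) {
  if (is.null(fit)) return(NULL)
  list(table = fit$table, n = fit$n, n_events = fit$n_events,
       ties = fit$ties, loglik = fit$loglik)
}

.serialize_surv <- function(s) {
  out <- s
  out$univariate_maa <- .serialize_cox(s$univariate_maa)
  if (!is.null(s$stage_stratified)) {
    out$stage_stratified <- list(
      univariate = lapply(s$stage_stratified$univariate, .serialize_cox),
      multivariate = .serialize_cox(s$stage_stratified$multivariate))
  }
  out
}

#' Command-line entry point
#'
#' Implements `maabalance <subcommand> --config cfg.yaml --out DIR
#' [--seed N] [--threshold X] [--force]`.  Subcommands: `simulate` (write
#' a synthetic cohort), `all` (full pipeline).  An executable wrapper
#' lives in `inst/cli/maabalance`.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status 0 invisibly on success; stops on error.
#' @export
maa_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: maabalance {all|simulate} --config CFG --out DIR [--seed N] [--threshold X] [--force]"
  if (length(args) < 1L) stop(usage, call. = FALSE)
  sub <- args[[1L]]
  opt <- list(force = FALSE)
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--force") { opt$force <- TRUE; i <- i + 1L; next }
    if (i == length(args)) stop("missing value for ", a, call. = FALSE)
    val <- args[[i + 1L]]
    opt[[sub("^--", "", a)]] <- val
    i <- i + 2L
  }
  if (is.null(opt$config) || is.null(opt$out)) stop(usage, call. = FALSE)
  cfg <- read_pipeline_config(opt$config)
  seed <- if (!is.null(opt$seed)) as.integer(opt$seed) else NULL
  thr <- if (!is.null(opt$threshold)) as.numeric(opt$threshold) else NULL
  if (sub == "all") {
    run_all(cfg, out_dir = opt$out, seed = seed, threshold = thr,
            force = opt$force)
  } else if (sub == "simulate") {
    if (is.null(cfg$simulate)) stop("config has no 'simulate' block")
    sp <- do.call(sim_params, utils::modifyList(
      cfg$simulate, list(seed = seed %||% cfg$seed)))
    write_cohort(generate_cohort(sp), opt$out, force = opt$force)
  } else {
    stop(usage, call. = FALSE)
  }
  invisible(0L)
}
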
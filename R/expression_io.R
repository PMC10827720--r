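#' Construct an expression matrix object
#'
#' Light S3 container for a features-by-samples expression matrix.  Rows are
#' transcript (isoform) or gene identifiers, columns are sample barcodes.
#'
#' @param values numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param feature_level `"isoform"` or `"gene"`.
#' @param log_transformed logical; `TRUE` once values are on log2 scale.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, feature_level = c("isoform", "gene"),
                              log_transformed = FALSE) {
  feature_level <- match.arg(feature_level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (!log_transformed && any(values < 0))
    stop("linear-scale expression values must be non-negative")
  structure(list(values = values,
                 feature_level = feature_level,
                 log_transformed = log_transformed),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d %s features x %d samples (%s scale)\n",
              nrow(x$values), x$feature_level, ncol(x$values),
              if (x$log_transformed) "log2" else "linear"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Feature and sample identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample barcodes with the first column holding
#' feature identifiers (RSEM-isoform-style TSV).  Every data cell must be
#' numeric; `NA` or text cells are rejected with their coordinates so that a
#' corrupted download fails loudly instead of propagating.
#'
#' @param path TSV file path.
#' @param feature_level declared level of the row identifiers.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, feature_level = c("isoform", "gene")) {
  feature_level <- match.arg(feature_level)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed expression file: ", path)
  ids <- raw[[1L]]
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                dimnames = dimnames(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop(sprintf("non-numeric expression cell at row %d (feature '%s'), column '%s'",
                 b[1L], ids[b[1L]], colnames(body)[b[2L]]))
  }
  rownames(num) <- ids
  expression_matrix(num, feature_level = feature_level)
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: header `feature_id` followed by
#' sample barcodes, values printed with 15 significant digits so a round
#' trip preserves them to at least 12.
#'
#' @param mat an `ExpressionMatrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  df <- data.frame(feature_id = rownames(mat$values),
                   format(mat$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Isoform-to-gene map with designated regulator isoforms
#'
#' @param map named character vector: names are isoform ids, values gene
#'   symbols.
#' @param regulators named list: one entry per master regulator, each a
#'   character vector of its designated isoform ids (all must be in `map`).
#' @return An `IsoformMap` object.
#' @export
isoform_map <- function(map, regulators = list()) {
  if (is.null(names(map)) || any(!nzchar(names(map))))
    stop("`map` must be a named character vector (isoform id -> gene symbol)")
  if (anyDuplicated(names(map)))
    stop("each isoform must map to exactly one gene symbol")
  for (tf in names(regulators)) {
    missing <- setdiff(regulators[[tf]], names(map))
    if (length(missing))
      stop("designated isoforms of ", tf, " absent from map: ",
           paste(missing, collapse = ", "))
  }
  structure(list(map = map, regulators = regulators), class = "IsoformMap")
}

#' Default isoform map for the TTF1 / p40 regulator pair
#'
#' UCSC transcript identifiers of the designated isoforms: the four
#' N-terminally truncated p63 isoforms collectively detected as p40
#' (\eqn{\Delta}Np63\eqn{\alpha}/\eqn{\beta}/\eqn{\gamma}/\eqn{\epsilon})
#' and the three TTF1 (NKX2-1) transcripts.
#'
#' @return An [isoform_map()].
#' @export
default_isoform_map <- function() {
  p40 <- c("uc003fsc.2", "uc003fsd.2", "uc003fsb.2", "uc010hzd.1")
  ttf1 <- c("uc001wtt.2", "uc001wtu.2", "uc001wtv.2")
  map <- c(stats::setNames(rep("TP63", length(p40)), p40),
           stats::setNames(rep("NKX2-1", length(ttf1)), ttf1))
  isoform_map(map, regulators = list(TTF1 = ttf1, p40 = p40))
}

#' Aggregate an isoform-level matrix to gene level
#'
#' Two aggregation rules are supported: `sum` adds the expression of all
#' isoforms of a gene elementwise (the convention used for regulator
#' expression), and `max_variance` keeps, for each gene, the single isoform
#' with the largest variance across samples (the convention for collapsing
#' probe/transcript-level data).  Variance ties break to the
#' lexicographically smallest isoform id, so builds are deterministic.
#' Unmapped isoforms are dropped with a message reporting the count.
#'
#' @param mat isoform-level `ExpressionMatrix`.
#' @param map an [isoform_map()].
#' @param rule `"sum"` or `"max_variance"`.
#' @return Gene-level `ExpressionMatrix`.
#' @export
aggregate_to_gene <- function(mat, map, rule = c("sum", "max_variance")) {
  rule <- match.arg(rule)
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(map, "IsoformMap"))
  if (mat$feature_level != "isoform")
    stop("`mat` must be at isoform level")
  iso <- intersect(rownames(mat$values), names(map$map))
  n_dropped <- nrow(mat$values) - length(iso)
  if (length(iso) == 0L)
    stop("no isoform of `mat` appears in the mapping")
  if (n_dropped > 0L)
    message(n_dropped, " unmapped isoform(s) dropped during aggregation")
  genes <- map$map[iso]
  vals <- mat$values[iso, , drop = FALSE]
  out <- if (rule == "sum") {
    rowsum(vals, group = genes, reorder = TRUE)
  } else {
    v <- apply(vals, 1L, stats::var)
    keep <- vapply(split(iso, genes), function(members) {
      members <- members[order(members)]          # tie -> smallest isoform id
      members[which.max(v[members])]
    }, character(1L))
    m <- vals[keep, , drop = FALSE]
    rownames(m) <- names(keep)
    m[order(rownames(m)), , drop = FALSE]
  }
  expression_matrix(out, feature_level = "gene",
                    log_transformed = mat$log_transformed)
}

#' Log2-transform an expression matrix
#'
#' Applies \eqn{v \mapsto \log_2(v + \mathrm{pseudocount})}.  The default
#' pseudocount of 1 keeps zero expression at zero on the log scale.
#'
#' @param mat linear-scale `ExpressionMatrix`.
#' @param pseudocount positive offset added before the log.
#' @return Log-scale `ExpressionMatrix`.
#' @export
log_transform <- function(mat, pseudocount = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (mat$log_transformed)
    stop("matrix is already log-transformed")
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L || pseudocount <= 0)
    stop("`pseudocount` must be a positive scalar")
  if (any(mat$values < 0))
    stop("negative values cannot be log-transformed")
  expression_matrix(log2(mat$values + pseudocount),
                    feature_level = mat$feature_level, log_transformed = TRUE)
}

.stage_levels <- c("I", "II", "IIIA", "IIIB", "IV")

.normalize_stage <- function(x) {
  s <- toupper(gsub("[[:space:]]+", "", as.character(x)))
  s <- sub("^STAGE", "", s)
  s[!nzchar(s)] <- NA_character_
  unknown <- !is.na(s) & !(s %in% .stage_levels)
  if (any(unknown)) {
    warning(sum(unknown), " unknown stage label(s) set to missing: ",
            paste(unique(s[unknown]), collapse = ", "))
    s[unknown] <- NA_character_
  }
  factor(s, levels = .stage_levels)
}

#' Read a clinical table
#'
#' Reads a TSV with one row per patient/sample.  Required columns:
#' `sample_id`, `os_time` (days), `os_event` (0/1).  Optional: `rfs_time`,
#' `rfs_event`, `stage`, `sex`, `age`, `pack_years`.  Stage labels are
#' normalized case-insensitively with `"Stage"` prefixes and whitespace
#' stripped; unrecognized labels become missing with a warning.  Rows
#' lacking survival status are kept but flagged in the `has_survival`
#' column so each model can apply its own complete-case rule.
#'
#' @param path TSV path.
#' @return A `ClinicalTable` data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = TRUE)
  as_clinical_table(df)
}

#' Validate and type a clinical data frame
#' @param df data frame with the columns described in [read_clinical()].
#' @return A `ClinicalTable` data frame.
#' @export
as_clinical_table <- function(df) {
  req <- c("sample_id", "os_time", "os_event")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("clinical table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    os_time = as.numeric(df$os_time),
                    os_event = as.numeric(df$os_event),
                    stringsAsFactors = FALSE)
  bad_event <- !is.na(out$os_event) & !(out$os_event %in% c(0, 1))
  if (any(bad_event))
    stop("os_event must be 0/1; offending sample(s): ",
         paste(utils::head(out$sample_id[bad_event], 5L), collapse = ", "))
  if (any(out$os_time < 0, na.rm = TRUE))
    stop("survival times must be non-negative")
  for (col in c("rfs_time", "rfs_event", "age", "pack_years"))
    out[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  if (any(!is.na(out$rfs_event) & !(out$rfs_event %in% c(0, 1))))
    stop("rfs_event must be 0/1")
  out$stage <- if ("stage" %in% names(df)) .normalize_stage(df$stage)
               else factor(rep(NA_character_, nrow(df)), levels = .stage_levels)
  out$sex <- if ("sex" %in% names(df)) factor(df$sex) else
             factor(rep(NA_character_, nrow(df)))
  out$has_survival <- !is.na(out$os_time) & !is.na(out$os_event)
  class(out) <- c("ClinicalTable", "data.frame")
  out
}
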
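#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rnorm rexp rbinom runif rweibull uniroot
#'   setNames complete.cases as.formula predict p.adjust pchisq qnorm stepfun
#' @importFrom utils read.delim write.table head
NULL

# Levels accepted for each categorical clinical column.  Encodings follow the
# usual dichotomies used for ccRCC survival modelling (grade 3&4 vs 1&2,
# stage III&IV vs I&II, M1 vs M0, ...); "unknown"-type levels are retained at
# parse time and dropped listwise at model-fitting time.
CLINICAL_LEVELS <- list(
  age_group   = c("older", "younger"),
  gender      = c("male", "female"),
  grade_group = c("G1&2", "G3&4"),
  stage_group = c("I&II", "III&IV"),
  t_group     = c("T1&2", "T3&4"),
  n_status    = c("N0", "N1", "NX"),
  m_status    = c("M0", "M1", "MX"),
  hemoglobin  = c("low", "normal", "unknown"),
  platelet    = c("elevated", "normal", "unknown"),
  calcium     = c("low", "normal", "unknown")
)

# Per-variable risk coding used by the Cox/nomogram layer: indicator = 1 for
# the first named level, 0 for the second, NA otherwise (listwise deletion).
COVARIATE_CODING <- list(
  age_group   = c(risk = "older",    ref = "younger"),
  gender      = c(risk = "male",     ref = "female"),
  grade_group = c(risk = "G3&4",     ref = "G1&2"),
  stage_group = c(risk = "III&IV",   ref = "I&II"),
  t_group     = c(risk = "T3&4",     ref = "T1&2"),
  n_status    = c(risk = "N1",       ref = "N0"),
  m_status    = c(risk = "M1",       ref = "M0"),
  hemoglobin  = c(risk = "low",      ref = "normal"),
  platelet    = c(risk = "elevated", ref = "normal"),
  calcium     = c(risk = "low",      ref = "normal")
)

REQUIRED_CLINICAL_COLS <- c("sample_id", "os_time", "os_event")

#' Construct an expression matrix container
#'
#' A light container for a gene-by-sample matrix of log-scale expression
#' values together with a tumor/normal group label per sample.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids). Values are assumed to be on
#'   a log scale and already normalized; the package never normalizes.
#' @param sample_group Character or factor of length `ncol(values)` with
#'   levels `"tumor"` and `"normal"`, in column order.
#' @return An object of class `mps_expression`: a list with elements
#'   `values` and `sample_group` (named factor).
#' @export
expression_matrix <- function(values, sample_group) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) && nrow(values) > 0)
    stop("`values` must have gene symbols as rownames", call. = FALSE)
  if (is.null(colnames(values)) && ncol(values) > 0)
    stop("`values` must have sample ids as colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene symbol(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (length(values) && any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  sample_group <- as.character(sample_group)
  if (length(sample_group) != ncol(values))
    stop("`sample_group` must have one entry per sample column", call. = FALSE)
  if (length(sample_group) && !all(sample_group %in% c("tumor", "normal")))
    stop("`sample_group` levels must be 'tumor' or 'normal'", call. = FALSE)
  structure(
    list(values = values,
         sample_group = setNames(factor(sample_group, levels = c("tumor", "normal")),
                                 colnames(values))),
    class = "mps_expression")
}

#' @export
print.mps_expression <- function(x, ...) {
  cat(sprintf("<mps_expression> %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$sample_group == "tumor"), sum(x$sample_group == "normal")))
  invisible(x)
}

#' @export
dim.mps_expression <- function(x) dim(x$values)

#' Sample ids of tumor (or normal) samples
#' @param expr An `mps_expression`.
#' @param group `"tumor"` or `"normal"`.
#' @return Character vector of sample ids.
#' @export
samples_in_group <- function(expr, group = c("tumor", "normal")) {
  group <- match.arg(group)
  names(expr$sample_group)[expr$sample_group == group]
}

#' Construct a clinical table
#'
#' Validates a per-sample clinical data frame: overall-survival time and
#' event indicator plus the dichotomized covariates used downstream.
#' Times are held in days internally; `time_unit = "months"` converts on the
#' way in (x 30.44).
#'
#' @param df Data frame with columns `sample_id`, `os_time`, `os_event` and
#'   optionally the categorical covariates (`age_group`, `gender`,
#'   `grade_group`, `stage_group`, `t_group`, `n_status`, `m_status`,
#'   `hemoglobin`, `platelet`, `calcium`).
#' @param time_unit Unit of `os_time` in `df`; `"days"` (default) or
#'   `"months"`.
#' @return A data frame of class `mps_clinical` (times in days).
#' @export
clinical_table <- function(df, time_unit = c("days", "months")) {
  time_unit <- match.arg(time_unit)
  if (!is.data.frame(df)) stop("`df` must be a data frame", call. = FALSE)
  missing_cols <- setdiff(REQUIRED_CLINICAL_COLS, names(df))
  if (length(missing_cols))
    stop("missing required clinical column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  df$os_time <- as.numeric(df$os_time)
  if (nrow(df) && (anyNA(df$os_time) || any(df$os_time < 0)))
    stop("os_time must be nonnegative and non-missing", call. = FALSE)
  if (time_unit == "months") df$os_time <- df$os_time * 30.44
  if (nrow(df) && !all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 or 1", call. = FALSE)
  df$os_event <- as.integer(df$os_event)
  for (col in names(CLINICAL_LEVELS)) {
    if (!col %in% names(df)) next
    vals <- as.character(df[[col]])
    bad <- setdiff(unique(vals[!is.na(vals)]), CLINICAL_LEVELS[[col]])
    if (length(bad))
      stop(sprintf("column '%s' has unknown level(s): %s", col,
                   paste(bad, collapse = ", ")), call. = FALSE)
    df[[col]] <- factor(vals, levels = CLINICAL_LEVELS[[col]])
  }
  class(df) <- c("mps_clinical", "data.frame")
  df
}

#' Construct a gene panel
#'
#' An mPS panel: per gene a favorable-state indicator pair (`score_high`,
#' `score_low`, exactly one of which is 1) and a positive weight. The
#' molecular prognostic score of a sample is the sum of Gene-Score x
#' Gene-Weight over panel genes.
#'
#' @param symbol Character vector of unique gene symbols.
#' @param score_high,score_low Integer 0/1 vectors; `score_high[g] = 1` means
#'   above-median expression of gene `g` scores 1 (and below-median 0),
#'   `score_low[g] = 1` the converse. Exactly one of the two is 1 per gene.
#' @param weight Positive numeric weights.
#' @param provenance Free-text provenance string.
#' @return A data frame of class `mps_panel`.
#' @export
gene_panel <- function(symbol, score_high, score_low, weight,
                       provenance = "unspecified") {
  symbol <- as.character(symbol)
  if (length(symbol) == 0L) stop("empty panel", call. = FALSE)
  if (anyDuplicated(symbol))
    stop("duplicate panel symbol(s): ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "),
         call. = FALSE)
  n <- length(symbol)
  if (length(score_high) != n || length(score_low) != n || length(weight) != n)
    stop("panel columns have mismatched lengths", call. = FALSE)
  if (!all(score_high %in% c(0, 1)) || !all(score_low %in% c(0, 1)) ||
      any(score_high + score_low != 1))
    stop("per gene exactly one of score_high/score_low must be 1", call. = FALSE)
  weight <- as.numeric(weight)
  if (anyNA(weight) || any(weight <= 0))
    stop("panel weights must be positive", call. = FALSE)
  out <- data.frame(symbol = symbol,
                    score_high = as.integer(score_high),
                    score_low = as.integer(score_low),
                    weight = weight,
                    stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  class(out) <- c("mps_panel", "data.frame")
  out
}

#' The published 21-gene ccRCC panel
#'
#' The 21-gene clear cell renal cell carcinoma mPS panel shipped with the
#' package, with the published favorable-state indicators and weights.
#'
#' @return An `mps_panel` with 21 entries (weights sum to 74.616).
#' @export
panel_table2 <- function() {
  path <- system.file("extdata", "panel_table2.tsv", package = "mpscore",
                      mustWork = TRUE)
  read_panel(path)
}
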
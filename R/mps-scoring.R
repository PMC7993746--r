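# Apply a gene panel to a cohort: weighted-sum molecular prognostic score
# per sample plus threshold stratification. The deployable core.

#' Stratification scheme
#'
#' Half-open binning exactly as published for the 21-gene ccRCC panel:
#' three groups low (mPS < 22), median (22 <= mPS < 30), high (mPS >= 30),
#' or two groups low (mPS < 22) / high (mPS >= 22) for small cohorts.
#' Thresholds are fixed constants of the scheme, not re-estimated.
#'
#' @param thresholds Strictly ascending numeric cut points.
#' @param labels Stratum names, one more than `thresholds`.
#' @return List of class `stratification_scheme`.
#' @export
stratification_scheme <- function(thresholds = c(22, 30),
                                  labels = NULL) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) < 1L || is.unsorted(thresholds, strictly = TRUE))
    stop("`thresholds` must be strictly ascending", call. = FALSE)
  if (is.null(labels)) {
    labels <- if (length(thresholds) == 1L) c("low", "high")
              else if (length(thresholds) == 2L) c("low", "median", "high")
              else paste0("stratum", seq_len(length(thresholds) + 1L))
  }
  if (length(labels) != length(thresholds) + 1L)
    stop("need one more label than thresholds", call. = FALSE)
  structure(list(thresholds = thresholds, labels = as.character(labels)),
            class = "stratification_scheme")
}

#' Per-gene median reference
#'
#' Cutoffs frozen from a source cohort so a panel can be applied to new
#' samples without re-estimating medians.
#'
#' @param cutoffs Named numeric vector (one cutoff per panel gene).
#' @param source Free-text tag of the source cohort.
#' @return List of class `median_reference`.
#' @export
median_reference <- function(cutoffs, source = "unspecified") {
  if (is.null(names(cutoffs)) || anyNA(cutoffs))
    stop("`cutoffs` must be a complete named vector", call. = FALSE)
  structure(list(cutoffs = cutoffs, source = source),
            class = "median_reference")
}

#' Compute mPS from a binary score matrix
#'
#' mPS(sample) = sum over panel genes of Gene-Score x Gene-Weight; bounded
#' by 0 and the sum of panel weights.
#'
#' @param scores Binary gene-by-sample matrix containing every panel gene.
#' @param panel An `mps_panel`.
#' @return Data frame (`mps_result`): `sample_id`, `mps`.
#' @export
compute_mps <- function(scores, panel) {
  stopifnot(inherits(panel, "mps_panel"))
  missing_genes <- setdiff(panel$symbol, rownames(scores))
  if (length(missing_genes))
    stop("score matrix missing panel gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  s <- scores[panel$symbol, , drop = FALSE]
  if (!all(s %in% c(0, 1))) stop("score matrix must be binary", call. = FALSE)
  mps <- as.numeric(t(s) %*% panel$weight)
  data.frame(sample_id = colnames(scores), mps = mps,
             stringsAsFactors = FALSE)
}

#' Stratify mPS results
#'
#' Assigns stratum `k` when `thresholds[k-1] <= mps < thresholds[k]`
#' (half-open bins, top stratum closed above by +Inf).
#'
#' @param results Data frame with an `mps` column.
#' @param scheme A [stratification_scheme()].
#' @return `results` with a `stratum` factor column added.
#' @export
stratify <- function(results, scheme = stratification_scheme()) {
  stopifnot(inherits(scheme, "stratification_scheme"))
  idx <- findInterval(results$mps, scheme$thresholds) + 1L
  results$stratum <- factor(scheme$labels[idx], levels = scheme$labels)
  results
}

#' Score a cohort with a gene panel
#'
#' Binarizes each panel gene against its median (per-cohort medians by
#' default, mirroring how a panel is applied to an external validation
#' cohort; pass a [median_reference()] to transfer construction-cohort
#' cutoffs), maps states to Gene-Scores using the panel's favorable-state
#' indicators, then computes mPS and stratifies. Deterministic.
#'
#' @param expr An `mps_expression` (tumor samples are scored).
#' @param panel An `mps_panel`.
#' @param medians `NULL` (per-cohort medians) or a [median_reference()].
#' @param scheme A [stratification_scheme()].
#' @param mode `"strict"` errors on any missing panel gene; `"permissive"`
#'   imputes a missing gene at its median state (i.e. the low state, so the
#'   gene contributes its `score_low` value). More than 20% missing panel
#'   genes is an error in either mode.
#' @return Data frame (`mps_result`): `sample_id`, `mps`, `stratum`.
#' @export
score_cohort <- function(expr, panel, medians = NULL,
                         scheme = stratification_scheme(),
                         mode = c("strict", "permissive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(panel, "mps_panel"))
  tumor_ids <- samples_in_group(expr, "tumor")
  if (length(tumor_ids) == 0L) stop("no tumor samples to score", call. = FALSE)
  if (length(tumor_ids) == 1L)
    warning("single-sample cohort: per-cohort medians tie every gene to ",
            "its own value, so all genes take the low state", call. = FALSE)
  present <- intersect(panel$symbol, rownames(expr$values))
  absent <- setdiff(panel$symbol, present)
  if (length(absent) > 0.2 * nrow(panel))
    stop(sprintf("%d of %d panel genes absent from expression (> 20%%): %s",
                 length(absent), nrow(panel),
                 paste(absent, collapse = ", ")), call. = FALSE)
  if (length(absent) && mode == "strict")
    stop("panel gene(s) absent from expression: ",
         paste(absent, collapse = ", "), call. = FALSE)
  x <- expr$values[present, tumor_ids, drop = FALSE]
  cutoffs <- if (is.null(medians)) {
    apply(x, 1L, median)
  } else {
    stopifnot(inherits(medians, "median_reference"))
    miss <- setdiff(present, names(medians$cutoffs))
    if (length(miss))
      stop("median reference missing gene(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    medians$cutoffs[present]
  }
  pan <- panel[match(present, panel$symbol), , drop = FALSE]
  high_state <- x > cutoffs
  scores <- matrix(0L, nrow = nrow(panel), ncol = length(tumor_ids),
                   dimnames = list(panel$symbol, tumor_ids))
  for (i in seq_along(present)) {
    g <- present[i]
    scores[g, ] <- if (pan$score_high[i] == 1L) as.integer(high_state[i, ])
                   else as.integer(!high_state[i, ])
  }
  if (length(absent)) {
    message("imputing median (low) state for absent gene(s): ",
            paste(absent, collapse = ", "))
    for (g in absent)
      scores[g, ] <- panel$score_low[match(g, panel$symbol)]
  }
  stratify(compute_mps(scores, panel), scheme)
}
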
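# Stage 1 of panel construction: genes that are both prognosis-associated
# (median-split overall survival) and differentially expressed between
# tumor and normal samples.

#' Median-split survival analysis for one gene
#'
#' Tumor samples are split at the cohort median expression of the gene
#' (strictly above the median = high group; ties go to the low group). The
#' hazard ratio of high vs low comes from a Cox proportional-hazards fit on
#' the binary indicator (Wald CI and p), and the groups are compared with a
#' log-rank test.
#'
#' @param expr An `mps_expression`.
#' @param clinical An `mps_clinical` (joined to `expr` on sample_id).
#' @param gene Gene symbol.
#' @return One-row data frame: `symbol`, `median_cutoff`, `hr`, `ci_low`,
#'   `ci_high`, `logrank_p`, `wald_p`, `scoreable` (FALSE when one split
#'   group is empty).
#' @export
median_split_survival <- function(expr, clinical, gene) {
  if (!gene %in% rownames(expr$values))
    stop("gene not present: ", gene, call. = FALSE)
  al <- align_samples(expr, clinical, mode = "permissive")
  x <- al$expr$values[gene, ]
  median_split_one(x, al$clinical$os_time, al$clinical$os_event, gene)
}

# Core per-gene computation on aligned vectors; returns a flagged row
# instead of an error for unscoreable (constant) genes.
median_split_one <- function(x, time, event, symbol) {
  cutoff <- median(x)
  high <- x > cutoff
  out <- data.frame(symbol = symbol, median_cutoff = cutoff,
                    hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    logrank_p = NA_real_, wald_p = NA_real_,
                    scoreable = FALSE, stringsAsFactors = FALSE)
  if (sum(high) < 2L || sum(!high) < 2L) return(out)
  if (sum(event) < 1L) stop("no events in cohort", call. = FALSE)
  fit <- survival::coxph(survival::Surv(time, event) ~ high, ties = "efron")
  beta <- unname(fit$coefficients[1L])
  se <- sqrt(fit$var[1L, 1L])
  if (!is.finite(beta) || !is.finite(se)) return(out)
  sd <- survival::survdiff(survival::Surv(time, event) ~ high)
  out$hr <- exp(beta)
  out$ci_low <- exp(beta - qnorm(0.975) * se)
  out$ci_high <- exp(beta + qnorm(0.975) * se)
  out$wald_p <- 2 * stats::pnorm(-abs(beta / se))
  out$logrank_p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
  out$scoreable <- TRUE
  out
}

#' Survival screen over all genes
#'
#' Runs [median_split_survival()] for every gene and returns the genes
#' whose log-rank p-value passes `alpha` (unadjusted, mirroring a raw
#' genome-wide screening count), sorted by p ascending. The full per-gene
#' table is retained for reporting.
#'
#' @param expr An `mps_expression`.
#' @param clinical An `mps_clinical`.
#' @param alpha Screening level in `(0, 1]`; `alpha = 0` returns no genes.
#' @return List with `hits` (rows passing, sorted by `logrank_p`) and
#'   `results` (all genes, input order).
#' @export
screen_survival <- function(expr, clinical, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("`alpha` must be in [0, 1]", call. = FALSE)
  al <- align_samples(expr, clinical, mode = "permissive")
  time <- al$clinical$os_time; event <- al$clinical$os_event
  if (sum(event) < 1L) stop("no events in cohort", call. = FALSE)
  rows <- lapply(rownames(al$expr$values), function(g)
    median_split_one(al$expr$values[g, ], time, event, g))
  results <- do.call(rbind, rows)
  hits <- results[results$scoreable & !is.na(results$logrank_p) &
                    results$logrank_p < alpha, , drop = FALSE]
  hits <- hits[order(hits$logrank_p), , drop = FALSE]
  rownames(hits) <- rownames(results) <- NULL
  list(hits = hits, results = results)
}

#' Tumor-vs-normal differential expression
#'
#' Moderated t-statistics via limma's empirical-Bayes machinery: per gene,
#' `log2fc` is the tumor-minus-normal mean difference on the log2 scale,
#' variances are shrunk toward a pooled prior estimated across genes, and
#' p-values are Benjamini-Hochberg adjusted. A gene `passes` when
#' `adj_p < alpha` and `|log2fc| > lfc`.
#'
#' @param expr An `mps_expression` with at least 2 tumor and 2 normal
#'   samples.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc Absolute log2 fold-change cutoff (default 2).
#' @return Data frame: `symbol`, `log2fc`, `t_stat`, `p`, `adj_p`,
#'   `passes`, in input gene order.
#' @export
differential_expression <- function(expr, alpha = 0.05, lfc = 2) {
  grp <- expr$sample_group
  if (sum(grp == "tumor") < 2L || sum(grp == "normal") < 2L)
    stop("need at least 2 tumor and 2 normal samples", call. = FALSE)
  rv <- apply(expr$values, 1L, stats::var)
  if (all(rv == 0))
    stop("all genes have zero variance; cannot moderate variances",
         call. = FALSE)
  design <- cbind(intercept = 1, tumor = as.integer(grp == "tumor"))
  fit <- limma::lmFit(expr$values, design)
  fit <- limma::eBayes(fit)
  tab <- limma::topTable(fit, coef = "tumor", number = Inf, sort.by = "none",
                         adjust.method = "BH")
  out <- data.frame(symbol = rownames(expr$values),
                    log2fc = tab$logFC, t_stat = tab$t,
                    p = tab$P.Value, adj_p = tab$adj.P.Val,
                    stringsAsFactors = FALSE)
  out$passes <- out$adj_p < alpha & abs(out$log2fc) > lfc
  rownames(out) <- NULL
  out
}

#' Intersect survival hits with DE hits
#'
#' Deterministic set intersection of the two screening stages, ordered by
#' survival p-value ascending.
#'
#' @param survival_hits `hits` data frame from [screen_survival()] (or a
#'   character vector of symbols, returned in input order).
#' @param de_hits Data frame from [differential_expression()] restricted to
#'   passing genes (or a character vector of symbols).
#' @return Character vector of gene symbols.
#' @export
intersect_prognostic_de <- function(survival_hits, de_hits) {
  if (is.data.frame(survival_hits)) {
    surv_sym <- survival_hits$symbol[order(survival_hits$logrank_p)]
  } else surv_sym <- as.character(survival_hits)
  if (is.data.frame(de_hits)) {
    de_sym <- if ("passes" %in% names(de_hits)) de_hits$symbol[de_hits$passes]
              else de_hits$symbol
  } else de_sym <- as.character(de_hits)
  surv_sym[surv_sym %in% de_sym]
}
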
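# Shared fixtures, all generated in code.

# Small cohort with planted structure and no clinical-covariate hazard
# (betas zero => per-gene median-split HR is exactly the planted HR).
small_cohort <- function(seed = 1, n_tumor = 150, n_genes = 60,
                         n_prognostic = 6, n_de = 6, censor_rate = 0.3,
                         planted_log_hr = log(2), ...) {
  generate_cohort(simulation_config(
    n_tumor = n_tumor, n_normal = 30, n_genes = n_genes,
    n_prognostic = n_prognostic, n_de = n_de,
    planted_log_hr = planted_log_hr, censor_rate = censor_rate,
    covariate_betas = setNames(rep(0, 10), names(mpscore:::DEFAULT_COV_BETAS)),
    seed = seed, ...))
}

# Minimal hand-built clinical table.
toy_clinical <- function(time, event, ...) {
  clinical_table(data.frame(
    sample_id = sprintf("S%02d", seq_along(time)),
    os_time = time, os_event = event, ...,
    stringsAsFactors = FALSE))
}

# A tiny expression container.
toy_expression <- function(values, groups) {
  expression_matrix(values, groups)
}

# Binary score matrix with informative and null features for RF/NN tests:
# informative rows copy the label with `flip` probability of disagreement.
toy_scores <- function(n_informative, n_null, n_samples, flip = 0.15,
                       seed = 1) {
  withr::with_seed(seed, {
    labels <- rbinom(n_samples, 1, 0.5)
    inf <- t(vapply(seq_len(n_informative), function(i) {
      ifelse(runif(n_samples) < flip, 1L - labels, labels)
    }, integer(n_samples)))
    nul <- matrix(rbinom(n_null * n_samples, 1, 0.5), nrow = n_null)
    scores <- rbind(inf, nul)
    rownames(scores) <- c(sprintf("INF%02d", seq_len(n_informative)),
                          sprintf("NULL%02d", seq_len(n_null)))
    colnames(scores) <- sprintf("S%03d", seq_len(n_samples))
    list(scores = scores, labels = labels)
  })
}
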
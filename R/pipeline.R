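# End-to-end orchestration: simulate -> screen -> build panel -> score ->
# evaluate, with one global seed expanded into per-stage seeds, per-stage
# output files and manifests. Rerunning a config reproduces identical
# outputs.

#' Pipeline configuration
#'
#' Bundles the stage parameters and a single global seed. The global seed
#' is expanded into independent per-stage seeds by a fixed affine
#' derivation (`stage_seed(seed, k)`), so stages are reproducible in
#' isolation.
#'
#' @param sim A [simulation_config()] (its `seed` is overridden by the
#'   derived stage seed).
#' @param alpha Survival-screen level.
#' @param de_alpha,de_lfc DE cutoffs (adjusted p, |log2 FC|).
#' @param rf An [rf_config()].
#' @param nn An [nn_config()].
#' @param strata Numeric thresholds for [stratification_scheme()], or
#'   `"median"` to split each scored cohort at its own median mPS (the
#'   published thresholds are constants of the published weight scale and
#'   do not transfer to freshly trained panels).
#' @param label_horizon Horizon (days) for the 3-year-status training
#'   labels.
#' @param horizons Nomogram horizons (days).
#' @param n_boot Calibration bootstrap resamples.
#' @param covariates Clinical covariates offered to the Cox screen.
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            alpha = 0.05, de_alpha = 0.05, de_lfc = 2,
                            rf = rf_config(), nn = nn_config(),
                            strata = "median",
                            label_horizon = 3 * 365.25,
                            horizons = c(3, 5) * 365.25,
                            n_boot = 200,
                            covariates = c("age_group", "gender",
                                           "grade_group", "stage_group",
                                           "t_group", "n_status", "m_status",
                                           "hemoglobin", "platelet",
                                           "calcium"),
                            seed = 1L, out_dir = tempfile("mps_run_")) {
  structure(list(sim = sim, alpha = alpha, de_alpha = de_alpha,
                 de_lfc = de_lfc, rf = rf, nn = nn, strata = strata,
                 label_horizon = label_horizon, horizons = horizons,
                 n_boot = n_boot, covariates = covariates,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Derive a per-stage seed from the global seed
#' @param seed Global seed.
#' @param stage Stage index (1-based).
#' @return Integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + 104729 * stage) %% .Machine$integer.max)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(out_dir, stage, config, seed, inputs, outputs,
                           counts = list()) {
  manifest <- list(stage = stage, seed = seed,
                   config_hash = config_hash(config),
                   inputs = inputs, outputs = outputs, counts = counts,
                   package_version = as.character(utils::packageVersion("mpscore")))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the full mPS pipeline on a synthetic cohort
#'
#' Chains the stages: (1) simulate a construction cohort and an independent
#' held-out cohort from the same generator settings; (2) screen
#' (median-split survival + moderated-t DE + intersection); (3) build the
#' panel (Gene-Scores on the intersect genes, random-forest selection on
#' 3-year status, neural-network training, weight extraction); (4) score
#' both cohorts; (5) evaluate (KM/log-rank by stratum, Cox screen over mPS
#' group + clinical covariates, C-index, nomogram, calibration). Every
#' stage writes its outputs and a manifest under `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List with the stage results (`cohort`, `holdout`, `screen`,
#'   `panel`, `scores`, `evaluation`) and `out_dir`.
#' @export
run_mps_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # stage 1: simulate construction + held-out cohorts
  sim_cfg <- config$sim; sim_cfg$seed <- stage_seed(config$seed, 1L)
  cohort <- generate_cohort(sim_cfg)
  hold_cfg <- config$sim; hold_cfg$seed <- stage_seed(config$seed, 6L)
  holdout <- generate_cohort(hold_cfg)
  write_expression(cohort$expression, file.path(out, "expression.tsv"))
  write_clinical(cohort$clinical, file.path(out, "clinical.tsv"))
  write_ground_truth(cohort$truth, file.path(out, "truth.json"))
  write_manifest(out, "simulate", config, sim_cfg$seed,
                 inputs = list(), outputs = c("expression.tsv", "clinical.tsv",
                                              "truth.json"),
                 counts = list(n_tumor = sim_cfg$n_tumor,
                               n_genes = sim_cfg$n_genes))

  # stage 2: survival screen + DE + intersection
  scr <- screen_survival(cohort$expression, cohort$clinical,
                         alpha = config$alpha)
  de <- differential_expression(cohort$expression, alpha = config$de_alpha,
                                lfc = config$de_lfc)
  intersect_genes <- intersect_prognostic_de(scr$hits, de)
  write.table(scr$results, file.path(out, "survival_screen.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(de, file.path(out, "differential_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(intersect_genes, file.path(out, "intersect_genes.txt"))
  write_manifest(out, "screen", config, NA,
                 inputs = c("expression.tsv", "clinical.tsv"),
                 outputs = c("survival_screen.tsv",
                             "differential_expression.tsv",
                             "intersect_genes.txt"),
                 counts = list(genes_screened = nrow(scr$results),
                               survival_hits = nrow(scr$hits),
                               de_hits = sum(de$passes),
                               intersect = length(intersect_genes)))
  if (length(intersect_genes) == 0L)
    stop("screen produced no candidate genes; cannot build a panel",
         call. = FALSE)

  # stage 3: Gene-Scores, RF selection, NN training, panel assembly
  gs <- assign_gene_scores(cohort$expression, scr$results, intersect_genes)
  status <- event_status_at(cohort$clinical, config$label_horizon)
  known <- names(status)[status != "unknown"]
  labels <- as.integer(status[known] == "dead")
  rf_cfg <- config$rf; rf_cfg$seed <- stage_seed(config$seed, 3L)
  imp <- rf_select_features(gs$scores[, known, drop = FALSE], labels, rf_cfg)
  selected <- imp$symbol[imp$selected]
  if (length(selected) == 0L)
    stop("random forest selected no genes at the importance cutoff",
         call. = FALSE)
  nn_cfg <- config$nn; nn_cfg$seed <- stage_seed(config$seed, 4L)
  model <- train_nn(gs$scores[selected, known, drop = FALSE], labels, nn_cfg)
  weights <- extract_gene_weights(model)
  panel <- build_panel(selected[weights[selected] > 0], gs$directions,
                       weights,
                       provenance = sprintf("synthetic build, seed %d",
                                            config$seed))
  write_panel(panel, file.path(out, "panel.tsv"))
  jsonlite::write_json(
    list(rf = unclass(rf_cfg), nn = unclass(nn_cfg),
         importances = imp,
         loss = list(first = model$loss_trace[1L],
                     last = model$loss_trace[length(model$loss_trace)])),
    file.path(out, "panel_provenance.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(out, "build_panel", config, rf_cfg$seed,
                 inputs = c("expression.tsv", "clinical.tsv",
                            "intersect_genes.txt"),
                 outputs = c("panel.tsv", "panel_provenance.json"),
                 counts = list(candidates = length(intersect_genes),
                               selected = nrow(panel),
                               training_samples = length(known)))

  # stage 4: score construction and held-out cohorts
  scheme_for <- function(res_mps) {
    if (identical(config$strata, "median"))
      stratification_scheme(median(res_mps), c("low", "high"))
    else stratification_scheme(config$strata)
  }
  raw_self <- score_cohort(cohort$expression, panel,
                           scheme = stratification_scheme(sum(panel$weight)/2,
                                                          c("low", "high")))
  self_scores <- stratify(raw_self[c("sample_id", "mps")],
                          scheme_for(raw_self$mps))
  raw_hold <- score_cohort(holdout$expression, panel,
                           scheme = stratification_scheme(sum(panel$weight)/2,
                                                          c("low", "high")))
  hold_scores <- stratify(raw_hold[c("sample_id", "mps")],
                          scheme_for(raw_hold$mps))
  write_scores(self_scores, file.path(out, "scores_construction.tsv"))
  write_scores(hold_scores, file.path(out, "scores_holdout.tsv"))
  write_manifest(out, "score", config, NA,
                 inputs = c("panel.tsv"),
                 outputs = c("scores_construction.tsv", "scores_holdout.tsv"),
                 counts = list(samples_scored = nrow(self_scores) +
                                 nrow(hold_scores)))

  # stage 5: evaluation on the held-out cohort
  hold_clin <- holdout$clinical
  hold_clin$mps_group <- ifelse(
    hold_scores$stratum[match(hold_clin$sample_id, hold_scores$sample_id)] ==
      "high", 1, 0)
  km <- km_logrank(hold_clin, hold_scores$stratum[
    match(hold_clin$sample_id, hold_scores$sample_id)])
  cind <- concordance_index(hold_scores$mps[
    match(hold_clin$sample_id, hold_scores$sample_id)],
    hold_clin, higher = "survival")
  screen_vars <- c("mps_group", intersect(config$covariates, names(hold_clin)))
  cox <- cox_screen(hold_clin, screen_vars, alpha = 0.05)
  nomo <- NULL; calib <- NULL
  if (!is.null(cox$multivariate)) {
    # drop horizons beyond the cohort's follow-up range
    max_fu <- max(cox$multivariate$data$os_time)
    horizons <- config$horizons[config$horizons <= max_fu]
    if (length(horizons) == 0L) horizons <- 0.75 * max_fu
    nomo <- suppressMessages(build_nomogram(cox$multivariate,
                                            horizons = horizons))
    calib <- calibration(nomo, horizons[1L], n_boot = config$n_boot,
                         bins = 3, seed = stage_seed(config$seed, 5L))
  }
  evaluation <- list(km = km, c_index = cind, cox = cox, nomogram = nomo,
                     calibration = calib)
  eval_json <- list(
    logrank_statistic = km$statistic, logrank_p = km$p, c_index = cind,
    cox_selected = cox$selected,
    nomogram_c_index = if (!is.null(nomo)) nomo$c_index else NA,
    calibration = if (!is.null(calib)) as.data.frame(calib) else NULL)
  jsonlite::write_json(eval_json, file.path(out, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_manifest(out, "evaluate", config, stage_seed(config$seed, 5L),
                 inputs = c("scores_holdout.tsv", "clinical.tsv"),
                 outputs = c("evaluation.json"),
                 counts = list(samples_evaluated = nrow(hold_clin)))

  list(cohort = cohort, holdout = holdout,
       screen = list(survival = scr, de = de, intersect = intersect_genes),
       panel = panel, importances = imp, nn = model,
       scores = list(construction = self_scores, holdout = hold_scores),
       evaluation = evaluation, out_dir = out)
}
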
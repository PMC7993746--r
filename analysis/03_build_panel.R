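#!/usr/bin/env Rscript
# Stage 3 — panel construction: Gene-Scores, random-forest selection,
# neural-network training, per-gene weight extraction.
#
# Candidate genes (the screen intersection) are binarized to Gene-Scores
# (score 1 = prognostically favorable expression state). A random forest
# (500 trees, depth <= 10, stratified 10-fold CV) classifies 3-year vital
# status from the scores; genes are ranked by averaged impurity-decrease
# importance and the top 21 kept, matching the published panel size (the
# raw 0.5 importance cutoff is specific to the original cohort's scale).
# The 21-4-2-2 ReLU/softmax network is trained by Adam (lr 0.001, 1000
# epochs) on cross-entropy, and each gene's weight is the L1 norm of its
# outgoing first-layer weights.

suppressPackageStartupMessages(library(mpscore))

seed <- 20260920
cohort_dir <- "results/cohort"; screen_dir <- "results/screen"
out <- "results/panel"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

expr <- read_expression(file.path(cohort_dir, "expression.tsv"))
clinical <- read_clinical(file.path(cohort_dir, "clinical.tsv"))
survival_results <- read.delim(file.path(screen_dir, "survival_screen.tsv"))
candidates <- readLines(file.path(screen_dir, "intersect_genes.txt"))

gs <- assign_gene_scores(expr, survival_results, candidates)
status <- event_status_at(clinical, 3 * 365.25)
known <- names(status)[status != "unknown"]
labels <- as.integer(status[known] == "dead")
cat(sprintf("3-year status: %d dead, %d alive, %d unknown (censored early, excluded).\n",
            sum(labels), sum(labels == 0), sum(status == "unknown")))

rf_cfg <- rf_config(n_trees = 500, max_depth = 10, n_folds = 10,
                    top_k = 21, seed = stage_seed(seed, 3))
imp <- rf_select_features(gs$scores[, known, drop = FALSE], labels, rf_cfg)
selected <- imp$symbol[imp$selected]
cat(sprintf("Random forest selected %d genes (importance %.2f-%.2f).\n",
            length(selected),
            min(imp$importance[imp$selected]),
            max(imp$importance[imp$selected])))

nn_cfg <- nn_config(learning_rate = 0.001, epochs = 1000,
                    seed = stage_seed(seed, 4))
model <- train_nn(gs$scores[selected, known, drop = FALSE], labels, nn_cfg)
cat(sprintf("Neural network: cross-entropy %.4f -> %.4f over %d epochs.\n",
            model$loss_trace[1], model$loss_trace[nn_cfg$epochs],
            nn_cfg$epochs))

weights <- extract_gene_weights(model)
panel <- build_panel(selected[weights[selected] > 0], gs$directions, weights,
                     provenance = sprintf("synthetic build, seed %d", seed))
write_panel(panel, file.path(out, "panel.tsv"))
write.table(imp, file.path(out, "rf_importance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(
  list(rf = unclass(rf_cfg), nn = unclass(nn_cfg),
       loss_first = model$loss_trace[1],
       loss_last = model$loss_trace[nn_cfg$epochs]),
  file.path(out, "provenance.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("Panel: %d genes, weights %.3f-%.3f (sum %.3f), written to %s.\n",
            nrow(panel), min(panel$weight), max(panel$weight),
            sum(panel$weight), file.path(out, "panel.tsv")))
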
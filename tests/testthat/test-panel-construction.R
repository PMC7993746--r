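# RF selection, Gene-Score binarization, NN training, weight extraction.

test_that("rf config validates its fields", {
  expect_error(rf_config(n_trees = 0), "n_trees")
  expect_error(rf_config(n_folds = 1), "n_folds")
  expect_error(rf_config(max_depth = 0), "max_depth")
})

test_that("rf selection: constant features score zero, cutoffs bound selection", {
  d <- toy_scores(n_informative = 3, n_null = 5, n_samples = 120, seed = 2)
  d$scores["NULL01", ] <- 0L                     # constant feature
  imp <- rf_select_features(d$scores, d$labels,
                            rf_config(n_trees = 100, n_folds = 4, seed = 3))
  expect_equal(imp$importance[imp$symbol == "NULL01"], 0)
  expect_false(imp$selected[imp$symbol == "NULL01"])
  imp_inf <- rf_select_features(d$scores, d$labels,
                                rf_config(n_trees = 100, n_folds = 4,
                                          importance_cutoff = Inf, seed = 3))
  expect_false(any(imp_inf$selected))
  imp_k <- rf_select_features(d$scores, d$labels,
                              rf_config(n_trees = 100, n_folds = 4,
                                        top_k = 2, seed = 3))
  expect_equal(sum(imp_k$selected), 2L)
})

test_that("rf selection is deterministic given the seed", {
  d <- toy_scores(n_informative = 2, n_null = 6, n_samples = 80, seed = 4)
  cfg <- rf_config(n_trees = 80, n_folds = 4, seed = 9)
  a <- rf_select_features(d$scores, d$labels, cfg)
  b <- rf_select_features(d$scores, d$labels, cfg)
  expect_identical(a, b)
})

test_that("informative features outrank null features in importance", {
  ok <- vapply(1:10, function(s) {
    d <- toy_scores(n_informative = 5, n_null = 20, n_samples = 200,
                    seed = 100 + s)
    imp <- rf_select_features(d$scores, d$labels,
                              rf_config(n_trees = 100, n_folds = 5, seed = s))
    inf <- grepl("^INF", imp$symbol)
    mean(imp$importance[inf]) > mean(imp$importance[!inf])
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("rf selection rejects degenerate inputs", {
  d <- toy_scores(2, 2, 40, seed = 5)
  expect_error(rf_select_features(d$scores, rep(1L, 40), rf_config()),
               "both classes")
  expect_error(rf_select_features(d$scores, d$labels,
                                  rf_config(n_folds = 50)), "folds")
  expect_error(rf_select_features(d$scores * 2, d$labels, rf_config()),
               "binary")
})

test_that("gene scores follow the favorable-state convention", {
  # protective gene (HR < 1): above median scores 1; risky gene (HR > 1):
  # at-or-below median scores 1; exact-median values take the low state
  m <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40), nrow = 2, byrow = TRUE,
              dimnames = list(c("PROT", "RISK"), sprintf("T%d", 1:4)))
  expr <- expression_matrix(m, rep("tumor", 4))
  sr <- data.frame(symbol = c("PROT", "RISK"), hr = c(0.5, 2),
                   median_cutoff = c(2.5, 25))
  gs <- assign_gene_scores(expr, sr, c("PROT", "RISK"))
  expect_equal(unname(gs$scores["PROT", ]), c(0L, 0L, 1L, 1L))
  expect_equal(unname(gs$scores["RISK", ]), c(1L, 1L, 0L, 0L))
  expect_equal(gs$directions$score_high, c(1L, 0L))
  expect_equal(gs$directions$score_low, c(0L, 1L))
  # exact median -> low state -> contributes score_low's value
  sr2 <- data.frame(symbol = "PROT", hr = 0.5, median_cutoff = 3)
  gs2 <- assign_gene_scores(expr, sr2, "PROT")
  expect_equal(unname(gs2$scores["PROT", 3]), 0L)   # value 3 == cutoff
  sr3 <- data.frame(symbol = "RISK", hr = 1, median_cutoff = 25)
  expect_message(gs3 <- assign_gene_scores(expr, sr3, "RISK"), "tie-broken")
  expect_equal(gs3$directions$score_low, 1L)
})

test_that("nn config and training validate inputs", {
  expect_error(nn_config(epochs = 0), "epochs")
  expect_error(nn_config(learning_rate = 0), "learning_rate")
  d <- toy_scores(2, 2, 30, seed = 6)
  expect_error(train_nn(d$scores * 3, d$labels), "binary")
  expect_error(train_nn(d$scores, d$labels[-1]), "per sample")
})

test_that("softmax outputs sum to one for random inputs", {
  d <- toy_scores(3, 3, 40, seed = 7)
  model <- train_nn(d$scores, d$labels, nn_config(epochs = 5, seed = 1))
  probs <- predict(model, d$scores)
  expect_equal(unname(rowSums(probs)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(probs >= 0))
})

test_that("training reduces cross-entropy on separable scores and is deterministic", {
  d <- toy_scores(n_informative = 4, n_null = 2, n_samples = 100,
                  flip = 0.02, seed = 8)
  cfg <- nn_config(epochs = 300, seed = 2)
  model <- train_nn(d$scores, d$labels, cfg)
  expect_length(model$loss_trace, 300L)
  expect_true(all(is.finite(model$loss_trace)))
  expect_lt(model$loss_trace[300], model$loss_trace[1])
  model2 <- train_nn(d$scores, d$labels, cfg)
  expect_identical(model$W1, model2$W1)
  # the trained net actually classifies the separable data
  pred <- predict(model, d$scores)[, "dead"] > 0.5
  expect_gt(mean(pred == (d$labels == 1)), 0.9)
})

test_that("gene-weight extraction reduces the first layer as documented", {
  fake <- structure(list(W1 = rbind(c(0.5, -1.0, 0.25, 0.25),
                                    c(0, 0, 0, 0)),
                         gene_symbols = c("A", "B")),
                    class = "nn_model")
  expect_warning(w <- extract_gene_weights(fake), "zero outgoing")
  expect_equal(unname(w["A"]), 2.0)
  expect_equal(unname(w["B"]), 0)
  expect_equal(attr(w, "zero_weight"), "B")
  expect_equal(unname(suppressWarnings(extract_gene_weights(fake, "l2"))["A"]),
               sqrt(0.25 + 1 + 0.0625 * 2))
  expect_equal(unname(suppressWarnings(extract_gene_weights(fake, "sum"))["A"]), 0)
  expect_error(extract_gene_weights(list()), "trained")
})

test_that("weight extraction is equivariant to gene permutation of the model", {
  d <- toy_scores(3, 2, 60, seed = 9)
  model <- train_nn(d$scores, d$labels, nn_config(epochs = 50, seed = 3))
  w <- extract_gene_weights(model)
  perm <- c(3, 1, 5, 2, 4)
  permuted <- model
  permuted$W1 <- model$W1[perm, ]
  permuted$gene_symbols <- model$gene_symbols[perm]
  wp <- extract_gene_weights(permuted)
  attr(wp, "zero_weight") <- attr(w, "zero_weight") <- NULL
  expect_equal(wp, w[perm])
})

test_that("panel assembly enforces alignment and positivity", {
  dirs <- data.frame(symbol = c("A", "B", "C"),
                     score_high = c(1L, 0L, 1L), score_low = c(0L, 1L, 0L))
  w <- c(A = 1.5, B = 2.5, C = 0)
  expect_warning(p <- build_panel(c("A", "B", "C"), dirs, w), "zero-weight")
  expect_equal(p$symbol, c("A", "B"))
  expect_error(build_panel(character(), dirs, w), "empty panel")
  expect_error(build_panel(c("A", "Z"), dirs, w), "misaligned")
  p2 <- build_panel(c("A", "B"), dirs, w)
  expect_s3_class(p2, "mps_panel")
  expect_equal(sum(p2$weight), 4)
})
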
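# Stage 2 of panel construction: random-forest feature selection over the
# binarized Gene-Score matrix, a small feed-forward neural network trained
# on 3-year vital status, and per-gene weights extracted from the trained
# input layer.

#' Random-forest selection configuration
#'
#' @param n_trees Trees per forest (default 500).
#' @param max_depth Maximum tree depth (default 10); enforced through the
#'   terminal-node bound `maxnodes = 2^max_depth`.
#' @param n_folds Stratified cross-validation folds (default 10); one
#'   forest is trained per training split and importances are averaged.
#' @param importance_cutoff Selection cutoff on the averaged mean decrease
#'   in node impurity (default 0.5, on the raw importance scale).
#' @param top_k Optional alternative mode: select the `top_k` genes by
#'   averaged importance instead of thresholding (the raw cutoff is
#'   scale-dependent and not portable across cohort sizes).
#' @param seed Integer seed.
#' @return A validated list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 500, max_depth = 10, n_folds = 10,
                      importance_cutoff = 0.5, top_k = NULL, seed = 1L) {
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (!is.null(top_k) && top_k < 1) stop("top_k must be >= 1", call. = FALSE)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 n_folds = as.integer(n_folds),
                 importance_cutoff = importance_cutoff,
                 top_k = top_k, seed = as.integer(seed)),
            class = "rf_config")
}

# Stratified fold assignment: within each class, samples are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in unique(labels)) {
    idx <- sample(which(labels == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Random-forest feature selection on Gene-Scores
#'
#' Trains one classification forest per stratified cross-validation
#' training split (binary 3-year vital status as the outcome, binarized
#' Gene-Scores as features) and averages the mean-decrease-in-impurity
#' importance of each gene over the folds. A gene is selected when its
#' averaged importance reaches `importance_cutoff` (or is among `top_k`).
#'
#' @param scores Binary gene-by-sample matrix (rows = genes).
#' @param labels Binary per-sample outcome (0 = alive, 1 = deceased);
#'   samples with unknown status must be excluded upstream.
#' @param config An [rf_config()].
#' @return Data frame: `symbol`, `importance`, `selected`, sorted by
#'   importance descending.
#' @export
rf_select_features <- function(scores, labels, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  if (!all(scores %in% c(0, 1))) stop("score matrix must be binary", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != ncol(scores))
    stop("one label per sample column required", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("labels must contain both classes", call. = FALSE)
  if (ncol(scores) < config$n_folds)
    stop("fewer samples than folds", call. = FALSE)
  y <- factor(labels, levels = c(0L, 1L))
  x_all <- t(scores)
  withr::with_seed(config$seed, {
    fold <- stratified_folds(labels, config$n_folds)
    imp <- matrix(0, nrow = nrow(scores), ncol = config$n_folds,
                  dimnames = list(rownames(scores), NULL))
    for (f in seq_len(config$n_folds)) {
      train <- fold != f
      rf <- randomForest::randomForest(
        x = x_all[train, , drop = FALSE], y = y[train],
        ntree = config$n_trees,
        maxnodes = min(2L^config$max_depth, sum(train)))
      imp[, f] <- rf$importance[, "MeanDecreaseGini"]
    }
  })
  avg <- rowMeans(imp)
  if (is.null(config$top_k)) {
    selected <- avg >= config$importance_cutoff
  } else {
    selected <- rank(-avg, ties.method = "first") <= config$top_k
  }
  out <- data.frame(symbol = rownames(scores), importance = avg,
                    selected = selected, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binarize expression to Gene-Scores
#'
#' Each gene's expression is dichotomized at its cohort median (strictly
#' above = high state, ties low), and one of the two states is mapped to
#' score 1 by the gene's hazard-ratio direction. The package's fixed
#' convention is that score 1 marks the prognostically favorable state:
#' for HR(high vs low) > 1 the low state scores 1, for HR < 1 the high
#' state scores 1, so larger total scores always predict longer survival.
#' A gene with HR exactly 1 is tie-broken to the low state (logged).
#'
#' @param expr An `mps_expression` (tumor columns are used).
#' @param survival_results Per-gene table from [screen_survival()] (needs
#'   `symbol`, `hr`, `median_cutoff`).
#' @param genes Genes to score (must appear in both inputs).
#' @return List with `scores` (binary gene-by-sample matrix over tumor
#'   samples), `directions` (data frame `symbol`, `score_high`,
#'   `score_low`, `median_cutoff`, `hr`).
#' @export
assign_gene_scores <- function(expr, survival_results, genes) {
  missing_genes <- setdiff(genes, survival_results$symbol)
  if (length(missing_genes))
    stop("no survival result for gene(s): ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  missing_expr <- setdiff(genes, rownames(expr$values))
  if (length(missing_expr))
    stop("gene(s) absent from expression: ",
         paste(missing_expr, collapse = ", "), call. = FALSE)
  sr <- survival_results[match(genes, survival_results$symbol), , drop = FALSE]
  if (anyNA(sr$hr))
    stop("unscoreable gene(s) cannot be assigned scores: ",
         paste(sr$symbol[is.na(sr$hr)], collapse = ", "), call. = FALSE)
  ties <- sr$symbol[sr$hr == 1]
  if (length(ties))
    message("HR exactly 1 for ", paste(ties, collapse = ", "),
            "; favorable state tie-broken to low")
  score_high <- as.integer(sr$hr < 1)   # high expression favorable iff HR < 1
  score_low <- 1L - score_high
  tumor_ids <- samples_in_group(expr, "tumor")
  x <- expr$values[genes, tumor_ids, drop = FALSE]
  high_state <- x > sr$median_cutoff
  scores <- matrix(0L, nrow = length(genes), ncol = ncol(x),
                   dimnames = list(genes, colnames(x)))
  for (i in seq_along(genes)) {
    scores[i, ] <- if (score_high[i] == 1L) as.integer(high_state[i, ])
                   else as.integer(!high_state[i, ])
  }
  list(scores = scores,
       directions = data.frame(symbol = sr$symbol, score_high = score_high,
                               score_low = score_low,
                               median_cutoff = sr$median_cutoff, hr = sr$hr,
                               stringsAsFactors = FALSE))
}

#' Neural-network configuration
#'
#' Fixed architecture: one input node per panel gene, hidden layers of 4
#' and 2 ReLU units, and a 2-node softmax output (alive / deceased), with
#' mean cross-entropy loss optimized by full-batch Adam.
#'
#' @param learning_rate Adam step size (default 0.001).
#' @param epochs Training epochs (default 1000).
#' @param hidden Hidden layer sizes (fixed default `c(4, 2)`).
#' @param seed Integer seed for weight initialization.
#' @return A validated list of class `nn_config`.
#' @export
nn_config <- function(learning_rate = 0.001, epochs = 1000,
                      hidden = c(4L, 2L), seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 hidden = as.integer(hidden), seed = as.integer(seed)),
            class = "nn_config")
}

relu <- function(z) pmax(z, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

nn_forward <- function(model, x) {
  h1 <- relu(sweep(x %*% model$W1, 2L, model$b1, `+`))
  h2 <- relu(sweep(h1 %*% model$W2, 2L, model$b2, `+`))
  out <- softmax_rows(sweep(h2 %*% model$W3, 2L, model$b3, `+`))
  list(h1 = h1, h2 = h2, probs = out)
}

#' Train the scoring neural network
#'
#' Fully-connected feed-forward network (inputs -> 4 ReLU -> 2 ReLU -> 2
#' softmax) trained by full-batch Adam on mean cross-entropy against the
#' binary 3-year vital status. The second output node is the probability
#' of death. Deterministic given the config seed.
#'
#' @param scores Binary gene-by-sample matrix (rows = genes).
#' @param labels Binary per-sample outcome (0 = alive, 1 = deceased).
#' @param config An [nn_config()].
#' @return List of class `nn_model`: weight matrices `W1`, `W2`, `W3`,
#'   biases `b1`, `b2`, `b3`, `loss_trace` (length = epochs),
#'   `death_output` (= 2), `gene_symbols`.
#' @export
train_nn <- function(scores, labels, config = nn_config()) {
  stopifnot(inherits(config, "nn_config"))
  if (!all(scores %in% c(0, 1))) stop("score matrix must be binary", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != ncol(scores))
    stop("one label per sample column required", call. = FALSE)
  x <- t(scores)                                   # n x p
  n <- nrow(x); p <- ncol(x)
  sizes <- c(p, config$hidden, 2L)
  y <- cbind(alive = 1 - labels, dead = labels)    # one-hot
  withr::with_seed(config$seed, {
    init <- function(fan_in, fan_out)              # He initialization
      matrix(rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
    model <- list(W1 = init(sizes[1], sizes[2]), b1 = numeric(sizes[2]),
                  W2 = init(sizes[2], sizes[3]), b2 = numeric(sizes[3]),
                  W3 = init(sizes[3], sizes[4]), b3 = numeric(sizes[4]))
  })
  adam <- lapply(model, function(w) list(m = w * 0, v = w * 0))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  trace <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    fw <- nn_forward(model, x)
    probs <- pmax(fw$probs, 1e-12)
    loss <- -mean(rowSums(y * log(probs)))
    if (!is.finite(loss))
      stop("NaN/Inf loss at epoch ", ep, call. = FALSE)
    trace[ep] <- loss
    # backprop (softmax + cross-entropy collapses to probs - y)
    d3 <- (fw$probs - y) / n                       # n x 2
    gW3 <- t(fw$h2) %*% d3; gb3 <- colSums(d3)
    d2 <- (d3 %*% t(model$W3)) * (fw$h2 > 0)
    gW2 <- t(fw$h1) %*% d2; gb2 <- colSums(d2)
    d1 <- (d2 %*% t(model$W2)) * (fw$h1 > 0)
    gW1 <- t(x) %*% d1; gb1 <- colSums(d1)
    grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3)
    for (nm in names(model)) {
      adam[[nm]]$m <- b1 * adam[[nm]]$m + (1 - b1) * grads[[nm]]
      adam[[nm]]$v <- b2 * adam[[nm]]$v + (1 - b2) * grads[[nm]]^2
      mhat <- adam[[nm]]$m / (1 - b1^ep)
      vhat <- adam[[nm]]$v / (1 - b2^ep)
      model[[nm]] <- model[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(c(model, list(loss_trace = trace, death_output = 2L,
                          gene_symbols = rownames(scores))),
            class = "nn_model")
}

#' Predict death probability from a trained network
#' @param object An `nn_model`.
#' @param scores Binary gene-by-sample matrix aligned to the training genes.
#' @param ... Unused.
#' @return Matrix of class probabilities (columns alive, dead), one row per
#'   sample.
#' @export
predict.nn_model <- function(object, scores, ...) {
  probs <- nn_forward(object, t(scores))$probs
  colnames(probs) <- c("alive", "dead")
  rownames(probs) <- colnames(scores)
  probs
}

#' Extract per-gene weights from the trained network
#'
#' Collapses each gene's outgoing first-layer weight vector to one positive
#' scalar. Default is the L1 norm (sum of absolute weights); L2 and plain
#' sum are available alternatives.
#'
#' @param model An `nn_model`.
#' @param reduce `"l1"` (default), `"l2"` or `"sum"`.
#' @return Named numeric vector of weights; genes whose entire outgoing row
#'   is zero get weight 0 and are flagged in attribute `"zero_weight"`.
#' @export
extract_gene_weights <- function(model, reduce = c("l1", "l2", "sum")) {
  if (!inherits(model, "nn_model") || is.null(model$W1))
    stop("`model` must be a trained nn_model", call. = FALSE)
  reduce <- match.arg(reduce)
  w <- switch(reduce,
              l1 = rowSums(abs(model$W1)),
              l2 = sqrt(rowSums(model$W1^2)),
              sum = rowSums(model$W1))
  names(w) <- model$gene_symbols
  zero <- names(w)[w == 0]
  if (length(zero))
    warning("zero outgoing weights for gene(s): ",
            paste(zero, collapse = ", "), call. = FALSE)
  attr(w, "zero_weight") <- zero
  w
}

#' Assemble a gene panel from construction outputs
#'
#' @param symbols Selected gene symbols.
#' @param directions Data frame from [assign_gene_scores()] (`symbol`,
#'   `score_high`, `score_low`).
#' @param weights Named per-gene weights from [extract_gene_weights()];
#'   zero-weight genes are dropped with a warning.
#' @param provenance Free-text provenance.
#' @return An `mps_panel`.
#' @export
build_panel <- function(symbols, directions, weights,
                        provenance = "constructed panel") {
  if (length(symbols) == 0L) stop("empty panel", call. = FALSE)
  if (!all(symbols %in% directions$symbol) || !all(symbols %in% names(weights)))
    stop("misaligned inputs: every symbol needs a direction and a weight",
         call. = FALSE)
  w <- weights[symbols]
  if (any(w == 0)) {
    warning("dropping zero-weight gene(s): ",
            paste(symbols[w == 0], collapse = ", "), call. = FALSE)
    symbols <- symbols[w > 0]
    w <- w[symbols]
    if (length(symbols) == 0L) stop("empty panel", call. = FALSE)
  }
  d <- directions[match(symbols, directions$symbol), , drop = FALSE]
  gene_panel(symbols, d$score_high, d$score_low, w, provenance = provenance)
}
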
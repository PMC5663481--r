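#' Curate a training set
#'
#' Keeps only leaf categories with strictly more than `min_specimens`
#' specimens (default 30), dropping smaller categories together with
#' their objects. Classes are not reweighted: abundant categories keep
#' their abundance.
#'
#' @param labels data.frame with `object_id` and `level1`..`level4`
#'   columns (see [read_label_table()]).
#' @param features numeric feature matrix whose rows correspond to
#'   `labels$object_id` (rownames or row order).
#' @param min_specimens curation threshold (strictly-greater-than).
#' @return a `training_set`: list with `features`, `labels` (curated
#'   rows), `leaf_counts` and the implied [taxonomy_tree()].
#' @export
curate_training_set <- function(labels, features, min_specimens = 30L) {
  stopifnot(nrow(labels) == nrow(features))
  counts <- table(labels$level4)
  keep_classes <- names(counts)[counts > min_specimens]
  keep <- labels$level4 %in% keep_classes
  if (!any(keep)) {
    msg <- paste(sprintf("%s=%d", names(counts), as.integer(counts)),
                 collapse = ", ")
    stop("no category has more than ", min_specimens,
         " specimens; counts: ", msg)
  }
  labels <- labels[keep, , drop = FALSE]
  features <- features[keep, , drop = FALSE]
  structure(list(features = features, labels = labels,
                 leaf_counts = table(labels$level4),
                 tree = taxonomy_tree(labels)),
            class = "training_set")
}

#' Train the random-forest classifier
#'
#' A probability random forest with `n_trees` trees (default 500),
#' `floor(sqrt(p))` candidate features per split, bootstrap sampling and
#' unlimited depth, over the leaf (level-4) labels. Deterministic given
#' `seed`. The model records the feature catalog version it was trained
#' on.
#'
#' @param train a `training_set`, or a feature matrix (then `labels`
#'   must give the leaf labels).
#' @param seed integer RNG seed.
#' @param n_trees number of trees.
#' @param labels leaf labels when `train` is a plain matrix.
#' @param catalog_version recorded version string (taken from the
#'   feature matrix attribute when present).
#' @return an `hcfm_model`.
#' @export
train_classifier <- function(train, seed = 1L, n_trees = 500L,
                             labels = NULL, catalog_version = NULL) {
  if (inherits(train, "training_set")) {
    x <- train$features
    y <- train$labels$level4
  } else {
    x <- train
    y <- labels
  }
  if (length(unique(y)) < 2L) stop("at least 2 leaf categories required")
  if (is.null(catalog_version))
    catalog_version <- attr(x, "catalog_version") %||% "unversioned"
  x <- as.data.frame(unclass(x))
  fit <- ranger::ranger(x = x, y = factor(y), num.trees = n_trees,
                        mtry = max(1L, floor(sqrt(ncol(x)))),
                        probability = TRUE, importance = "impurity",
                        seed = seed, num.threads = 1L)
  structure(list(forest = fit, classes = levels(factor(y)),
                 feature_names = colnames(x),
                 catalog_version = catalog_version, seed = seed,
                 n_trees = n_trees),
            class = "hcfm_model")
}

#' @export
print.hcfm_model <- function(x, ...) {
  cat(sprintf("hcfm_model: %d trees over %d classes, %d features (catalog %s), seed %d\n",
              x$n_trees, length(x$classes), length(x$feature_names),
              x$catalog_version, x$seed))
  invisible(x)
}

check_model_features <- function(model, features) {
  v <- attr(features, "catalog_version")
  if (!is.null(v) && !identical(v, model$catalog_version))
    stop("feature catalog version '", v,
         "' does not match the model's '", model$catalog_version, "'")
  if (!all(model$feature_names %in% colnames(features)))
    stop("feature columns do not match the model")
  invisible(TRUE)
}

#' Class probabilities, assignment and confidence score
#'
#' The forest returns a probability per leaf; each object is assigned to
#' the class with the highest probability (ties broken to the lowest
#' class index) and scored with confidence = highest minus
#' second-highest probability (second-highest is 0 for a single-class
#' probability vector).
#'
#' @param model an `hcfm_model`.
#' @param features numeric matrix of catalog features.
#' @return a `prediction_result` data.frame: `predicted`, `confidence`,
#'   plus one probability column per class (prefix `p_`).
#' @export
predict_with_confidence <- function(model, features) {
  check_model_features(model, features)
  x <- as.data.frame(unclass(features))[, model$feature_names, drop = FALSE]
  probs <- stats::predict(model$forest, data = x,
                          num.threads = 1L)$predictions
  res <- prediction_from_probs(probs, model$classes)
  res
}

#' Assignment and confidence from a probability matrix
#'
#' @param probs matrix (objects x classes) of probabilities summing to 1
#'   per row.
#' @param classes class names (defaults to `colnames(probs)`).
#' @return data.frame `predicted`, `confidence`, probability columns.
#' @export
prediction_from_probs <- function(probs, classes = colnames(probs)) {
  probs <- as.matrix(probs)
  top_idx <- max.col(probs, ties.method = "first")
  top <- probs[cbind(seq_len(nrow(probs)), top_idx)]
  second <- if (ncol(probs) > 1L)
    apply(probs, 1, function(p) sort(p, decreasing = TRUE)[2])
  else rep(0, nrow(probs))
  out <- data.frame(predicted = classes[top_idx],
                    confidence = top - second,
                    stringsAsFactors = FALSE)
  pm <- as.data.frame(probs)
  names(pm) <- paste0("p_", classes)
  cbind(out, pm)
}

#' Filter predictions by confidence
#'
#' Retains predictions with confidence >= `cutoff`, and, when true
#' labels are supplied, reports the retained fraction and accuracy as a
#' function of the cutoff.
#'
#' @param predictions a `prediction_result` data.frame.
#' @param cutoff confidence cutoff in [0, 1].
#' @param truth optional true leaf labels (same length).
#' @param grid cutoffs for the accuracy-vs-cutoff curve.
#' @return list with `retained` (filtered predictions), `fraction`, and,
#'   with truth, `accuracy` and a `curve` data.frame.
#' @export
filter_by_confidence <- function(predictions, cutoff, truth = NULL,
                                 grid = seq(0, 1, by = 0.1)) {
  stopifnot(cutoff >= 0, cutoff <= 1)
  keep <- predictions$confidence >= cutoff
  out <- list(retained = predictions[keep, , drop = FALSE],
              fraction = mean(keep))
  if (!is.null(truth)) {
    out$accuracy <- if (any(keep))
      mean(predictions$predicted[keep] == truth[keep]) else NA_real_
    out$curve <- do.call(rbind, lapply(grid, function(g) {
      k <- predictions$confidence >= g
      data.frame(cutoff = g, fraction = mean(k),
                 accuracy = if (any(k))
                   mean(predictions$predicted[k] == truth[k]) else NA_real_)
    }))
  }
  out
}

#' Stratified fold assignment
#'
#' @param y class labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer fold id per observation (1..folds), each class spread
#'   evenly over folds.
#' @export
stratified_folds <- function(y, folds = 10L, seed = 1L) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Aggregate leaf truth/prediction pairs over the hierarchy
#'
#' Maps leaf labels to their ancestors at each of the 4 levels and
#' computes per-level accuracy, per-category recall and the per-level
#' confusion matrix.
#'
#' @param predicted,truth leaf (level-4) label vectors.
#' @param tree a `taxonomy_tree` covering all labels.
#' @return list per level: `accuracy`, `recall` (named vector),
#'   `confusion` (truth x predicted table).
#' @export
hierarchical_metrics <- function(predicted, truth, tree) {
  stopifnot(length(predicted) == length(truth))
  out <- list()
  for (lev in 1:4) {
    p <- ancestor_at_level(tree, predicted, lev)
    t <- ancestor_at_level(tree, truth, lev)
    cats <- sort(unique(tree$paths[[paste0("level", lev)]]))
    conf <- table(factor(t, levels = cats), factor(p, levels = cats),
                  dnn = c("truth", "predicted"))
    present <- rowSums(conf) > 0
    recall <- rep(NA_real_, length(cats))
    names(recall) <- cats
    recall[present] <- diag(conf)[present] / rowSums(conf)[present]
    out[[paste0("level", lev)]] <- list(accuracy = mean(p == t),
                                        recall = recall, confusion = conf)
  }
  out
}

#' Cross-validated hierarchical evaluation
#'
#' Stratified k-fold cross-validation over a curated training set: in
#' each fold a forest is trained on the remaining folds and the held-out
#' objects are predicted; out-of-fold leaf predictions are then
#' aggregated over the 4-level hierarchy. A fold losing a class entirely
#' (possible for very small classes) triggers a warning and the affected
#' objects are excluded from that fold's test set.
#'
#' @param train a `training_set`.
#' @param folds number of folds (default 10).
#' @param seed RNG seed (forest seeds are derived per fold).
#' @param n_trees trees per fold model.
#' @param feature_idx optional column subset used for training (e.g.
#'   from [brightfield_only_subset()]).
#' @return a `hierarchical_report`: list with `per_level` (see
#'   [hierarchical_metrics()]), `leaf_accuracy`, `predictions`
#'   (out-of-fold data.frame with `fold`, `truth`, `predicted`,
#'   `confidence`).
#' @export
evaluate_hierarchical <- function(train, folds = 10L, seed = 1L,
                                  n_trees = 500L, feature_idx = NULL) {
  x <- train$features
  if (!is.null(feature_idx)) x <- x[, feature_idx, drop = FALSE]
  y <- train$labels$level4
  fold <- stratified_folds(y, folds, seed)
  pred <- rep(NA_character_, length(y))
  conf <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- which(fold == f)
    if (!length(te)) next
    missing_cl <- setdiff(unique(y[te]), unique(y[tr]))
    if (length(missing_cl)) {
      warning("fold ", f, " lost class(es) ",
              paste(missing_cl, collapse = ", "),
              " from training; excluded from this fold's evaluation")
      te <- te[!(y[te] %in% missing_cl)]
      if (!length(te)) next
    }
    m <- train_classifier(x[tr, , drop = FALSE], seed = seed + f,
                          n_trees = n_trees, labels = y[tr],
                          catalog_version = attr(train$features,
                                                 "catalog_version") %||%
                            "unversioned")
    p <- predict_with_confidence(m, x[te, , drop = FALSE])
    pred[te] <- p$predicted
    conf[te] <- p$confidence
  }
  ok <- !is.na(pred)
  per_level <- hierarchical_metrics(pred[ok], y[ok], train$tree)
  structure(list(per_level = per_level,
                 leaf_accuracy = per_level$level4$accuracy,
                 predictions = data.frame(fold = fold[ok], truth = y[ok],
                                          predicted = pred[ok],
                                          confidence = conf[ok],
                                          stringsAsFactors = FALSE)),
            class = "hierarchical_report")
}

#' @export
print.hierarchical_report <- function(x, ...) {
  acc <- vapply(x$per_level, `[[`, numeric(1), "accuracy")
  cat("hierarchical_report: accuracy",
      paste(sprintf("L%d %.1f%%", 1:4, 100 * acc), collapse = ", "), "\n")
  invisible(x)
}

#' Normalized Gini feature importance
#'
#' Impurity-decrease importance of the trained forest divided by its
#' mean, so values above 1 mark features more important than average;
#' the mean of the reported values is exactly 1.
#'
#' @param model an `hcfm_model`.
#' @return named numeric vector, one value per feature.
#' @export
feature_importance <- function(model) {
  imp <- model$forest$variable.importance
  m <- mean(imp)
  if (m == 0) return(imp * 0)
  imp / m
}

#' Accuracy as a function of feature count
#'
#' For each cross-validation fold, features are ranked by importance
#' computed on the training portion only; for every `k` in `k_grid` a
#' forest is retrained on the top-k features and evaluated on the
#' held-out portion. Held-out data never influences the ranking.
#'
#' @param train a `training_set`.
#' @param k_grid feature counts to evaluate (each <= number of
#'   features).
#' @param folds number of folds.
#' @param seed RNG seed.
#' @param n_trees trees per model.
#' @return data.frame `k`, `accuracy` (mean over folds), plus the
#'   per-fold accuracies as attribute `per_fold` and per-fold rankings
#'   as attribute `rankings`.
#' @export
feature_reduction_curve <- function(train, k_grid, folds = 5L, seed = 1L,
                                    n_trees = 500L) {
  x <- train$features
  y <- train$labels$level4
  p <- ncol(x)
  if (any(k_grid > p)) stop("k_grid entries must be <= ", p)
  fold <- stratified_folds(y, folds, seed)
  acc <- matrix(NA_real_, folds, length(k_grid),
                dimnames = list(NULL, k_grid))
  rankings <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- fold == f
    full <- train_classifier(x[tr, , drop = FALSE], seed = seed + f,
                             n_trees = n_trees, labels = y[tr])
    rank_f <- order(feature_importance(full), decreasing = TRUE)
    rankings[[f]] <- rank_f
    for (j in seq_along(k_grid)) {
      keep <- rank_f[seq_len(k_grid[j])]
      m <- train_classifier(x[tr, keep, drop = FALSE], seed = seed + f,
                            n_trees = n_trees, labels = y[tr])
      pr <- predict_with_confidence(m, x[te, keep, drop = FALSE])
      acc[f, j] <- mean(pr$predicted == y[te])
    }
  }
  out <- data.frame(k = k_grid, accuracy = colMeans(acc, na.rm = TRUE))
  attr(out, "per_fold") <- acc
  attr(out, "rankings") <- rankings
  out
}
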
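# small synthetic classification task: k Gaussian classes separated along
# two informative features, the rest pure noise
toy_task <- function(n_per = 50, k = 3, p = 12, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(paste0("cls", seq_len(k)), each = n_per)
  ang <- 2 * pi * (seq_len(k) - 1) / k
  x <- matrix(rnorm(n_per * k * p), n_per * k, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  x[, 1] <- x[, 1] + sep * cos(ang)[rep(seq_len(k), each = n_per)]
  x[, 2] <- x[, 2] + sep * sin(ang)[rep(seq_len(k), each = n_per)]
  labels <- data.frame(object_id = seq_along(y), level1 = "root",
                       level2 = ifelse(y == "cls1", "left", "right"),
                       level3 = y, level4 = y, stringsAsFactors = FALSE)
  list(x = x, y = y, labels = labels)
}

test_that("curation keeps categories with strictly more than 30 specimens", {
  counts <- c(A = 40, B = 30, C = 31)
  labels <- data.frame(object_id = seq_len(sum(counts)), level1 = "r",
                       level2 = "r", level3 = "r",
                       level4 = rep(names(counts), counts))
  feats <- matrix(rnorm(sum(counts) * 4), ncol = 4,
                  dimnames = list(NULL, paste0("f", 1:4)))
  ts <- curate_training_set(labels, feats)
  expect_setequal(names(ts$leaf_counts), c("A", "C"))
  expect_equal(nrow(ts$features), 71L)
  # all classes above threshold: identity
  ts2 <- curate_training_set(labels[labels$level4 == "A" |
                                      labels$level4 == "C", ],
                             feats[labels$level4 != "B", ])
  expect_equal(nrow(ts2$features), 71L)
  # every class at the threshold: rejected with a counts report
  lab30 <- labels[labels$level4 == "B", ]
  expect_error(curate_training_set(lab30, feats[labels$level4 == "B", ]),
               "B=30")
})

test_that("argmax assignment and confidence follow the definitions", {
  p <- rbind(c(0.7, 0.2, 0.1), c(0.5, 0.5, 0.0))
  colnames(p) <- c("a", "b", "c")
  r <- prediction_from_probs(p)
  expect_equal(r$predicted, c("a", "a"))             # tie -> lowest index
  expect_equal(r$confidence, c(0.5, 0))
  r1 <- prediction_from_probs(matrix(1, 2, 1, dimnames = list(NULL, "only")))
  expect_equal(r1$confidence, c(1, 1))               # second-highest is 0
})

test_that("forests separate separable classes and are seed-deterministic", {
  tk <- toy_task(n_per = 100, k = 2, sep = 5)
  m1 <- train_classifier(tk$x, seed = 7, n_trees = 200, labels = tk$y)
  expect_lt(m1$forest$prediction.error, 0.05)        # OOB accuracy >= 0.95
  probe <- toy_task(n_per = 30, k = 2, sep = 5, seed = 99)$x
  p1 <- predict_with_confidence(m1, probe)
  m2 <- train_classifier(tk$x, seed = 7, n_trees = 200, labels = tk$y)
  p2 <- predict_with_confidence(m2, probe)
  expect_identical(p1, p2)
  expect_true(all(abs(rowSums(as.matrix(p1[, -(1:2)])) - 1) < 1e-9))
  expect_true(all(p1$confidence >= 0 & p1$confidence <= 1))
})

test_that("training on permuted labels yields chance-level accuracy", {
  tk <- toy_task(n_per = 60, k = 3, sep = 5, seed = 3)
  set.seed(17)
  yperm <- sample(tk$y)
  ts <- list(features = tk$x,
             labels = data.frame(object_id = seq_along(yperm), level1 = "r",
                                 level2 = "r", level3 = yperm,
                                 level4 = yperm),
             tree = taxonomy_tree(data.frame(level1 = "r", level2 = "r",
                                             level3 = unique(yperm),
                                             level4 = unique(yperm))))
  class(ts) <- "training_set"
  rep <- evaluate_hierarchical(ts, folds = 5, seed = 5, n_trees = 150)
  # chance is 1/3; allow ~4 binomial sd (n = 180)
  expect_lt(abs(rep$leaf_accuracy - 1 / 3), 0.15)
})

test_that("confidence filtering retains high-confidence predictions", {
  tk <- toy_task(n_per = 80, k = 3, sep = 2.5, seed = 11)
  fold <- stratified_folds(tk$y, 4, seed = 2)
  m <- train_classifier(tk$x[fold != 1, ], seed = 3, n_trees = 200,
                        labels = tk$y[fold != 1])
  pr <- predict_with_confidence(m, tk$x[fold == 1, ])
  truth <- tk$y[fold == 1]
  all_kept <- filter_by_confidence(pr, 0, truth = truth)
  expect_equal(nrow(all_kept$retained), nrow(pr))
  expect_equal(all_kept$fraction, 1)
  mid <- filter_by_confidence(pr, 0.5, truth = truth)
  expect_lte(nrow(mid$retained), nrow(pr))
  # accuracy among retained does not drop as the cutoff rises (up to noise)
  expect_gte(mid$accuracy, all_kept$accuracy - 0.05)
  curve <- all_kept$curve
  expect_equal(curve$fraction[1], 1)
  expect_true(all(diff(curve$fraction) <= 0))
})

test_that("hierarchical metrics aggregate leaves through the tree", {
  tree <- taxonomy_tree(data.frame(
    level1 = c("g1", "g1", "g2"), level2 = c("m1", "m1", "m2"),
    level3 = c("s1", "s2", "s3"), level4 = c("a", "b", "c")))
  # perfect leaf predictions: 100% at all 4 levels
  truth <- c("a", "b", "c", "a")
  perf <- hierarchical_metrics(truth, truth, tree)
  for (lev in 1:4)
    expect_equal(perf[[paste0("level", lev)]]$accuracy, 1)
  # all wrong at leaf but sibling within the same level-1 group
  pred <- c("b", "a", "c", "b")
  mix <- hierarchical_metrics(pred, truth, tree)
  expect_equal(mix$level4$accuracy, 0.25)            # only "c" correct
  expect_equal(mix$level1$accuracy, 1)
  # hand-built 3x3 confusion vs brute-force aggregation oracle
  conf <- matrix(c(5, 1, 0,
                   2, 6, 1,
                   0, 0, 7), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  truth_v <- rep(rownames(conf), rowSums(conf))
  pred_v <- unlist(lapply(1:3, function(i)
    rep(colnames(conf), conf[i, ])))
  hm <- hierarchical_metrics(pred_v, truth_v, tree)
  # oracle: map each cell to ancestors and count matches by brute force
  for (lev in 1:4) {
    anc <- function(l) ancestor_at_level(tree, l, lev)
    acc_oracle <- sum(vapply(seq_along(truth_v), function(i)
      anc(truth_v[i]) == anc(pred_v[i]), logical(1))) / length(truth_v)
    expect_equal(hm[[paste0("level", lev)]]$accuracy, acc_oracle)
  }
  expect_equal(unname(hm$level4$recall["c"]), 1)
  expect_equal(unname(hm$level1$recall["g1"]), 14 / 15)
})

test_that("correctness at the leaf implies correctness at every level", {
  tree <- six_class_taxonomy()
  leaves <- tree$paths$level4
  set.seed(23)
  truth <- sample(leaves, 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.6, truth, sample(leaves, 60, replace = TRUE))
  hm <- hierarchical_metrics(pred, truth, tree)
  leaf_ok <- pred == truth
  for (lev in 1:3) {
    up_ok <- ancestor_at_level(tree, pred, lev) ==
      ancestor_at_level(tree, truth, lev)
    expect_true(all(up_ok[leaf_ok]))
    expect_gte(hm[[paste0("level", lev)]]$accuracy, hm$level4$accuracy)
  }
})

test_that("normalized importance has mean 1 and ranks signal above noise", {
  tk <- toy_task(n_per = 80, k = 2, p = 10, sep = 4, seed = 13)
  m <- train_classifier(tk$x, seed = 5, n_trees = 300, labels = tk$y)
  imp <- feature_importance(m)
  expect_equal(mean(imp), 1)
  expect_gt(imp[["f1"]], 1)
  expect_lt(imp[["f5"]], 1)
  expect_gt(imp[["f1"]], imp[["f5"]])
})

test_that("feature reduction ranks within folds and needs both features", {
  # 4 classes defined by the sign quadrant of (f1, f2): one feature alone
  # can at best separate half of the classes
  set.seed(19)
  n <- 240
  f1 <- rnorm(n, sign(rnorm(n)) * 3)
  f2 <- rnorm(n, sign(rnorm(n)) * 3)
  y <- paste0("q", (f1 > 0) + 2 * (f2 > 0))
  x <- cbind(f1 = f1, f2 = f2, f3 = rnorm(n), f4 = rnorm(n))
  ts <- structure(list(features = x,
                       labels = data.frame(object_id = 1:n, level1 = "r",
                                           level2 = "r", level3 = y,
                                           level4 = y)),
                  class = "training_set")
  curve <- feature_reduction_curve(ts, k_grid = c(1, 2, 4), folds = 3,
                                   seed = 2, n_trees = 150)
  expect_equal(curve$k, c(1, 2, 4))
  expect_lt(curve$accuracy[1], curve$accuracy[2])
  rk <- attr(curve, "rankings")
  expect_length(rk, 3)
  for (f in 1:3) expect_setequal(rk[[f]][1:2], 1:2)  # informative pair first
  expect_error(feature_reduction_curve(ts, k_grid = 5, folds = 3, seed = 2),
               "<=")
})

test_that("an independent forest implementation agrees on a separable task", {
  tk <- toy_task(n_per = 60, k = 3, sep = 5, seed = 8)
  probe <- toy_task(n_per = 25, k = 3, sep = 5, seed = 77)
  m <- train_classifier(tk$x, seed = 4, n_trees = 200, labels = tk$y)
  ours <- predict_with_confidence(m, probe$x)$predicted
  set.seed(4)
  rf <- randomForest::randomForest(tk$x, factor(tk$y), ntree = 200)
  theirs <- as.character(predict(rf, probe$x))
  expect_gte(mean(ours == theirs), 0.95)
  expect_gte(mean(ours == probe$y), 0.95)
})

test_that("predicting with a mismatched catalog version is rejected", {
  tk <- toy_task(n_per = 40, k = 2, sep = 5, seed = 6)
  m <- train_classifier(tk$x, seed = 1, n_trees = 50, labels = tk$y,
                        catalog_version = "v1")
  x2 <- tk$x
  attr(x2, "catalog_version") <- "v2"
  expect_error(predict_with_confidence(m, x2), "version")
  # and missing feature columns are rejected
  x3 <- tk$x[, -1]
  expect_error(predict_with_confidence(m, x3), "feature")
})
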
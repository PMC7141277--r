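subjects_df <- function(n_hc, n_ns) {
  data.frame(subject_id = sprintf("s%03d", seq_len(n_hc + n_ns)),
             group = rep(c("HC", "NS"), c(n_hc, n_ns)),
             stringsAsFactors = FALSE)
}

# widely separated two-Gaussian features, effect >> noise: the class means
# differ by 4 on the informative columns with negligible within-class
# spread there, plus pure-noise nuisance columns
separable_features <- function(n0 = 30, n1 = 20, p = 12, seed = 5) {
  set.seed(seed)
  n <- n0 + n1
  shift <- rep(c(0, 4), c(n0, n1))
  info <- matrix(rep(shift, p %/% 2), n)
  noise <- matrix(rnorm(n * (p - p %/% 2), 0, 0.2), n)
  x <- cbind(info, noise)
  rownames(x) <- sprintf("s%03d", seq_len(n))
  labels <- c(rep(0L, n0), rep(1L, n1))
  names(labels) <- rownames(x)
  list(x = x, y = labels)
}

test_that("halving 58 HC + 54 NS yields 29 + 27 per half, a disjoint partition", {
  subj <- subjects_df(58, 54)
  h <- split_nonideation_halves(subj, seed = 1)
  for (half in h) {
    expect_equal(sum(half$group == "HC"), 29)
    expect_equal(sum(half$group == "NS"), 27)
  }
  expect_length(intersect(h$half1$subject_id, h$half2$subject_id), 0)
  expect_setequal(c(h$half1$subject_id, h$half2$subject_id),
                  subj$subject_id)
})

test_that("odd group counts put the surplus subject in half 1", {
  h <- split_nonideation_halves(subjects_df(57, 54), seed = 3)
  expect_equal(sum(h$half1$group == "HC"), 29)
  expect_equal(sum(h$half2$group == "HC"), 28)
  expect_error(split_nonideation_halves(subjects_df(0, 0)), "no subjects")
  bad <- data.frame(subject_id = "a", group = "SI")
  expect_error(split_nonideation_halves(bad), "HC, NS")
})

test_that("imbalance ratio is negatives over positives at 2 decimals", {
  expect_equal(imbalance_ratio(rep(c(0, 1), c(112, 41))), 2.73)
  expect_equal(imbalance_ratio(rep(c(0, 1), c(50, 50))), 1.00)
  expect_equal(imbalance_ratio(rep(1, 10)), 0.00)
  expect_error(imbalance_ratio(rep(0, 5)), "no positive")
})

test_that("split plans realize the stratified 4:1:1 design", {
  ids <- sprintf("s%03d", 1:97)
  labels <- rep(c(0L, 1L), c(56, 41))  # one non-ideation half + all SI
  plan <- make_split_plan(ids, labels, random_state = 0)
  expect_true(length(plan$test_ids) %in% c(19, 20))
  # class proportions within one subject of the parent ratio
  test_pos <- sum(plan$labels[plan$test_ids])
  expect_lte(abs(test_pos - 41 / 5), 1)
  expect_setequal(c(plan$test_ids, unlist(plan$folds)), ids)
  expect_length(intersect(plan$test_ids, plan$train_ids), 0)
  expect_equal(sort(unlist(plan$folds)), sort(plan$train_ids))
  # folds are pairwise disjoint and near-balanced per class
  for (f in 1:4) for (g in (f + 1):5)
    expect_length(intersect(plan$folds[[f]], plan$folds[[g]]), 0)
  fold_pos <- vapply(plan$folds, function(f) sum(plan$labels[f]), numeric(1))
  expect_lte(diff(range(fold_pos)), 1)
})

test_that("split plans are deterministic per random_state and guard small classes", {
  ids <- sprintf("s%02d", 1:40)
  labels <- rep(c(0L, 1L), c(25, 15))
  p1 <- make_split_plan(ids, labels, random_state = 4)
  p2 <- make_split_plan(ids, labels, random_state = 4)
  p3 <- make_split_plan(ids, labels, random_state = 5)
  expect_identical(p1, p2)
  expect_false(identical(p1$test_ids, p3$test_ids))
  tiny <- rep(c(0L, 1L), c(35, 5))  # 4 positives in training < 5 folds
  expect_error(make_split_plan(ids, tiny, 0), "class 1")
  expect_error(make_split_plan(ids, rep(0L, 40), 0), "both classes")
})

test_that("metric kernel matches hand-checkable cases and the pairwise oracle", {
  m <- compute_binary_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1), 0.5)
  expect_equal(c(m$acc, m$sen, m$spe, m$auc), c(1, 1, 1, 1))
  expect_equal(compute_binary_metrics(c(1, 0), c(0.2, 0.8))$auc, 0)
  # tied case: (2 concordant + 0.5 * 1 tie) / 4
  expect_equal(compute_binary_metrics(c(1, 0, 1, 0),
                                      c(0.6, 0.6, 0.4, 0.2))$auc, 0.625)
  set.seed(8)
  for (rep in 1:10) {
    n <- sample(6:25, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # coarse scores force ties
    expect_equal(compute_binary_metrics(truth, scores)$auc,
                 auc_pairwise(truth, scores))
  }
  expect_error(compute_binary_metrics(rep(1, 4), runif(4)), "single class")
})

test_that("the hand-rolled AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (rep in 1:5) {
    truth <- c(0, 1, sample(0:1, 28, replace = TRUE))
    scores <- rnorm(30)
    expect_equal(compute_binary_metrics(truth, scores)$auc,
                 as.numeric(pROC::auc(pROC::roc(truth, scores,
                                                quiet = TRUE,
                                                direction = "<"))))
  }
})

test_that("AUC properties: monotone-transform invariance and complement symmetry", {
  set.seed(14)
  truth <- c(0, 1, sample(0:1, 18, replace = TRUE))
  scores <- rnorm(20)
  base <- compute_binary_metrics(truth, scores)$auc
  expect_equal(compute_binary_metrics(truth, exp(scores))$auc, base)
  expect_equal(compute_binary_metrics(truth, 2 * scores + 5)$auc, base)
  expect_equal(compute_binary_metrics(truth, -scores)$auc, 1 - base)
})

test_that("ROC curves run from (0,0) to (1,1) and never decrease", {
  set.seed(15)
  truth <- c(0, 1, sample(0:1, 38, replace = TRUE))
  roc <- compute_binary_metrics(truth, round(rnorm(40), 1))$roc
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("both model kinds separate a wide two-Gaussian problem perfectly", {
  d <- separable_features()
  for (kind in c("xgb", "lr")) {
    plan <- make_split_plan(rownames(d$x), d$y, random_state = 1)
    rep <- fit_and_evaluate(d$x, d$y, plan,
                            classifier_spec(kind, n_estimators = 50))
    expect_equal(rep$test$acc, 1.0)
    expect_equal(rep$test$auc, 1.0)
    expect_gt(rep$cv$acc, 0.95)
  }
})

test_that("tree reports record the default depth and round count", {
  d <- separable_features(n0 = 20, n1 = 15, seed = 6)
  plan <- make_split_plan(rownames(d$x), d$y, random_state = 0)
  spec <- classifier_spec("xgb", n_estimators = 1000)
  expect_equal(spec$max_depth, 5L)
  expect_equal(spec$n_estimators, 1000L)
  rep <- fit_and_evaluate(d$x, d$y, plan, classifier_spec("xgb",
                                                          n_estimators = 20))
  expect_equal(rep$max_depth, 5L)
  expect_equal(rep$model, "xgb")
})

test_that("label-permuted features calibrate near chance over 10 random states", {
  set.seed(33)
  x <- matrix(rnorm(100 * 20), 100)
  rownames(x) <- sprintf("s%03d", 1:100)
  y <- sample(rep(c(0L, 1L), c(60, 40)))
  names(y) <- rownames(x)
  res <- run_iterated_classification(x, y,
                                     classifier_spec("xgb",
                                                     n_estimators = 40),
                                     random_states = 0:9)
  expect_gte(res$averaged$test$auc, 0.35)
  expect_lte(res$averaged$test$auc, 0.65)
})

test_that("scale_pos_weight at the imbalance ratio does not hurt sensitivity when separable", {
  d <- separable_features(n0 = 40, n1 = 15, seed = 9)
  plan <- make_split_plan(rownames(d$x), d$y, random_state = 2)
  plain <- fit_and_evaluate(d$x, d$y, plan,
                            classifier_spec("xgb", n_estimators = 50))
  weighted <- fit_and_evaluate(d$x, d$y, plan,
                               classifier_spec("xgb", n_estimators = 50,
                                               scale_pos_weight =
                                                 imbalance_ratio(d$y)))
  expect_gte(weighted$test$sen, plain$test$sen)
  expect_gte(weighted$cv$sen, plain$cv$sen)
})

test_that("aggregation averages metrics and selects the best AUC with tie-break", {
  d <- separable_features(n0 = 20, n1 = 15, seed = 10)
  plan <- make_split_plan(rownames(d$x), d$y, random_state = 0)
  r <- fit_and_evaluate(d$x, d$y, plan, classifier_spec("xgb",
                                                        n_estimators = 10))
  r2 <- r
  r$test$auc <- 0.6
  r$random_state <- 3L
  r2$test$auc <- 0.8
  r2$random_state <- 7L
  agg <- aggregate_iterations(list(r, r2))
  expect_equal(agg$averaged$test$auc, 0.7)
  expect_equal(agg$best$random_state, 7L)
  # tie: lowest random_state wins
  r2b <- r2; r2b$test$auc <- 0.6; r2b$random_state <- 1L
  agg2 <- aggregate_iterations(list(r, r2b))
  expect_equal(agg2$best$random_state, 1L)
  expect_error(aggregate_iterations(list()), "no reports")
  # identical reports average to themselves
  agg3 <- aggregate_iterations(list(r, r))
  expect_equal(agg3$averaged$test$auc, r$test$auc)
  expect_equal(agg3$averaged$cv$acc, r$cv$acc)
})

test_that("degenerate single-class partitions abort evaluation", {
  d <- separable_features(n0 = 20, n1 = 15, seed = 11)
  plan <- make_split_plan(rownames(d$x), d$y, random_state = 1)
  y_bad <- d$y
  y_bad[plan$test_ids] <- 0L
  expect_error(fit_and_evaluate(d$x, y_bad, plan,
                                classifier_spec("lr")),
               "single-class|both classes")
})
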
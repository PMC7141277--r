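#' Split non-ideation subjects into two stratified halves
#'
#' To soften the negative:positive imbalance, the non-ideation subjects
#' (healthy controls and depressed non-ideation patients) are split into
#' two halves, stratified by group; each half is later concatenated with
#' all ideation subjects and classified separately. Odd group counts put
#' the surplus subject into half 1.
#'
#' @param subjects data.frame with columns `subject_id` and `group`
#'   (groups must be HC or NS).
#' @param seed integer seed for the random split.
#' @return list of two data.frames, `half1` and `half2`.
#' @export
split_nonideation_halves <- function(subjects, seed = 0L) {
  if (nrow(subjects) == 0) stop_invalid("no subjects to split")
  if (!all(subjects$group %in% c("HC", "NS")))
    stop_invalid("halving applies to non-ideation groups (HC, NS) only")
  pick <- with_seed(seed, {
    lapply(split(seq_len(nrow(subjects)), subjects$group), function(idx) {
      idx <- idx[sample(length(idx))]
      n1 <- ceiling(length(idx) / 2)
      list(h1 = idx[seq_len(n1)], h2 = idx[-seq_len(n1)])
    })
  })
  h1 <- sort(unlist(lapply(pick, `[[`, "h1"), use.names = FALSE))
  h2 <- sort(unlist(lapply(pick, `[[`, "h2"), use.names = FALSE))
  list(half1 = subjects[h1, , drop = FALSE],
       half2 = subjects[h2, , drop = FALSE])
}

#' Classifier settings
#'
#' @param kind `"xgb"` (extreme gradient-boosted trees) or `"lr"`
#'   (logistic regression, ridge-penalized with the common library
#'   default of an L2 penalty at C = 1 and an unpenalized intercept).
#' @param max_depth tree depth for `"xgb"` (default 5).
#' @param n_estimators boosting rounds for `"xgb"` (default 1000).
#' @param scale_pos_weight optional positive-class weight for `"xgb"`;
#'   set it to [imbalance_ratio()] of the training labels to counter
#'   class imbalance. `NULL` (default) leaves classes unweighted.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("xgb", "lr"), max_depth = 5,
                            n_estimators = 1000, scale_pos_weight = NULL) {
  kind <- match.arg(kind)
  if (max_depth < 1) stop_invalid("max_depth must be >= 1")
  if (n_estimators < 1) stop_invalid("n_estimators must be >= 1")
  structure(list(kind = kind, max_depth = as.integer(max_depth),
                 n_estimators = as.integer(n_estimators),
                 scale_pos_weight = scale_pos_weight),
            class = "classifier_spec")
}

#' Stratified 4:1 train/test split with stratified k-fold CV on the train set
#'
#' Realizes the 4:1:1 train/validation/test design: one fifth of each
#' class is held out as the test partition (stratified rounding, at least
#' one subject per class), and the training remainder is divided into
#' `n_folds` stratified folds, each serving once as the validation set.
#'
#' @param ids subject identifiers.
#' @param labels binary labels (1 = positive), parallel to `ids`.
#' @param random_state integer seed; the same state reproduces the plan.
#' @param n_folds number of cross-validation folds (default 5).
#' @return an object of class `split_plan`: list with `ids`, `labels`
#'   (named by id), `test_ids`, `train_ids`, `folds` (list of id vectors),
#'   `random_state`, `n_folds`.
#' @export
make_split_plan <- function(ids, labels, random_state = 0L, n_folds = 5L) {
  labels <- as.integer(labels)
  if (length(ids) != length(labels)) stop_invalid("ids/labels length mismatch")
  if (length(unique(labels)) < 2)
    stop_invalid("both classes must be present")
  names(labels) <- ids
  parts <- with_seed(derive_seed(random_state, 7L), {
    lapply(split(ids, labels), function(cls_ids) {
      cls_ids <- cls_ids[sample(length(cls_ids))]
      n_test <- max(1L, round(length(cls_ids) / 5))
      test <- cls_ids[seq_len(n_test)]
      train <- cls_ids[-seq_len(n_test)]
      list(test = test, train = train)
    })
  })
  for (cls in names(parts))
    if (length(parts[[cls]]$train) < n_folds)
      stop_invalid("class %s has fewer than %d training members",
                   cls, n_folds)
  test_ids <- unlist(lapply(parts, `[[`, "test"), use.names = FALSE)
  folds <- vector("list", n_folds)
  for (cls in names(parts)) {
    tr <- parts[[cls]]$train
    fid <- rep(seq_len(n_folds), length.out = length(tr))
    for (f in seq_len(n_folds))
      folds[[f]] <- c(folds[[f]], tr[fid == f])
  }
  train_ids <- unlist(lapply(parts, `[[`, "train"), use.names = FALSE)
  structure(list(ids = ids, labels = labels, test_ids = test_ids,
                 train_ids = train_ids, folds = folds,
                 random_state = as.integer(random_state),
                 n_folds = as.integer(n_folds)),
            class = "split_plan")
}

# Fit one classifier and return a probability-prediction closure.
fit_classifier <- function(x, y, spec) {
  if (spec$kind == "xgb") {
    params <- list(objective = "binary:logistic",
                   max_depth = spec$max_depth,
                   nthread = 1)
    if (!is.null(spec$scale_pos_weight))
      params$scale_pos_weight <- spec$scale_pos_weight
    dtrain <- xgboost::xgb.DMatrix(x, label = y)
    booster <- xgboost::xgb.train(params = params, data = dtrain,
                                  nrounds = spec$n_estimators, verbose = 0)
    function(newx) predict(booster, xgboost::xgb.DMatrix(newx))
  } else {
    fit_lr_ridge(x, y)
  }
}

# Ridge-penalized logistic regression: minimize
#   sum_i log(1 + exp(-y_i eta_i)) + (lambda / 2) ||w||^2,  eta = X w + b,
# the objective behind the common library default (L2 penalty, C = 1),
# with an unpenalized intercept. Because the optimal w lies in the row
# span of X, the fit is done in the kernel representation Z = U D from
# the eigendecomposition of X X' (exact for the L2 penalty), so the cost
# is governed by n, not by the feature count -- essential at p >> n.
# Newton/IRLS; deterministic; well-posed even for single-observation
# classes thanks to the penalty.
fit_lr_ridge <- function(x, y, lambda = 1, max_iter = 100, tol = 1e-9) {
  n <- nrow(x)
  K <- tcrossprod(x)
  e <- eigen(K, symmetric = TRUE)
  keep <- e$values > max(e$values, 1) * 1e-12
  d <- sqrt(e$values[keep])
  U <- e$vectors[, keep, drop = FALSE]
  Z <- U * rep(d, each = n)
  r <- ncol(Z)
  beta <- numeric(r)
  b0 <- 0
  for (it in seq_len(max_iter)) {
    eta <- as.vector(Z %*% beta) + b0
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    g <- c(crossprod(Z, p - y) + lambda * beta, sum(p - y))
    H <- rbind(cbind(crossprod(Z, Z * w) + diag(lambda, r),
                     crossprod(Z, w)),
               c(crossprod(w, Z), sum(w)))
    step <- solve(H, g)
    beta <- beta - step[seq_len(r)]
    b0 <- b0 - step[r + 1]
    if (max(abs(step)) < tol) break
  }
  proj <- U * rep(1 / d, each = n)  # maps kernel rows to Z coordinates
  function(newx) {
    zn <- (newx %*% t(x)) %*% proj
    as.vector(1 / (1 + exp(-(zn %*% beta + b0))))
  }
}

#' Cross-validate, refit and score one split plan
#'
#' For each fold, fits on the remaining folds and scores the held-out
#' fold (cross-validation metrics are fold means); then refits on the full
#' training partition and scores the test partition. Class probabilities
#' are thresholded at 0.5 for ACC/SEN/SPE; AUC is threshold-free.
#'
#' @param features numeric matrix with row names matching the plan's ids.
#' @param labels binary labels named by subject id (or parallel to
#'   `rownames(features)`).
#' @param plan a [make_split_plan()].
#' @param spec a [classifier_spec()].
#' @param index_type,half_id optional labels carried into the report.
#' @return an object of class `metrics_report`.
#' @export
fit_and_evaluate <- function(features, labels, plan, spec = classifier_spec(),
                             index_type = NA_character_, half_id = NA) {
  if (is.null(rownames(features)))
    stop_invalid("features must carry subject ids as row names")
  labels <- as.integer(labels)
  names(labels) <- if (!is.null(names(labels))) names(labels)
                   else rownames(features)
  if (!all(plan$ids %in% rownames(features)))
    stop_invalid("plan ids missing from the feature matrix")

  score_part <- function(train_ids, eval_ids) {
    ytr <- labels[train_ids]
    yev <- labels[eval_ids]
    if (length(unique(ytr)) < 2 || length(unique(yev)) < 2)
      stop_invalid("degenerate single-class partition")
    pred <- fit_classifier(features[train_ids, , drop = FALSE], ytr, spec)
    compute_binary_metrics(yev, pred(features[eval_ids, , drop = FALSE]))
  }

  cv <- lapply(seq_len(plan$n_folds), function(f) {
    held <- plan$folds[[f]]
    score_part(setdiff(plan$train_ids, held), held)
  })
  cv_mean <- function(metric)
    mean(vapply(cv, `[[`, numeric(1), metric))
  test <- score_part(plan$train_ids, plan$test_ids)

  structure(list(
    cv = list(acc = cv_mean("acc"), sen = cv_mean("sen"),
              spe = cv_mean("spe"), auc = cv_mean("auc")),
    test = list(acc = test$acc, sen = test$sen, spe = test$spe,
                auc = test$auc),
    roc = test$roc,
    model = spec$kind,
    max_depth = if (spec$kind == "xgb") spec$max_depth else NA_integer_,
    n_estimators = if (spec$kind == "xgb") spec$n_estimators else NA_integer_,
    scale_pos_weight = spec$scale_pos_weight,
    index_type = index_type,
    half_id = half_id,
    random_state = plan$random_state), class = "metrics_report")
}

#' @exportS3Method base::print
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report [%s%s%s, random_state %s]\n  CV:   ACC %.3f SEN %.3f SPE %.3f AUC %.3f\n  Test: ACC %.3f SEN %.3f SPE %.3f AUC %.3f\n",
    x$model,
    if (is.na(x$index_type)) "" else paste0("-", x$index_type),
    if (is.na(x$half_id)) "" else paste0("-", x$half_id),
    x$random_state,
    x$cv$acc, x$cv$sen, x$cv$spe, x$cv$auc,
    x$test$acc, x$test$sen, x$test$spe, x$test$auc))
  invisible(x)
}

#' Average iterated reports and pick the best by test AUC
#'
#' @param reports non-empty list of like-labelled `metrics_report`s from
#'   different random states.
#' @return list with `averaged` (metric-wise arithmetic means, class
#'   `metrics_report`) and `best` (the single report with the highest test
#'   AUC; ties resolved toward the lowest random state).
#' @export
aggregate_iterations <- function(reports) {
  if (length(reports) == 0) stop_invalid("no reports to aggregate")
  avg_block <- function(block) {
    out <- lapply(c("acc", "sen", "spe", "auc"), function(m)
      mean(vapply(reports, function(r) r[[block]][[m]], numeric(1))))
    names(out) <- c("acc", "sen", "spe", "auc")
    out
  }
  averaged <- reports[[1]]
  averaged$cv <- avg_block("cv")
  averaged$test <- avg_block("test")
  averaged$roc <- NULL
  averaged$random_state <- NA_integer_

  aucs <- vapply(reports, function(r) r$test$auc, numeric(1))
  states <- vapply(reports, function(r) r$random_state, numeric(1))
  cand <- which(aucs == max(aucs))
  best <- reports[[cand[which.min(states[cand])]]]
  list(averaged = averaged, best = best)
}

#' Iterated train/test evaluation over a set of random states
#'
#' Repeats [make_split_plan()] + [fit_and_evaluate()] for each random
#' state (default 0..9) and aggregates with [aggregate_iterations()].
#'
#' @inheritParams fit_and_evaluate
#' @param random_states integer vector of split seeds.
#' @param n_folds folds for the CV stage.
#' @return list with `reports`, `averaged`, `best`.
#' @export
run_iterated_classification <- function(features, labels,
                                        spec = classifier_spec(),
                                        random_states = 0:9, n_folds = 5L,
                                        index_type = NA_character_,
                                        half_id = NA) {
  ids <- rownames(features)
  reports <- lapply(random_states, function(rs) {
    plan <- make_split_plan(ids, labels, random_state = rs,
                            n_folds = n_folds)
    fit_and_evaluate(features, labels, plan, spec,
                     index_type = index_type, half_id = half_id)
  })
  agg <- aggregate_iterations(reports)
  list(reports = reports, averaged = agg$averaged, best = agg$best)
}
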
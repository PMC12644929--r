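#' Specification of the cell/non-cell classifier training protocol
#'
#' Mirrors the training protocol of the analysis: a 75/25 stratified
#' train/test split, ten-fold cross-validated tuning on the training set,
#' an L1-penalised logistic regression tuned over a log-spaced penalty grid
#' from 1e-4 to 1e-1, and a 500-tree random forest tuned over 25
#' (predictors-per-split, minimum-node-size) combinations, with the best
#' hyperparameters chosen by mean cross-validated ROC-AUC.
#'
#' @param model_family `"lr_l1"` or `"rf"`.
#' @param lr_grid_size number of log-spaced penalty values between 1e-4 and
#'   1e-1 (the grid range is fixed; its resolution is not, default 20).
#' @param rf_n_trees random-forest tree count (default 500).
#' @param rf_min_node_grid candidate minimum node sizes (5 values spanning
#'   2..40); combined with 5 mtry values spanning 1..p this yields the
#'   25-combination tuning grid.
#' @param split_fraction training share of the stratified split (0.75).
#' @param n_cv_folds number of stratified cross-validation folds (10).
#' @param include_condition if `TRUE`, the categorical `condition` column is
#'   added to the shape descriptors as a predictor.
#' @param seed integer seed controlling the split, fold assignment and
#'   forest growth.
#' @return object of class `classifier_spec`.
#' @export
classifier_spec <- function(model_family = c("rf", "lr_l1"),
                            lr_grid_size = 20L,
                            rf_n_trees = 500L,
                            rf_min_node_grid = c(2L, 5L, 10L, 20L, 40L),
                            split_fraction = 0.75,
                            n_cv_folds = 10L,
                            include_condition = FALSE,
                            seed = 1L) {
  model_family <- match.arg(model_family)
  assert_number(split_fraction, "split_fraction", 1e-9, 1 - 1e-9)
  if (lr_grid_size < 1) stopf("`lr_grid_size` must be >= 1")
  if (length(rf_min_node_grid) < 1) stopf("rf min-node grid must be non-empty")
  structure(list(model_family = model_family,
                 lr_penalty_grid = 10^seq(-4, -1, length.out = lr_grid_size),
                 rf_n_trees = as.integer(rf_n_trees),
                 rf_min_node_grid = as.integer(rf_min_node_grid),
                 split_fraction = split_fraction,
                 n_cv_folds = as.integer(n_cv_folds),
                 include_condition = include_condition,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

classifier_predictors <- function() {
  c("area", "perimeter", "major", "minor", "feret", "min_feret",
    "aspect_ratio", "roundness", "circularity", "solidity")
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling.
#'
#' @param prob predicted probabilities of the positive class.
#' @param truth logical or 0/1 vector of positive-class membership.
#' @return AUC in \[0, 1\]; `NA` if only one class is present.
#' @export
roc_auc <- function(prob, truth) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (np == 0 || nn == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}

# Confusion-matrix metrics at a probability threshold; positive = "cell".
binary_metrics <- function(prob, truth_cell, threshold = 0.5) {
  pred <- prob >= threshold
  tp <- sum(pred & truth_cell); fp <- sum(pred & !truth_cell)
  fn <- sum(!pred & truth_cell); tn <- sum(!pred & !truth_cell)
  n <- tp + fp + fn + tn
  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  spec <- if (tn + fp > 0) tn / (tn + fp) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1, kappa = kappa,
    roc_auc = roc_auc(prob, truth_cell), sensitivity = rec,
    specificity = spec)
}

# Stratified assignment: sample within each class. Returns logical
# (in training set) for splits, or integer fold ids.
stratified_split <- function(truth_cell, fraction) {
  in_train <- logical(length(truth_cell))
  for (cl in c(TRUE, FALSE)) {
    idx <- which(truth_cell == cl)
    n_tr <- round(length(idx) * fraction)
    in_train[sample(idx, n_tr)] <- TRUE
  }
  in_train
}

stratified_folds <- function(truth_cell, k) {
  fold <- integer(length(truth_cell))
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(truth_cell == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Design matrix: numeric descriptors plus optional condition dummies.
build_design <- function(table, predictors, cond_levels = NULL) {
  missing_cols <- setdiff(predictors, names(table))
  if (length(missing_cols))
    stopf("missing predictor column(s): %s", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[predictors])
  if (!is.null(cond_levels) && length(cond_levels) > 1) {
    for (lv in cond_levels[-1]) {
      x <- cbind(x, as.numeric(table$condition == lv))
      colnames(x)[ncol(x)] <- paste0("condition_", lv)
    }
  }
  x
}

lr_cv_auc <- function(x, y, fold, lambda_grid) {
  k <- max(fold)
  lam <- sort(lambda_grid, decreasing = TRUE)
  aucs <- matrix(NA_real_, k, length(lam))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], factor(y[tr]),
                          family = "binomial", alpha = 1, lambda = lam,
                          standardize = TRUE)
    p <- stats::predict(fit, x[!tr, , drop = FALSE], type = "response")
    # glmnet may drop trailing lambdas; align by column count
    for (j in seq_len(ncol(p))) aucs[f, j] <- roc_auc(p[, j], y[!tr])
  }
  list(lambda = lam, mean_auc = colMeans(aucs, na.rm = TRUE))
}

rf_cv_auc <- function(x, y, fold, grid, n_trees, seed) {
  k <- max(fold)
  mean_auc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    aucs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- ranger::ranger(
        x = x[tr, , drop = FALSE], y = factor(y[tr], levels = c(FALSE, TRUE)),
        num.trees = n_trees, mtry = grid$mtry[g],
        min.node.size = grid$min_node[g], probability = TRUE,
        seed = seed + g, num.threads = 1L, verbose = FALSE)
      p <- stats::predict(fit, x[!tr, , drop = FALSE],
                          num.threads = 1L)$predictions[, "TRUE"]
      aucs[f] <- roc_auc(p, y[!tr])
    }
    mean_auc[g] <- mean(aucs, na.rm = TRUE)
  }
  mean_auc
}

#' Train and tune a cell/non-cell classifier
#'
#' Performs the stratified 75/25 split, tunes the requested model family by
#' mean ten-fold cross-validated ROC-AUC on the training set, refits the
#' best hyperparameters on the full training set, and evaluates on the
#' held-out test set. Deterministic given `spec$seed`.
#'
#' @param table labelled particle table with the descriptor columns and a
#'   `label` column in `{"cell", "non_cell"}`.
#' @param spec a [classifier_spec()].
#' @return list with `report` (class `classifier_report`: family, best
#'   hyperparameters, mean CV ROC-AUC, test metrics, feature importances,
#'   test-set fingerprint) and `model` (class `popfluor_model`, usable with
#'   [apply_model()]).
#' @export
train_and_tune <- function(table, spec = classifier_spec()) {
  stopifnot(inherits(spec, "classifier_spec"))
  if (!"label" %in% names(table)) stopf("`table` must have a `label` column")
  truth <- table$label == "cell"
  if (length(unique(truth)) < 2L)
    stopf("training data contains a single class; need both cell and non_cell")
  if (nrow(table) < spec$n_cv_folds)
    stopf("fewer rows (%d) than cross-validation folds (%d)",
          nrow(table), spec$n_cv_folds)
  cond_levels <- if (spec$include_condition) sort(unique(table$condition)) else NULL
  x <- build_design(table, classifier_predictors(), cond_levels)
  p <- ncol(x)

  withr::with_seed(spec$seed, {
    in_train <- stratified_split(truth, spec$split_fraction)
    fold <- stratified_folds(truth[in_train], spec$n_cv_folds)
  })
  xtr <- x[in_train, , drop = FALSE]; ytr <- truth[in_train]
  xte <- x[!in_train, , drop = FALSE]; yte <- truth[!in_train]

  if (spec$model_family == "lr_l1") {
    cv <- lr_cv_auc(xtr, ytr, fold, spec$lr_penalty_grid)
    # ties broken toward the smaller penalty: equal ranking performance,
    # but less shrinkage keeps the probabilities calibrated at 0.5
    best_i <- max(which(cv$mean_auc == max(cv$mean_auc, na.rm = TRUE)))
    best <- list(penalty = cv$lambda[best_i])
    fit <- glmnet::glmnet(xtr, factor(ytr), family = "binomial", alpha = 1,
                          lambda = sort(spec$lr_penalty_grid, decreasing = TRUE),
                          standardize = TRUE)
    prob_te <- as.numeric(stats::predict(fit, xte, s = best$penalty,
                                         type = "response"))
    co <- as.matrix(stats::coef(fit, s = best$penalty))[-1, 1]
    imp <- abs(co) * apply(xtr, 2, stats::sd)   # standardized |coefficient|
    cv_auc <- cv$mean_auc[best_i]
  } else {
    mtry_grid <- unique(round(seq(1, p, length.out = 5)))
    grid <- expand.grid(mtry = mtry_grid, min_node = spec$rf_min_node_grid)
    mean_auc <- rf_cv_auc(xtr, ytr, fold, grid, spec$rf_n_trees, spec$seed)
    best_i <- which.max(mean_auc)
    best <- list(mtry = grid$mtry[best_i], min_node = grid$min_node[best_i])
    fit <- ranger::ranger(
      x = xtr, y = factor(ytr, levels = c(FALSE, TRUE)),
      num.trees = spec$rf_n_trees, mtry = best$mtry,
      min.node.size = best$min_node, probability = TRUE,
      importance = "impurity", seed = spec$seed, num.threads = 1L,
      verbose = FALSE)
    prob_te <- stats::predict(fit, xte, num.threads = 1L)$predictions[, "TRUE"]
    imp <- fit$variable.importance
    cv_auc <- mean_auc[best_i]
  }

  metrics <- binary_metrics(prob_te, yte)
  report <- structure(list(
    model_family = spec$model_family,
    best_hyperparameters = best,
    cv_roc_auc = cv_auc,
    metrics = metrics,
    feature_importances = imp,
    n_train = sum(in_train), n_test = sum(!in_train),
    test_fingerprint = which(!in_train),
    seed = spec$seed), class = "classifier_report")
  model <- structure(list(family = spec$model_family, fit = fit,
                          best = best, cond_levels = cond_levels,
                          predictors = classifier_predictors()),
                     class = "popfluor_model")
  list(report = report, model = model)
}

#' @exportS3Method base::print
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report %s: cv ROC-AUC %.3f, test ROC-AUC %.3f, accuracy %.3f>\n",
              x$model_family, x$cv_roc_auc, x$metrics[["roc_auc"]],
              x$metrics[["accuracy"]]))
  invisible(x)
}

#' Select the better classifier by held-out ROC-AUC
#'
#' @param reports list of `classifier_report`s evaluated on the same test
#'   set.
#' @return the winning report's `model_family`. Ties on ROC-AUC break by
#'   test accuracy, then by list order (with a warning).
#' @export
select_model <- function(reports) {
  if (length(reports) < 2L) stopf("need at least two reports to compare")
  fp <- lapply(reports, `[[`, "test_fingerprint")
  if (!all(vapply(fp[-1], identical, logical(1), fp[[1]])))
    stopf("reports were evaluated on different test sets and are not comparable")
  auc <- vapply(reports, function(r) r$metrics[["roc_auc"]], numeric(1))
  best <- which(auc == max(auc))
  if (length(best) > 1L) {
    acc <- vapply(reports[best], function(r) r$metrics[["accuracy"]], numeric(1))
    best <- best[acc == max(acc)]
    if (length(best) > 1L) {
      warnf("exact tie on ROC-AUC and accuracy; keeping the first family (%s)",
            reports[[best[1]]]$model_family)
    }
    best <- best[1]
  }
  reports[[best]]$model_family
}

#' Apply a fitted classifier to a particle table
#'
#' @param model a `popfluor_model` from [train_and_tune()].
#' @param table particle table with the model's predictor columns.
#' @param threshold probability cutoff; a particle is labelled `"cell"` iff
#'   its predicted cell probability is `>= threshold` (default 0.5).
#' @return `table` with `predicted_prob` filled in and `label` set to
#'   `"cell"` or `"non_cell"`; row count and order preserved.
#' @export
apply_model <- function(model, table, threshold = 0.5) {
  stopifnot(inherits(model, "popfluor_model"))
  if (nrow(table) == 0L) return(table)
  x <- build_design(table, model$predictors, model$cond_levels)
  prob <- if (model$family == "lr_l1") {
    as.numeric(stats::predict(model$fit, x, s = model$best$penalty,
                              type = "response"))
  } else {
    stats::predict(model$fit, x, num.threads = 1L)$predictions[, "TRUE"]
  }
  table$predicted_prob <- prob
  table$label <- ifelse(prob >= threshold, "cell", "non_cell")
  table
}
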
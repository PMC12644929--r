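# Classifier training, tuning, selection and application.

make_report <- function(family, auc, acc, fp = 1:10) {
  structure(list(model_family = family,
                 metrics = c(roc_auc = auc, accuracy = acc),
                 test_fingerprint = fp), class = "classifier_report")
}

test_that("the penalty grid spans 1e-4..1e-1 log-spaced", {
  g <- classifier_spec("lr_l1", lr_grid_size = 4L)$lr_penalty_grid
  expect_equal(g, c(1e-4, 1e-3, 1e-2, 1e-1))
})

test_that("a fully separable fixture is classified perfectly by both families", {
  cfg <- simulation_config(class_separation = 1, seed = 31L)
  tab <- simulate_feature_table(cfg, 300)
  for (spec in list(fast_lr_spec(seed = 5L), fast_rf_spec(seed = 5L))) {
    fit <- train_and_tune(tab, spec)
    expect_equal(fit$report$metrics[["roc_auc"]], 1.0)
    pred <- apply_model(fit$model, tab)
    expect_equal(pred$label, tab$label)
  }
})

test_that("permuted labels give chance-level held-out performance", {
  cfg <- simulation_config(seed = 32L)
  tab <- simulate_feature_table(cfg, 600)
  set.seed(99)
  tab$label <- sample(tab$label)
  fit <- train_and_tune(tab, fast_lr_spec(seed = 6L))
  expect_lt(abs(fit$report$metrics[["roc_auc"]] - 0.5), 0.12)
})

test_that("metrics satisfy their confusion-matrix identities", {
  cfg <- simulation_config(seed = 33L)
  tab <- simulate_feature_table(cfg, 500)
  fit <- train_and_tune(tab, fast_lr_spec(seed = 7L))
  m <- fit$report$metrics
  expect_identical(m[["recall"]], m[["sensitivity"]])
  expect_equal(m[["f1"]],
               2 * m[["precision"]] * m[["recall"]] /
                 (m[["precision"]] + m[["recall"]]))
  # brute-force confusion oracle on the same held-out predictions
  pred <- apply_model(fit$model, tab)
  truth <- tab$label == "cell"
  lab <- pred$predicted_prob >= 0.5
  te <- fit$report$test_fingerprint
  tp <- sum(lab[te] & truth[te]); fp <- sum(lab[te] & !truth[te])
  fn <- sum(!lab[te] & truth[te]); tn <- sum(!lab[te] & !truth[te])
  expect_equal(m[["accuracy"]], (tp + tn) / (tp + tn + fp + fn))
  expect_equal(m[["precision"]], tp / (tp + fp))
  expect_equal(m[["recall"]], tp / (tp + fn))
  expect_equal(m[["specificity"]], tn / (tn + fp))
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  prob <- runif(300)
  truth <- runif(300) < plogis(4 * (prob - 0.5))
  ours <- roc_auc(prob, truth)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, prob, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("training is deterministic given the seed", {
  cfg <- simulation_config(seed = 34L)
  tab <- simulate_feature_table(cfg, 300)
  a <- train_and_tune(tab, fast_rf_spec(seed = 11L))
  b <- train_and_tune(tab, fast_rf_spec(seed = 11L))
  expect_identical(a$report$metrics, b$report$metrics)
  expect_identical(a$report$best_hyperparameters, b$report$best_hyperparameters)
  expect_identical(a$report$test_fingerprint, b$report$test_fingerprint)
})

test_that("model selection ranks by AUC, then accuracy, then order", {
  r1 <- make_report("rf", 0.97, 0.90)
  r2 <- make_report("lr_l1", 0.93, 0.95)
  expect_equal(select_model(list(r1, r2)), "rf")
  r3 <- make_report("rf", 0.95, 0.95)
  r4 <- make_report("lr_l1", 0.95, 0.90)
  expect_equal(select_model(list(r3, r4)), "rf")
  r5 <- make_report("lr_l1", 0.95, 0.95)
  expect_warning(win <- select_model(list(r5, r3)), "tie")
  expect_equal(win, "lr_l1")
  # different test sets are incomparable
  r6 <- make_report("rf", 0.9, 0.9, fp = 2:11)
  expect_error(select_model(list(r1, r6)), "test set")
})

test_that("apply_model honours thresholds and validates columns", {
  cfg <- simulation_config(seed = 35L)
  tab <- simulate_feature_table(cfg, 200)
  fit <- train_and_tune(tab, fast_lr_spec(seed = 8L))
  expect_equal(nrow(apply_model(fit$model, tab[0, ])), 0L)
  all_cell <- apply_model(fit$model, tab, threshold = 0)
  expect_true(all(all_cell$label == "cell"))
  expect_error(apply_model(fit$model, tab[, c("area", "label")]),
               "solidity")
})

test_that("single-class or undersized inputs are rejected", {
  cfg <- simulation_config(seed = 36L)
  tab <- simulate_feature_table(cfg, 100)
  only_cells <- tab[tab$label == "cell", ]
  expect_error(train_and_tune(only_cells, fast_lr_spec()), "single class")
  expect_error(train_and_tune(tab[1:5, ], classifier_spec(n_cv_folds = 10L)),
               "folds")
})

test_that("a solidity-only contrast puts solidity first in importance", {
  set.seed(77)
  n <- 400
  is_cell <- rep(c(TRUE, FALSE), each = n / 2)
  base <- function() rnorm(n, 10, 1)
  tab <- tibble::tibble(
    area = base(), perimeter = base(), major = base(), minor = base(),
    feret = base(), min_feret = base(), aspect_ratio = base(),
    roundness = base(), circularity = base(),
    solidity = ifelse(is_cell, rnorm(n, 0.95, 0.02), rnorm(n, 0.6, 0.05)),
    condition = "x",
    label = ifelse(is_cell, "cell", "non_cell"))
  fit <- train_and_tune(tab, fast_rf_spec(seed = 12L))
  imp <- fit$report$feature_importances
  expect_equal(names(which.max(imp)), "solidity")
})
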
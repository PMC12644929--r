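# Synthetic generator: determinism, degenerate scenes, mixture structure.

test_that("empty scene reproduces the configured background levels", {
  cfg <- simulation_config(n_cells = 0L, n_debris = 0L,
                           image_shape = c(128L, 128L), seed = 3L)
  res <- simulate_micrograph(cfg)
  expect_equal(nrow(res$ground_truth), 0L)
  expect_lt(abs(mean(res$micrograph$phase) - cfg$background_level), 1)
  expect_lt(abs(mean(res$micrograph$fluor) - cfg$fluor_background_level), 1)
  expect_true(all(res$micrograph$phase >= 0 & res$micrograph$phase <= 255))
})

test_that("p_high = 0 yields only low-expression cells", {
  cfg <- simulation_config(n_cells = 15L, n_debris = 0L, p_high = 0,
                           image_shape = c(256L, 256L), seed = 4L)
  res <- simulate_micrograph(cfg)
  expect_true(all(res$ground_truth$expression_class == "low"))
})

test_that("identical seeds give bit-identical images and tables", {
  cfg <- simulation_config(n_cells = 10L, n_debris = 3L,
                           image_shape = c(256L, 256L), seed = 9L)
  a <- simulate_micrograph(cfg)
  b <- simulate_micrograph(cfg)
  expect_identical(a$micrograph$phase, b$micrograph$phase)
  expect_identical(a$micrograph$fluor, b$micrograph$fluor)
  expect_identical(a$ground_truth, b$ground_truth)
  ta <- simulate_feature_table(cfg, 200)
  tb <- simulate_feature_table(cfg, 200)
  expect_identical(ta, tb)
})

test_that("high-expression counts follow the configured binomial fraction", {
  # brute force over 200 seeded populations of 50 cells at p_high = 0.2
  highs <- vapply(1:200, function(s) {
    cfg <- simulation_config(n_cells = 50L, p_high = 0.2, seed = s)
    sum(simulate_cell_population(cfg, 50)$expression_class == "high")
  }, numeric(1))
  # mean of Binomial(50, 0.2) is 10; 3 SEs of the mean over 200 draws
  se <- sqrt(50 * 0.2 * 0.8 / 200)
  expect_lt(abs(mean(highs) - 10), 3 * se)
  # and the micrograph path draws from the same law
  cfg <- simulation_config(n_cells = 50L, p_high = 0.2,
                           image_shape = c(1024L, 1024L), seed = 1L)
  gt <- simulate_micrograph(cfg)$ground_truth
  expect_true(sum(gt$expression_class == "high", na.rm = TRUE) %in% 0:50)
  expect_equal(nrow(gt), 60L)  # 50 cells + 10 debris
})

test_that("maximal class separation makes solidity alone perfectly separating", {
  cfg <- simulation_config(class_separation = 1, seed = 21L)
  tab <- simulate_feature_table(cfg, 100)
  expect_setequal(unique(tab$label), c("cell", "non_cell"))
  cells <- tab$solidity[tab$label == "cell"]
  debris <- tab$solidity[tab$label == "non_cell"]
  cut <- (min(cells) + max(debris)) / 2
  expect_true(max(debris) < min(cells))
  expect_equal(mean((tab$solidity >= cut) == (tab$label == "cell")), 1.0)
})

test_that("identical class distributions are uninformative to a classifier", {
  cfg <- simulation_config(class_separation = 0, p_cell = 0.5, seed = 8L)
  tab <- simulate_feature_table(cfg, 800)
  fit <- train_and_tune(tab, fast_lr_spec(seed = 2L))
  expect_lt(abs(fit$report$metrics[["roc_auc"]] - 0.5), 0.15)
})

test_that("skewness of simulated fluorescence grows with component separation", {
  sk <- vapply(c(3.2, 4.2, 5.2), function(ml) {
    cfg <- simulation_config(p_high = 0.1,
                             high_expr_params = c(ml, 0.25),
                             fluor_noise_sd = 1, seed = 5L)
    moment_skewness(simulate_cell_population(cfg, 3000)$value)
  }, numeric(1))
  expect_true(all(diff(sk) > 0))
})

test_that("overcrowded configurations fail with a density error", {
  cfg <- simulation_config(n_cells = 400L, image_shape = c(128L, 128L),
                           seed = 2L)
  expect_error(simulate_micrograph(cfg), "density")
})
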
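# Population statistics: moments, the IQR baseline criterion, summaries,
# subpopulation fold changes, hypothesis tests, CFU normalisation.

# brute-force central-moment oracle
cm <- function(x, k) sum((x - sum(x) / length(x))^k) / length(x)

test_that("moment skewness and kurtosis match the direct-moment oracle", {
  expect_equal(moment_skewness(c(-1, 0, 1)), 0)
  x <- c(1, 2, 3, 4, 10)
  expect_equal(moment_skewness(x), cm(x, 3) / cm(x, 2)^1.5)
  expect_equal(moment_kurtosis(x), cm(x, 4) / cm(x, 2)^2)
  # symmetric two-point mass attains the kurtosis lower bound 1
  expect_equal(moment_kurtosis(rep(c(-1, 1), 10)), 1)
  expect_error(moment_skewness(rep(2, 5)), "variance")
  expect_error(moment_kurtosis(rep(2, 5)), "variance")
  expect_error(moment_skewness(1:2), "n >= 3")
})

test_that("the baseline threshold is Q75 + 1.5 IQR under linear interpolation", {
  expect_equal(fit_baseline(rep(5, 10))$threshold_I, 5)  # constant: IQR 0
  # order-statistic oracle for 1..100 (type-7 interpolation, by hand):
  # q75 at position 0.75*99+1 = 75.25; q25 at 25.75
  bl <- fit_baseline(as.numeric(1:100))
  expect_equal(bl$q75, 75.25)
  expect_equal(bl$iqr, 75.25 - 25.75)
  expect_equal(bl$threshold_I, 75.25 + 1.5 * 49.5)
  expect_error(fit_baseline(numeric(0)), "empty")
})

test_that("the IQR criterion flags ~0.35% of null-normal draws", {
  set.seed(1234)
  bl <- fit_baseline(rnorm(1e5))
  # Monte-Carlo oracle of the classical outlier rate on fresh draws
  frac <- mean(relative_fluorescence(rnorm(1e5), bl) > 1)
  expect_lt(abs(frac - 0.0035), 0.001)
})

test_that("relative fluorescence uses a strict > 1 high rule", {
  bl <- fit_baseline(c(rep(0, 3), 2, 2))   # q75 = 2, iqr = 2, I = 5
  expect_equal(bl$threshold_I, 5)
  pop <- tibble::tibble(condition = "a", timepoint = 1, replicate = "r1",
                        value = c(5, 2.5, 10))
  rel <- relative_fluorescence(pop, bl)
  expect_equal(rel$rel_value, c(1, 0.5, 2))
  expect_equal(rel$high, c(FALSE, FALSE, TRUE))  # boundary not high
  degenerate <- fit_baseline(rep(0, 8))
  expect_error(relative_fluorescence(pop, degenerate), "degenerate")
})

test_that("summaries pool replicates exactly as concatenation", {
  v1 <- c(0.2, 0.4, 0.6, 1.4, 2.0)
  v2 <- c(0.1, 0.3, 0.5, 0.7, 3.0)
  pop <- tibble::tibble(
    condition = "a", timepoint = 1,
    replicate = rep(c("r1", "r2"), each = 5),
    rel_value = c(v1, v2))
  s <- summarize_population(pop)
  all_v <- c(v1, v2)
  expect_equal(s$n_replicates, 2L)
  expect_equal(s$n_cells, 10L)
  expect_equal(s$median_rel_fluor, median(all_v))
  expect_equal(s$iqr_rel_fluor,
               quantile(all_v, 0.75, names = FALSE) -
                 quantile(all_v, 0.25, names = FALSE))
  expect_equal(s$proportion_high, 100 * mean(all_v > 1))
  expect_equal(s$max_rel_fluor, 3.0)
  expect_equal(s$skewness, cm(all_v, 3) / cm(all_v, 2)^1.5)
  expect_equal(s$kurtosis, cm(all_v, 4) / cm(all_v, 2)^2)
  # single replicate at exactly baseline
  one <- tibble::tibble(condition = "a", timepoint = 1, replicate = "r1",
                        rel_value = rep(1, 25))
  s1 <- summarize_population(one)
  expect_equal(s1$median_rel_fluor, 1)
  expect_equal(s1$proportion_high, 0)
  expect_equal(s1$iqr_rel_fluor, 0)
})

test_that("replicate exclusion drops only undersized replicates", {
  pop <- tibble::tibble(
    condition = "a", timepoint = 1,
    replicate = rep(c("r1", "r2"), c(25, 5)),
    value = rnorm(30))
  expect_warning(kept <- exclude_small_replicates(pop, 20L), "excluding")
  expect_equal(unique(kept$replicate), "r1")
})

test_that("top-quantile fold changes follow the order-statistic oracle", {
  pop <- tibble::tibble(condition = "a", timepoint = rep(c(1, 2), each = 200),
                        replicate = rep(rep(c("r1", "r2"), each = 100), 2),
                        rel_value = rep(2, 400))
  fc <- top_quantile_foldchange(pop, 0.01)
  expect_true(all(fc$replicate_foldchanges$fold_change == 2))
  # one replicate: 99 cells at 0.1 and one at 5.0; top 1% is the single 5.0
  pop2 <- tibble::tibble(condition = "a", timepoint = 1, replicate = "r1",
                         rel_value = c(rep(0.1, 99), 5.0))
  fc2 <- top_quantile_foldchange(pop2, 0.01)
  expect_equal(fc2$replicate_foldchanges$fold_change, 5.0)
  # undersized replicates are excluded with a warning; all-excluded errors
  tiny <- tibble::tibble(condition = "a", timepoint = 1, replicate = "r1",
                         rel_value = rep(1, 10))
  expect_error(expect_warning(top_quantile_foldchange(tiny, 0.01), "excluding"),
               "excluded")
})

test_that("identical groups yield no significant differences", {
  g <- rep(c(1.0, 1.1, 0.9, 1.2, 1.05), 3)
  tp <- factor(rep(c("t1", "t2", "t3"), each = 5))
  ht <- hypothesis_tests(g, tp)
  expect_equal(ht$omnibus$statistic, 0)
  expect_equal(ht$omnibus$p_value, 1)
  expect_false(any(ht$posthoc$significant))
  # degenerate constant group errors, naming the failing test
  expect_error(hypothesis_tests(c(1, 1, 1, 2, 3, 4),
                                factor(rep(c("a", "b"), each = 3))),
               "Shapiro")
})

test_that("the gate routes non-normal data to Kruskal-Wallis + Dunn", {
  set.seed(5)
  vals <- c(rlnorm(40, 0, 1), rlnorm(40, 1.5, 1))
  grp <- factor(rep(c("a", "b"), each = 40))
  ht <- hypothesis_tests(vals, grp)
  expect_equal(ht$gate$branch, "nonparametric")
  expect_equal(ht$omnibus$test, "kruskal_wallis")
  expect_match(ht$posthoc$method[1], "dunn_holm")
  # Dunn z agrees with the Kruskal-Wallis statistic in the 2-group case
  expect_equal(ht$posthoc$estimate[1]^2, unname(ht$omnibus$statistic),
               tolerance = 1e-12)
})

test_that("Holm-Bonferroni follows the step-down arithmetic", {
  # step-down oracle for p = {0.01, 0.02, 0.04}, m = 3:
  # 3*0.01 = 0.03; max(0.03, 2*0.02) = 0.04; max(0.04, 1*0.04) = 0.04
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "holm"),
               c(0.03, 0.04, 0.04))
  set.seed(8)
  vals <- c(rlnorm(30), rlnorm(30, 1), rlnorm(30, 2))
  grp <- factor(rep(c("a", "b", "c"), each = 30))
  dt <- dunn_test(vals, grp, p_adjust = "holm")
  expect_equal(dt$p_adjusted, p.adjust(dt$p_value, method = "holm"))
})

test_that("normal probability coordinates use (i - 0.5)/n positions", {
  two <- normal_probability_data(c(3, 1))
  expect_equal(two$theoretical, qnorm(c(0.25, 0.75)))
  expect_equal(two$ordered, c(1, 3))
  # a perfect normal-quantile input is exactly linear
  v <- qnorm((seq_len(200) - 0.5) / 200)
  npp <- normal_probability_data(v)
  expect_equal(cor(npp$theoretical, npp$ordered), 1)
  # lognormal data bend convex: right tail above the fitted line and
  # positive skewness
  set.seed(9)
  ln <- rlnorm(500)
  npp2 <- normal_probability_data(ln)
  fit <- lm(ordered ~ theoretical, data = npp2)
  expect_gt(tail(residuals(fit), 1), 0)
  expect_gt(moment_skewness(ln), 0)
})

test_that("CFU normalisation tracks dilution, wash volume and weight", {
  expect_equal(cfu_per_gram(0, 10, 10, 1000, 0.1), 0)
  # 50 colonies at 1e3 dilution, 10 uL plated of a 1000 uL wash, 0.1 g
  expect_equal(cfu_per_gram(50, 1e3, 10, 1000, 0.1), 5e7)
  expect_equal(cfu_per_gram(50, 1e3, 10, 1000, 0.2),
               cfu_per_gram(50, 1e3, 10, 1000, 0.1) / 2)
  expect_error(cfu_per_gram(5, 10, 10, 1000, 0), "> 0")
})

test_that("relative statistics are invariant to global intensity rescaling", {
  set.seed(10)
  ctrl <- rlnorm(500, 2, 0.4)
  test_v <- rlnorm(500, 2.4, 0.6)
  stats_of <- function(scale) {
    bl <- fit_baseline(ctrl * scale)
    pop <- tibble::tibble(condition = "a", timepoint = 1, replicate = "r1",
                          value = test_v * scale)
    summarize_population(relative_fluorescence(pop, bl))
  }
  s1 <- stats_of(1); s7 <- stats_of(7.3)
  for (col in c("median_rel_fluor", "iqr_rel_fluor", "proportion_high",
                "max_rel_fluor", "skewness", "kurtosis"))
    expect_equal(s7[[col]], s1[[col]], tolerance = 1e-12)
})

test_that("every sample satisfies kurtosis >= skewness^2 + 1", {
  set.seed(11)
  for (i in 1:20) {
    x <- switch(1 + i %% 4, rnorm(50), rlnorm(50, 0, 1.5), runif(50),
                c(rnorm(45), rnorm(5, 20)))
    expect_gte(moment_kurtosis(x), moment_skewness(x)^2 + 1 - 1e-12)
  }
})
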
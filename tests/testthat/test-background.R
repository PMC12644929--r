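# Background mask, square sampling and per-image correction.

test_that("percentile mask inverts the target-fraction foreground", {
  cst <- matrix(50, 16, 16)
  expect_true(all(background_mask(cst)))
  half <- matrix(rep(c(40, 220), each = 128), 16, 16)
  bm <- background_mask(half)       # default: foreground = bright half
  expect_true(all(bm[half == 40]))
  expect_true(all(!bm[half == 220]))
  # mask and its inversion tile the image exactly
  expect_equal(sum(bm) + sum(!bm), length(half))
  # dark-foreground orientation flips the roles (phase-contrast biomass)
  bm2 <- background_mask(half, dark_foreground = TRUE)
  expect_true(all(bm2[half == 220]))
})

test_that("uniform background estimates are seed-independent and exact", {
  fl <- matrix(7, 32, 32)
  bm <- matrix(TRUE, 32, 32)
  for (s in c(1L, 99L)) {
    est <- estimate_background(fl, bm, n_squares = 50, seed = s)
    expect_equal(est$median_background, 7)
    expect_equal(est$n_valid_squares, 50L)
  }
  one <- estimate_background(fl, bm, n_squares = 1, seed = 3L)
  expect_equal(one$median_background, 7)
})

test_that("square placement is seed-deterministic and mask-respecting", {
  set.seed(1)
  fl <- matrix(runif(40 * 40, 0, 50), 40, 40)
  bm <- matrix(FALSE, 40, 40); bm[5:20, 5:20] <- TRUE
  a <- estimate_background(fl, bm, n_squares = 30, seed = 7L)
  b <- estimate_background(fl, bm, n_squares = 30, seed = 7L)
  expect_identical(a$square_means, b$square_means)
  # a tiny background region yields fewer squares, with a warning
  bm_small <- matrix(FALSE, 40, 40); bm_small[5:8, 5:8] <- TRUE
  expect_warning(small <- estimate_background(fl, bm_small, n_squares = 30,
                                              seed = 2L), "background squares")
  expect_lt(small$n_valid_squares, 30L)
  bm_none <- matrix(FALSE, 40, 40)
  expect_error(estimate_background(fl, bm_none, seed = 1L), "background mask")
})

test_that("two equal plateaus give a median between them in expectation", {
  fl <- matrix(rep(c(10, 30), each = 512), 32, 32)
  bm <- matrix(TRUE, 32, 32)
  meds <- vapply(1:100, function(s)
    estimate_background(fl, bm, n_squares = 10, seed = s)$median_background,
    numeric(1))
  # each square mean is 10, 30, or a straddling mixture; the median of an
  # even-count sample can also fall halfway
  expect_true(all(meds >= 10 & meds <= 30))
  expect_lt(abs(mean(meds) - 20), 4)
})

test_that("correction subtracts each image's own median background", {
  recs <- tibble::tibble(
    image_id = c("a", "a", "b"), condition = "c1", replicate = "r1",
    timepoint = 1, mean_fluor = c(100, 30, 50), label = "cell")
  ests <- list(
    structure(list(image_id = "a", median_background = 40), class = "background_estimate"),
    structure(list(image_id = "b", median_background = 10), class = "background_estimate"))
  pop <- correct_fluorescence(recs, ests)
  expect_equal(pop$value, c(60, -10, 40))  # negatives retained
  # affine shift: within-image differences preserved exactly
  expect_equal(diff(pop$value[1:2]), diff(recs$mean_fluor[1:2]))
  expect_error(correct_fluorescence(recs, ests[1]), "\\bb\\b")
})

test_that("corrected low-expression cells recover the low-component mean", {
  cfg <- simulation_config(n_cells = 25L, n_debris = 0L, p_high = 0, seed = 18L)
  res <- simulate_micrograph(cfg)
  p <- detect_particles(res$micrograph)
  p$label <- "cell"; p$timepoint <- 0
  bm <- background_mask(res$micrograph$phase, dark_foreground = TRUE)
  est <- estimate_background(res$micrograph$fluor, bm, seed = 4L,
                             image_id = res$micrograph$image_id)
  pop <- correct_fluorescence(p, est)
  m <- match_particles(p, res$ground_truth)
  truth <- res$ground_truth$true_fluorescence[match(m$object_id,
                                                    res$ground_truth$object_id)]
  got <- pop$value[m$particle_row]
  expect_equal(mean(got), mean(truth), tolerance = 0.1)
})
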
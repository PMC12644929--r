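# Segmentation: 8-bit conversion, thresholding, morphology, particle
# detection and the area filter.

test_that("8-bit conversion follows the min-max + round-half-up contract", {
  expect_true(all(to_grayscale_8bit(matrix(7, 4, 4)) == 0L))
  two <- to_grayscale_8bit(matrix(c(3, 9), 2, 2))
  expect_setequal(unique(as.vector(two)), c(0L, 255L))
  # direct arithmetic: x scaled by 255/256 then rounded half up
  m <- to_grayscale_8bit(matrix(c(0, 128, 256, 0), 2, 2))
  expect_equal(sort(unique(as.vector(m))), c(0L, 128L, 255L))
  expect_equal(m[2, 1], as.integer(floor(128 * 255 / 256 + 0.5)))
  expect_error(to_grayscale_8bit(matrix(numeric(0), 0, 0)), "empty")
})

test_that("threshold is mean minus k population SDs", {
  # constant image: sd = 0, threshold = mean, empty strict-below foreground
  cst <- matrix(42, 8, 8)
  expect_equal(compute_threshold(cst, 2), 42)
  expect_equal(sum(cst < compute_threshold(cst, 2)), 0L)
  # half 100s / half 200s at k = 1: 150 - 50 = 100
  half <- matrix(rep(c(100, 200), each = 32), 8, 8)
  expect_equal(compute_threshold(half, 1), 100)
  # Gaussian tail: at k = 4 the foreground fraction ~ pnorm(-4)
  set.seed(11)
  g <- matrix(rnorm(1000 * 1000), 1000, 1000)
  frac <- mean(g < compute_threshold(g, 4))
  expect_gt(frac, 1e-5)
  expect_lt(frac, 6e-5)
})

test_that("mask refinement opens, preserves and splits as specified", {
  cfg_od <- segmentation_config(morphology_sequence = c("erode", "dilate"))
  empty <- matrix(0, 32, 32)
  expect_equal(sum(refine_mask(empty, cfg_od)), 0)
  # opening preserves one solid ellipse as one component
  m <- matrix(0, 64, 64)
  m[raster_ellipse(12, 6, 30, pad = 20)] <- 1
  out <- refine_mask(m, cfg_od)
  expect_equal(max(label_components(out)), 1L)
  # two overlapping discs (dumbbell) split by watershed
  dumb <- matrix(0, 64, 40)
  g <- expand.grid(r = 1:64, c = 1:40)
  keep <- (g$r - 22)^2 + (g$c - 20)^2 <= 100 | (g$r - 40)^2 + (g$c - 20)^2 <= 100
  dumb[as.matrix(g[keep, c("r", "c")])] <- 1
  expect_equal(max(label_components(dumb)), 1L)
  split <- refine_mask(dumb, segmentation_config(morphology_sequence = "watershed"))
  expect_equal(max(label_components(split)), 2L)
})

test_that("component labelling is 8-connected", {
  m <- matrix(0, 6, 6)
  m[2, 2] <- 1; m[3, 3] <- 1; m[5, 5] <- 1
  lab <- label_components(m)
  expect_equal(max(lab), 2L)
  expect_equal(lab[2, 2], lab[3, 3])
})

test_that("area filter retains exactly the in-window particles", {
  mg0 <- micrograph(matrix(150, 64, 64), matrix(0, 64, 64), 0.05)
  expect_equal(nrow(detect_particles(mg0)), 0L)
  # disc areas 0.1, 0.5, 7.0 um^2 at 0.05 um/px -> radii in px
  radii <- sqrt(c(0.1, 0.5, 7.0) / 0.05^2 / pi)
  mg <- disc_micrograph(radii, pixel_size = 0.05)
  p <- detect_particles(mg, segmentation_config(k_sd = 2))
  expect_equal(nrow(p), 1L)
  expect_true(p$area > 0.25 && p$area < 6.0)
  # pixel size is mandatory: the filter is physical
  broken <- mg; broken$pixel_size <- NA_real_
  expect_error(detect_particles(broken), "pixel_size")
})

test_that("well-separated synthetic cells are recovered and matched", {
  cfg <- simulation_config(n_cells = 30L, n_debris = 0L, seed = 14L)
  res <- simulate_micrograph(cfg)
  p <- detect_particles(res$micrograph)
  m <- match_particles(p, res$ground_truth)
  expect_gte(nrow(m), 28L)
  expect_true(all(m$dist <= 2))
  # area conservation: retained particle area cannot exceed mask foreground
  thr <- compute_threshold(res$micrograph$phase, 2)
  mask <- refine_mask(res$micrograph$phase < thr, segmentation_config())
  expect_lte(sum(p$area), sum(mask) * res$micrograph$pixel_size^2)
})

test_that("mean particle fluorescence is measured on the fluorescence channel", {
  mg <- disc_micrograph(c(8, 8), fluor_levels = c(50, 120), pixel_size = 0.05)
  p <- detect_particles(mg, segmentation_config(k_sd = 2))
  expect_equal(nrow(p), 2L)
  expect_equal(sort(round(p$mean_fluor, -1)), c(50, 120), tolerance = 0.2)
})
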
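# Shared fixtures: rasterized reference shapes and small configs.
# All fixtures are built in code at test time.

# pixel sets ((row, col), 1-based) for reference shapes on a clear field
raster_disc <- function(radius, pad = 5L) {
  n <- 2L * (radius + pad)
  ctr <- n / 2
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  keep <- (g$r - ctr)^2 + (g$c - ctr)^2 <= radius^2
  as.matrix(g[keep, c("r", "c")])
}

raster_square <- function(side, pad = 5L) {
  g <- expand.grid(r = pad + seq_len(side), c = pad + seq_len(side))
  as.matrix(g)
}

raster_ellipse <- function(a, b, angle_deg = 0, pad = 5L) {
  n <- 2L * (ceiling(max(a, b)) + pad)
  ctr <- n / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(r = seq_len(n), c = seq_len(n))
  dx <- g$c - ctr; dy <- g$r - ctr
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[keep, c("r", "c")])
}

# a phase/fluor micrograph with dark discs of the given pixel radii on a
# constant bright background (no noise), fluor carrying known levels
disc_micrograph <- function(radii, fluor_levels = NULL, shape = c(256L, 256L),
                            pixel_size = 0.05, bg = 200, dark = 100) {
  phase <- matrix(bg, shape[1], shape[2])
  fluor <- matrix(10, shape[1], shape[2])
  centres <- cbind(seq(60, shape[1] - 60, length.out = length(radii)),
                   rep(shape[2] / 2, length(radii)))
  for (i in seq_along(radii)) {
    g <- expand.grid(r = seq_len(shape[1]), c = seq_len(shape[2]))
    keep <- (g$r - centres[i, 1])^2 + (g$c - centres[i, 2])^2 <= radii[i]^2
    px <- as.matrix(g[keep, c("r", "c")])
    phase[px] <- dark
    if (!is.null(fluor_levels)) fluor[px] <- fluor_levels[i]
  }
  micrograph(phase, fluor, pixel_size, image_id = "fixture")
}

fast_lr_spec <- function(seed = 1L, ...) {
  classifier_spec("lr_l1", lr_grid_size = 8L, seed = seed, ...)
}

fast_rf_spec <- function(seed = 1L, ...) {
  classifier_spec("rf", rf_n_trees = 100L, rf_min_node_grid = c(5L, 20L),
                  n_cv_folds = 5L, seed = seed, ...)
}
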
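#' Segmentation configuration
#'
#' @param k_sd threshold multiplier in \[1, 4\]: foreground candidates are
#'   pixels more than `k_sd` population standard deviations below the mean
#'   phase intensity. 2 suits clean liquid-culture-style fields; 4 suits
#'   noisier leaf-wash-style fields.
#' @param area_min,area_max particle area filter in square micrometres
#'   (defaults 0.25 and 6.0).
#' @param morphology_sequence ordered character vector over
#'   `c("watershed", "erode", "dilate")` applied to the thresholded mask.
#' @param n_bg_squares,bg_square_size background sampling: number of
#'   squares (default 50) and square side in pixels (default 2).
#' @param bg_target target foreground fraction of the percentile
#'   auto-threshold used to build the background mask (default 0.5).
#' @param seed integer seed used for background square placement.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(k_sd = 2, area_min = 0.25, area_max = 6.0,
                                morphology_sequence = c("watershed", "erode", "dilate"),
                                n_bg_squares = 50L, bg_square_size = 2L,
                                bg_target = 0.5, seed = 1L) {
  assert_number(k_sd, "k_sd", 1, 4)
  if (!(area_min > 0 && area_min < area_max))
    stopf("need 0 < area_min < area_max")
  bad <- setdiff(morphology_sequence, c("watershed", "erode", "dilate"))
  if (length(bad)) stopf("unknown morphology operation(s): %s",
                         paste(bad, collapse = ", "))
  structure(list(k_sd = k_sd, area_min = area_min, area_max = area_max,
                 morphology_sequence = morphology_sequence,
                 n_bg_squares = as.integer(n_bg_squares),
                 bg_square_size = as.integer(bg_square_size),
                 bg_target = bg_target, seed = as.integer(seed)),
            class = "segmentation_config")
}

#' Convert an intensity image to 8-bit grayscale
#'
#' Linear min-max rescale to \[0, 255\] followed by round-half-up. A
#' constant image maps to all zeros (its range is degenerate).
#'
#' @param image numeric matrix of finite intensities.
#' @return integer matrix with values in 0..255.
#' @export
to_grayscale_8bit <- function(image) {
  if (length(image) == 0L) stopf("empty image")
  if (!all(is.finite(image))) stopf("image contains non-finite intensities")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    out <- matrix(0L, nrow(image), ncol(image))
  } else {
    scaled <- (image - rng[1]) / (rng[2] - rng[1]) * 255
    out <- matrix(as.integer(floor(scaled + 0.5)), nrow(image), ncol(image))
  }
  out
}

#' Phase-contrast foreground threshold
#'
#' `mean(phase) - k_sd * sd(phase)` with the population (1/n) standard
#' deviation; pixels strictly below the threshold are foreground
#' candidates (cells are dark in phase contrast).
#'
#' @param phase numeric matrix (8-bit scale).
#' @param k_sd multiplier in \[1, 4\].
#' @return scalar intensity threshold.
#' @export
compute_threshold <- function(phase, k_sd) {
  assert_number(k_sd, "k_sd", 1, 4)
  mean(phase) - k_sd * pop_sd(as.numeric(phase))
}

# 3x3 box structuring element (one-pixel radius, 8-neighbourhood).
brush3 <- function() EBImage::makeBrush(3L, shape = "box")

# Split touching objects: watershed on the distance map, then remove, from
# the higher-numbered basin only, pixels 8-adjacent to a different basin.
# Removing one side keeps a single-pixel separation line while guaranteeing
# that no 8-connectivity remains between basins.
watershed_split <- function(mask) {
  if (!any(mask > 0)) return(mask)
  lab <- EBImage::watershed(EBImage::distmap(mask))
  lab <- as.matrix(lab)
  drop <- matrix(FALSE, nrow(lab), ncol(lab))
  n <- nrow(lab); m <- ncol(lab)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    sr <- max(1, 1 + s[1]):min(n, n + s[1])
    tr <- max(1, 1 - s[1]):min(n, n - s[1])
    sc <- max(1, 1 + s[2]):min(m, m + s[2])
    tc <- max(1, 1 - s[2]):min(m, m - s[2])
    a <- lab[tr, tc, drop = FALSE]   # pixel under consideration
    b <- lab[sr, sc, drop = FALSE]   # its neighbour
    hit <- a > 0 & b > 0 & a != b & a > b
    drop[tr, tc] <- drop[tr, tc] | hit
  }
  out <- mask
  out[drop] <- 0
  out
}

#' Refine a binary mask morphologically
#'
#' Applies the configured sequence of operations: `watershed` (split
#' touching convex objects along distance-map basins), `erode` and `dilate`
#' (one-pixel-radius 3x3 structuring element).
#'
#' @param mask binary (0/1 or logical) matrix.
#' @param config a [segmentation_config()].
#' @return binary 0/1 matrix of the same shape.
#' @export
refine_mask <- function(mask, config = segmentation_config()) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  for (op in config$morphology_sequence) {
    m <- switch(op,
      watershed = watershed_split(m),
      erode = as.matrix(EBImage::erode(m, brush3())),
      dilate = as.matrix(EBImage::dilate(m, brush3())))
    m <- matrix(as.numeric(m > 0), nrow(m), ncol(m))
  }
  m
}

#' Label connected components with 8-connectivity
#'
#' @param mask binary matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  lab <- as.matrix(EBImage::bwlabel(m))   # 4-connected
  k <- max(lab)
  if (k < 2) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  # merge labels touching diagonally (union-find)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  n <- nrow(lab); m2 <- ncol(lab)
  for (s in list(c(1, 1), c(1, -1))) {
    tr <- 1:(n - 1); sr <- 2:n
    if (s[2] == 1) { tc <- 1:(m2 - 1); sc <- 2:m2 } else { tc <- 2:m2; sc <- 1:(m2 - 1) }
    a <- lab[tr, tc]; b <- lab[sr, sc]
    hit <- which(a > 0 & b > 0 & a != b)
    for (i in hit) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  matrix(as.integer(out), nrow(out), ncol(out))
}

#' Detect size-filtered particles and measure them
#'
#' Thresholds the phase channel (`mean - k_sd * sd`, strict), refines the
#' mask with the configured morphology, labels 8-connected components,
#' retains components whose physical area lies in
#' `[area_min, area_max]` square micrometres, and measures the full shape
#' descriptor set plus the mean fluorescence-channel intensity over each
#' particle's pixels.
#'
#' @param mg a [micrograph()].
#' @param config a [segmentation_config()].
#' @return tibble of particle records: provenance columns, `area` (um^2),
#'   `mean_fluor`, `perimeter`, `major`, `minor`, `angle`, `circularity`,
#'   `feret`, `min_feret`, `feret_x`, `feret_y`, `feret_angle`,
#'   `aspect_ratio`, `roundness`, `solidity` (conventions as in
#'   [shape_descriptors()]), 0-based `centroid_r`/`centroid_c`, and
#'   `label = "unknown"`.
#' @export
detect_particles <- function(mg, config = segmentation_config()) {
  stopifnot(inherits(mg, "micrograph"))
  if (is.null(mg$pixel_size) || !is.finite(mg$pixel_size) || mg$pixel_size <= 0)
    stopf("micrograph has no valid pixel_size; the area filter is physical (um^2)")
  thr <- compute_threshold(mg$phase, config$k_sd)
  mask <- matrix(as.numeric(mg$phase < thr), nrow(mg$phase), ncol(mg$phase))
  mask <- refine_mask(mask, config)
  lab <- label_components(mask)
  k <- max(lab)
  if (k == 0L) return(empty_particle_table())
  ps2 <- mg$pixel_size^2
  rows <- vector("list", k)
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  for (i in seq_len(k)) {
    px <- idx[labs == i, , drop = FALSE]
    area <- nrow(px) * ps2
    if (area < config$area_min || area > config$area_max) next
    d <- shape_descriptors(px, mg$pixel_size)
    d$image_id <- mg$image_id
    d$condition <- mg$condition
    d$replicate <- mg$replicate
    d$mean_fluor <- mean(mg$fluor[px])
    d$centroid_r <- mean(px[, 1]) - 1
    d$centroid_c <- mean(px[, 2]) - 1
    d$label <- "unknown"
    d$predicted_prob <- NA_real_
    rows[[i]] <- d
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty_particle_table())
  out <- dplyr::bind_rows(rows)
  dplyr::select(out, dplyr::all_of(particle_columns()),
                "centroid_r", "centroid_c")
}

particle_columns <- function() {
  c("image_id", "condition", "replicate", "area", "mean_fluor", "perimeter",
    "major", "minor", "angle", "circularity", "feret", "min_feret",
    "feret_x", "feret_y", "feret_angle", "aspect_ratio", "roundness",
    "solidity", "label", "predicted_prob")
}

empty_particle_table <- function() {
  out <- tibble::tibble(
    image_id = character(), condition = character(), replicate = character(),
    area = numeric(), mean_fluor = numeric(), perimeter = numeric(),
    major = numeric(), minor = numeric(), angle = numeric(),
    circularity = numeric(), feret = numeric(), min_feret = numeric(),
    feret_x = numeric(), feret_y = numeric(), feret_angle = numeric(),
    aspect_ratio = numeric(), roundness = numeric(), solidity = numeric(),
    label = character(), predicted_prob = numeric(),
    centroid_r = numeric(), centroid_c = numeric())
  out
}

#' Match detected particles to ground-truth objects
#'
#' Greedy nearest-centroid matching within a pixel tolerance, used to score
#' segmentation recall on synthetic scenes.
#'
#' @param particles particle table with `centroid_r`/`centroid_c` (0-based).
#' @param ground_truth ground-truth tibble from [simulate_micrograph()].
#' @param max_dist maximum centroid distance in pixels (default 2).
#' @return tibble with one row per matched pair: `object_id`, `particle_row`,
#'   `dist`.
#' @export
match_particles <- function(particles, ground_truth, max_dist = 2) {
  if (nrow(particles) == 0L || nrow(ground_truth) == 0L)
    return(tibble::tibble(object_id = integer(), particle_row = integer(),
                          dist = numeric()))
  d <- outer(ground_truth$centroid_r, particles$centroid_r, "-")^2 +
       outer(ground_truth$centroid_c, particles$centroid_c, "-")^2
  d <- sqrt(d)
  pairs <- which(d <= max_dist, arr.ind = TRUE)
  if (!nrow(pairs))
    return(tibble::tibble(object_id = integer(), particle_row = integer(),
                          dist = numeric()))
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_g <- logical(nrow(ground_truth)); used_p <- logical(nrow(particles))
  res <- list()
  for (i in seq_len(nrow(pairs))) {
    g <- pairs[i, 1]; p <- pairs[i, 2]
    if (used_g[g] || used_p[p]) next
    used_g[g] <- TRUE; used_p[p] <- TRUE
    res[[length(res) + 1L]] <- tibble::tibble(
      object_id = ground_truth$object_id[g], particle_row = as.integer(p),
      dist = d[g, p])
  }
  dplyr::bind_rows(res)
}
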
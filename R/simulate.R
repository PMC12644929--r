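#' Configuration for the synthetic micrograph and population generator
#'
#' The generator emulates the raw material of a single-cell bioreporter
#' experiment: dark, roughly elliptical bacterial cells on a brighter, noisy
#' phase-contrast background, with a co-registered fluorescence channel in
#' which per-cell intensity is drawn from a right-skewed two-component
#' lognormal mixture (a majority low-expression component and a minority
#' high-expression subpopulation of fraction `p_high`). Non-cell debris is
#' added so that the downstream cell/non-cell classifier has something real
#' to do: specks below the detectable area window, oversized blobs, concave
#' fragments with low solidity, and highly elongated fibres.
#'
#' @param image_shape integer vector (rows, cols) of the image in pixels.
#' @param pixel_size physical pixel size in micrometres per pixel. The
#'   default 0.065 um/px is typical for a 100x oil-immersion objective on a
#'   standard camera chip; it is a free parameter, not a measured value.
#' @param n_cells,n_debris number of cells / debris objects per field.
#' @param cell_area_range interval of true cell areas in square micrometres.
#'   The default (0.5, 4.0) sits inside the 0.25-6.0 um^2 particle-detection
#'   window so that simulated cells are detectable by construction.
#' @param cell_axis_ratio_range interval (>= 1) of cell major/minor ratios.
#' @param background_level,background_noise_sd phase-contrast background
#'   mean and Gaussian pixel-noise SD, on the 8-bit 0-255 scale.
#' @param cell_contrast how much darker (intensity units) cell interiors are
#'   than the phase background; must be positive.
#' @param p_high fraction of cells in the high-expression component, in
#'   \[0, 1\].
#' @param low_expr_params,high_expr_params length-2 numeric `(meanlog,
#'   sdlog)` of the lognormal fluorescence components, intensity units on
#'   the 8-bit scale after background correction.
#' @param fluor_background_level,fluor_noise_sd fluorescence background mean
#'   and noise SD.
#' @param class_separation in \[0, 1\]: how far debris shape-descriptor
#'   distributions sit from the cell distributions in
#'   [simulate_feature_table()]. 0 makes the classes indistinguishable;
#'   1 makes a rule on solidity alone perfectly separating. The default 0.8
#'   gives a moderately separable, realistic problem.
#' @param p_cell fraction of particles that are true cells in
#'   [simulate_feature_table()].
#' @param seed integer seed; every generator draw is deterministic given it.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(image_shape = c(512L, 512L),
                              pixel_size = 0.065,
                              n_cells = 30L,
                              n_debris = 10L,
                              cell_area_range = c(0.5, 4.0),
                              cell_axis_ratio_range = c(1.2, 3.5),
                              background_level = 180,
                              background_noise_sd = 6,
                              cell_contrast = 60,
                              p_high = 0.1,
                              low_expr_params = c(meanlog = log(15), sdlog = 0.35),
                              high_expr_params = c(meanlog = log(120), sdlog = 0.25),
                              fluor_background_level = 8,
                              fluor_noise_sd = 3,
                              class_separation = 0.8,
                              p_cell = 0.6,
                              seed = 1L) {
  assert_number(pixel_size, "pixel_size", lo = 1e-6)
  assert_number(p_high, "p_high", 0, 1)
  assert_number(class_separation, "class_separation", 0, 1)
  assert_number(p_cell, "p_cell", 0, 1)
  assert_number(cell_contrast, "cell_contrast", lo = 1e-9)
  assert_number(seed, "seed")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stopf("`image_shape` must be (rows, cols), both >= 8")
  if (length(cell_area_range) != 2L || cell_area_range[1] <= 0 ||
      diff(cell_area_range) <= 0)
    stopf("`cell_area_range` must be an increasing positive interval")
  if (cell_axis_ratio_range[1] < 1 || diff(cell_axis_ratio_range) < 0)
    stopf("`cell_axis_ratio_range` must be an interval with lower bound >= 1")
  for (p in list(low_expr_params, high_expr_params)) {
    if (length(p) != 2L || p[2] <= 0) stopf("expression params must be (meanlog, sdlog > 0)")
  }
  for (lvl in c(background_level, fluor_background_level)) {
    assert_number(lvl, "intensity level", 0, 255)
  }
  structure(list(
    image_shape = as.integer(image_shape), pixel_size = pixel_size,
    n_cells = as.integer(n_cells), n_debris = as.integer(n_debris),
    cell_area_range = cell_area_range,
    cell_axis_ratio_range = cell_axis_ratio_range,
    background_level = background_level,
    background_noise_sd = background_noise_sd,
    cell_contrast = cell_contrast, p_high = p_high,
    low_expr_params = unname(low_expr_params),
    high_expr_params = unname(high_expr_params),
    fluor_background_level = fluor_background_level,
    fluor_noise_sd = fluor_noise_sd,
    class_separation = class_separation, p_cell = p_cell,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

# Pixel set of a (possibly rotated) filled ellipse. Centre in 1-based matrix
# coordinates (row, col); angle in degrees, measured in the (x = col,
# y = row) plane. Returns a 2-column matrix of (row, col) indices.
ellipse_pixels <- function(shape, centre, a, b, angle_deg) {
  th <- angle_deg * pi / 180
  rmax <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(centre[1] - rmax)):min(shape[1], ceiling(centre[1] + rmax))
  cols <- max(1L, floor(centre[2] - rmax)):min(shape[2], ceiling(centre[2] + rmax))
  g <- expand.grid(r = rows, c = cols)
  dy <- g$r - centre[1]; dx <- g$c - centre[2]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  cbind(g$r[keep], g$c[keep])
}

# Sample one debris object: type, pixel set and nominal axes.
debris_pixels <- function(cfg, centre, type) {
  ps2 <- cfg$pixel_size^2
  switch(type,
    speck = {             # below the detectable window
      area_px <- stats::runif(1, 0.3, 0.8) * (0.25 / ps2)
      r <- sqrt(area_px / pi)
      list(px = ellipse_pixels(cfg$image_shape, centre, r, r, 0),
           major = 2 * r, minor = 2 * r, angle = 0)
    },
    blob = {              # above the window
      area_px <- stats::runif(1, 6.5, 9.0) / ps2
      ar <- stats::runif(1, 1, 1.6)
      a <- sqrt(area_px * ar / pi); b <- a / ar
      ang <- stats::runif(1, 0, 180)
      list(px = ellipse_pixels(cfg$image_shape, centre, a, b, ang),
           major = 2 * a, minor = 2 * b, angle = ang)
    },
    fragment = {          # in-range area, concave (two lobes at an angle)
      area_px <- stats::runif(1, 1.0, 4.0) / ps2
      a <- sqrt(area_px / (2 * pi) * 3); b <- a / 3
      ang <- stats::runif(1, 0, 180)
      off <- a * 0.9
      th <- ang * pi / 180
      c1 <- centre
      c2 <- centre + c(off * sin(th + pi / 2), off * cos(th + pi / 2))
      px <- rbind(ellipse_pixels(cfg$image_shape, c1, a, b, ang),
                  ellipse_pixels(cfg$image_shape, c2, a, b, ang + 90))
      list(px = unique(px), major = 2 * a, minor = 2 * b, angle = ang)
    },
    fibre = {             # in-range area, extreme aspect ratio
      area_px <- stats::runif(1, 0.8, 3.0) / ps2
      ar <- stats::runif(1, 6, 10)
      a <- sqrt(area_px * ar / pi); b <- max(a / ar, 1.1)
      ang <- stats::runif(1, 0, 180)
      list(px = ellipse_pixels(cfg$image_shape, centre, a, b, ang),
           major = 2 * a, minor = 2 * b, angle = ang)
    }
  )
}

#' Simulate one two-channel micrograph with ground truth
#'
#' Renders `n_cells` elliptical cells and `n_debris` debris objects at
#' non-overlapping positions, draws each cell's fluorescence from the
#' two-component lognormal mixture, adds Gaussian pixel noise to both
#' channels, and clips/rounds to the 8-bit range. Object placement uses
#' bounded rejection sampling; if a field is too crowded to place all
#' objects the function errors rather than silently dropping objects.
#'
#' @param config a [simulation_config()].
#' @param image_id,condition,replicate provenance labels stored on the
#'   returned micrograph.
#' @return list with elements `micrograph` (class `micrograph`: `phase` and
#'   `fluor` integer matrices on the 0-255 scale, `pixel_size`, `image_id`,
#'   `condition`, `replicate`) and `ground_truth` (tibble, one row per
#'   synthesized object: 0-based centroid, orientation, full axes in px,
#'   `is_cell`, `expression_class`, `true_fluorescence`).
#' @export
simulate_micrograph <- function(config, image_id = "img1",
                                condition = "synthetic", replicate = "r1") {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, {
    shp <- config$image_shape
    ps2 <- config$pixel_size^2
    n_obj <- config$n_cells + config$n_debris
    phase_sig <- matrix(config$background_level, shp[1], shp[2])
    fluor_sig <- matrix(config$fluor_background_level, shp[1], shp[2])

    # --- place objects with pixel-level collision rejection --------------
    # occupied = pixels already taken, dilated by a 3-px margin so that
    # neighbouring objects stay separable after mask refinement
    occupied <- matrix(FALSE, shp[1], shp[2])
    margin <- 3L
    mark_occupied <- function(px) {
      for (dr in -margin:margin) for (dc in -margin:margin) {
        r <- px[, 1] + dr; c <- px[, 2] + dc
        ok <- r >= 1 & r <= shp[1] & c >= 1 & c <= shp[2]
        occupied[cbind(r[ok], c[ok])] <<- TRUE
      }
    }
    gt <- vector("list", n_obj)
    debris_types <- c("speck", "blob", "fragment", "fibre")
    expr_class <- if (config$n_cells > 0)
      ifelse(stats::runif(config$n_cells) < config$p_high, "high", "low")
    else character(0)

    for (k in seq_len(n_obj)) {
      is_cell <- k <= config$n_cells
      if (is_cell) {
        area_px <- stats::runif(1, config$cell_area_range[1],
                                config$cell_area_range[2]) / ps2
        ar <- stats::runif(1, config$cell_axis_ratio_range[1],
                           config$cell_axis_ratio_range[2])
        a <- sqrt(area_px * ar / pi); b <- a / ar
        ang <- stats::runif(1, 0, 180)
        edge <- a + 2
      } else {
        type <- sample(debris_types, 1L)
        edge <- 35
      }
      px <- NULL
      for (try in seq_len(200L)) {
        centre <- c(stats::runif(1, edge + 1, shp[1] - edge),
                    stats::runif(1, edge + 1, shp[2] - edge))
        cand <- if (is_cell) {
          list(px = ellipse_pixels(shp, centre, a, b, ang),
               major = 2 * a, minor = 2 * b, angle = ang)
        } else debris_pixels(config, centre, type)
        if (nrow(cand$px) > 0L && !any(occupied[cand$px])) {
          px <- cand$px
          if (!is_cell) { d <- cand }
          break
        }
      }
      if (is.null(px))
        stopf(paste0("could not place object %d of %d after 200 attempts; ",
                     "the configured object density exceeds what a %dx%d ",
                     "field can hold without overlap"),
              k, n_obj, shp[1], shp[2])
      mark_occupied(px)

      if (is_cell) {
        fl <- stats::rlnorm(1, config$low_expr_params[1], config$low_expr_params[2])
        if (expr_class[k] == "high")
          fl <- stats::rlnorm(1, config$high_expr_params[1], config$high_expr_params[2])
        phase_sig[px] <- config$background_level - config$cell_contrast
        fluor_sig[px] <- config$fluor_background_level + fl
        gt[[k]] <- tibble::tibble(
          object_id = k, is_cell = TRUE, type = "cell",
          centroid_r = mean(px[, 1]) - 1, centroid_c = mean(px[, 2]) - 1,
          orientation_deg = ang %% 180, major_px = 2 * a, minor_px = 2 * b,
          area_px = nrow(px), expression_class = expr_class[k],
          true_fluorescence = fl)
      } else {
        # debris slightly less dark than cells, dim in fluorescence
        phase_sig[px] <- config$background_level - 0.7 * config$cell_contrast
        fluor_sig[px] <- config$fluor_background_level + stats::runif(1, 0, 5)
        gt[[k]] <- tibble::tibble(
          object_id = k, is_cell = FALSE, type = type,
          centroid_r = mean(px[, 1]) - 1, centroid_c = mean(px[, 2]) - 1,
          orientation_deg = d$angle %% 180, major_px = d$major,
          minor_px = d$minor, area_px = nrow(px),
          expression_class = NA_character_, true_fluorescence = NA_real_)
      }
    }

    phase <- phase_sig + matrix(stats::rnorm(prod(shp), 0, config$background_noise_sd),
                                shp[1], shp[2])
    fluor <- fluor_sig + matrix(stats::rnorm(prod(shp), 0, config$fluor_noise_sd),
                                shp[1], shp[2])
    mg <- micrograph(
      phase = matrix(as.integer(floor(clip(phase, 0, 255) + 0.5)), shp[1], shp[2]),
      fluor = matrix(as.integer(floor(clip(fluor, 0, 255) + 0.5)), shp[1], shp[2]),
      pixel_size = config$pixel_size, image_id = image_id,
      condition = condition, replicate = replicate)
    list(micrograph = mg,
         ground_truth = if (n_obj > 0) dplyr::bind_rows(gt) else tibble::tibble())
  })
}

#' Construct a micrograph object
#'
#' @param phase,fluor numeric/integer matrices of identical shape on the
#'   8-bit 0-255 scale (phase contrast and green fluorescence).
#' @param pixel_size micrometres per pixel (> 0).
#' @param image_id,condition,replicate provenance labels.
#' @return object of class `micrograph`.
#' @export
micrograph <- function(phase, fluor, pixel_size, image_id = "img1",
                       condition = "unknown", replicate = "r1") {
  if (!all(dim(phase) == dim(fluor)))
    stopf("phase and fluorescence channels must share shape")
  assert_number(pixel_size, "pixel_size", lo = 1e-9)
  structure(list(phase = phase, fluor = fluor, pixel_size = pixel_size,
                 image_id = image_id, condition = condition,
                 replicate = replicate),
            class = "micrograph")
}

#' @exportS3Method base::print
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph %s: %d x %d px, %.3f um/px, condition=%s, replicate=%s>\n",
              x$image_id, nrow(x$phase), ncol(x$phase), x$pixel_size,
              x$condition, x$replicate))
  invisible(x)
}

# Approximate perimeter of an ellipse with semi-axes a, b (Ramanujan).
ellipse_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Simulate a labelled particle feature table
#'
#' Draws shape descriptors for `n_particles` particles directly in feature
#' space (no image rendering): a fraction `p_cell` are true cells with
#' compact, convex geometry; the rest are debris whose solidity, aspect
#' ratio and area distributions are pulled away from the cell distributions
#' by `class_separation`. At `class_separation = 0` the two classes are
#' drawn from identical distributions; at 1 all debris solidity falls
#' strictly below all cell solidity, so a threshold on solidity alone
#' separates the classes. This stands in for a manually labelled training
#' table.
#'
#' @param config a [simulation_config()].
#' @param n_particles number of rows to generate (> 0).
#' @param condition condition label attached to every row (also usable as a
#'   categorical predictor downstream).
#' @return tibble in the particle-record dialect (see [detect_particles()])
#'   with a ground-truth `label` column in `{"cell", "non_cell"}`.
#' @export
simulate_feature_table <- function(config, n_particles, condition = "synthetic") {
  stopifnot(inherits(config, "simulation_config"))
  if (n_particles <= 0) stopf("`n_particles` must be > 0")
  withr::with_seed(config$seed, {
    n <- as.integer(n_particles)
    s <- config$class_separation
    is_cell <- stats::runif(n) < config$p_cell

    # base (cell-like) geometry for every particle
    area <- stats::runif(n, config$cell_area_range[1], config$cell_area_range[2])
    ar <- stats::runif(n, config$cell_axis_ratio_range[1],
                       config$cell_axis_ratio_range[2])
    solidity <- clip(stats::rnorm(n, 0.95, 0.025), 0.86, 1.0)

    # debris: perturb geometry away from the cell distributions by s
    nd <- sum(!is_cell)
    if (nd > 0) {
      dtype <- sample(c("fragment", "fibre", "speck_blob"), nd, replace = TRUE)
      sol_d <- solidity[!is_cell] - s * (0.15 + stats::runif(nd, 0, 0.25))
      ar_d <- ar[!is_cell]
      area_d <- area[!is_cell]
      fib <- dtype == "fibre"
      ar_d[fib] <- ar_d[fib] + s * stats::runif(sum(fib), 3, 7)
      sb <- dtype == "speck_blob"
      big <- stats::runif(sum(sb)) < 0.5
      area_d[sb] <- area_d[sb] * (1 - s) +
        s * ifelse(big, stats::runif(sum(sb), 6.0, 9.0),
                   stats::runif(sum(sb), 0.05, 0.25))
      solidity[!is_cell] <- clip(sol_d, 0.30, 1.0)
      ar[!is_cell] <- ar_d
      area[!is_cell] <- area_d
    }

    major <- 2 * sqrt(area * ar / pi)           # um
    minor <- major / ar
    perim <- ellipse_perimeter(major / 2, minor / 2) / sqrt(solidity) *
      stats::rlnorm(n, 0, 0.03)
    circ <- clip(4 * pi * area / perim^2, 0, 1)
    roundness <- clip(4 * area / (pi * major^2) * stats::rlnorm(n, 0, 0.03), 0, 1)
    feret <- major * stats::rlnorm(n, 0.01, 0.02)
    min_feret <- minor * stats::rlnorm(n, 0.01, 0.02)

    # fluorescence: cells from the expression mixture, debris dim
    expr <- ifelse(stats::runif(n) < config$p_high, "high", "low")
    fl <- ifelse(expr == "high",
                 stats::rlnorm(n, config$high_expr_params[1], config$high_expr_params[2]),
                 stats::rlnorm(n, config$low_expr_params[1], config$low_expr_params[2]))
    mean_fluor <- clip(config$fluor_background_level +
                         ifelse(is_cell, fl, stats::runif(n, 0, 5)) +
                         stats::rnorm(n, 0, config$fluor_noise_sd), 0, 255)

    tibble::tibble(
      image_id = "synthetic_features", condition = condition, replicate = "r1",
      area = area, mean_fluor = mean_fluor, perimeter = perim,
      major = major, minor = minor, angle = stats::runif(n, 0, 180),
      circularity = circ, feret = feret, min_feret = min_feret,
      feret_x = stats::runif(n, 0, config$image_shape[2]),
      feret_y = stats::runif(n, 0, config$image_shape[1]),
      feret_angle = stats::runif(n, 0, 180),
      aspect_ratio = ar, roundness = roundness, solidity = solidity,
      label = ifelse(is_cell, "cell", "non_cell"),
      expression_class = ifelse(is_cell, expr, NA_character_),
      predicted_prob = NA_real_)
  })
}

#' Simulate background-corrected single-cell populations
#'
#' Draws per-cell fluorescence directly from the configured mixture, applies
#' the 8-bit saturation that a real camera imposes (values clip at 255
#' before background subtraction), and adds per-cell measurement noise.
#' This is the population-level view of the same generative model that
#' [simulate_micrograph()] renders as images; it is used when thousands of
#' cells are needed and the image stage has been validated separately.
#'
#' @param config a [simulation_config()]; `p_high`, the expression
#'   parameters, the fluorescence background and noise SD are used.
#' @param n_cells total number of cells.
#' @param condition,timepoint labels for the output rows.
#' @param n_replicates cells are split evenly across this many replicates.
#' @return tibble with columns `condition`, `timepoint`, `replicate`,
#'   `value` (background-corrected intensity) and `expression_class`.
#' @export
simulate_cell_population <- function(config, n_cells, condition = "synthetic",
                                     timepoint = 0, n_replicates = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_cells <= 0) stopf("`n_cells` must be > 0")
  withr::with_seed(config$seed, {
    n <- as.integer(n_cells)
    expr <- ifelse(stats::runif(n) < config$p_high, "high", "low")
    true_fl <- ifelse(
      expr == "high",
      stats::rlnorm(n, config$high_expr_params[1], config$high_expr_params[2]),
      stats::rlnorm(n, config$low_expr_params[1], config$low_expr_params[2]))
    raw <- clip(config$fluor_background_level + true_fl +
                  stats::rnorm(n, 0, config$fluor_noise_sd), 0, 255)
    tibble::tibble(
      condition = condition, timepoint = timepoint,
      replicate = paste0("r", rep_len(seq_len(n_replicates), n)),
      value = raw - config$fluor_background_level,
      expression_class = expr)
  })
}
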
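#' Background mask from the percentile auto-threshold
#'
#' The percentile rule picks the intensity threshold at which the
#' foreground occupies (as nearly as possible) the target fraction of
#' pixels; the returned mask is the inversion of that foreground, so
#' `TRUE` marks background. By default foreground is the bright side
#' (appropriate when biomass is bright, as in a fluorescence channel); set
#' `dark_foreground = TRUE` when masking biomass from a phase-contrast
#' channel, where cells are dark.
#'
#' @param image numeric matrix on the 8-bit scale.
#' @param target foreground target fraction (default 0.5).
#' @param dark_foreground if `TRUE`, foreground = pixels below threshold.
#' @return logical matrix; `TRUE` = background.
#' @export
background_mask <- function(image, target = 0.5, dark_foreground = FALSE) {
  assert_number(target, "target", 1e-6, 1 - 1e-6)
  vals <- as.integer(round(clip(image, 0, 255)))
  n <- length(vals)
  cnt <- tabulate(vals + 1L, nbins = 256L)
  cum_le <- cumsum(cnt)                       # pixels with value <= t
  frac_fg <- if (dark_foreground) cum_le / n else (n - cum_le) / n
  # candidate thresholds t = 0..255; foreground is < t (dark) or > t (bright)
  t <- which.min(abs(frac_fg - target)) - 1L
  fg <- if (dark_foreground) image <= t else image > t
  if (all(fg)) fg[] <- FALSE     # degenerate (constant) image: no biomass
  !fg
}

#' Estimate background fluorescence from random squares
#'
#' Samples `n_squares` axis-aligned `square_size` x `square_size` squares,
#' without replacement, uniformly among all positions that lie entirely
#' inside the background mask; records each square's mean fluorescence and
#' summarises them by their median.
#'
#' @param fluor fluorescence channel matrix.
#' @param bg_mask logical background mask (e.g. from [background_mask()]).
#' @param n_squares number of squares (default 50).
#' @param square_size square side in pixels (default 2).
#' @param seed integer seed for square placement.
#' @param image_id identifier recorded on the estimate.
#' @return object of class `background_estimate`: `image_id`,
#'   `square_means`, `median_background`, `n_valid_squares`, and
#'   `pooled_pixel_median` (the median of all sampled square pixels,
#'   recorded alongside the median-of-means).
#' @export
estimate_background <- function(fluor, bg_mask, n_squares = 50L,
                                square_size = 2L, seed = 1L,
                                image_id = "img1") {
  if (!all(dim(fluor) == dim(bg_mask))) stopf("mask and image shapes differ")
  s <- as.integer(square_size)
  nr <- nrow(fluor) - s + 1L; nc <- ncol(fluor) - s + 1L
  if (nr < 1L || nc < 1L) stopf("image smaller than the background square")
  # positions whose s x s block is fully background: erode the mask by the
  # block via cumulative sums (integral image)
  m <- matrix(as.numeric(bg_mask), nrow(fluor), ncol(fluor))
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)   # transposed integral image
  ii <- t(ii)
  block_sum <- function(r, c) {                 # sum over r..r+s-1, c..c+s-1
    a <- ii[r + s - 1L, c + s - 1L]
    b <- if (r > 1L) ii[r - 1L, c + s - 1L] else 0
    d <- if (c > 1L) ii[r + s - 1L, c - 1L] else 0
    e <- if (r > 1L && c > 1L) ii[r - 1L, c - 1L] else 0
    a - b - d + e
  }
  g <- expand.grid(r = seq_len(nr), c = seq_len(nc))
  full <- mapply(block_sum, g$r, g$c) == s * s
  valid <- g[full, , drop = FALSE]
  if (nrow(valid) == 0L)
    stopf("no %dx%d square fits entirely inside the background mask", s, s)
  k <- min(n_squares, nrow(valid))
  if (k < n_squares)
    warnf("only %d of %d requested background squares could be placed", k,
          n_squares)
  withr::with_seed(seed, {
    pick <- valid[sample(nrow(valid), k), , drop = FALSE]
  })
  sq_means <- numeric(k)
  all_px <- numeric(0)
  for (i in seq_len(k)) {
    px <- fluor[pick$r[i]:(pick$r[i] + s - 1L), pick$c[i]:(pick$c[i] + s - 1L)]
    sq_means[i] <- mean(px)
    all_px <- c(all_px, as.numeric(px))
  }
  structure(list(image_id = image_id, square_means = sq_means,
                 median_background = stats::median(sq_means),
                 pooled_pixel_median = stats::median(all_px),
                 n_valid_squares = k),
            class = "background_estimate")
}

#' Correct cell fluorescence by per-image background subtraction
#'
#' Subtracts each image's median background intensity from every cell's
#' mean fluorescence in that image. Negative corrected values are retained
#' (clipping would bias the downstream skewness and kurtosis statistics).
#'
#' @param records particle table pre-filtered to `label == "cell"`, with a
#'   `timepoint` column (added by the caller if the condition label does
#'   not carry it).
#' @param estimates list of `background_estimate`s covering every
#'   `image_id` present in `records`.
#' @return tibble (cell population dialect): `condition`, `timepoint`,
#'   `replicate`, `image_id`, `value` = corrected fluorescence.
#' @export
correct_fluorescence <- function(records, estimates) {
  if (inherits(estimates, "background_estimate")) estimates <- list(estimates)
  med <- vapply(estimates, `[[`, numeric(1), "median_background")
  names(med) <- vapply(estimates, `[[`, character(1), "image_id")
  missing_ids <- setdiff(unique(records$image_id), names(med))
  if (length(missing_ids))
    stopf("no background estimate for image(s): %s",
          paste(missing_ids, collapse = ", "))
  if (!"timepoint" %in% names(records)) records$timepoint <- NA_real_
  tibble::tibble(
    condition = records$condition,
    timepoint = records$timepoint,
    replicate = records$replicate,
    image_id = records$image_id,
    value = records$mean_fluor - unname(med[records$image_id]))
}
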
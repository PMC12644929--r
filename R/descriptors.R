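# Shape descriptor measurement for a single particle's pixel set.
#
# Conventions (stated once, used everywhere):
#   - pixel coordinates are 0-based (row, col) in exported tables; internal
#     matrices are 1-based;
#   - angles are degrees in [0, 180), measured from the +x axis (columns)
#     in the (x = col, y = row) plane; rows increase downwards;
#   - lengths are in micrometres via `pixel_size`, areas in um^2.

# Perimeter of the particle boundary: marching-squares contour (base R
# contourLines at level 0.5 on the padded mask) with a circular three-point
# moving average of the vertices to remove staircase bias. Accurate to a
# few percent against disc/square/ellipse closed forms.
particle_perimeter_px <- function(px) {
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  nr <- max(px[, 1]) - r0 + 1L; nc <- max(px[, 2]) - c0 + 1L
  m <- matrix(0, nr + 2L, nc + 2L)
  m[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- 1
  cl <- grDevices::contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)),
                                z = m, levels = 0.5)
  closed_len <- function(x, y) sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
  best <- 0
  for (cc in cl) {
    x <- cc$x; y <- cc$y; n <- length(x)
    if (n >= 4L) {
      xs <- (x + x[c(n, 1:(n - 1))] + x[c(2:n, 1)]) / 3
      ys <- (y + y[c(n, 1:(n - 1))] + y[c(2:n, 1)]) / 3
    } else { xs <- x; ys <- y }
    best <- max(best, closed_len(xs, ys))
  }
  best
}

# Convex hull of the pixel corner points, as an (x = col, y = row) matrix
# in counter-clockwise order. Hull of the corners of the centre-hull pixels
# equals the hull of all pixel corners (Minkowski sum with the unit square).
pixel_corner_hull <- function(px) {
  ctr <- cbind(x = px[, 2], y = px[, 1])
  h <- grDevices::chull(ctr)
  hp <- ctr[h, , drop = FALSE]
  corners <- rbind(
    cbind(hp[, 1] - 0.5, hp[, 2] - 0.5), cbind(hp[, 1] + 0.5, hp[, 2] - 0.5),
    cbind(hp[, 1] - 0.5, hp[, 2] + 0.5), cbind(hp[, 1] + 0.5, hp[, 2] + 0.5))
  h2 <- grDevices::chull(corners)
  corners[h2, , drop = FALSE]
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Maximum caliper: brute force over hull vertex pairs (hulls are small).
feret_max <- function(hull) {
  n <- nrow(hull)
  best <- c(0, 1, 1)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((hull[i, ] - hull[j, ])^2))
    if (d > best[1]) best <- c(d, i, j)
  }
  best
}

# Minimum caliper width: for each hull edge, the maximal vertex distance
# from the edge's supporting line; the minimum over edges is MinFeret.
feret_min <- function(hull) {
  n <- nrow(hull)
  if (n < 2) return(0)
  if (n == 2) return(0)
  wmin <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    nrm <- c(-e[2], e[1]) / len
    w <- max(abs((hull[, 1] - hull[i, 1]) * nrm[1] +
                 (hull[, 2] - hull[i, 2]) * nrm[2]))
    wmin <- min(wmin, w)
  }
  wmin
}

#' Measure the shape descriptor set of one particle
#'
#' Computes, from a particle's pixel set: area; perimeter (marching-squares
#' boundary length); best-fit-ellipse `major`, `minor` and orientation
#' `angle` (from second-order moments with the 1/12 single-pixel
#' correction); `circularity` = 4*pi*A/P^2 capped at 1; Feret calipers
#' (`feret` = maximum caliper with its 0-based start coordinates `feret_x`,
#' `feret_y` and `feret_angle`; `min_feret` = minimum caliper width) from
#' the convex hull of the pixel corners; `aspect_ratio` = major/minor;
#' `roundness` = 4*A/(pi*major^2) capped at 1; `solidity` = area /
#' convex-hull area. A single-pixel particle takes the degenerate values
#' major = minor = `pixel_size` and solidity = 1.
#'
#' @param px two-column matrix of 1-based (row, col) pixel indices.
#' @param pixel_size micrometres per pixel.
#' @return one-row tibble of descriptors in physical units.
#' @export
shape_descriptors <- function(px, pixel_size) {
  if (is.null(dim(px))) px <- matrix(px, ncol = 2)
  if (nrow(px) == 0L) stopf("empty pixel set")
  assert_number(pixel_size, "pixel_size", lo = 1e-12)
  ps <- pixel_size
  n <- nrow(px)
  area <- n * ps^2

  if (n == 1L) {
    return(tibble::tibble(
      area = area, perimeter = 4 * ps, major = ps, minor = ps, angle = 0,
      circularity = min(1, 4 * pi * area / (4 * ps)^2),
      feret = sqrt(2) * ps, min_feret = ps,
      feret_x = px[1, 2] - 1.5, feret_y = px[1, 1] - 1.5, feret_angle = 45,
      aspect_ratio = 1, roundness = min(1, 4 * area / (pi * ps^2)),
      solidity = 1))
  }

  perim <- particle_perimeter_px(px) * ps

  # best-fit ellipse from second moments (x = col, y = row)
  x <- px[, 2]; y <- px[, 1]
  cxx <- central_moment(x, 2) + 1 / 12
  cyy <- central_moment(y, 2) + 1 / 12
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)
  major <- 4 * sqrt(ev$values[1]) * ps
  minor <- 4 * sqrt(max(ev$values[2], 0)) * ps
  if (minor <= 0) minor <- ps
  angle <- (atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi) %% 180

  hull <- pixel_corner_hull(px)
  fm <- feret_max(hull)
  p1 <- hull[fm[2], ]; p2 <- hull[fm[3], ]
  # start point: the endpoint with the smaller x (then smaller y)
  if (p2[1] < p1[1] || (p2[1] == p1[1] && p2[2] < p1[2])) { tmp <- p1; p1 <- p2; p2 <- tmp }
  fangle <- (atan2(p2[2] - p1[2], p2[1] - p1[1]) * 180 / pi) %% 180
  hull_area <- polygon_area(hull)

  tibble::tibble(
    area = area,
    perimeter = perim,
    major = major, minor = minor, angle = angle,
    circularity = min(1, 4 * pi * area / perim^2),
    feret = fm[1] * ps, min_feret = feret_min(hull) * ps,
    feret_x = p1[1] - 1, feret_y = p1[2] - 1, feret_angle = fangle,
    aspect_ratio = major / minor,
    roundness = min(1, 4 * area / (pi * major^2)),
    solidity = n / hull_area)
}
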
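# File dialects: 8-bit grayscale TIFF per channel, one-header-row CSV for
# particle, population and background tables. All readers return the same
# tibbles the in-memory pipeline produces, so read(write(x)) == x.

#' Write a micrograph as per-channel 8-bit grayscale TIFFs
#'
#' @param mg a [micrograph()].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths (`<image_id>_phase.tif`,
#'   `<image_id>_fluor.tif`).
#' @export
write_micrograph <- function(mg, dir) {
  stopifnot(inherits(mg, "micrograph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(mg$image_id, c("_phase.tif", "_fluor.tif")))
  tiff::writeTIFF(mg$phase / 255, paths[1], bits.per.sample = 8L)
  tiff::writeTIFF(mg$fluor / 255, paths[2], bits.per.sample = 8L)
  invisible(paths)
}

#' Read a two-channel micrograph from TIFF files
#'
#' 8-bit images are used as stored; deeper bit depths are converted with
#' [to_grayscale_8bit()] (linear min-max rescale).
#'
#' @param phase_path,fluor_path TIFF paths (single-channel grayscale).
#' @param pixel_size micrometres per pixel (required: the particle area
#'   filter is physical).
#' @param image_id,condition,replicate provenance labels.
#' @return a [micrograph()].
#' @export
read_micrograph <- function(phase_path, fluor_path, pixel_size,
                            image_id = basename(phase_path),
                            condition = "unknown", replicate = "r1") {
  read_chan <- function(p) {
    v <- tiff::readTIFF(p, as.is = TRUE)
    if (length(dim(v)) == 3L) v <- v[, , 1]
    if (max(v) > 255) to_grayscale_8bit(v) else matrix(as.integer(v), nrow(v), ncol(v))
  }
  micrograph(read_chan(phase_path), read_chan(fluor_path), pixel_size,
             image_id = image_id, condition = condition, replicate = replicate)
}

#' Write / read a particle table as CSV
#'
#' Stable column names match the descriptor list of [detect_particles()].
#' @param particles particle tibble.
#' @param path CSV path.
#' @return `read_particles()` returns the tibble.
#' @export
write_particles <- function(particles, path) {
  utils::write.csv(particles, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_particles
#' @export
read_particles <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a cell-population table as CSV
#'
#' Columns: `condition`, `timepoint`, `replicate`, `image_id`,
#' `corrected_fluorescence` (stored name of the in-memory `value` column).
#' @param pop population tibble with a `value` column.
#' @param path CSV path.
#' @export
write_population <- function(pop, path) {
  out <- pop
  names(out)[names(out) == "value"] <- "corrected_fluorescence"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  names(out)[names(out) == "corrected_fluorescence"] <- "value"
  out
}

#' Write background estimates as CSV
#'
#' @param estimates list of `background_estimate`s.
#' @param path CSV path.
#' @export
write_background_estimates <- function(estimates, path) {
  if (inherits(estimates, "background_estimate")) estimates <- list(estimates)
  df <- dplyr::bind_rows(lapply(estimates, function(e) {
    tibble::tibble(image_id = e$image_id, n_valid_squares = e$n_valid_squares,
                   median_background = e$median_background,
                   pooled_pixel_median = e$pooled_pixel_median)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an externally produced single-cell measurement table
#'
#' Ingests per-cell measurement exports (one row per cell) such as those
#' produced by particle-analysis software, mapping the named columns onto
#' the population dialect used by the statistics functions.
#'
#' @param path CSV path.
#' @param value_col column holding the (corrected) fluorescence value.
#' @param condition_col,timepoint_col,replicate_col metadata columns.
#' @return population tibble (`condition`, `timepoint`, `replicate`,
#'   `value`).
#' @export
read_single_cell_table <- function(path, value_col = "corrected_fluorescence",
                                   condition_col = "condition",
                                   timepoint_col = "timepoint",
                                   replicate_col = "replicate") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(value_col, condition_col, timepoint_col, replicate_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("single-cell table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tibble::tibble(condition = as.character(df[[condition_col]]),
                 timepoint = df[[timepoint_col]],
                 replicate = as.character(df[[replicate_col]]),
                 value = as.numeric(df[[value_col]]))
}
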
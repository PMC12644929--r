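# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Clip numeric values into an interval
#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Population (1/n) standard deviation; pixel sets are complete populations.
pop_sd <- function(x) {
  n <- length(x)
  sqrt(sum((x - mean(x))^2) / n)
}

# k-th central sample moment with 1/n normalisation.
central_moment <- function(x, k) mean((x - mean(x))^k)

assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lo), format(hi))
  }
  invisible(x)
}

# Deterministic fan-out of a single pipeline seed to stage seeds.
# Offsets are fixed so that a run is reproducible from the one global seed.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, fixtures = 211L, split = 307L, cv = 401L,
               rf = 503L, background = 601L, pipeline = 701L)
  if (!stage %in% names(offsets)) stopf("unknown stage '%s'", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}
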
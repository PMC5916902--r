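# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is_scalar_number(x)) {
    stop("`", name, "` must be a single finite number", call. = FALSE)
  }
  if (positive && x <= 0) {
    stop("`", name, "` must be positive", call. = FALSE)
  }
  if (nonneg && x < 0) {
    stop("`", name, "` must be non-negative", call. = FALSE)
  }
  invisible(x)
}

# Deterministic rounding: half-up, so the zero-dispersion count limit is exact.
round_half_up <- function(x) floor(x + 0.5)

# Multiplicative lognormal noise with unit mean and a given coefficient of
# variation; cv = 0 returns 1s so the zero-noise limit is exact.
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Derive a per-stage child seed from the global seed
#'
#' Every stochastic stage of the package draws its randomness from a child
#' seed computed as `(seed + 1000003 * offset) mod (2^31 - 1)`, where the
#' offset is a fixed integer per stage. This keeps each simulation stage
#' individually reproducible under a single global seed, and keeps derived
#' seeds within the 32-bit integer range.
#'
#' @param seed Integer global seed.
#' @param stage One of `"binding"`, `"polysome"`, `"chase"`, `"qpcr"`,
#'   `"microarray"`, `"enrichment"`, `"pipeline"`.
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  offsets <- c(
    binding = 1, polysome = 2, chase = 3, qpcr = 4,
    microarray = 5, enrichment = 6, pipeline = 7
  )
  assert_scalar_number(seed, "seed")
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  as.integer((as.double(seed) + 1000003 * offsets[[stage]]) %% 2147483647)
}
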
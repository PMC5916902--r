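#' Fit a densitometry calibration from a serial dilution
#'
#' Least-squares line through the origin, `signal = slope * amount`: zero
#' loaded protein gives zero signal on the membrane. A free-intercept
#' variant is available for films with a background offset. The reported
#' r-squared uses the uncentered total sum of squares, the no-intercept
#' convention.
#'
#' @param amounts Positive relative amounts of the dilution series (>= 2
#'   distinct values).
#' @param signals Non-negative measured signals, same length.
#' @param intercept Fit a free intercept instead of forcing the origin.
#' @return An object of class `dilution_calibration` with `slope`,
#'   `intercept`, `r_squared` and `calibration_range`.
#' @export
fit_dilution_calibration <- function(amounts, signals, intercept = FALSE) {
  stopifnot(is.numeric(amounts), is.numeric(signals),
            length(amounts) == length(signals))
  if (length(unique(amounts)) < 2L) {
    stop("at least 2 distinct dilution amounts are required", call. = FALSE)
  }
  if (any(amounts <= 0)) stop("amounts must be positive", call. = FALSE)
  if (any(signals < 0)) stop("signals must be non-negative", call. = FALSE)
  if (all(signals == 0)) stop("all signals are zero", call. = FALSE)
  if (intercept) {
    fit <- stats::lm(signals ~ amounts)
    slope <- unname(stats::coef(fit)[2L])
    b0 <- unname(stats::coef(fit)[1L])
  } else {
    slope <- sum(signals * amounts) / sum(amounts^2)
    b0 <- 0
  }
  if (slope <= 0) {
    stop("calibration slope must be positive", call. = FALSE)
  }
  fitted <- b0 + slope * amounts
  r2 <- 1 - sum((signals - fitted)^2) / sum(signals^2)
  structure(
    list(slope = slope, intercept = b0, r_squared = r2,
         calibration_range = range(amounts)),
    class = "dilution_calibration"
  )
}

#' @export
print.dilution_calibration <- function(x, ...) {
  cat(sprintf(
    "<dilution_calibration> slope %.4g (intercept %.4g), r2 %.4f, range [%g, %g]\n",
    x$slope, x$intercept, x$r_squared,
    x$calibration_range[1], x$calibration_range[2]))
  invisible(x)
}

#' Convert a densitometry signal to a relative amount
#'
#' `amount = (signal - intercept) / slope / loading_factor`. Amounts falling
#' outside the calibrated dilution range are still returned but flagged in
#' the `out_of_range` attribute.
#'
#' @param signal Measured signal(s).
#' @param calibration A [fit_dilution_calibration()] result.
#' @param loading_factor Positive per-lane loading-control factor(s).
#' @return Relative amount(s), with attribute `out_of_range` (logical).
#' @export
signal_to_amount <- function(signal, calibration, loading_factor = 1) {
  stopifnot(inherits(calibration, "dilution_calibration"))
  if (any(loading_factor <= 0)) {
    stop("`loading_factor` must be positive", call. = FALSE)
  }
  amount <- ((signal - calibration$intercept) / calibration$slope) /
    loading_factor
  flag <- amount < calibration$calibration_range[1] |
    amount > calibration$calibration_range[2]
  structure(amount, out_of_range = flag)
}

#' A cycloheximide-chase time course
#'
#' @param protein,condition Labels.
#' @param times Minutes, strictly increasing from 0.
#' @param amounts Positive relative amounts (1 at t = 0 up to measurement
#'   noise).
#' @param loading_control Optional per-lane loading factors (already applied
#'   or for the record).
#' @return An object of class `chase_series`.
#' @export
chase_series <- function(protein, condition, times, amounts,
                         loading_control = NULL) {
  stopifnot(is.numeric(times), is.numeric(amounts),
            length(times) == length(amounts))
  if (times[1L] != 0 || is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing from 0", call. = FALSE)
  }
  if (any(amounts <= 0)) stop("`amounts` must be positive", call. = FALSE)
  structure(
    list(protein = protein, condition = condition, times = times,
         amounts = amounts, loading_control = loading_control),
    class = "chase_series"
  )
}

#' @export
print.chase_series <- function(x, ...) {
  cat(sprintf("<chase_series> %s [%s], %d time points over %g min\n",
              x$protein, x$condition, length(x$times), max(x$times)))
  invisible(x)
}

#' Fit single-exponential decay to a chase series
#'
#' Ordinary least squares of `log2(amount)` on time with a free intercept
#' (so t = 0 measurement noise does not distort the rate). The decay
#' constant is `k = -slope * ln(2)` per minute, clipped at 0 with a warning
#' when the fitted slope is positive (apparent growth); the half-life is
#' `ln(2) / k`, `Inf` when `k = 0`.
#'
#' @param series A [chase_series()] or a data frame / list with `times` and
#'   `amounts`.
#' @return An object of class `decay_fit` with `k`, `half_life`, `intercept`
#'   (fitted log2 amount at t = 0), `residual_sd` and `n`.
#' @export
fit_exponential_decay <- function(series) {
  if (!inherits(series, "chase_series")) {
    series <- chase_series(protein = "", condition = "",
                           times = series$times, amounts = series$amounts)
  }
  t <- series$times
  a <- series$amounts
  if (length(t) < 3L) stop("at least 3 time points are required", call. = FALSE)
  fit <- stats::lm(log2(a) ~ t)
  slope <- unname(stats::coef(fit)[2L])
  if (slope > 0) {
    warning("fitted amounts increase with time; decay constant clipped at 0",
            call. = FALSE)
    slope <- 0
  }
  k <- -slope * log(2)
  structure(
    list(
      protein = series$protein, condition = series$condition,
      k = k, half_life = if (k == 0) Inf else log(2) / k,
      intercept = unname(stats::coef(fit)[1L]),
      residual_sd = stats::sigma(fit), n = length(t)
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit> %s [%s]: k = %.4g /min, half-life = %s min (n = %d)\n",
    x$protein, x$condition, x$k,
    if (is.finite(x$half_life)) sprintf("%.2f", x$half_life) else "Inf",
    x$n))
  invisible(x)
}

#' Build chase series from raw densitometry signals
#'
#' Converts signals to amounts through a dilution calibration and per-lane
#' loading factors, then normalizes to the t = 0 amount.
#'
#' @param chase Data frame with columns `protein`, `condition`, `time_min`,
#'   `signal` and optionally `loading_signal`.
#' @param calibration A [fit_dilution_calibration()] result.
#' @return A list of [chase_series()], one per (protein, condition).
#' @export
chase_from_signals <- function(chase, calibration) {
  needed <- c("protein", "condition", "time_min", "signal")
  if (!all(needed %in% names(chase))) {
    stop("`chase` must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  loading <- chase$loading_signal %||% rep(1, nrow(chase))
  loading <- loading / mean(loading)
  amounts <- as.numeric(signal_to_amount(chase$signal, calibration, loading))
  out <- lapply(split(seq_len(nrow(chase)),
                      interaction(chase$protein, chase$condition, drop = TRUE)),
    function(idx) {
      g <- chase[idx, , drop = FALSE]
      ord <- order(g$time_min)
      a <- amounts[idx][ord]
      a0 <- a[g$time_min[ord] == 0]
      if (length(a0) != 1L) {
        stop("each series needs exactly one t = 0 measurement", call. = FALSE)
      }
      chase_series(g$protein[1L], g$condition[1L],
                   times = g$time_min[ord], amounts = a / a0)
    })
  unname(out)
}
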
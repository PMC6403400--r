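#' Detect per-pixel focus times from polarity inversions
#'
#' The reference (non-spiking) focus detector. During a sweep a pixel first
#' emits a run of one polarity while its contrast builds toward focus, then
#' the opposite polarity as the image defocuses again; the moment of best
#' focus is the polarity inversion. For each pixel this function finds every
#' adjacent pair of opposite-polarity events, takes the pair with the
#' smallest time gap as the inversion, and estimates the focus time as the
#' arithmetic midpoint of that pair (the average timing of the consecutive
#' ON and OFF events). If several pairs tie for the smallest gap, the mean
#' of the tied midpoints is used. A pixel with more than one polarity change
#' is flagged ambiguous — the overlapping-edges failure mode — but still
#' reported; a pixel with no polarity change is invalid.
#'
#' @param events An [event_stream()] (or any tibble with `t_us`, `x`, `y`,
#'   `p`), assumed to cover a single sweep.
#' @return A tibble with one row per pixel that emitted at least one event:
#'   `x`, `y`, `t_f_us` (focus time, `NA` when invalid), `valid`,
#'   `ambiguous`, `gap_us` (inversion gap), `n_events`,
#'   `leading_polarity` (majority polarity of the first half of the train).
#' @export
detect_focus_times <- function(events) {
  stopifnot(all(c("t_us", "x", "y", "p") %in% names(events)))
  if (nrow(events) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), t_f_us = numeric(),
                          valid = logical(), ambiguous = logical(),
                          gap_us = numeric(), n_events = integer(),
                          leading_polarity = integer()))
  }
  events |>
    tibble::as_tibble() |>
    dplyr::arrange(.data$t_us) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(res = list(detect_tf_train(.data$t_us, .data$p)),
                     .groups = "drop") |>
    tidyr::unnest_wider("res")
}

# Inversion detection on a single pixel's (t, p) train, already time-sorted.
detect_tf_train <- function(t_us, p) {
  nev <- length(t_us)
  lead_n <- max(1L, ceiling(nev / 2))
  leading <- if (sum(p[seq_len(lead_n)]) >= 0) 1L else -1L
  flips <- which(diff(p) != 0L)
  if (length(flips) == 0L) {
    return(list(t_f_us = NA_real_, valid = FALSE, ambiguous = FALSE,
                gap_us = NA_real_, n_events = nev,
                leading_polarity = leading))
  }
  gaps <- t_us[flips + 1L] - t_us[flips]
  best <- which(gaps == min(gaps))
  mids <- (t_us[flips[best]] + t_us[flips[best] + 1L]) / 2
  list(t_f_us = mean(mids), valid = TRUE,
       ambiguous = length(flips) > 1L,
       gap_us = as.numeric(min(gaps)), n_events = nev,
       leading_polarity = leading)
}

#' Closed-form threshold-crossing time for a Gaussian blur spot
#'
#' For a pixel at distance `r` from the center of a constant-amplitude
#' Gaussian spot `I = A * exp(-r^2 / (2 sigma(t)^2))`, the k-th contrast
#' threshold crossing after a reference intensity `I0` happens when the
#' spread reaches `sigma_k = sqrt(r^2 / (2 * (log A - log I0 - p * k * n)))`,
#' so the event time is `sigma_inverse(sigma_k)`. The sign of the threshold
#' step follows the event polarity (the sign of dI/dt): ON events (`p = +1`)
#' shrink the target spread, OFF events grow it. Serves as the independent
#' oracle for the event generator's timestamps.
#'
#' @param k Crossing index (1 = first event after the reference), >= 1.
#' @param pixel_r Distance from the pixel to the spot center (m, on sensor).
#' @param A Spot amplitude.
#' @param I0 Intensity at the reference (last event, or sweep start).
#' @param n Contrast threshold (> 0).
#' @param sigma_inverse Function mapping a spread `sigma` (m) to a time (s);
#'   must be the inverse of a strictly monotone branch of `sigma(t)`.
#' @param polarity +1 for ON crossings, -1 for OFF.
#' @return Event time(s) in seconds.
#' @export
predict_event_time <- function(k, pixel_r, A, I0, n, sigma_inverse,
                               polarity = 1L) {
  if (any(k < 1)) abort("`k` must be >= 1.")
  if (n <= 0) abort("`n` must be > 0.")
  if (!polarity %in% c(-1L, 1L)) abort("`polarity` must be +1 or -1.")
  arg <- log(A) - log(I0) - polarity * k * n
  if (any(arg <= 0)) {
    abort("crossing level above the spot amplitude: sqrt argument <= 0.")
  }
  sigma_k <- sqrt(pixel_r^2 / (2 * arg))
  vapply(sigma_k, sigma_inverse, numeric(1))
}

#' Numeric inverse of the PSF spread trajectory on one side of focus
#'
#' Builds `sigma^{-1}` for an object at depth `z` under a sweep: the spread
#' `sigma(t) = alpha * s(z, d(t))` decreases to zero at the focus time and
#' grows again, so it is invertible on each side separately.
#'
#' @param z Object depth (m).
#' @param profile A [sweep_profile()].
#' @param cfg An [optical_config()].
#' @param side `"before"` (approaching focus) or `"after"`.
#' @return A function mapping `sigma` (m) to time (s). Errors if the sweep
#'   never focuses `z` (non-invertible segment).
#' @export
sigma_inverse_fn <- function(z, profile = sweep_profile(),
                             cfg = optical_config(),
                             side = c("before", "after")) {
  side <- match.arg(side)
  lo <- min(profile$d_start, profile$d_end)
  hi <- max(profile$d_start, profile$d_end)
  if (z < lo || z > hi) {
    abort("`z` is not focused within the sweep: sigma(t) has no invertible zero.")
  }
  t_f <- sweep_time_of(z, profile)
  bounds <- if (side == "before") c(profile$t_start, t_f) else
    c(t_f, profile$t_end)
  sig_at <- function(t) psf_sigma(blur_diameter(z, sweep_focus_at(t, profile),
                                                cfg), cfg)
  function(sigma) {
    if (sigma <= 0) return(t_f)
    if (abs(bounds[2] - bounds[1]) < 1e-12) {
      abort("degenerate branch: focus at the window edge.")
    }
    smax <- sig_at(if (side == "before") bounds[1] else bounds[2])
    if (sigma > smax) abort("`sigma` outside the branch range.")
    stats::uniroot(function(t) sig_at(t) - sigma,
                   interval = bounds, tol = 1e-13)$root
  }
}
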
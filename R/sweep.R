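#' Focal-sweep profile
#'
#' Describes one sweep of the liquid lens: the time window, the trajectory of
#' the in-focus distance `d(t)`, and the repetition period. The default sweep
#' covers the working depth range 0.12 m to 5.5 m in 5 ms.
#'
#' Two trajectory shapes are supported. `"power"` (default) is linear in
#' optical power `1/d` (diopters), which matches how a current-driven liquid
#' lens actually moves its focus: the lens power is proportional to the coil
#' current, so a current ramp sweeps diopters at a constant rate. `"linear"`
#' interpolates `d` itself linearly and is provided for experimentation.
#' Either way `d(t)` is strictly monotone on the window, which is what makes
#' a detected focus time invertible to a unique depth.
#'
#' @param t_start,t_end Sweep window (s), `t_end > t_start`.
#' @param d_start,d_end In-focus distance at the window ends (m); both must
#'   be positive and distinct.
#' @param shape `"power"` (linear in 1/d) or `"linear"` (linear in d).
#' @param period Sweep repetition period (s), >= window length.
#' @return An object of class `sweep_profile`.
#' @examples
#' sp <- sweep_profile()
#' sweep_focus_at(0.0025, sp)
#' @export
sweep_profile <- function(t_start = 0, t_end = 5e-3,
                          d_start = 0.12, d_end = 5.5,
                          shape = c("power", "linear"),
                          period = 10e-3) {
  shape <- match.arg(shape)
  if (!(t_end > t_start)) abort("sweep window must have positive length.")
  if (d_start <= 0 || d_end <= 0 || d_start == d_end) {
    abort("`d_start` and `d_end` must be positive and distinct.")
  }
  if (period < t_end - t_start) abort("`period` must cover the sweep window.")
  structure(
    list(
      t_start = as.numeric(t_start),
      t_end = as.numeric(t_end),
      d_start = as.numeric(d_start),
      d_end = as.numeric(d_end),
      shape = shape,
      period = as.numeric(period)
    ),
    class = "sweep_profile"
  )
}

#' @export
print.sweep_profile <- function(x, ...) {
  cat(sprintf(
    "<sweep_profile> %s in [%g, %g] ms, d: %g -> %g m, period %g ms\n",
    x$shape, x$t_start * 1e3, x$t_end * 1e3, x$d_start, x$d_end,
    x$period * 1e3))
  invisible(x)
}

#' In-focus distance at a time within the sweep
#'
#' Evaluates the sweep trajectory `d(t)`. Strictly monotone in `t` over the
#' window; times outside the window are a range error.
#'
#' @param t Time(s) in seconds, within `[t_start, t_end]`.
#' @param profile A [sweep_profile()].
#' @return In-focus distance(s) in meters.
#' @export
sweep_focus_at <- function(t, profile = sweep_profile()) {
  stopifnot(inherits(profile, "sweep_profile"))
  eps <- 1e-12
  if (any(t < profile$t_start - eps | t > profile$t_end + eps)) {
    abort("`t` outside the sweep window.")
  }
  u <- (t - profile$t_start) / (profile$t_end - profile$t_start)
  u <- pmin(pmax(u, 0), 1)
  if (profile$shape == "power") {
    p0 <- 1 / profile$d_start
    p1 <- 1 / profile$d_end
    1 / (p0 + u * (p1 - p0))
  } else {
    profile$d_start + u * (profile$d_end - profile$d_start)
  }
}

#' Time at which the sweep focuses a given distance
#'
#' Closed-form inverse of [sweep_focus_at()].
#'
#' @param d In-focus distance(s) in meters, within the swept range.
#' @param profile A [sweep_profile()].
#' @return Time(s) in seconds.
#' @export
sweep_time_of <- function(d, profile = sweep_profile()) {
  stopifnot(inherits(profile, "sweep_profile"))
  lo <- min(profile$d_start, profile$d_end)
  hi <- max(profile$d_start, profile$d_end)
  if (any(d < lo - 1e-12 | d > hi + 1e-12)) {
    abort("`d` outside the swept focus range.")
  }
  u <- if (profile$shape == "power") {
    p0 <- 1 / profile$d_start
    p1 <- 1 / profile$d_end
    (1 / d - p0) / (p1 - p0)
  } else {
    (d - profile$d_start) / (profile$d_end - profile$d_start)
  }
  profile$t_start + pmin(pmax(u, 0), 1) * (profile$t_end - profile$t_start)
}

# Optical-power sweep rate in diopters per second (signed).
sweep_power_rate <- function(profile) {
  (1 / profile$d_end - 1 / profile$d_start) / (profile$t_end - profile$t_start)
}
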
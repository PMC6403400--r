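#' Optical configuration of the focal-sweep camera
#'
#' Bundles the parameters of the compound optical system and of the event
#' camera that the whole pipeline shares: the equivalent focal length of the
#' lens stack, its numerical aperture (f-number), the proportionality between
#' the geometric blur-circle diameter and the Gaussian point-spread-function
#' width (`sigma = alpha * s`), the sensor pixel pitch and resolution, and the
#' log-intensity contrast threshold `n` of the event pixels.
#'
#' The default focal length is the thin-lenses-in-contact approximation of the
#' three-lens stack (liquid lens at mid-range, offset lens, objective), see
#' [equivalent_focal()]. The default contrast threshold `n = 0.15` is a
#' conventional setting for silicon-retina contrast detectors; the sensor it
#' emulates does not publish a factory value, so this default is a package
#' choice rather than a measured constant.
#'
#' @param f_eq Equivalent focal length of the compound system (m).
#' @param N Numerical aperture (f-number, dimensionless).
#' @param alpha PSF proportionality constant, `sigma = alpha * s`
#'   (dimensionless).
#' @param pixel_pitch Sensor pixel size (m).
#' @param sensor_shape Integer vector `c(rows, cols)`.
#' @param event_threshold_n Log-intensity contrast threshold (> 0).
#' @return An object of class `optical_config` (a named list).
#' @examples
#' cfg <- optical_config()
#' cfg$f_eq
#' @export
optical_config <- function(f_eq = equivalent_focal(lens_stack(), f_ll = 0.085),
                           N = 2,
                           alpha = 0.5,
                           pixel_pitch = 15e-6,
                           sensor_shape = c(480L, 640L),
                           event_threshold_n = 0.15) {
  stopifnot(length(f_eq) == 1, length(N) == 1, length(alpha) == 1,
            length(pixel_pitch) == 1, length(sensor_shape) == 2)
  if (!is.finite(f_eq) || f_eq <= 0) abort("`f_eq` must be > 0.")
  if (!is.finite(N) || N <= 0) abort("`N` must be > 0.")
  if (!is.finite(alpha) || alpha <= 0) abort("`alpha` must be > 0.")
  if (!is.finite(pixel_pitch) || pixel_pitch <= 0) {
    abort("`pixel_pitch` must be > 0.")
  }
  if (any(sensor_shape < 1)) abort("`sensor_shape` must be positive.")
  if (!is.finite(event_threshold_n) || event_threshold_n <= 0) {
    abort("`event_threshold_n` must be > 0.")
  }
  structure(
    list(
      f_eq = as.numeric(f_eq),
      N = as.numeric(N),
      alpha = as.numeric(alpha),
      pixel_pitch = as.numeric(pixel_pitch),
      sensor_shape = as.integer(sensor_shape),
      event_threshold_n = as.numeric(event_threshold_n)
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  f_eq: %.4g m   N: %.3g   alpha: %.3g\n", x$f_eq, x$N, x$alpha))
  cat(sprintf("  pixel_pitch: %.3g m   sensor: %d x %d   threshold n: %.3g\n",
              x$pixel_pitch, x$sensor_shape[1], x$sensor_shape[2],
              x$event_threshold_n))
  invisible(x)
}

#' Three-lens stack of the focal-sweep optical system
#'
#' Describes the electrically tunable liquid lens (focal range `f_ll_range`),
#' the negative offset (relay) lens and the fixed objective that together
#' form the compound system in front of the event camera. Defaults follow the
#' hardware the method was designed around: a liquid lens tunable from 50 to
#' 120 mm, a -150 mm offset lens and a 35 mm f/2 objective.
#'
#' @param f_ll_range Numeric length-2, min and max liquid-lens focal length (m).
#' @param f_offset Offset-lens focal length (m, may be negative).
#' @param f_objective Objective focal length (m).
#' @param D_cam_obj Optional camera-to-object distance (m) used by
#'   [focus_distance()].
#' @return An object of class `lens_stack`.
#' @export
lens_stack <- function(f_ll_range = c(0.050, 0.120),
                       f_offset = -0.150,
                       f_objective = 0.035,
                       D_cam_obj = NA_real_) {
  stopifnot(length(f_ll_range) == 2)
  if (!(f_ll_range[1] < f_ll_range[2])) {
    abort("`f_ll_range` must be increasing (min < max).")
  }
  structure(
    list(
      f_ll_range = as.numeric(f_ll_range),
      f_offset = as.numeric(f_offset),
      f_objective = as.numeric(f_objective),
      D_cam_obj = as.numeric(D_cam_obj)
    ),
    class = "lens_stack"
  )
}

#' Approximate equivalent focal length of the lens stack
#'
#' Thin-lenses-in-contact approximation
#' `1/f_eq = 1/f_ll + 1/f_offset + 1/f_objective`. The true equivalent focal
#' length depends on the (unpublished) inter-lens separations, so this helper
#' is explicitly approximate; pass a measured `f_eq` to [optical_config()]
#' when one is available.
#'
#' @param stack A [lens_stack()].
#' @param f_ll Liquid-lens focal length (m); may be a vector. Must lie within
#'   `stack$f_ll_range`.
#' @return Equivalent focal length(s) in meters.
#' @export
equivalent_focal <- function(stack = lens_stack(), f_ll) {
  stopifnot(inherits(stack, "lens_stack"))
  if (any(f_ll < stack$f_ll_range[1] - 1e-12) ||
      any(f_ll > stack$f_ll_range[2] + 1e-12)) {
    abort("`f_ll` outside the liquid-lens focal range.")
  }
  1 / (1 / f_ll + 1 / stack$f_offset + 1 / stack$f_objective)
}

#' Geometric blur-circle diameter during a focal sweep
#'
#' Diameter of the ideal defocus blur circle for an object at depth `z` when
#' the system is focused at distance `d`:
#' `s = (f_eq^2 / N) * |z - d| / ((d - f_eq) * z)`.
#' The formula is symmetric in usage: during a sweep the object depth `z` is
#' fixed and the in-focus distance `d = d(t)` varies, but `s(z, d)` is the
#' same function either way.
#'
#' @param z Object depth (m), > 0. Vectorized; `Inf` is allowed and gives the
#'   limiting blur `f_eq^2 / (N * (d - f_eq))`.
#' @param d In-focus distance (m), must exceed `cfg$f_eq`.
#' @param cfg An [optical_config()].
#' @return Blur-spot diameter(s) in meters (>= 0).
#' @export
blur_diameter <- function(z, d, cfg = optical_config()) {
  stopifnot(inherits(cfg, "optical_config"))
  if (any(!is.na(z) & z <= 0)) abort("`z` must be > 0.")
  if (any(!is.na(d) & d <= cfg$f_eq)) abort("`d` must exceed `f_eq`.")
  K <- cfg$f_eq^2 / cfg$N
  nn <- max(length(z), length(d))
  zr <- rep_len(z, nn)
  dr <- rep_len(d, nn)
  s <- K * abs(zr - dr) / ((dr - cfg$f_eq) * zr)
  inf <- is.infinite(zr)
  s[inf] <- K / (dr[inf] - cfg$f_eq)  # |z - d|/z -> 1 as z -> Inf
  s
}

#' Gaussian PSF spread from the blur-circle diameter
#'
#' `sigma = alpha * s`. Lens aberrations and diffraction smear the ideal blur
#' disc into an approximately Gaussian spot whose spread is proportional to
#' the disc diameter.
#'
#' @param s Blur-circle diameter (m), >= 0.
#' @param cfg An [optical_config()] supplying `alpha`.
#' @return PSF spread `sigma` in meters.
#' @export
psf_sigma <- function(s, cfg = optical_config()) {
  stopifnot(inherits(cfg, "optical_config"))
  if (any(!is.na(s) & s < 0)) abort("`s` must be >= 0.")
  cfg$alpha * s
}

#' Thin-lens in-focus distance from the camera-to-object distance
#'
#' `d = f_eq + f_eq^2 / (D_cam_obj - f_eq)`: the conjugate distance at which
#' the compound system of focal length `f_eq` images an object placed
#' `D_cam_obj` from the camera. Strictly decreasing in `D_cam_obj`, with the
#' limit `d -> f_eq` as `D_cam_obj -> Inf`.
#'
#' @param f_eq Equivalent focal length (m).
#' @param D_cam_obj Camera-to-object distance (m), must exceed `f_eq`.
#' @return In-focus distance `d` (m).
#' @export
focus_distance <- function(f_eq, D_cam_obj) {
  if (any(f_eq <= 0)) abort("`f_eq` must be > 0.")
  if (any(D_cam_obj <= f_eq)) abort("`D_cam_obj` must exceed `f_eq`.")
  f_eq + f_eq^2 / (D_cam_obj - f_eq)
}

#' Invert the blur-circle equation: depth from residual blur at focus time
#'
#' Solves the blur-circle relation for the object depth given the blur
#' diameter `s_tf` measured at the detected focus time and the in-focus
#' distance `d` at that time:
#' `z = -/+ d * K / (s_tf * (d - f_eq) -/+ K)` with `K = f_eq^2 / N`.
#' The `near` branch (object closer than `d`, `+` signs) and the `far` branch
#' (object beyond `d`, `-` signs) bracket `d`; which one applies is determined
#' by the sweep direction at the detected crossing. With `s_tf = 0` both
#' branches return `z = d` (zero blur means in focus), making this an exact
#' inverse of [blur_diameter()] on either side.
#'
#' @param s_tf Blur diameter at the detected focus time (m).
#' @param d In-focus distance at that time (m).
#' @param cfg An [optical_config()].
#' @param branch `"near"` (z < d) or `"far"` (z > d).
#' @param tol Relative tolerance below which the far-branch denominator is
#'   treated as singular (object at infinity).
#' @return Depth(s) `z` in meters.
#' @export
depth_from_focus <- function(s_tf, d, cfg = optical_config(),
                             branch = c("near", "far"), tol = 1e-12) {
  stopifnot(inherits(cfg, "optical_config"))
  branch <- match.arg(branch)
  if (any(s_tf < 0)) abort("`s_tf` must be >= 0.")
  if (any(d <= cfg$f_eq)) abort("`d` must exceed `f_eq`.")
  K <- cfg$f_eq^2 / cfg$N
  denom <- if (branch == "near") s_tf * (d - cfg$f_eq) + K else
    K - s_tf * (d - cfg$f_eq)
  if (any(abs(denom) <= tol * K)) {
    abort("singular configuration: blur diameter at the branch limit.")
  }
  if (branch == "far" && any(denom < 0)) {
    abort("blur diameter exceeds the far-branch limit f_eq^2/(N*(d - f_eq)).")
  }
  d * K / denom
}

#' Hyperfocal distance
#'
#' Distance beyond which every object's blur circle stays below the circle of
#' confusion `coc`, so depth differences can no longer be resolved:
#' `H = f_eq^2 / (N * coc) + f_eq` (standard textbook form). Detected depths
#' beyond `H` are flagged unresolvable by [assemble_depth_map()].
#'
#' @param cfg An [optical_config()].
#' @param coc Circle-of-confusion diameter (m); defaults to one pixel pitch.
#' @return Hyperfocal distance in meters.
#' @export
hyperfocal <- function(cfg = optical_config(), coc = cfg$pixel_pitch) {
  stopifnot(inherits(cfg, "optical_config"))
  if (any(coc <= 0)) abort("`coc` must be > 0.")
  cfg$f_eq^2 / (cfg$N * coc) + cfg$f_eq
}
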
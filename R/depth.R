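#' Assemble a metric depth map from per-pixel focus times
#'
#' Converts detected focus times to depth through the sweep trajectory:
#' at the detected polarity inversion the object is, by construction, at the
#' in-focus distance, so `z = d(t_f)` ([sweep_focus_at()]). The blur-circle
#' inversion ([depth_from_focus()]) is exposed separately for off-focus use
#' and round-trip validation. Focus times outside the sweep window
#' invalidate the pixel (counted in the `invalid_tf` attribute), and depths
#' at or beyond the hyperfocal distance are never reported valid (beyond it
#' the optics cannot resolve depth).
#'
#' @param tf Tibble of focus times: columns `x`, `y`, `t_f_us`, `valid` and
#'   optionally `ambiguous`, as produced by [detect_focus_times()] or
#'   [snn_focus_times()].
#' @param profile The [sweep_profile()] the events came from.
#' @param cfg An [optical_config()].
#' @param shape Map shape `c(rows, cols)`; defaults to the extent of `tf`.
#' @return A tibble of class `depth_map` with one row per pixel of the map:
#'   `x`, `y`, `z` (m, `NA` when invalid), `valid`, `ambiguous`; attributes
#'   `shape`, `profile`, `cfg`, `invalid_tf` (count of focus times outside
#'   the window) and `beyond_hyperfocal`.
#' @export
assemble_depth_map <- function(tf, profile = sweep_profile(),
                               cfg = optical_config(), shape = NULL) {
  stopifnot(all(c("x", "y", "t_f_us", "valid") %in% names(tf)))
  if (is.null(shape)) {
    shape <- if (nrow(tf)) c(max(tf$y) + 1L, max(tf$x) + 1L) else c(0L, 0L)
  }
  grid <- tidyr::expand_grid(y = seq_len(shape[1]) - 1L,
                             x = seq_len(shape[2]) - 1L)
  if (!"ambiguous" %in% names(tf)) tf$ambiguous <- NA
  tf <- dplyr::select(tibble::as_tibble(tf), "x", "y", "t_f_us", "valid",
                      "ambiguous")
  dm <- dplyr::left_join(grid, tf, by = c("x", "y")) |>
    dplyr::mutate(valid = dplyr::coalesce(.data$valid, FALSE),
                  ambiguous = dplyr::coalesce(.data$ambiguous, FALSE))

  t_s <- dm$t_f_us * 1e-6
  in_window <- !is.na(t_s) & t_s >= profile$t_start - 1e-12 &
    t_s <= profile$t_end + 1e-12
  invalid_tf <- sum(dm$valid & !in_window, na.rm = TRUE)
  ok <- dm$valid & in_window
  z <- rep(NA_real_, nrow(dm))
  z[ok] <- sweep_focus_at(t_s[ok], profile)
  H <- hyperfocal(cfg)
  beyond <- !is.na(z) & z >= H
  z[beyond] <- NA_real_
  dm$z <- z
  dm$valid <- ok & !beyond
  dm <- dplyr::select(dm, "x", "y", "z", "valid", "ambiguous")
  structure(dm,
            class = c("depth_map", class(dm)),
            shape = as.integer(shape),
            profile = profile, cfg = cfg,
            invalid_tf = invalid_tf,
            beyond_hyperfocal = sum(beyond))
}

#' @export
print.depth_map <- function(x, ...) {
  sh <- attr(x, "shape")
  cat(sprintf("<depth_map> %d x %d, %d/%d valid, %d ambiguous\n",
              sh[1], sh[2], sum(x$valid), nrow(x), sum(x$ambiguous,
                                                       na.rm = TRUE)))
  NextMethod()
}

#' Depth map as a matrix
#'
#' @param dm A [assemble_depth_map()] result.
#' @return Numeric matrix (m) with `NA` at invalid pixels.
#' @export
depth_matrix <- function(dm) {
  stopifnot(inherits(dm, "depth_map"))
  sh <- attr(dm, "shape")
  m <- matrix(NA_real_, sh[1], sh[2])
  m[cbind(dm$y + 1L, dm$x + 1L)] <- dm$z
  m
}

#' Evaluate a depth map against scene ground truth
#'
#' Per-pixel relative error `|z_est - z_true| / z_true`, restricted to
#' pixels that are both valid in the map and depth-labelled in the scene.
#'
#' @param dm A [assemble_depth_map()] result.
#' @param scene The [dff_scene()] ground truth (same shape).
#' @param breaks Histogram bin specification (passed to [graphics::hist()]
#'   semantics via [base::cut()]; a count or a vector of break points, in
#'   percent).
#' @return An object of class `dff_error_report`: list with
#'   `mean_relative_error` and `std_relative_error` (percent), `n_pixels`,
#'   `errors` (per-pixel tibble with `x`, `y`, `z_est`, `z_true`,
#'   `rel_error_pct`) and `histogram` (tibble of bin mids and counts).
#' @export
evaluate_depth <- function(dm, scene, breaks = 30) {
  stopifnot(inherits(dm, "depth_map"), inherits(scene, "dff_scene"))
  sh <- attr(dm, "shape")
  if (!all(sh == dim(scene$depth))) {
    abort("depth map and scene shapes differ.")
  }
  z_true <- scene$depth[cbind(dm$y + 1L, dm$x + 1L)]
  keep <- dm$valid & !is.na(z_true)
  if (!any(keep)) abort("no valid pixel overlaps the ground truth.")
  zt <- z_true[keep]
  ze <- dm$z[keep]
  err <- tibble::tibble(
    x = dm$x[keep], y = dm$y[keep],
    z_est = ze, z_true = zt,
    rel_error_pct = 100 * abs(ze - zt) / zt
  )
  h <- graphics::hist(err$rel_error_pct, breaks = breaks, plot = FALSE)
  structure(
    list(mean_relative_error = mean(err$rel_error_pct),
         std_relative_error = stats::sd(err$rel_error_pct),
         n_pixels = nrow(err),
         errors = err,
         histogram = tibble::tibble(bin_mid = h$mids, count = h$counts)),
    class = "dff_error_report")
}

#' @export
print.dff_error_report <- function(x, ...) {
  cat(sprintf(
    "<dff_error_report> mean relative error %.2f%% (sd %.2f%%) over %d pixels\n",
    x$mean_relative_error, x$std_relative_error, x$n_pixels))
  invisible(x)
}

#' @rdname evaluate_depth
#' @param x A `dff_error_report`.
#' @param ... Unused.
#' @export
tidy.dff_error_report <- function(x, ...) {
  x$errors
}

#' @rdname evaluate_depth
#' @export
glance.dff_error_report <- function(x, ...) {
  tibble::tibble(mean_relative_error = x$mean_relative_error,
                 std_relative_error = x$std_relative_error,
                 n_pixels = x$n_pixels)
}
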
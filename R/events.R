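#' Address-event stream
#'
#' Events are the camera's only output: a pixel emits an ON event (`p = +1`)
#' when its log-intensity has risen by the contrast threshold `n` since its
#' last event, and an OFF event (`p = -1`) when it has fallen by `n`.
#' A stream is a time-sorted tibble with columns `t_us` (integer
#' microseconds), `x`, `y` (0-based column/row, origin top-left) and `p`
#' (+1/-1), carrying the sensor shape and sweep metadata as attributes.
#'
#' @param t_us,x,y,p Event fields.
#' @param sensor_shape `c(rows, cols)` of the emitting array.
#' @param profile The [sweep_profile()] during which the events were
#'   recorded (or `NULL`).
#' @param threshold_n Contrast threshold used.
#' @return A tibble of class `event_stream`, sorted by `t_us`, then row-major
#'   position, then polarity (stable order for equal timestamps).
#' @export
event_stream <- function(t_us = integer(), x = integer(), y = integer(),
                         p = integer(), sensor_shape = c(64L, 64L),
                         profile = NULL, threshold_n = NA_real_) {
  if (any(t_us < 0)) abort("event timestamps must be >= 0.")
  if (any(p != 1L & p != -1L)) abort("polarity must be +1 or -1.")
  if (any(x < 0 | x >= sensor_shape[2] | y < 0 | y >= sensor_shape[1])) {
    abort("event coordinates outside the sensor.")
  }
  ev <- tibble::tibble(t_us = t_us, x = as.integer(x), y = as.integer(y),
                       p = as.integer(p))
  ev <- dplyr::arrange(ev, .data$t_us, .data$y, .data$x, .data$p)
  structure(ev,
            class = c("event_stream", class(ev)),
            sensor_shape = as.integer(sensor_shape),
            sweep = profile,
            threshold_n = threshold_n)
}

#' @export
print.event_stream <- function(x, ...) {
  sh <- attr(x, "sensor_shape")
  cat(sprintf("<event_stream> %d events on a %d x %d array\n",
              nrow(x), sh[1], sh[2]))
  NextMethod()
}

#' Simulate the event camera over one focal sweep
#'
#' Renders the scene at successive in-focus distances `d(t)` along the sweep
#' and converts the per-pixel log-intensity trajectory into ON/OFF
#' address-events with the standard contrast-detector model: each pixel keeps
#' the log-intensity at its last event as a reference; whenever the current
#' log-intensity exceeds the reference by the threshold `n` an ON event is
#' emitted (below by `n`, OFF), the reference stepping by exactly `n` per
#' event so that a large step of `k * n` within one render interval yields
#' `k` events. Event times are placed by linear interpolation of the
#' threshold crossing inside the render step and quantized to 1 microsecond
#' (the temporal resolution of the emulated sensor).
#'
#' @param scene A [dff_scene()]; its matrix shape defines the active pixel
#'   array.
#' @param profile A [sweep_profile()].
#' @param cfg An [optical_config()] (supplies the threshold `n` and optics).
#' @param dt Render step (s). Smaller steps tighten the crossing-time
#'   interpolation; the event times converge to the closed-form prediction
#'   as `dt` shrinks.
#' @param t0_reset If `TRUE` (default) every pixel's reference is initialized
#'   to its intensity at the sweep start, so a static scene emits nothing.
#'   If `FALSE` references start at the background level and the first frame
#'   may emit events encoding the initial contrast.
#' @param sigma_px_cap,normalize Passed to [render_frame()].
#' @param quantize Quantize timestamps to integer microseconds (default).
#'   `FALSE` keeps exact interpolated times (diagnostic use, e.g. convergence
#'   studies below the microsecond floor).
#' @param refractory_us Optional per-pixel refractory period in microseconds
#'   (0 = none, the default model).
#' @return An [event_stream()].
#' @export
generate_events <- function(scene, profile = sweep_profile(),
                            cfg = optical_config(), dt = 25e-6,
                            t0_reset = TRUE, sigma_px_cap = 12,
                            normalize = TRUE, quantize = TRUE,
                            refractory_us = 0) {
  stopifnot(inherits(scene, "dff_scene"), inherits(profile, "sweep_profile"),
            inherits(cfg, "optical_config"))
  if (dt <= 0) abort("`dt` must be > 0.")
  n <- cfg$event_threshold_n
  rows <- nrow(scene$depth); cols <- ncol(scene$depth)
  npix <- rows * cols
  floor_eps <- 1e-6

  span <- profile$t_end - profile$t_start
  nstep <- max(1L, ceiling(span / dt))
  times <- profile$t_start + seq(0L, nstep) * dt
  times[nstep + 1L] <- profile$t_end

  log_frame <- function(t) {
    fr <- render_frame(scene, sweep_focus_at(t, profile), cfg,
                       sigma_px_cap = sigma_px_cap, normalize = normalize,
                       warn_clamp = FALSE)
    if (any(fr < floor_eps)) {
      fr <- pmax(fr, floor_eps)
      attr(fr, "floored") <- TRUE
    }
    log(fr)
  }

  prev <- log_frame(times[1])
  floored <- isTRUE(attr(prev, "floored"))
  ref <- if (t0_reset) as.vector(prev) else
    rep(log(max(scene$background_level, floor_eps)), npix)
  last_t <- rep(-Inf, npix)

  acc_pix <- vector("list", nstep)
  acc_t <- vector("list", nstep)
  acc_p <- vector("list", nstep)

  for (k in seq_len(nstep)) {
    cur <- log_frame(times[k + 1L])
    floored <- floored || isTRUE(attr(cur, "floored"))
    curv <- as.vector(cur)
    prevv <- as.vector(prev)
    delta <- curv - ref
    sgn <- sign(delta)
    nev <- pmax(0L, floor(abs(delta) / n))
    idx <- which(nev > 0L)
    if (length(idx)) {
      reps <- nev[idx]
      pix <- rep.int(idx, reps)
      j <- sequence(reps)
      sg <- rep.int(sgn[idx], reps)
      level <- ref[pix] + sg * j * n
      den <- curv[pix] - prevv[pix]
      frac <- (level - prevv[pix]) / den
      frac[!is.finite(frac)] <- 1
      frac <- pmin(pmax(frac, 0), 1)
      tev <- times[k] + frac * (times[k + 1L] - times[k])
      if (refractory_us > 0) {
        keep <- logical(length(pix))
        # enforce the dead time sequentially within the step
        for (i in seq_along(pix)) {
          ok <- (tev[i] - last_t[pix[i]]) * 1e6 >= refractory_us
          keep[i] <- ok
          if (ok) last_t[pix[i]] <- tev[i]
        }
        pix <- pix[keep]; tev <- tev[keep]; sg <- sg[keep]
      }
      acc_pix[[k]] <- pix
      acc_t[[k]] <- tev
      acc_p[[k]] <- as.integer(sg)
      ref[idx] <- ref[idx] + sgn[idx] * nev[idx] * n
    }
    prev <- cur
  }
  if (floored) {
    warn("nonpositive intensities were floor-clamped before taking logs.")
  }

  pix <- unlist(acc_pix) %||% integer()
  tev <- unlist(acc_t) %||% numeric()
  pol <- unlist(acc_p) %||% integer()
  row <- (pix - 1L) %% rows          # 0-based row (y)
  col <- (pix - 1L) %/% rows         # 0-based col (x)
  t_us <- if (quantize) as.integer(round(tev * 1e6)) else tev * 1e6
  event_stream(t_us = t_us, x = col, y = row, p = pol,
               sensor_shape = c(rows, cols), profile = profile,
               threshold_n = n)
}
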
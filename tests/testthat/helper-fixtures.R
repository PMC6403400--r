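# Shared builders for the test suite. Everything is generated in code; the
# default optics/sweep are the package defaults (paper-style hardware).

test_cfg <- function(...) optical_config(...)
test_profile <- function(...) sweep_profile(...)

# A single point source on a black background, for closed-form PSF checks.
point_scene <- function(rows = 33, cols = 33, z = 0.3) {
  refl <- matrix(0, rows, cols)
  refl[(rows + 1) / 2, (cols + 1) / 2] <- 1
  dep <- matrix(NA_real_, rows, cols)
  dep[(rows + 1) / 2, (cols + 1) / 2] <- z
  dff_scene(refl, dep, background_level = 0)
}

# Independent geometric-optics oracle for the blur-circle diameter: image the
# focus plane and the object plane through the thin lens, then use similar
# triangles on the aperture cone at the sensor plane.
blur_oracle <- function(z, d, f, N) {
  aperture <- f / N
  v_d <- f * d / (d - f) # sensor sits at the conjugate of the focus plane
  v_z <- f * z / (z - f) # image plane of the object
  aperture * abs(v_d - v_z) / v_z
}

# Hand-rolled event tibble for driving the spiking circuit directly.
manual_events <- function(t_us, p, x = 0L, y = 0L, shape = c(1L, 1L)) {
  event_stream(t_us = as.integer(t_us), x = rep_len(x, length(t_us)),
               y = rep_len(y, length(t_us)), p = as.integer(p),
               sensor_shape = shape)
}

# Cached expensive simulations shared across test files (built on first use).
sphere_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- test_cfg()
      sp <- test_profile()
      scene <- make_fixture("sphere", z = 0.3)
      events <- generate_events(scene, sp, cfg)
      cache <<- list(cfg = cfg, profile = sp, scene = scene, events = events)
    }
    cache
  }
})
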
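test_that("a static (featureless) scene emits no events", {
  sc <- make_fixture("uniform", z = 0.4)
  ev <- generate_events(sc, sweep_profile(), test_cfg())
  expect_equal(nrow(ev), 0)
})

test_that("event counts obey the reference-stepping threshold arithmetic", {
  cfg <- test_cfg()
  sp <- sweep_profile()
  sc <- make_fixture("bar", z = 0.3)
  ev <- generate_events(sc, sp, cfg)
  n <- cfg$event_threshold_n
  lg <- function(t) {
    log(pmax(render_frame(sc, sweep_focus_at(t, sp), cfg,
                          warn_clamp = FALSE), 1e-6))
  }
  l0 <- lg(sp$t_start)
  l1 <- lg(sp$t_end)
  drift <- tibble::as_tibble(ev) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(net = sum(.data$p) * n, .groups = "drop")
  # per pixel, the reference ratchets by n per event, so the net polarity
  # sum times n must track the total log-intensity change to within n
  for (i in seq_len(nrow(drift))) {
    true_change <- l1[drift$y[i] + 1, drift$x[i] + 1] -
      l0[drift$y[i] + 1, drift$x[i] + 1]
    expect_lt(abs(drift$net[i] - true_change), n + 1e-9)
  }
})

test_that("coarser contrast thresholds produce fewer events", {
  sp <- sweep_profile()
  sc <- make_fixture("bar", z = 0.3)
  counts <- vapply(c(0.08, 0.15, 0.3), function(n) {
    nrow(generate_events(sc, sp, test_cfg(event_threshold_n = n)))
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("reversing the sweep mirrors the stream with flipped polarities", {
  # time symmetry: the reversed sweep's intensity trajectory is the forward
  # one played backwards, so each event pairs with a mirror-image event of
  # the opposite polarity at T - t
  cfg <- test_cfg()
  sc <- make_fixture("bar", z = 0.3)
  sp_f <- sweep_profile()
  fwd <- generate_events(sc, sp_f, cfg)
  rev <- generate_events(sc, sweep_profile(d_start = 5.5, d_end = 0.12),
                         cfg)
  cnt <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(fwd), .data$x,
                                     .data$y),
                     on_f = sum(.data$p > 0), off_f = sum(.data$p < 0),
                     .groups = "drop"),
    dplyr::summarise(dplyr::group_by(tibble::as_tibble(rev), .data$x,
                                     .data$y),
                     on_r = sum(.data$p > 0), off_r = sum(.data$p < 0),
                     .groups = "drop"),
    by = c("x", "y"))
  # per pixel, ON counts forward match OFF counts backward and vice versa
  expect_gt(mean(abs(cnt$on_f - cnt$off_r) <= 2 &
                   abs(cnt$off_f - cnt$on_r) <= 2), 0.95)
  # detected focus times mirror about the window
  t_total_us <- (sp_f$t_end - sp_f$t_start) * 1e6
  tfm <- dplyr::inner_join(
    dplyr::filter(detect_focus_times(fwd), .data$valid),
    dplyr::filter(detect_focus_times(rev), .data$valid),
    by = c("x", "y"), suffix = c("_f", "_r"))
  mirror_err <- abs((t_total_us - tfm$t_f_us_r) - tfm$t_f_us_f)
  expect_lt(stats::median(mirror_err), 100)
})

test_that("streams are quantized, sorted, and well-formed", {
  s <- sphere_sim()
  ev <- s$events
  expect_true(is.integer(ev$t_us))
  expect_true(!is.unsorted(ev$t_us))
  expect_true(all(ev$p %in% c(-1L, 1L)))
  expect_true(all(ev$x >= 0 & ev$x < 64 & ev$y >= 0 & ev$y < 64))
  expect_identical(attr(ev, "sensor_shape"), c(64L, 64L))
})

test_that("nonpositive intensities are floored with a warning", {
  cfg <- test_cfg()
  sc <- point_scene(17, 17, z = 0.3) # black background -> zero intensity
  expect_warning(generate_events(sc, sweep_profile(), cfg, dt = 1e-4,
                                 normalize = FALSE),
                 "floor")
})

test_that("disabling the start-of-sweep reference reset emits boot events", {
  cfg <- test_cfg()
  sp <- sweep_profile()
  sc <- make_fixture("bar", z = 0.3)
  ev_reset <- generate_events(sc, sp, cfg, t0_reset = TRUE)
  ev_boot <- generate_events(sc, sp, cfg, t0_reset = FALSE)
  # the un-reset stream additionally encodes the initial contrast pattern
  expect_gt(nrow(ev_boot), nrow(ev_reset))
})

test_that("a refractory period thins dense trains without reordering", {
  cfg <- test_cfg()
  sp <- sweep_profile()
  sc <- make_fixture("bar", z = 0.3)
  ev0 <- generate_events(sc, sp, cfg)
  ev1 <- generate_events(sc, sp, cfg, refractory_us = 50)
  expect_lt(nrow(ev1), nrow(ev0))
  gaps <- tibble::as_tibble(ev1) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(g = min(c(diff(sort(.data$t_us)), Inf)),
                     .groups = "drop")
  expect_true(all(gaps$g >= 50 - 1)) # 1 us quantization slack
})

test_that("event stream constructor validates coordinates and polarity", {
  expect_error(event_stream(0L, 5L, 0L, 1L, sensor_shape = c(4L, 4L)),
               "outside")
  expect_error(event_stream(0L, 0L, 0L, 2L), "polarity")
  expect_error(event_stream(-5L, 0L, 0L, 1L), ">= 0")
})
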
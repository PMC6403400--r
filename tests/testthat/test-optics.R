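test_that("blur diameter vanishes exactly at focus and approaches the far limit", {
  cfg <- test_cfg(f_eq = 0.02, N = 2)
  expect_equal(blur_diameter(0.5, 0.5, cfg), 0)
  expect_equal(blur_diameter(1.234, 1.234, cfg), 0)
  lim <- cfg$f_eq^2 / (cfg$N * (0.5 - cfg$f_eq))
  expect_equal(blur_diameter(Inf, 0.5, cfg), lim)
  expect_lt(abs(blur_diameter(1e9, 0.5, cfg) - lim) / lim, 1e-6)
})

test_that("blur diameter matches an independent similar-triangles construction", {
  grid <- expand.grid(f = c(0.02, 0.0297, 0.035), N = c(1.4, 2, 4),
                      d = c(0.3, 0.5, 1.2), z = c(0.15, 0.5, 1.0, 4))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cfg <- test_cfg(f_eq = g$f, N = g$N)
    expect_equal(blur_diameter(g$z, g$d, cfg),
                 blur_oracle(g$z, g$d, g$f, g$N), tolerance = 1e-12)
  }
})

test_that("blur diameter rejects invalid geometry", {
  cfg <- test_cfg()
  expect_error(blur_diameter(-1, 0.5, cfg), "z")
  expect_error(blur_diameter(0.5, cfg$f_eq / 2, cfg), "f_eq")
})

test_that("blur diameter is zero iff in focus and grows with defocus in diopters", {
  cfg <- test_cfg()
  d <- 0.4
  dz <- abs(1 / seq(0.15, 3, length.out = 200) - 1 / d)
  s <- blur_diameter(seq(0.15, 3, length.out = 200), d, cfg)
  expect_true(all((s == 0) == (dz == 0)))
  ord <- order(dz)
  expect_true(all(diff(s[ord]) >= -1e-15))
})

test_that("PSF spread is proportional to the blur diameter", {
  cfg <- test_cfg(alpha = 0.5)
  expect_equal(psf_sigma(0, cfg), 0)
  expect_equal(psf_sigma(2e-4, cfg), 1e-4)
  expect_equal(psf_sigma(blur_diameter(0.7, 0.7, cfg), cfg), 0)
  expect_error(psf_sigma(-1e-5, cfg), ">= 0")
})

test_that("thin-lens focus distance has the 2f-2f conjugate and far limit", {
  expect_equal(focus_distance(0.035, 0.070), 0.070)
  expect_lt(abs(focus_distance(0.035, 1e9) - 0.035), 1e-9)
  d <- focus_distance(0.035, seq(0.05, 10, length.out = 500))
  expect_true(all(diff(d) < 0)) # strictly decreasing in the object distance
  expect_error(focus_distance(0.035, 0.01), "exceed")
})

test_that("depth inversion recovers the object depth on both branches", {
  cfg <- test_cfg()
  for (z in c(0.15, 0.3, 0.49)) { # nearer than d
    s <- blur_diameter(z, 0.5, cfg)
    expect_equal(depth_from_focus(s, 0.5, cfg, branch = "near"), z,
                 tolerance = 1e-9)
  }
  for (z in c(0.51, 1, 3)) { # beyond d
    s <- blur_diameter(z, 0.5, cfg)
    expect_equal(depth_from_focus(s, 0.5, cfg, branch = "far"), z,
                 tolerance = 1e-9)
  }
  # zero blur means in focus for either branch
  expect_equal(depth_from_focus(0, 0.5, cfg, branch = "near"), 0.5)
  expect_equal(depth_from_focus(0, 0.5, cfg, branch = "far"), 0.5)
})

test_that("near and far branches bracket the in-focus distance", {
  cfg <- test_cfg()
  d <- 0.6
  K <- cfg$f_eq^2 / cfg$N
  s <- 0.5 * K / (d - cfg$f_eq) # inside the far-branch admissible range
  zn <- depth_from_focus(s, d, cfg, branch = "near")
  zf <- depth_from_focus(s, d, cfg, branch = "far")
  expect_lt(zn, d)
  expect_gt(zf, d)
})

test_that("depth inversion flags singular blur diameters", {
  cfg <- test_cfg()
  K <- cfg$f_eq^2 / cfg$N
  s_sing <- K / (0.5 - cfg$f_eq)
  expect_error(depth_from_focus(s_sing, 0.5, cfg, branch = "far"))
  expect_error(depth_from_focus(2 * s_sing, 0.5, cfg, branch = "far"))
})

test_that("analytic inversion round-trips over random optics", {
  set.seed(42)
  nrep <- 2000
  f <- runif(nrep, 0.01, 0.05)
  N <- runif(nrep, 1.2, 8)
  d <- runif(nrep, 0.1, 3)
  z <- runif(nrep, 0.1, 6)
  for (i in seq_len(nrep)) {
    if (d[i] <= f[i] * 1.5) d[i] <- f[i] * 1.5 + d[i]
    cfg <- test_cfg(f_eq = f[i], N = N[i])
    s <- blur_diameter(z[i], d[i], cfg)
    br <- if (z[i] < d[i]) "near" else "far"
    zr <- depth_from_focus(s, d[i], cfg, branch = br)
    expect_lt(abs(zr - z[i]) / z[i], 1e-6)
  }
})

test_that("hyperfocal distance follows the textbook form", {
  cfg <- test_cfg(f_eq = 0.035, N = 2, pixel_pitch = 15e-6)
  # independent hand computation: 0.035^2 / (2 * 15e-6) + 0.035
  expect_equal(hyperfocal(cfg), 40.86833, tolerance = 1e-6)
  expect_lt(abs(hyperfocal(cfg, coc = 1e6) - cfg$f_eq), 1e-9)
  h1 <- hyperfocal(test_cfg(f_eq = 0.035, N = 2), coc = 15e-6) - 0.035
  h2 <- hyperfocal(test_cfg(f_eq = 0.035, N = 4), coc = 15e-6) - 0.035
  expect_equal(h1 / h2, 2, tolerance = 1e-12)
  expect_error(hyperfocal(cfg, coc = 0), "> 0")
})

test_that("lens stack composes an approximate equivalent focal length", {
  st <- lens_stack()
  expect_equal(st$f_ll_range, c(0.050, 0.120))
  expect_equal(st$f_offset, -0.150)
  expect_equal(st$f_objective, 0.035)
  f_mid <- equivalent_focal(st, 0.085)
  expect_equal(1 / f_mid, 1 / 0.085 + 1 / -0.15 + 1 / 0.035)
  expect_error(equivalent_focal(st, 0.2), "range")
  expect_error(lens_stack(f_ll_range = c(0.12, 0.05)), "increasing")
})

test_that("configuration constructors validate their invariants", {
  expect_error(optical_config(f_eq = -1), "f_eq")
  expect_error(optical_config(N = 0), "N")
  expect_error(optical_config(alpha = 0), "alpha")
  expect_error(optical_config(event_threshold_n = 0), "event_threshold_n")
})
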
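test_that("LIF dynamics follow the closed-form leaky integrator", {
  p <- lif_params(tau_m = 20e-3, v_threshold = 10)
  st <- list(v = 0, refrac = 0)
  # rest stays at rest
  for (i in 1:50) st <- lif_step(st, 0, 1e-3, p)
  expect_equal(st$v, 0)
  # sub-threshold pulse decays as w * exp(-t / tau)
  st <- lif_step(list(v = 0, refrac = 0), 1, 1e-3, p)
  v0 <- st$v
  for (i in 1:40) st <- lif_step(st, 0, 1e-3, p)
  expect_equal(st$v, v0 * exp(-40e-3 / 20e-3), tolerance = 1e-9)
  # supra-threshold pulse spikes exactly once then resets
  st <- lif_step(list(v = 0, refrac = 0), 12, 1e-3, p)
  expect_true(st$spiked)
  expect_equal(st$v, p$v_reset)
  st <- lif_step(st, 0, 1e-3, p)
  expect_false(st$spiked)
})

test_that("refractory neurons ignore input until the dead time elapses", {
  p <- lif_params(tau_m = 20e-3, v_threshold = 1, t_refractory = 5e-3)
  st <- lif_step(list(v = 0, refrac = 0), 2, 1e-3, p)
  expect_true(st$spiked)
  st <- lif_step(st, 2, 1e-3, p) # still refractory
  expect_false(st$spiked)
  for (i in 1:5) st <- lif_step(st, 0, 1e-3, p)
  st <- lif_step(st, 2, 1e-3, p)
  expect_true(st$spiked)
})

test_that("circuit parameter validation names the violated constraint", {
  expect_error(circuit_params(w_excit = 2, theta_out = 1.8),
               "single_epsp_subthreshold")
  expect_error(circuit_params(theta_out = 5), "pairing_suprathreshold")
  expect_error(circuit_params(w_block_in = 2, theta_block = 1.4),
               "blocker_single_subthreshold")
  expect_error(circuit_params(theta_block = 3), "blocker_two_spikes")
  expect_error(circuit_params(w_block_self = 0.01), "blocker_reprimes")
  expect_error(circuit_params(w_inhib = 0.5), "inhibition_cancels")
  expect_error(circuit_params(w_self = 1), "self_sustaining")
  expect_error(circuit_params(w_sync = -1), "sync_dominates")
})

test_that("the pixel circuit has five neurons wired to one shared Sync", {
  pc <- build_pixel_circuit()
  expect_length(pc$neurons, 5)
  expect_setequal(names(pc$neurons), c("ON", "OFF", "B_on", "B_off", "OUT"))
  expect_equal(pc$sync, "shared")
  w <- pc$wiring
  # the disynaptic blocker path (1 + 1) must match the direct path (2) so
  # inhibition lands together with the EPSP it cancels
  expect_equal(w$delay_steps[w$pre == "ON" & w$post == "OUT"], 2L)
  expect_equal(w$delay_steps[w$pre == "ON" & w$post == "B_on"] +
                 w$delay_steps[w$pre == "B_on" & w$post == "OUT"], 2L)
  expect_lt(w$weight[w$pre == "Sync"], 0)
})

test_that("network sizing is exactly five neurons per pixel", {
  net1 <- build_network(c(1L, 1L))
  expect_equal(neuron_count(net1), 5L)
  net6 <- build_network(c(2L, 3L))
  expect_equal(neuron_count(net6), 30L)
  big <- build_network(c(480L, 640L),
                       roi = list(x = c(0L, 446L), y = c(0L, 446L)))
  expect_equal(neuron_count(big), 999045L)
  expect_equal(neuron_count(big, include_sync = TRUE), 999046L)
  expect_error(build_network(c(4L, 4L), roi = list(x = c(2L, 1L),
                                                   y = c(0L, 3L))), "empty")
  expect_error(build_network(c(4L, 4L), roi = list(x = c(0L, 5L),
                                                   y = c(0L, 3L))),
               "outside")
})

test_that("an ON-ON-OFF train fires OUT at the polarity inversion", {
  net <- build_network(c(1L, 1L))
  dt_us <- net$params$dt * 1e6
  ev <- manual_events(c(1000L, 1400L, 2100L), c(1L, 1L, -1L))
  rec <- run_network(net, ev, sync_times = 5e-3, record = "full")
  tf <- snn_focus_times(rec)
  expect_true(tf$valid)
  # decoded focus time lands within one step of the OFF event
  expect_lt(abs(tf$t_f_us - 2100), dt_us)
  # the OUT-to-Sync interval encodes the same thing
  expect_lt(abs((rec$sync_us - rec$onset_us) - (5000 - 2100 - 2 * dt_us)),
            dt_us)
})

test_that("same-polarity trains of any length and spacing never fire OUT", {
  net <- build_network(c(1L, 1L))
  spacings <- list(50L, 100L, 400L, 1500L)
  for (sp_us in spacings) {
    for (len in c(1L, 2L, 3L, 8L, 40L)) {
      t_us <- 500L + sp_us * (seq_len(len) - 1L)
      for (pol in c(1L, -1L)) {
        rec <- run_network(net, manual_events(t_us, rep(pol, len)),
                           sync_times = 5e-3)
        expect_true(is.na(rec$onset_us),
                    label = sprintf("no OUT for %d x p=%d at %d us", len,
                                    pol, sp_us))
      }
    }
  }
})

test_that("a lone inversion pair fires OUT even when widely separated", {
  net <- build_network(c(1L, 1L))
  ev <- manual_events(c(500L, 4200L), c(1L, -1L))
  rec <- run_network(net, ev, sync_times = 5e-3)
  expect_false(is.na(rec$onset_us))
})

test_that("the OUT train is contiguous from onset until Sync silences it", {
  net <- build_network(c(1L, 1L))
  dt_us <- net$params$dt * 1e6
  ev <- manual_events(c(800L, 1000L, 1600L, 1800L, 2400L, 3000L, 3600L),
                      c(1L, 1L, -1L, -1L, -1L, -1L, -1L))
  rec <- run_network(net, ev, sync_times = 5e-3, record = "full")
  sp <- attr(rec, "out_spikes")
  expect_gt(nrow(sp), 1)
  # self-excitation keeps OUT firing every step: one contiguous train,
  # post-inversion OFF spikes never re-trigger a second onset
  expect_true(all(abs(diff(sort(sp$t_us)) - dt_us) < 1e-6))
  # and nothing fires after the Sync inhibition lands
  expect_true(all(sp$t_us <= rec$sync_us + dt_us))
  expect_equal(rec$n_out_spikes, nrow(sp))
})

test_that("an empty stream produces no OUT spikes anywhere", {
  net <- build_network(c(4L, 4L))
  rec <- run_network(net, manual_events(integer(), integer(),
                                        shape = c(4L, 4L)),
                     sync_times = 5e-3)
  expect_true(all(is.na(rec$onset_us)))
})

test_that("pixel circuits are independent under event interleaving", {
  net <- build_network(c(2L, 2L), params = circuit_params())
  a <- tibble::tibble(t_us = c(1000L, 1500L, 2000L),
                      x = 0L, y = 0L, p = c(1L, 1L, -1L))
  b <- tibble::tibble(t_us = c(900L, 1600L, 2500L),
                      x = 1L, y = 1L, p = c(-1L, -1L, 1L))
  ev1 <- event_stream(c(a$t_us, b$t_us), c(a$x, b$x), c(a$y, b$y),
                      c(a$p, b$p), sensor_shape = c(2L, 2L))
  rec1 <- run_network(net, ev1, sync_times = 5e-3)
  # same events, one pixel's train shifted in among the other's
  ev2 <- event_stream(c(b$t_us, a$t_us), c(b$x, a$x), c(b$y, a$y),
                      c(b$p, a$p), sensor_shape = c(2L, 2L))
  rec2 <- run_network(net, ev2, sync_times = 5e-3)
  expect_equal(dplyr::arrange(tibble::as_tibble(rec1), x, y)$onset_us,
               dplyr::arrange(tibble::as_tibble(rec2), x, y)$onset_us)
})

test_that("translating all inputs translates the OUT onset (mod one step)", {
  net <- build_network(c(1L, 1L))
  dt_us <- net$params$dt * 1e6
  base <- c(700L, 1100L, 1900L)
  rec0 <- run_network(net, manual_events(base, c(1L, 1L, -1L)),
                      sync_times = 5e-3)
  for (shift in c(130L, 450L, 1000L)) {
    rec <- run_network(net, manual_events(base + shift, c(1L, 1L, -1L)),
                       sync_times = 5e-3)
    expect_lt(abs((rec$onset_us - rec0$onset_us) - shift), dt_us + 1e-9)
  }
})

test_that("unsorted streams error and off-ROI events are counted, not used", {
  net <- build_network(c(2L, 2L), roi = list(x = c(0L, 0L), y = c(0L, 0L)))
  bad <- tibble::tibble(t_us = c(2000L, 1000L), x = 0L, y = 0L,
                        p = c(1L, -1L))
  expect_error(run_network(net, bad, sync_times = 5e-3), "sorted")
  ev <- event_stream(c(1000L, 1200L, 1400L, 2000L),
                     x = c(0L, 1L, 0L, 0L), y = c(0L, 1L, 0L, 0L),
                     p = c(1L, 1L, 1L, -1L), sensor_shape = c(2L, 2L))
  rec <- run_network(net, ev, sync_times = 5e-3)
  expect_equal(attr(rec, "ignored_events"), 1L)
  expect_false(is.na(rec$onset_us[1]))
})

test_that("sync input must follow the sweep start", {
  net <- build_network(c(1L, 1L))
  expect_error(run_network(net, manual_events(100L, 1L),
                           sync_times = numeric()), "nonempty")
})
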
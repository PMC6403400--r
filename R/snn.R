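#' Leaky integrate-and-fire parameters
#'
#' Membrane dynamics shared by the circuit neurons: exponential leak toward
#' `v_rest` with time constant `tau_m`, instantaneous (delta-current)
#' synaptic increments, spike and reset to `v_reset` at `v_threshold`, and an
#' optional absolute refractory period.
#'
#' @param tau_m Membrane time constant (s), > 0.
#' @param v_rest,v_reset,v_threshold Membrane potentials (arbitrary units),
#'   `v_threshold > v_rest`.
#' @param t_refractory Absolute refractory period (s), >= 0.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 50e-3, v_rest = 0, v_reset = 0,
                       v_threshold = 1, t_refractory = 0) {
  if (tau_m <= 0) abort("`tau_m` must be > 0.")
  if (!(v_threshold > v_rest)) abort("`v_threshold` must exceed `v_rest`.")
  if (t_refractory < 0) abort("`t_refractory` must be >= 0.")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_reset = v_reset,
                 v_threshold = v_threshold, t_refractory = t_refractory),
            class = "lif_params")
}

#' Advance LIF membrane state by one step
#'
#' Exact exponential decay toward rest over `dt`, followed by the
#' instantaneous synaptic increment and the threshold test. Vectorized over
#' neurons. Neurons inside their refractory period ignore input and stay at
#' the reset potential.
#'
#' @param state List with numeric `v` (membrane potentials) and
#'   `refrac` (remaining refractory time, s); as returned by this function
#'   or built as `list(v = ..., refrac = ...)`.
#' @param input_current Synaptic increment(s) added after the decay
#'   (delta-current synapse).
#' @param dt Step (s), > 0.
#' @param params A [lif_params()].
#' @return Updated state, with a logical `spiked` element.
#' @export
lif_step <- function(state, input_current, dt, params = lif_params()) {
  if (dt <= 0) abort("`dt` must be > 0.")
  lam <- exp(-dt / params$tau_m)
  refr <- pmax(state$refrac %||% 0, 0)
  v <- params$v_rest + (state$v - params$v_rest) * lam
  active <- refr <= 0
  v <- ifelse(active, v + input_current, params$v_reset)
  spiked <- active & v >= params$v_threshold
  v[spiked] <- params$v_reset
  refr <- ifelse(spiked, params$t_refractory, pmax(refr - dt, 0))
  list(v = v, refrac = refr, spiked = spiked)
}

#' Parameters of the per-pixel focus-detection circuit
#'
#' The circuit uses five neurons per pixel — ON and OFF input relays, two
#' blockers `B_on`/`B_off`, and an output neuron OUT — plus one Sync neuron
#' shared by the whole array. The published description is behavioral, so
#' the defaults here are chosen to satisfy the behavioral constraints that
#' [validate_circuit_params()] enforces rather than to match any particular
#' hardware values:
#'
#' * a single ON or OFF EPSP leaves OUT below threshold;
#' * an EPSP residual plus one opposite-polarity EPSP within the pairing
#'   window crosses it;
#' * a blocker needs two same-polarity spikes to fire, then re-primes itself
#'   (self-excitation) so it fires on every further spike of its polarity;
#' * each blocker IPSP is at least as large as an OUT EPSP and, through the
#'   delay layout (direct path 2 steps, disynaptic blocker path 1 + 1),
#'   arrives at OUT simultaneously with the EPSP it cancels — this exact
#'   cancellation is what keeps arbitrarily long same-polarity runs
#'   sub-threshold while leaving the first event of the run as the pairing
#'   residual;
#' * the OUT self-EPSP alone re-fires OUT, sustaining the output train;
#' * the Sync weight dominates everything and the Sync spike resets state.
#'
#' The membrane window `tau_m` is deliberately long compared to the sweep
#' (50 ms vs 5 ms): the pairing residual must survive from the last
#' pre-focus event to the first post-focus one, and the Sync reset — not the
#' leak — is what clears state between sweeps.
#'
#' @param dt Simulation step (s).
#' @param tau_m Membrane time constant (s) for all circuit neurons.
#' @param w_input,theta_input Input relay drive and threshold (a pixel event
#'   makes its relay fire in the same step).
#' @param w_excit EPSP weight ON/OFF -> OUT.
#' @param theta_out OUT firing threshold (above rest).
#' @param w_block_in,theta_block,w_block_self Blocker input weight,
#'   threshold, and self-priming weight.
#' @param w_inhib Blocker -> OUT IPSP magnitude.
#' @param w_self OUT -> OUT self-excitation.
#' @param w_sync Sync -> OUT weight (strongly negative).
#' @param pairing_window Largest time between opposite-polarity events that
#'   must still trigger OUT (s); defaults to a full 5 ms sweep.
#' @param v_rest,v_reset Rest and reset potentials.
#' @return An object of class `circuit_params` (validated).
#' @export
circuit_params <- function(dt = 50e-6, tau_m = 50e-3,
                           w_input = 2, theta_input = 1,
                           w_excit = 1, theta_out = 1.8,
                           w_block_in = 1, theta_block = 1.4,
                           w_block_self = 1, w_inhib = 1,
                           w_self = 3, w_sync = -10,
                           pairing_window = 5e-3,
                           v_rest = 0, v_reset = 0) {
  p <- structure(
    list(dt = dt, tau_m = tau_m, w_input = w_input,
         theta_input = theta_input, w_excit = w_excit,
         theta_out = theta_out, w_block_in = w_block_in,
         theta_block = theta_block, w_block_self = w_block_self,
         w_inhib = w_inhib, w_self = w_self, w_sync = w_sync,
         pairing_window = pairing_window, v_rest = v_rest,
         v_reset = v_reset),
    class = "circuit_params")
  validate_circuit_params(p)
  p
}

#' Validate the behavioral constraints of the circuit parameters
#'
#' Errors naming the first violated constraint; returns the parameters
#' invisibly when all hold.
#'
#' @param p A `circuit_params` list.
#' @export
validate_circuit_params <- function(p) {
  if (p$dt <= 0) abort("constraint 'positive_step' failed: dt must be > 0.")
  if (p$tau_m <= 0) abort("constraint 'positive_tau' failed: tau_m must be > 0.")
  lam <- exp(-p$pairing_window / p$tau_m)
  gap <- function(theta) theta - p$v_rest
  fail <- function(name, msg) {
    abort(sprintf("circuit constraint '%s' failed: %s", name, msg))
  }
  if (p$w_input < p$theta_input) {
    fail("input_relay", "a pixel event must fire its input relay.")
  }
  if (!(p$w_excit < gap(p$theta_out))) {
    fail("single_epsp_subthreshold",
         "one ON or OFF EPSP alone must not fire OUT.")
  }
  if (!(p$w_excit * lam + p$w_excit > gap(p$theta_out))) {
    fail("pairing_suprathreshold",
         "an EPSP residual plus one opposite EPSP within the pairing window must fire OUT.")
  }
  if (!(p$w_block_in < gap(p$theta_block))) {
    fail("blocker_single_subthreshold",
         "one input spike must not fire a blocker.")
  }
  if (!(p$w_block_in * lam + p$w_block_in >= gap(p$theta_block))) {
    fail("blocker_two_spikes",
         "two same-polarity spikes within the pairing window must fire the blocker.")
  }
  if (!(p$w_block_self * lam + p$w_block_in >= gap(p$theta_block))) {
    fail("blocker_reprimes",
         "a primed blocker must fire on every further same-polarity spike.")
  }
  if (!(p$w_inhib >= p$w_excit)) {
    fail("inhibition_cancels",
         "the blocker IPSP must be at least one OUT EPSP.")
  }
  if (!(p$w_self > gap(p$theta_out) &&
        p$w_self - p$w_inhib > gap(p$theta_out))) {
    fail("self_sustaining",
         "the OUT self-EPSP must re-fire OUT even against one blocker IPSP.")
  }
  if (!(p$w_sync <= -(p$w_self + 2 * p$w_excit))) {
    fail("sync_dominates",
         "the Sync IPSP must dominate self-excitation plus concurrent input.")
  }
  invisible(p)
}

#' Build the five-neuron circuit of one pixel
#'
#' Returns the neuron roles, wiring (pre, post, weight, delay in steps) and
#' a reference to the shared Sync source. The direct input -> OUT delay is
#' two steps while the disynaptic input -> blocker -> OUT path is 1 + 1, so
#' a blocker IPSP always lands on OUT in the same step as the EPSP of the
#' spike that triggered it.
#'
#' @param params A [circuit_params()] (validated on construction).
#' @return An object of class `pixel_circuit`.
#' @export
build_pixel_circuit <- function(params = circuit_params()) {
  validate_circuit_params(params)
  neurons <- c(ON = 1L, OFF = 2L, B_on = 3L, B_off = 4L, OUT = 5L)
  wiring <- tibble::tribble(
    ~pre,    ~post,   ~weight,            ~delay_steps,
    "ON",    "OUT",   params$w_excit,      2L,
    "OFF",   "OUT",   params$w_excit,      2L,
    "ON",    "B_on",  params$w_block_in,   1L,
    "OFF",   "B_off", params$w_block_in,   1L,
    "B_on",  "OUT",  -params$w_inhib,      1L,
    "B_off", "OUT",  -params$w_inhib,      1L,
    "B_on",  "B_on",  params$w_block_self, 1L,
    "B_off", "B_off", params$w_block_self, 1L,
    "OUT",   "OUT",   params$w_self,       1L,
    "Sync",  "OUT",   params$w_sync,       1L
  )
  structure(list(neurons = neurons, sync = "shared", wiring = wiring,
                 params = params),
            class = "pixel_circuit")
}

#' Build the focus-detection network for a region of interest
#'
#' One five-neuron pixel circuit per ROI pixel plus a single Sync neuron
#' shared by the whole array (driven externally by the lens sweep, so it is
#' not counted in the per-pixel budget).
#'
#' @param sensor_shape `c(rows, cols)` of the sensor.
#' @param roi Region of interest, a list with `x = c(x0, x1)` and
#'   `y = c(y0, y1)` in 0-based inclusive pixel coordinates; `NULL` takes
#'   the full sensor.
#' @param params A [circuit_params()].
#' @return An object of class `snn_network`.
#' @examples
#' net <- build_network(c(480, 640), roi = list(x = c(0, 446), y = c(0, 446)))
#' neuron_count(net)
#' @export
build_network <- function(sensor_shape = c(64L, 64L), roi = NULL,
                          params = circuit_params()) {
  validate_circuit_params(params)
  stopifnot(length(sensor_shape) == 2)
  if (is.null(roi)) {
    roi <- list(x = c(0L, sensor_shape[2] - 1L),
                y = c(0L, sensor_shape[1] - 1L))
  }
  if (roi$x[1] > roi$x[2] || roi$y[1] > roi$y[2]) abort("empty roi.")
  if (roi$x[1] < 0 || roi$y[1] < 0 ||
      roi$x[2] >= sensor_shape[2] || roi$y[2] >= sensor_shape[1]) {
    abort("roi outside the sensor.")
  }
  nx <- roi$x[2] - roi$x[1] + 1L
  ny <- roi$y[2] - roi$y[1] + 1L
  structure(list(sensor_shape = as.integer(sensor_shape),
                 roi = lapply(roi, as.integer),
                 n_pixels = as.integer(nx * ny),
                 circuit = build_pixel_circuit(params),
                 params = params),
            class = "snn_network")
}

#' Number of neurons in the network
#'
#' Exactly five per ROI pixel; the shared Sync neuron is excluded by default
#' (it belongs to the lens, not to any pixel).
#'
#' @param network An [build_network()] result.
#' @param include_sync Count the shared Sync neuron too.
#' @return Integer neuron count.
#' @export
neuron_count <- function(network, include_sync = FALSE) {
  stopifnot(inherits(network, "snn_network"))
  5L * network$n_pixels + if (include_sync) 1L else 0L
}

#' @export
print.snn_network <- function(x, ...) {
  cat(sprintf("<snn_network> %d pixels (roi x:%d..%d y:%d..%d), %d neurons + shared Sync\n",
              x$n_pixels, x$roi$x[1], x$roi$x[2], x$roi$y[1], x$roi$y[2],
              neuron_count(x)))
  invisible(x)
}

#' Run the spiking network on an event stream
#'
#' Fixed-step simulation (default step 50 us) with delta-current synapses
#' and exact exponential decay between steps. Each sweep ends with a Sync
#' spike (externally driven by the lens): the Sync IPSP lands one step after
#' `sync_time` and the whole state is reset, so the OUT spike train —
#' started at the first polarity inversion and maintained by
#' self-excitation — stops there, encoding the focus time in the OUT-to-Sync
#' interval.
#'
#' @param network An [build_network()] result.
#' @param events An [event_stream()] (must be time-sorted).
#' @param sync_times Numeric vector of sweep-end times (s), one per sweep,
#'   increasing; each sweep covers the interval from the previous sync (or
#'   the sweep metadata start) to its own sync.
#' @param record `"onset"` (default; first OUT spike and spike count per
#'   pixel) or `"full"` (additionally every OUT spike, for diagnostics).
#' @return An object of class `snn_record`: a tibble with one row per
#'   (pixel, sweep) — `x`, `y`, `sweep`, `onset_us` (first OUT spike, `NA`
#'   if OUT never fired), `n_out_spikes`, `sync_us` — with attributes
#'   `ignored_events` (events outside the ROI) and, for `record = "full"`,
#'   `out_spikes` (tibble of all OUT spike times).
#' @export
run_network <- function(network, events, sync_times,
                        record = c("onset", "full")) {
  stopifnot(inherits(network, "snn_network"))
  record <- match.arg(record)
  p <- network$params
  dt <- p$dt
  ev <- tibble::as_tibble(events)
  if (nrow(ev) && is.unsorted(ev$t_us)) {
    abort("event stream is not time-sorted.")
  }
  if (length(sync_times) < 1 || is.unsorted(sync_times, strictly = TRUE)) {
    abort("`sync_times` must be a nonempty increasing vector.")
  }
  roi <- network$roi
  inside <- ev$x >= roi$x[1] & ev$x <= roi$x[2] &
    ev$y >= roi$y[1] & ev$y <= roi$y[2]
  ignored <- sum(!inside)
  ev <- ev[inside, , drop = FALSE]

  nx <- roi$x[2] - roi$x[1] + 1L
  n <- network$n_pixels
  sweep_meta <- attr(events, "sweep")
  seg_start0 <- if (!is.null(sweep_meta)) sweep_meta$t_start else
    min(0, if (nrow(ev)) min(ev$t_us) * 1e-6 else 0)

  res <- vector("list", length(sync_times))
  full <- if (record == "full") list() else NULL
  prev_sync <- seg_start0
  tsec <- ev$t_us * 1e-6
  for (si in seq_along(sync_times)) {
    sync <- sync_times[si]
    if (sync <= prev_sync) abort("`sync_times` must follow the sweep start.")
    seg <- ev[tsec > prev_sync - 1e-12 & tsec <= sync, , drop = FALSE]
    sim <- simulate_segment(seg, prev_sync, sync, n, nx, roi, p, record)
    onset_us <- ifelse(is.na(sim$onset_step), NA_real_,
                       (prev_sync + sim$onset_step * dt) * 1e6)
    res[[si]] <- tibble::tibble(
      x = roi$x[1] + (seq_len(n) - 1L) %% nx,
      y = roi$y[1] + (seq_len(n) - 1L) %/% nx,
      sweep = si,
      onset_us = onset_us,
      n_out_spikes = sim$n_spikes,
      sync_us = sync * 1e6
    )
    if (record == "full" && length(sim$spikes)) {
      full[[si]] <- dplyr::mutate(sim$spikes, sweep = si)
    }
    prev_sync <- sync
  }
  out <- dplyr::bind_rows(res)
  structure(out,
            class = c("snn_record", class(out)),
            ignored_events = ignored,
            dt = dt,
            params = p,
            out_spikes = if (record == "full") dplyr::bind_rows(full) else NULL)
}

# Vectorized fixed-step simulation of one sweep segment. Pixels are columns;
# the five neuron populations are five state vectors. Scheduling matrices
# hold future synaptic deliveries (rows = steps).
simulate_segment <- function(seg, t0, sync, n, nx, roi, p, record) {
  dt <- p$dt
  sync_step <- max(1L, as.integer(ceiling((sync - t0) / dt - 1e-9)))
  S <- sync_step + 1L # one extra step so the Sync IPSP lands and is observable
  pid <- (seg$y - roi$y[1]) * nx + (seg$x - roi$x[1]) + 1L
  step <- as.integer(ceiling((seg$t_us * 1e-6 - t0) / dt - 1e-9))
  step[step < 1L] <- 1L
  step[step > sync_step] <- sync_step
  on_by_step <- split(pid[seg$p > 0], step[seg$p > 0])
  off_by_step <- split(pid[seg$p < 0], step[seg$p < 0])

  lam <- exp(-dt / p$tau_m)
  rest <- p$v_rest
  v_on <- v_off <- v_bon <- v_boff <- v_out <- rep(rest, n)
  sched_out <- matrix(0, S + 2L, n)
  sched_bon <- matrix(0, S + 2L, n)
  sched_boff <- matrix(0, S + 2L, n)
  # externally driven Sync spike at the sync step; IPSP one delay later
  sched_out[sync_step + 1L, ] <- sched_out[sync_step + 1L, ] + p$w_sync

  onset_step <- rep(NA_integer_, n)
  n_spikes <- integer(n)
  spikes <- if (record == "full") vector("list", S) else NULL

  for (s in seq_len(S)) {
    v_on <- rest + (v_on - rest) * lam
    v_off <- rest + (v_off - rest) * lam
    v_bon <- rest + (v_bon - rest) * lam
    v_boff <- rest + (v_boff - rest) * lam
    v_out <- rest + (v_out - rest) * lam

    v_out <- v_out + sched_out[s, ]
    v_bon <- v_bon + sched_bon[s, ]
    v_boff <- v_boff + sched_boff[s, ]
    key <- as.character(s)
    ion <- on_by_step[[key]]
    ioff <- off_by_step[[key]]
    if (length(ion)) v_on[ion] <- v_on[ion] + p$w_input
    if (length(ioff)) v_off[ioff] <- v_off[ioff] + p$w_input

    s_on <- v_on >= p$theta_input
    s_off <- v_off >= p$theta_input
    s_bon <- v_bon >= p$theta_block
    s_boff <- v_boff >= p$theta_block
    s_out <- v_out >= p$theta_out
    v_on[s_on] <- p$v_reset
    v_off[s_off] <- p$v_reset
    v_bon[s_bon] <- p$v_reset
    v_boff[s_boff] <- p$v_reset
    v_out[s_out] <- p$v_reset

    if (any(s_out)) {
      first <- s_out & is.na(onset_step)
      onset_step[first] <- s
      n_spikes[s_out] <- n_spikes[s_out] + 1L
      if (record == "full") {
        spikes[[s]] <- tibble::tibble(pixel = which(s_out), step = s)
      }
    }

    if (s + 2L <= S + 2L) {
      if (any(s_on)) {
        sched_out[s + 2L, s_on] <- sched_out[s + 2L, s_on] + p$w_excit
        sched_bon[s + 1L, s_on] <- sched_bon[s + 1L, s_on] + p$w_block_in
      }
      if (any(s_off)) {
        sched_out[s + 2L, s_off] <- sched_out[s + 2L, s_off] + p$w_excit
        sched_boff[s + 1L, s_off] <- sched_boff[s + 1L, s_off] + p$w_block_in
      }
      if (any(s_bon)) {
        sched_out[s + 1L, s_bon] <- sched_out[s + 1L, s_bon] - p$w_inhib
        sched_bon[s + 1L, s_bon] <- sched_bon[s + 1L, s_bon] + p$w_block_self
      }
      if (any(s_boff)) {
        sched_out[s + 1L, s_boff] <- sched_out[s + 1L, s_boff] - p$w_inhib
        sched_boff[s + 1L, s_boff] <- sched_boff[s + 1L, s_boff] + p$w_block_self
      }
      if (any(s_out)) {
        sched_out[s + 1L, s_out] <- sched_out[s + 1L, s_out] + p$w_self
      }
    }
  }
  sp <- NULL
  if (record == "full") {
    sp <- dplyr::bind_rows(spikes)
    if (nrow(sp)) {
      sp$t_us <- (t0 + sp$step * dt) * 1e6
      sp$x <- roi$x[1] + (sp$pixel - 1L) %% nx
      sp$y <- roi$y[1] + (sp$pixel - 1L) %/% nx
    }
  }
  list(onset_step = onset_step, n_spikes = n_spikes, spikes = sp)
}

#' Focus times decoded from a network run
#'
#' The focus time a pixel circuit reports is its first OUT spike corrected
#' for the known decoding constants: the two-step feed-forward synaptic
#' latency of the direct input path, and half a step to center the estimate
#' in the quantization bin of the triggering event. Pixels whose OUT never
#' fired are invalid.
#'
#' @param rec An [run_network()] result.
#' @param sweep Which sweep to decode (default 1).
#' @return A tibble `x`, `y`, `t_f_us`, `valid`, `ambiguous` (always `NA`
#'   here: the spiking pathway does not flag multi-inversion trains; use
#'   [detect_focus_times()] for that diagnostic).
#' @export
snn_focus_times <- function(rec, sweep = 1L) {
  stopifnot(inherits(rec, "snn_record"))
  dt_us <- attr(rec, "dt") * 1e6
  rec |>
    tibble::as_tibble() |>
    dplyr::filter(.data$sweep == !!sweep) |>
    dplyr::transmute(
      x = .data$x, y = .data$y,
      t_f_us = .data$onset_us - 2 * dt_us - dt_us / 2,
      valid = !is.na(.data$onset_us),
      ambiguous = NA
    )
}
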
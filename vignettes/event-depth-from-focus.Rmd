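---
title: "Event-based depth from focus: model, circuit, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-based depth from focus: model, circuit, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventdff)
```

## The measurement principle

An event camera does not produce frames. Each pixel watches its own
log-intensity and emits an *ON* event when it has risen by a contrast
threshold $n$ since the pixel's last event, or an *OFF* event when it has
fallen by $n$. When such a camera looks through an optical system whose
in-focus distance $d(t)$ is swept by an electrically tunable liquid lens,
every object edge first sharpens (contrast rising, one polarity) and then
blurs again (contrast falling, the opposite polarity). The instant a pixel's
event polarity inverts is the moment the object in front of it was in focus,
and the in-focus distance at that instant *is* the object's metric depth.
Depth estimation therefore reduces to timestamping one polarity inversion
per pixel — no frames, no deconvolution, no search over blur scales.

`eventdff` implements this measurement end to end in simulation:

1. **optics** — blur-circle geometry, Gaussian point-spread function (PSF),
   thin-lens conjugates, hyperfocal limit, and the closed-form inversion
   from blur back to depth;
2. **scene simulation** — rendering depth-labelled reflectance maps through
   the time-varying blur and converting per-pixel log-intensity
   trajectories into ON/OFF address-events;
3. **focus detection** — both a five-neuron-per-pixel spiking circuit (the
   actual algorithm) and a non-spiking polarity-inversion detector used as
   its reference;
4. **depth assembly** — mapping focus times through the sweep trajectory to
   metric depth, with validity and ambiguity masks and error metrics.

## Optical model

For an object at depth $z$ with the system focused at $d$, the diameter of
the geometric blur circle is

$$ s(z, d) \;=\; \frac{f_{eq}^2}{N}\,\frac{|z - d|}{(d - f_{eq})\,z}, $$

with $f_{eq}$ the equivalent focal length of the compound system and $N$
its f-number. The formula is usually written with the focus held and the
object moving; during a sweep the roles invert ($z$ fixed, $d(t)$ moving),
but $s$ is the same symmetric function of the pair, and the implementation
treats it that way. Diffraction and aberrations smear the ideal disc into
an approximately Gaussian spot of spread $\sigma = \alpha s$. Solving the
first equation for $z$ gives the off-focus depth inversion exposed as
`depth_from_focus()`; its two sign branches correspond to objects nearer or
farther than $d$, bracket $d$, and coincide there when $s = 0$. At the
detected inversion the object is by construction at the in-focus distance,
so the default decoder simply takes $z = d(t_f)$ and the branch machinery
is exercised by the round-trip test suite instead.

Two more standard relations close the model: the thin-lens conjugate
$d = f_{eq} + f_{eq}^2 / (D - f_{eq})$ linking the camera-to-object
distance to the focus position, and the hyperfocal distance
$H = f_{eq}^2/(N\,c) + f_{eq}$ (circle of confusion $c$, one pixel pitch by
default) beyond which depth cannot be resolved; `assemble_depth_map()`
never reports a depth at or past $H$ as valid.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `f_eq` | 0.0297 | m | thin-lenses-in-contact combination of a 50–120 mm liquid lens (taken mid-range), a −150 mm offset lens and a 35 mm objective; the true value depends on unpublished lens separations, so `f_eq` is a direct config knob and the combination is explicitly approximate |
| `N` | 2 | — | the objective is an f/2 |
| `alpha` | 0.5 | — | classic choice: Gaussian spread ≈ blur-circle radius |
| `pixel_pitch` | 15e-6 | m | VGA-format event sensor |
| `event_threshold_n` | 0.15 | — | conventional contrast-detector setting; the emulated sensor's own threshold is tuned per scene and never published, so this default is a package choice |
| sweep | 0.12 → 5.5 m in 5 ms | | the system's working depth range; 5 ms per sweep |

The sweep trajectory is linear in optical power ($1/d$, diopters) because a
liquid lens's power tracks its drive current; a linear-in-$d$ option exists
for experiments. Monotonicity of $d(t)$ is what makes the focus time
invertible to a unique depth, and is enforced.

## Event generation

Frames are rendered along the sweep (default step 25 µs) by convolving each
depth layer with a normalized Gaussian kernel of $\sigma(z, d(t))$ in
pixels and compositing far-to-near over the background; occlusion
blur-bleeding between layers is deliberately not modeled. Each pixel then
ratchets a reference: whenever the current log-intensity is $\pm n$ away
from it, an event is emitted and the reference steps by exactly $\pm n$, so
a change of $k\,n$ inside one render step yields $k$ events (the alternative
reading — reset-to-current — leaves multi-event bursts ill-defined, which
is why step-by-$n$ was chosen). Event times are interpolated linearly
within the render step and quantized to 1 µs, the temporal resolution of
the modeled sensor. No refractory period is applied by default (one is
available), and sensor noise is out of scope.

One modeling wrinkle deserves a note. The closed-form crossing-time
prediction for a Gaussian spot is derived with a *constant* amplitude
$I = A\exp(-r^2/2\sigma^2)$, while an energy-conserving renderer
necessarily dims a point source's peak as it defocuses. The renderer
therefore has two modes: the default normalized kernel for scenes, and a
unit-peak amplitude mode (`normalize = FALSE`) that realizes the
constant-$A$ spot exactly and is what the closed-form oracle is checked
against. In that check the render step is halved twice and the simulated
timestamps converge to the analytic crossing times; the comparison is made
on crossing indices that are resolved at every step size, because the final
collapse of the spot through focus happens inside a single coarse step and
the events it produces only appear at finer resolution.

## The spiking focus detector

Per pixel, five leaky integrate-and-fire neurons: ON and OFF input relays,
two blockers $B_{on}$/$B_{off}$, and an output neuron OUT; one Sync neuron,
driven by the lens at the end of each sweep, is shared by the whole array
(hence exactly $5 \times \text{pixels}$ neurons per region of interest).
The intended behavior is purely relational: a single EPSP must not fire
OUT; an EPSP residual plus one opposite-polarity EPSP must; two
same-polarity spikes arm the corresponding blocker, whose inhibition keeps
runs of one polarity from ever summing to threshold; OUT is self-excitatory,
so its first spike — the focus mark — starts a train that persists until the
Sync inhibition and state reset end it. Depth is encoded in the OUT→Sync
interval.

The published description gives no weights or time constants, so the
defaults here were *derived* from those constraints rather than copied,
and the constructor validates every constraint by name. Two choices matter
and were far from obvious:

* **Delay layout.** The direct input→OUT path takes two simulation steps
  while the disynaptic input→blocker→OUT path takes 1 + 1. A blocker IPSP
  therefore lands on OUT in the *same step* as the EPSP of the spike that
  armed it, cancelling it exactly (`w_inhib = w_excit`). With any other
  layout the EPSP arrives first and a fast same-polarity pair fires OUT
  spuriously before inhibition can act.
* **Long membrane window.** All circuit neurons use $\tau_m = 50$ ms,
  an order of magnitude longer than the 5 ms sweep. With exact
  cancellation, a same-polarity run leaves only its *first* EPSP as a
  persistent residual (bounded below one threshold gap, so the run can
  never fire OUT on its own), and that residual is precisely what pairs
  with the first opposite-polarity event to cross threshold at the
  inversion. A short membrane window cannot do both jobs at once: any
  leak fast enough to forget a dense run also forgets the residual the
  pairing needs. State hygiene across sweeps is the Sync reset's job, not
  the leak's.

The blockers also self-prime (a sub-threshold self-EPSP after each spike)
so they fire on *every* same-polarity spike from the second one onward, not
merely on even-numbered ones; without this, run-length parity leaks into
the membrane state at the inversion.

The simulation itself is fixed-step (50 µs default) with delta-current
synapses and exact exponential decay between steps, vectorized across
pixels. Decoding subtracts two known constants from the first OUT spike
time: the two-step feed-forward latency, and half a step to center the
estimate within the quantization bin of the event that triggered it. Both
are structural properties of the simulator, not fitted values.

### Spiking vs. reference detector

The non-spiking reference (`detect_focus_times()`) scans each pixel's train
for adjacent opposite-polarity pairs, takes the pair with the smallest gap,
and returns the midpoint of that pair (averaging midpoints on ties). The
two detectors differ by construction: the circuit marks the *first* event
after the inversion, the reference the midpoint of the straddling pair, so
they agree to within half the inversion gap. On textured surfaces — where
every pixel sits within a couple of pixels of a contrast edge and inversion
gaps are tens of microseconds — the two agree within two simulation steps
on essentially all pixels, which is what the cross-validation test asserts.
On wide featureless surfaces the gap (and hence the circuit's late bias)
grows linearly with a pixel's distance from the nearest edge; this is a
property of the measurement principle, not of either implementation, and is
the reason the bundled fixtures carry fine texture (see below).

## Fixtures: what they emulate and what they do not

All fixtures are generated programmatically, deterministic given a seed,
and default to small frames (64×64, or 64×96 for the two-bar scenes) so the
whole suite runs in seconds; the emulated sensor itself is 640×480 and the
network builder is exercised at full scale only for neuron accounting.

* `sphere` — a textured disc at one depth: the canonical single-object
  sweep. The texture is a 2-px checkerboard (reflectance 0.2/0.8), chosen
  from the gap analysis above: with the default optics the PSF spread
  crosses pixels at roughly $\alpha (f_{eq}^2/N)\,|\dot p|/\text{pitch}
  \approx 24$ px/ms, so keeping every object pixel within ~1 px of an edge
  keeps inversion gaps well under two simulation steps.
* `multi_depth` — three to five textured planes between 0.2 and 1.5 m
  (defaults 0.3/0.6/1.2 m): the parameter-recovery scene the acceptance
  script measures.
* `two_edges_far` / `two_edges_near` — the documented failure geometry:
  two plain vertical bars whose inner edges either stay outside each
  other's blur reach or overlap during the sweep. In the near case the
  overlap superimposes opposite polarities on the same pixels between the
  two focus times; the reference detector flags those pixels as ambiguous,
  and the circuit — which trusts the first opposite pair it sees — deduces
  depths that match neither object. The bars are full-height and 20 px
  wide: narrower bars make even the *separated* case non-monotone at flank
  pixels (the far edge's tail concentrates as blur shrinks), which would
  blur the dichotomy the fixture exists to show.
* `textured_plane`, `bar`, `uniform` — a full-frame random-texture plane,
  a single plain bar, and a featureless static scene (which must and does
  produce zero events).

What passing on these fixtures does **not** show: robustness to sensor
noise (shot noise, background activity, pixel mismatch are not modeled),
to real liquid-lens hysteresis, or to scenes whose surfaces are locally
featureless — there the late-bias analysis above applies and the reported
depth of an extended blank surface is systematically beyond its true depth.

## Numerical choices and degenerate inputs

* Blur kernels are truncated at radius $3\sigma$ (renormalized) and capped
  at a 12-px spread with a warning; far out of focus the image is
  featureless either way, and the cap bounds kernel cost. Frames near the
  image border use replicated-edge padding, which mildly distorts
  trajectories within a kernel radius of the border.
* Intensities are floored at $10^{-6}$ before logs, with a warning, so
  black backgrounds are representable.
* Sub-microsecond convergence studies can disable timestamp quantization
  (`quantize = FALSE`); everything user-facing stays in integer µs.
* Ties in the reference detector (several equally small gaps) average the
  candidate midpoints and set the ambiguity flag; the leading polarity is
  the majority of the first half of the train, which is robust to isolated
  stragglers. Whether asymmetric ON/OFF runs should weight the average is
  left as stated — unweighted midpoints.
* Focus times outside the sweep window invalidate their pixel (counted on
  the map); depths at or beyond the hyperfocal are masked.
* The problem sizes used throughout — 64-px fixtures, 25 µs render step,
  50 µs network step, $10^4$ draws for the inversion round-trip — are the
  package's chosen study conditions and are stated in the tests that use
  them.

## Known limitations

* The equivalent focal length uses the lenses-in-contact approximation by
  default, so the package's working depth range cannot be certified to
  match any particular physical rig; measure and set `f_eq` for real use.
* The event model is noise-free and refractory-free by default; real
  streams will need the refractory option and possibly pre-filtering.
* Multi-inversion disambiguation (e.g. by changing viewpoint) is out of
  scope; ambiguous pixels are flagged, not repaired.
* The HDF5 event layout is not provided — the CSV interchange format
  (`t_us,x,y,p`) is the supported one and round-trips bit-exactly.
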
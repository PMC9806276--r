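---
title: "Methods: from camera frame to nozzle, and how spotspray models it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from camera frame to nozzle, and how spotspray models it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotspray)
```

## The system being modelled

A boom sprayer carries downward-looking cameras at ~1 m height; an
onboard computer detects weeds in each frame and opens only the solenoid
nozzles whose ground lanes contain a weed. `spotspray` implements this
decision chain — calibration, detection, grid decision, wire protocol,
actuation limits — together with a field-pass simulator that reproduces
the statistical bookkeeping of a spray trial. This vignette records the
models, the parameters that matter, and the design decisions taken where
more than one reasonable choice existed.

## Geometry and the real-time constraint

The boom of width $B$ is split evenly over $n$ cameras with no overlap,
so one camera's pixel subtends

$$\text{mm/px} = \frac{B/n \times 1000}{W_\text{px}}$$

For the reference rig ($B = 3.3$ m, $n = 2$, $W_\text{px} = 1920$) this
is 0.859375, conventionally quoted as 0.859 mm/px. The scale is carried
unrounded internally; the 3-decimal value is used only where a quoted
figure depends on it (the 60-px grille row's 51.54 mm ground width is
$60 \times 0.859$). Mount height is configuration metadata: the scale is
fixed by boom span and pixel width, not by an optics model, so lens
distortion and perspective are explicitly out of scope.

Between two processed frames the vehicle advances $v / f$ (speed over
frame rate, ~41.6 mm at 4 km/h and 26.73 fps). The decision band must be
at least this deep on the ground or strips of soil pass unscanned;
`check_grille_constraint()` reports the margin and the simulator warns
when a configuration violates it. The constraint is monotone in speed —
speeding up can only break it, never repair it.

## The grille decision algorithm

A single row of `n_cells` cells tiles the image width exactly; cell
widths differ by at most one pixel (the remainder goes to the leftmost
cells — the tiling, not the paper's figure, dictates this choice). All
rectangles are 0-based half-open pixel rectangles, so intersection areas
are exact integers for integer inputs and the analytic
`max(0, overlap_x) * max(0, overlap_y)` equals pixel-by-pixel
rasterisation, which the test suite checks on a thousand random pairs.

A cell's bit is set when some box's overlap is **strictly greater** than
`area_threshold_px2`. The threshold defaults to 0: any positive overlap
opens the valve, maximising coverage redundancy, which is the stance the
hardware's design rationale (vibration, drift, placement error) argues
for. The threshold is absolute area rather than a fraction of cell area;
both readings are defensible and the absolute form keeps the
strict-inequality boundary semantics exact — a fraction can be emulated
by multiplying the cell area. Decisions are stateless per frame; no
cross-frame tracking is attempted (a deliberate non-goal: the band is
deep enough that per-frame re-evaluation suffices).

The grille row sits at the bottom of the frame by default, because the
ground image scrolls downward as the machine advances; `row_top_px` is
configurable, and any camera-to-nozzle offset or processing latency is a
simulator parameter defaulting to 0 (the source system does not state
either, and both default-zero choices are flagged in reports).

## Wire protocol and actuation limits

The frame layout (`0xAA`, valve count, LSB-first payload, XOR checksum)
is this package's own specification — the modelled system sends "a data
frame" without giving a wire format — documented bit-exactly so an
independent implementation interoperates. Decoding errors carry distinct
condition classes; the consumer holds the previous valve state for at
most 3 bad frames and then closes everything. The hold-then-close policy
is an invented fail-safe: holding bridges transient corruption, closing
bounds how long a corrupt link can keep spraying.

Solenoid valves cycle at 10 Hz at most, and small weeds need a base
opening time before the liquid atomises. `apply_rate_limit()` therefore
(1) extends every open interval to `min_open_s` (default 0.1 s, one full
10 Hz cycle), and (2) merges any open that would begin sooner than
`1/max_freq` after the previous one. Both operations only extend or
merge, so shaped coverage is always a superset of requested coverage —
the limiter never *causes* a miss, it can only overspray.

## The detector

The network is the standard single-stage layout: a MobileNetv3 backbone
truncated at its stride-8/16/32 stages, a squeeze-and-excitation (SE)
block appended to each of the three backbone outputs, a PANet neck
(top-down feature-pyramid fusion then a bottom-up path, fusing by
channel concatenation), and three heads with $3\times(5+C)$ channels.
Design choices where the source is silent:

* **Small vs Large backbone**: Small. It matches the reported model-size
  scale and the edge-compute intent; the layer table is data, swappable.
* **SE reduction ratio**: 4 (the MobileNetv3 convention), both inside
  bottlenecks and after the backbone outputs.
* **SE gate**: logistic sigmoid everywhere, so gates are strictly inside
  $(0,1)$; the hard-sigmoid variant saturates to exact 0/1 and would
  break that invariant.
* **Neck widths**: one common width (default 64, scaled by
  `width_mult`) for laterals and fusion convolutions — topology is
  specified, widths are not, and a uniform width keeps concatenations
  regular. Widths are logged via `n_parameters()` and the printed model.
* **Loss**: $\lambda_1 L_{cls} + \lambda_2 L_{loc} + \lambda_3 L_{obj}$
  with BCE for class and objectness and mean-squared error on the
  decoded box (centre in grid units; width/height as multiples of the
  anchor) for $L_{loc}$. The balance defaults $(0.5, 0.05, 1.0)$ follow
  single-stage convention; none are given by the source. MSE was chosen
  over an IoU-family localisation loss because its gradient is simple
  and exact — the package's backward passes are all hand-written and
  verified against central finite differences, and that verification is
  worth more here than the last percent of box accuracy.
* **Positive assignment**: cross-grid matching — a target claims its
  cell plus the horizontal and vertical neighbours within half a cell,
  on anchors within a 4:1 size ratio. Ties on one (cell, anchor) slot
  keep the first target in input order.

Everything runs in base R: convolutions are evaluated by kernel-offset
decomposition ($k^2$ strided-slice matrix products in BLAS), batch
normalisation uses per-channel spatial statistics (the training loop
steps one image at a time), and Adam follows a cosine-annealed learning
rate from `lr_max` to `lr_min`. The checkpoint is the lowest-mean-loss
epoch among the final 20% of epochs, where the annealed rate is small
and losses stable. One global seed fans out to deterministic sub-seeds
per stage (`derive_seed`), so adding a stage never perturbs another
stage's random stream.

A note on gradient checking: at a freshly initialised network every BN
output is exactly zero-mean, so SE pre-activations sit numerically *on*
the ReLU kink and two-sided finite differences disagree with any valid
subgradient there. The tests jitter parameters before differencing; this
is a property of the check, not of training, which leaves the kink after
one step.

Training at published scale (640-px input, 300 epochs, thousands of
images) is a GPU workload and out of scope; the architecture is the
same object at any `input_size` divisible by 32 and any `width_mult`,
and the package demonstrates optimisation end to end by overfitting 10
synthetic 64-px images for 50 epochs (loss falls below 10% of its
initial value in about 40 s on one CPU). The full-width network is still
built and run at 640 px in the tests to pin the stride-8/16/32 output
geometry and the parameter budget ($< 4\times10^6$).

**Evaluation.** Greedy confidence-ordered one-to-one matching at IoU
0.5; precision and recall as percentages, F1 as their harmonic mean, and
AP as the exact all-points area under the precision envelope (not the
legacy 11-point approximation — the definition is a continuous
integral). PR points are taken per *distinct* confidence level, so
detections tied in confidence enter the curve together and AP is
invariant to their ordering; a per-rank curve would not be. TN is
recorded in the counts structure but no formula consumes it.

## Spray-trial accounting

With $N$ weeds, $I$ identified and $H$ hit:
$u = I/N$, $w' = H/I$, $w = H/N$, and $w = u \times w'$ holds exactly on
unrounded rates for every valid count triple. Reported percentages are
**truncated** to 2 decimals, because that is the convention the
published trial table actually follows (86.4078% prints as 86.40;
half-up rounding would print 86.41 and fail to reproduce two of the nine
table entries). Composing truncated percentages can sit up to ~0.02
points below the direct ratio; the tests assert that bound. When $I = 0$
the relative rate is undefined and is reported as 0 with an explicit
degenerate flag.

## The field-pass simulator

`generate_scene()` draws weed positions as a homogeneous spatial Poisson
process (density in weeds/m², default plot 20 × 3 m, the trial-plot
size) and canopy radii from a log-normal (median ~45 mm — a young
rosette-stage weed, the growth stage at which targeted weeding is done).
`render_frame()` draws each canopy as an irregular green blob (two
angular harmonics modulating the radius) on textured soil, with optional
shadow / wet-soil / overexposure / occlusion styles emulating the
awkward imaging conditions a field camera meets; ground-truth boxes are
the canopy bounding squares, clipped to the image.

`simulate_pass()` advances the camera footprints frame by frame and
couples the real modules end to end: per-frame Bernoulli detection of
weeds overlapping the grille band → `decide_frame()` on the resulting
pixel boxes → `apply_rate_limit()` → ground strips
(`coverage_map()`: travel during the open interval plus a redundancy
margin defaulting to the band depth) → per-weed hit test. Ground lanes
are derived from the *same* pixel cells as the decisions, so lane
assignment and decision cell agree exactly; a weed near a boundary may
be covered by either neighbouring lane.

Two invented, configurable mechanisms emulate the empirically reported
speed degradation, which field observation attributes to terrain-induced
vibration: detection quality decays as
$p_\text{eff} = p \cdot e^{-q v}$ (default $q = 0.06$ per km/h), and
each sprayed strip is displaced by a lateral and longitudinal
$\mathcal{N}(0, \sigma_0 v)$ draw (default $\sigma_0 = 5$ mm per km/h —
centimetre-scale nozzle excursions at working speeds, enough to push
boundary weeds out of their lane). These defaults were fixed once, from
plausibility, to reproduce the qualitative 2→4 km/h decline; no claim is
made of matching the published trial numbers quantitatively, and the
package's statistical checks are calibration properties instead: the
empirical recognition count must fall inside the binomial interval
implied by $p_\text{eff}$ and each weed's frames-in-band, ideal
parameters must give exactly 100/100/100, and the mean absolute hit rate
over 50 paired seeds (common random numbers across speeds) must be
non-increasing in speed.

The hit criterion is "canopy centre inside a sprayed strip" — the
simplest testable proxy for a water-sensitive label on a leaf; an
area-coverage criterion (`hit_criterion = "area"`, midpoint quadrature
on a 21×21 grid) is available behind configuration.

What the generator deliberately does not model: real plant morphology
and occlusion between plants, droplet drift and atomisation physics,
pump pressure dynamics, terrain profiles, camera synchronisation.
Passing the simulator's tests therefore demonstrates the correctness and
calibration of the decision chain, not field performance of any real
detector or sprayer.

## Numerical choices and degenerate inputs

* Half-open integer pixel rectangles everywhere; intersection areas are
  exact, and the decision threshold uses strict inequality.
* `round_half_up()` for quoted figures (0.859; 51.54); truncation for
  trial-table percentages (see above); unrounded values carried
  internally.
* Anchor K-means uses 1−IoU distance with mean updates; empty clusters
  retain their centroid; initialisation is a seeded draw of k boxes;
  anchors are sorted by area. Identical inputs give identical anchors.
* BN epsilon $10^{-5}$; BCE evaluated in the numerically stable
  softplus form; sigmoid gates never reach 0 or 1 in finite arithmetic.
* Zero-denominator rates (no detections, no truths, nothing identified)
  are defined as 0 and flagged rather than NaN.
* Empty box lists, empty scenes and zero-density processes are valid
  inputs throughout.

## Problem sizes in the shipped tests

The suite runs the full-width network once at 640 px, trains the
toy-width network (≈80k parameters) on 10 images for 50 epochs, checks
the protocol on all 256 eight-valve frames plus 10,000 random vectors,
compares 1,000 grille intersections against rasterisation, and runs 150
simulated passes (3 speeds × 50 paired seeds) over a 60-weed plot plus
one 550-weed pass for the binomial calibration check. These sizes were
chosen so the whole suite exercises every code path at statistically
meaningful scale on a single CPU.

## Known limitations

* The detector trains at toy scale only; no claim about accuracy on real
  field imagery is made or testable here.
* JPEG images are not read (no JPEG codec among the dependencies); the
  synthetic pipeline uses PNG.
* The simulator's vibration and quality-decay models are mechanism
  emulations with two free parameters each, not fitted physical models.
* Camera overlap, lens distortion and multi-row grilles are out of
  scope by design.
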
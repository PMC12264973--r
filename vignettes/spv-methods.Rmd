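---
title: "Raster-scheduled simulated prosthetic vision: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Raster-scheduled simulated prosthetic vision: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spvsim)
```

## The problem

Epiretinal implants evoke phosphenes — localized flashes of light — by
electrically stimulating retinal ganglion cells and their axons. Charge-safety
limits prevent all electrodes from firing at once, so real devices partition
the array into *timing groups* that fire in rapid succession; we call the
spatial arrangement plus activation order of these groups a *raster pattern*.
`spvsim` simulates the percepts such a device produces, so that raster
patterns can be compared quantitatively (and by a virtual observer) without an
implant user or a VR lab.

The simulated device is a 10×10 electrode grid at 400 µm pitch centered on
the fovea, roughly an Argus II-class geometry spanning about 14–15° of visual
field. Per render frame (90 Hz) the pipeline runs: stimulus preprocessing →
gaze-contingent shift → raster group selection → electrode activation →
axon-map spatial model → leaky-integrator temporal model → percept frame.

## Coordinates and units

All geometry lives in a single retinal frame documented in `?retina_spec`:
micrometers on the retina, fovea at the origin, +x nasal, +y superior (right
eye), optic disc at (15°, 2°), horizontal raphe along `{y = 0, x < 0}`.
Degrees of visual field convert to retinal micrometers through one linear
constant, `um_per_degree` (default 280 µm/°, a standard human value). The
constant is configurable because published FOV figures for this array
geometry are mutually inconsistent (≈15° vs 14.6° for the same 10×10/400 µm
array); at 280 µm/° the 4000 µm footprint maps to 14.3°. The retina-to-field
image inversion is absorbed into the convention: percept fields are plotted
on the same axes as the stimulus.

## Spatial model: the axon map

Epiretinal stimulation activates not only somas near the electrode but also
passing axon bundles, producing elongated, comet-shaped phosphenes. The
brightness of percept-grid sample $(r, \theta)$ is

$$
b_I(r, \theta) \;=\; \max_{p \in R(\theta)} \sum_{e \in E}
a_e \, \exp\!\left( \frac{-d_e^2}{2\rho^2} + \frac{-d_{\mathrm{soma}}^2}{2\lambda^2} \right),
$$

where $R(\theta)$ is the axon path terminating at the sample, $d_e$ the
distance from path point $p$ to electrode $e$, $d_{\mathrm{soma}}$ the arc
length from $p$ back to the cell body, $\rho$ the radial spread and $\lambda$
the axonal elongation (both µm; defaults 300 and 1000, realistic values for
current epiretinal devices). $a_e \in [0,1]$ is the electrode amplitude —
the equation's electrode term is weighted linearly by amplitude, the minimal
extension consistent with gray levels being interpreted as current
amplitudes. The **max over the path** (not a sum) is essential: it produces
the merging, elongation and asymmetric-brightness interactions seen with
simultaneous multi-electrode stimulation, and it is why per-electrode
percepts are never precomputed and added — `phosphene_basis()` instead
stores electrode-distance Gaussians per path point and evaluates the
max-of-weighted-sums fresh for every frame.

### Axon trajectories

The axon-map literature specifies the model's form but not a canonical
trajectory equation, so the bundle family here is the package's own,
versioned (`"spiral-1"`) so cached maps stay reproducible. In optic-disc-
centered polar coordinates (angle φ measured from the temporal direction,
positive superior), a bundle emitted at angle $\varphi_0$ follows

$$\varphi(r) = \varphi_0 + \mathrm{sign}(\varphi_0)\, \beta(\varphi_0)\,
\left(\tfrac{r - r_0}{10}\right)^{1.7}, \qquad
\beta(\varphi_0) = 15^\circ \sin|\varphi_0|,$$

with $r_0 = 2°$ (the disc edge). Bundles therefore curve away from the
horizontal raphe, strongly for vertical emission angles and hardly at all
for near-horizontal and nasal ones. Any path segment that would cross the
temporal raphe is truncated just before the crossing, so the no-crossing
invariant holds by construction rather than by parameter tuning. Defaults:
500 bundles, 50 µm discretization step.

Each percept sample is assigned to its nearest discretized bundle point
(brute-force nearest neighbor within the percept window plus a 2° margin).
The sample's own axon starts *at the sample* ($d_{\mathrm{soma}} = 0$) and
joins the bundle at that nearest point, with the joining distance counted
toward arc length. This makes the $\lambda \to 0$ limit exactly the radial
Gaussian $\exp(-d^2/2\rho^2)$ at every sample — the closed-form oracle the
test suite checks to $10^{-3}$ — instead of inheriting an
assignment-quantization error of order the discretization step.

### Percept grid

Default 0.25°/sample over ±12° per axis. The configuration validator
enforces that the grid covers the electrode footprint plus a 3ρ margin, so
no phosphene mass is silently cropped. The tests and the acceptance script
run at a documented evaluation scale — 0.5°/sample, 300 bundles, 1–2 s
clips — chosen as the coarsest setting at which every qualitative property
(partition structure, wobble ordering, oracle agreement) is unchanged from
the defaults.

## Temporal model: coupled leaky integrators

Phosphenes fade under sustained stimulation and persist briefly after it.
Two coupled leaky integrators model this per pixel:

$$\frac{dn}{dt} = -\tau_n n + b_I, \qquad
\frac{db}{dt} = -\tau_b b - \alpha n + b_I,$$

with desensitization $n(t)$, perceived brightness $b(t)$, and presets
`"5Hz"` $(\tau_n, \tau_b, \alpha) = (0.2, 5, 0.2)$ and `"20Hz"`
$(0.2, 5, 0.25)$. Two deliberate readings documented here:

* $\tau_n, \tau_b$ are **rate coefficients** (1/s), exactly as the equations
  are written, although they are conventionally quoted in seconds. The
  literal reading gives brightness a fast 0.2 s effective time constant and
  desensitization a slow 5 s one — the physiologically sensible assignment.
* $b$ is clamped at 0 after each step. For the `"5Hz"` preset the algebraic
  steady state $b^* = b_I(1 - \alpha/\tau_n)/\tau_b$ is exactly 0 (complete
  fading) and the transient never goes negative; for `"20Hz"`
  ($\alpha > \tau_n$) the pre-clamp steady state is negative, so the clamp
  is what keeps sustained percepts at zero rather than below it.

Integration is forward Euler at the render step (1/90 s), matching a
per-frame game-engine update. Its truncation error against the exact
solution of the linear system is about 1.2% of the response peak for a 5 s
constant-input clip (first order: halving the step roughly halves it); the
test suite verifies this convergence behavior against an independent
closed-form/matrix-exponential oracle. Applications needing better than
~1% temporal fidelity should reduce `dt`, not reinterpret the parameters.

## Raster scheduling

`raster_clock()` stores the group interval exactly, as an integer number of
render frames: 4 frames at 90 Hz gives the 44.4 ms interval, a 22.5 Hz
group-event rate (exactly 90/4) and a 222.2 ms (4.5 Hz) five-group cycle.
Four patterns partition the array into equal timing groups:

* **horizontal / vertical** — contiguous two-row (two-column) bands,
  scanned top-to-bottom (left-to-right);
* **checkerboard** — the modular family $g(i,j) = (ai + bj) \bmod n$ with
  $(a, b)$ found by exhaustive search maximizing the minimum within-group
  nearest-neighbor distance (ties: smallest $(a,b)$ lexicographically; the
  10×10/5-group optimum is $(1,2)$ at $\sqrt 5 \times$ pitch ≈ 894 µm vs
  1 × pitch for the bands), and the activation order found by exhaustive
  search over the $n!$ permutations minimizing the apparent-motion
  consistency (ties: lexicographic). Both searches are tiny, so the optimum
  is certified, not heuristic;
* **random** — a seeded equal-size partition re-drawn every
  `reshuffle_every` raster frames.

"Re-randomized every five frames" is interpreted as five *raster* frames —
once per full 5-group cycle — so every electrode still fires exactly once
per cycle and the charge-safety partition semantics survive reshuffling.

The **apparent-motion index** quantifies scan coherence: over each
within-cycle group transition, each electrode of the incoming group
contributes its displacement from the nearest electrode of the outgoing
group; `consistency` is the norm of the mean unit displacement. The
cycle-wrap transition is excluded — the jump back to the first group is an
artifact of the index, not of perception. Band scans score consistency 1
(a pure downward or rightward sweep); the certified checkerboard scores
≈ 0.28.

Named conditions: `"main"` (5 groups, 44.4 ms), `"fast"` (5 groups at the
11.1 ms render period — 18 full cycles/s, paired with the `"20Hz"` temporal
preset as the nearest stated parameter set), `"four_group"` (4 groups with
the cycle kept at 4.5 Hz, i.e. 5 render frames per group — chosen over
keeping the 44.4 ms interval, which would change the cycle rate the
condition is named for), and `"no_raster"` (all electrodes every frame,
temporal model still on).

## Stimuli, gaze, and what the generators do not emulate

**Optotypes** are built on the standard 5×5 Sloan stroke grid (stroke = 1/5
letter height), white on black, default 41.1° of visual angle; the
construction is fully reproducible where a font file would not be.
**Moving bars** are full-field bars perpendicular to one of 8 compass
directions, crossing the canvas in the 5 s clip (width 10% of the field).
**Gaze traces** are fixation or smooth-pursuit trajectories with isotropic
Gaussian noise calibrated so the mean radial error equals `noise_deg`
(default 1.9°, matching consumer-VR eye-tracker precision; >94% of samples
fall within 5°). Head movement is folded into the gaze trace — the
simulator consumes a single fixation trajectory. The gaze-contingent step
shifts the frame by minus the gaze in whole pixels (no interpolation) with
zero padding, matching a dark VR surround.

Two things the synthetic setup deliberately does not reproduce:

* **Active scanning.** Human participants scanned the 41.1° letters with
  head and eye movements; the synthetic gaze only jitters around fixation.
  Under central fixation the ±7° implant footprint sees only the central
  strokes of a 41.1° letter — C, D, L and O render identically blank.
  Tests that need every letter distinguishable therefore size the letter
  into the footprint (12°); passing them shows the rendering and observer
  chain is correct, not that fixating observers could read wall-sized
  letters.
* **Human learning and difficulty.** The virtual observer has no learning
  curve and reports no subjective difficulty; human odds ratios are not
  reproduction targets.

## Virtual observer and metrics

The **template observer** compares the time-averaged percept against the 8
alternatives by normalized cross-correlation. Templates are rendered under
the no-raster, temporal-off condition at the evaluation ρ/λ and zero gaze —
the observer carries the same spatial distortions as the signal, so
differences between conditions isolate raster effects. Ties (e.g. an
all-zero percept) fall to the first alternative in fixed order
(alphabetical; compass clockwise from "up"). **Motion decisions** map the
net motion-energy drift onto the nearest compass direction.

**Motion energy** is estimated by brightness-centroid differencing, which
is robust for these near-binary fields. It reports both the signed mean
drift (deg/s; used for direction decisions) and the mean displacement
magnitude per transition ("wobble"). The distinction matters: a cyclic
raster's centroid excursions cancel in the signed mean over whole cycles,
so raster quality is compared on the wobble, where the checkerboard's
spatial interleaving beats the band scans by a factor of several.

**Confusion and bias**: presented × chosen counts over the 8 alternatives,
plus a per-response bias index (that response's share of all error trials).
Row sums equal per-stimulus trial counts by construction.

## Experiments and determinism

`run_experiment()` emits 6 blocks × 8 stimuli (48 trials per condition),
each block a seeded permutation of the alternatives. All randomness — block
orders, gaze noise, random-raster draws, random-observer choices — derives
from one experiment seed through an internal stream, and the package never
touches the caller's RNG state. `(config, seed)` therefore determine every
output byte: trial CSVs, percept PNGs and the YAML config echo re-run to
bit-identical results, which the acceptance checks verify on a full
48-trial condition at the evaluation scale.

## Known limitations

* No pulse-level waveforms, charge-density accounting, electrode–retina
  distance or impedance effects; amplitudes are abstract `[0, 1]` levels.
* The axon family is a documented geometric stand-in, not a fitted
  anatomical atlas; no optic-disc scotoma. Samples just below the temporal
  raphe take their elongation from bundles arcing several degrees below,
  an artifact of nearest-bundle assignment near the watershed.
* Forward Euler at 90 Hz carries ~1% temporal truncation error (above).
* The fixation-bound observer under-uses large stimuli (above); motion
  drift inherits a small nasal bias from the axon tails, which can tip
  near-boundary directions into a neighboring compass bin.
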
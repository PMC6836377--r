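---
title: "Quantifying planarian behavioral assays: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying planarian behavioral assays: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planaquant)
```

## What this package measures

Freshwater planarians are assayed for feeding and orientation behavior in
simple arenas: a 90-mm Petri dish with a piece of food for chemotactic
food-localization, a 60 x 30 mm rectangular field with a lateral light
source for photo-orientation, a stereomicroscope image pair for food intake,
and 240-fps video for ciliary beating. planaquant implements the
quantitative endpoints of these assays, together with a seeded synthetic
generator for every input modality, so each computation can be validated
against known ground truth without animals or recordings.

The endpoints are:

* **Feeding index** `A_f / A_w` — the binarized area of ingested-food
  fluorescence divided by the projected whole-body area, both in pixels.
* **Median gliding speed** — the median of per-interval speeds sampled every
  0.2 s, in mm/s.
* **Percent reaching the food** — the share of animals whose position comes
  within a reach radius (default 5 mm, comparable to the food cube) of the
  food position within a time limit (10, 30 or 60 min).
* **Target-quadrant time** — seconds spent in the quadrant containing the
  food (circular dish) or opposite the light (rectangular field).
* **Food-localization index** — quadrant time compensated to a common
  reference speed (below).
* **Ciliary beat frequency** — dominant temporal frequency of kymograph
  line scans, in Hz.
* **Population growth** — weekly trend across batches with 95% CI and the
  doubling time of the trend.

## Conventions

Rasters are numeric matrices indexed `[row, column]`, 1-based, origin at
the top-left. Trajectory coordinates are in mm with the origin at the arena
center, x rightward and y upward; the raster center maps to the origin when
video is converted to trajectories. Trajectories are sampled uniformly,
nominally every 0.2 s.

## The synthetic walker

No generative model of planarian locomotion accompanies the assays, so the
package uses the minimal model that exhibits the assays' qualitative
behavior: a **biased correlated random walk**. At each 0.2-s step the
heading updates as

$$\theta_{t+1} = \theta_t + \varepsilon_t +
  s\,\kappa\,\sin(\varphi_{goal} - \theta_t),
  \qquad \varepsilon_t \sim N(0, \sigma^2),$$

where $\varphi_{goal}$ points toward the food (or away from the light
edge), $\kappa$ (`kappa_food`) is the maximal steering gain and
$s \in [0,1]$ (`sensitivity`) scales it. The per-step speed is
gamma-distributed with mean `mean_speed` and coefficient of variation
`speed_cv` (gamma has positive support and is the simplest such noise
model; `speed_cv = 0` gives constant speed). `sensitivity` is the model's
stand-in for how strongly the water lets the animal respond to food cues;
`ca_sensitivity()` maps a free-Ca^2+ concentration onto it through a Hill
curve with half-saturation at 0.77 mM (the calcium level of the standard
defined planarian medium) and coefficient 2. That mapping is a modeling
convention for dose-response exploration, not a measured transfer function.

**Boundaries** reflect: a step that would exit the arena is mirrored back
inside and the heading is mirrored across the wall tangent. Reflection
keeps walkers in-arena without the absorbing artifacts of clamping, and
every emitted sample satisfies the containment predicate exactly.

**Start region.** Walkers start uniformly in a 5-mm-radius disc centered
30 mm from the food on the far side through the dish center (the release
point drawn in assay schematics), with `start = "center"` and
`start = "uniform"` as explicit alternatives. Symmetry-based null checks
(the 25% quadrant-occupancy expectation for unbiased walkers) use the
center start, because only a quadrant-symmetric initial condition makes
every quadrant exchangeable over a finite 90-s assay; the offset start
region is deliberately asymmetric.

**Stopping.** By default a walker freezes once within the reach radius of
the food (`stop_on_food`), matching the occupancy hot spot that fed animals
produce at the food.

### Calibration of the defaults

The walk has three free parameters with no measured values: `mean_speed`,
`turn_sigma` and `kappa_food`. They were fixed once, as follows, and are
not adjusted per analysis:

* `mean_speed = 0.5` mm/s — reported median speeds in these assays cluster
  around 0.38–0.60 mm/s; 0.5 mm/s is the midpoint of that range.
* `turn_sigma = 0.8` rad and `kappa_food = 0.1` — the steering gain must be
  small relative to heading noise, otherwise homing is effectively
  deterministic: any bias above a few tenths of `turn_sigma` drives every
  walker to the food well inside 10 min, and the 10-min endpoint saturates
  at 100% for all sensitivities. The chosen ratio places the drift time
  across the 30-mm start-to-food distance in the vicinity of the 10-min
  limit, so the percent-reached endpoint is graded across the sensitivity
  range at 10 min and approaches completeness by 60 min for biased walkers
  — the qualitative dose-response the assay is designed to resolve.

What the generator does **not** emulate: gliding-vs-crawling gait switches,
thigmotaxis (wall-following), inter-animal variability in bias, odor
plume dynamics (the goal direction is exact, not a sensed gradient), and
body shape (walkers are points; rasterization draws discs). Passing
round-trip tests therefore validates the computations, not the realism of
planarian paths.

## Feeding image analysis

`segment_body()` thresholds the body channel, fills holes, and keeps the
largest connected component — one animal per image is assumed, and images
with a dark body on a light background must be inverted first.
`quantify_feeding()` thresholds the fluorescence channel and counts `A_f`
**only inside the body mask**: fluorescence semantics are "ingested food",
so background speckle outside the animal is excluded (this restriction also
guarantees the index lies in [0, 1]). The identity
`feeding_index * A_w = A_f` holds exactly for every result.

Binarization uses Otsu's method computed on each image's own intensity
range, making the index invariant under rescaling of both channels; a fixed
numeric threshold can be supplied instead and is recorded in the result.
The original assay's threshold value is unknown, which is why the default
is a deterministic, data-driven rule rather than a hand-picked constant.

The synthetic counterpart, `render_feeding_image()`, draws an elliptical
body and grows a connected random blob covering a requested fraction of the
body pixels, storing exact ground-truth counts; `fill_fraction` is
recovered by `quantify_feeding()` within one-pixel rounding on noiseless
renders.

## Trajectory endpoints

**Quadrant geometry.** In the circular dish the target quadrant is the
quarter disc, bounded by two perpendicular diameters through the center,
whose angular bisector passes through the food. It is undefined when the
food sits exactly at the center — synthetic arenas therefore offset the
food (default 22.5 mm, half the dish radius). In the rectangular field it
is the farthest quarter of the long axis from the light edge, across the
full short axis. Membership uses half-open angular/linear intervals so
samples on a dividing line are counted exactly once.

**Dwell accounting.** Each sample owns one sampling interval `dt`;
quadrant seconds are `dt` times the number of in-quadrant samples, and the
fraction divides by `n * dt`. An alternating in/out path yields exactly
0.5.

**Speed compensation.** Animals in different waters move at different
speeds, so raw quadrant time confounds preference with mobility. The
food-localization index re-expresses quadrant time as if every animal
moved at a common reference median speed $v_{ref}$:

$$\mathrm{index} = t_{quadrant} \times \frac{v_{median}}{v_{ref}}.$$

Only the assumption "all individuals had the same speed" is given for this
adjustment; the formula above is the unique linear form with the replay
property: traversing the *same path* k-times faster divides
$t_{quadrant}$ by k and multiplies $v_{median}$ by k, leaving the index
unchanged (the alternative orientation, $t \times v_{ref}/v_{median}$,
fails this). The invariance is tested to 1e-9. Reference speeds used with
the assays include 0.38, 0.51 and 0.60 mm/s — the median speed of the
respective comparison group; 0.38 mm/s is the package default. Immobile
animals (median speed 0) have no defined index: they are flagged and
excluded rather than assigned infinity.

**Occupancy heat maps** are per-animal dwell-time histograms (3-mm bins by
default) averaged across animals and normalized to total mass 1;
out-of-arena cells are masked `NA`.

## Kymographs and beat frequency

`build_kymograph()` samples an intensity profile along a fixed line in
every frame — the classic line scan placed perpendicular to a row of cilia
— optionally averaging across parallel offset lines (`width_px`).
`estimate_beat_frequency()` subtracts each column's mean, averages the
columns' FFT power spectra, and takes the dominant peak in (0, fps/2) with
parabolic interpolation of log-power around the peak bin. At 240 fps and
2-s clips the spectral bin width is 0.5 Hz; parabolic interpolation gives
sub-bin resolution, and recovery is tested to ±0.5 Hz for beats of 5–40 Hz
under 10% pixel noise. Constant kymographs raise a "no periodic signal"
error rather than returning a spurious peak.

The synthetic scene renders a row of bright filaments whose tips oscillate
sinusoidally with per-cilium phase offsets; its Nyquist guard rejects
`fps <= 2 * beat_hz`.

## Population growth

`simulate_population()` is a weekly branching process: each individual
survives with probability `1 - death_p`, and each survivor fissions into
two with probability `fission_p`, giving expected weekly factor
`(1 - death_p)(1 + fission_p)`. `growth_summary()` reports the per-week
mean across batches with t-based 95% CIs (the trend is a summary, not a
fitted curve — the simplest faithful description of three batches), and
the doubling time as the first linear-interpolated crossing of `2 * n0`,
or "not reached". Counts are validated as finite and non-negative;
non-integer values are accepted because trends and interpolation operate
on means.

## The statistics workflow

The individual tests are standard and delegated to base R and established
packages (`nortest::lillie.test`, `var.test`, `t.test`, `wilcox.test`,
`aov`, `kruskal.test`, `multcomp::glht` for Dunnett, `p.adjust` for Holm).
What the package adds is the **auditable decision path**: such assay data
are conventionally analyzed with a normality screen followed by either
parametric or rank-based comparisons, but the selection rule is rarely
stated. `compare_groups()` codifies it:

1. Lilliefors-corrected KS normality per group at alpha 0.05 (groups with
   n < 4 or zero variance fail the screen conservatively).
2. All groups normal → parametric branch: one-way ANOVA (overall design),
   Dunnett contrasts against a control, or pairwise Welch t tests; for two
   groups an F test chooses Student vs Welch.
3. Otherwise → rank branch: Kruskal-Wallis or pairwise Wilcoxon rank-sum
   tests.
4. Pairwise families are Holm-adjusted; every screening p-value and the
   branch taken are recorded in the report.

A `branch` argument can force either branch — used, for example, to
measure the rank branch's null calibration (type-I error at alpha 0.05)
independent of the screen. `regression_r2()` reports OLS slope, intercept
and `r^2 = 1 - RSS/TSS` for dose-response correlations.

## Numerical choices and degenerate inputs

* Otsu on a constant image is undefined; constant channels yield empty
  foreground ("no body detected" for the body channel, `A_f = 0` for the
  fluorescence channel).
* `simulate_locomotion()` requires `dt` to divide the duration; otherwise
  the series is truncated to `floor(duration/dt)` steps with a warning.
* Tracking gap-fills empty frames by linear interpolation and flags them;
  more than 50% empty frames is an error, not a guess.
* Reflection is iterated (steps are small relative to the arena, so one
  pass almost always suffices) and residual excursions are clamped onto
  the boundary, keeping containment exact.
* Ties in rank tests fall back to the normal approximation
  (`wilcox.test`'s behavior); identical duplicated groups return p = 1.
* Seeds: every generator takes an integer seed and is bit-reproducible
  from it. `run_assay()` writes a manifest with MD5 checksums so reruns
  can be verified byte-for-byte.

## Problem sizes used in the validation suite

The shipped tests validate: feeding-index recovery on 100 x 40 px bodies
(A_w ≈ 3100 px) across fills 0–1; null quadrant occupancy with 1000
center-start walkers over 90 s; the dose-response over sensitivities
{0, 0.3, 0.6, 1} with 50 walkers per arm followed for 60 min; a 60-s
tracking round trip rasterized at 5 px/mm (RMSE < 0.2 mm); beat recovery
at {5, 10, 20, 40} Hz from 2-s 240-fps clips with 10% noise; doubling-time
recovery over 200 branching batches at weekly factor 1.414; and a
2000-replicate null calibration of the rank branch with 20 values per
group. These sizes were chosen to keep Monte-Carlo error well inside each
check's tolerance.

## Known limitations

* Single-animal assumption in images and videos; no identity-preserving
  multi-animal tracking.
* No gait segmentation (gliding vs crawling) or turning-angle ethograms.
* The compensation formula is validated by its invariance property, not
  against an external reference implementation, since the original
  adjustment arithmetic is unpublished.
* The Hill mapping from calcium to sensitivity is a convenience for
  simulation studies; fitting it to data is out of scope.
* Heat maps use simple square binning without smoothing.
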
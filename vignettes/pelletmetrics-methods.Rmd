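---
title: "Quantifying pellet morphology and viability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pellet morphology and viability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Filamentous actinomycetes such as *Lentzea aerocolonigenes* grow in
submerged culture as dense spherical hyphal agglomerates — pellets — whose
size, shape and internal viability structure are tightly linked to
secondary-metabolite productivity (here: rebeccamycin, an indolocarbazole
with antitumor activity). pelletmetrics implements the complete
quantification stack for such cultivations: brightfield macro-morphology,
stained-slice viability by confocal microscopy, pulse-shape flow cytometry,
productivity kinetics and per-day condition comparisons — together with a
seeded synthetic-data generator that supplies every input with known ground
truth.

```{r setup}
library(pelletmetrics)
```

## Why synthetic data

Raw cultivation images and cytometer runs are large, instrument-bound and
rarely published. Every pipeline stage here is therefore validated against
generated inputs whose true geometry is known analytically. The generators
are first-class, tested code: if a stage recovers the generator's truth it
is demonstrably correct *for data obeying the generator's model*; the
limitations section below spells out what that does and does not imply for
real micrographs and pulse trains.

## Brightfield macro-morphology

### Image model

`generate_pellet_image()` renders dark elliptical pellet cores (log-normal
diameter distribution; the defaults, meanlog 5.088 / sdlog 0.344, give a
mean of 172 um with sd 61 um, typical of an unsupplemented shake-flask
culture imaged at 4.5 um/px) surrounded by a fuzzy hyphal corona on a
bright background. The corona is a multiplicative radial darkening with
per-pixel speckle out to `corona_fraction` of the core radius. Where a
"pellet" ends is genuinely ambiguous in brightfield imaging; the
generator's convention is that the *core ellipse* is the object and the
corona is texture, and the ground-truth table refers to cores only.

Core masks are *area-matched* rasterizations: pixels are ranked by
sub-pixel coverage (8 x 8 supersampling) and the top `round(sum(coverage))`
selected, so counting mask pixels reproduces the analytic ellipse area to
better than one pixel area. Cores are placed by rejection sampling with a
minimum centre distance of the sum of the semi-major axes plus 2 px, and a
margin keeps each core (corona included) inside the frame; after 1000
consecutive rejections the generator refuses, naming the requested count
and frame size.

### Segmentation and measurement

The pipeline mirrors the classical Matlab workflow (adaptive threshold,
watershed, regionprops-style measurement, size/edge filters):

* `binarize_local_mean()` — a pixel is foreground when darker than the
  mean of its 65 x 65 px neighbourhood by more than `sensitivity` (default
  0.1) times the image dynamic range. The offset form (rather than a
  multiplicative scaling of the local mean) was chosen because it makes
  dark-mode on an image and bright-mode on its inversion *exactly*
  symmetric, and it behaves identically in dim and bright image regions.
  Window and sensitivity are free parameters of any adaptive threshold;
  the defaults segment the synthetic fixtures robustly and are exposed.
* `segment_watershed()` — fills enclosed holes (pellet interiors can
  binarize bright), then splits fused blobs by watershed on the Euclidean
  distance transform with h-maxima suppression of depth `h_min` (default
  2 px). An optional disk opening (`opening_px`, default 3 in the
  pipeline wrapper) strips the ragged single-pixel fringe that corona
  speckle leaves on outlines; without it the perimeter — and hence
  circularity — of small pellets is badly biased.
* `measure_regions()` — area is the pixel count times the pixel area;
  the area-equivalent circle diameter is $d_a = \sqrt{4A/\pi}$ and
  circularity $= 4\pi A / P^2$. The perimeter comes from the traced
  boundary chain with Vossepoel–Smeulders step weights (0.948 straight,
  1.340 diagonal): raw 1/sqrt(2) chain weights overestimate digital circle
  perimeters by about 5%, pushing circle circularity to ~0.90, while the
  corrected weights keep rendered circles at 1.00 +/- 0.05. Circularity is
  deliberately not clipped at 1 — any perimeter estimator carries bias and
  clipping would hide it. Feret extremes use exact rotating calipers over
  the convex hull of the pixel corner points; `feret_ratio` is min/max.
* `filter_regions()` — removes objects with projected area < 200 um^2 and
  objects touching the raster border (any pixel in the first/last row or
  column), then relabels contiguously. The filter is idempotent.
* `size_distributions()` — q0 (number-weighted) and q3 (d^3,
  volume-weighted) densities on 20-um bins from zero, each normalized to
  unit integral.

On noise-free synthetic fields the pipeline recovers per-pellet equivalent
diameters within max(2 px, 3%) of truth and detects every eligible object;
with the default noise it stays within the same envelope across 20 seeded
fields (the acceptance checks re-measure this at every run).

## Stained-slice viability (CLSM)

A slice through a pellet stained with a membrane-permeant green
nucleic-acid stain and propidium iodide separates into three regions:
solely green (live), solely red (dead, where PI displaces the green stain)
and doubly stained overlap. `generate_clsm_pair()` renders the concentric
model — green over the disk minus the dead core, red over core plus an
overlap band — with analytic truth shares.

`analyze_slice()` runs per channel: Otsu threshold (maximum between-class
variance on a 256-bin histogram), then `close_and_fill()` — closing with a
5-px disk followed by flood-fill of enclosed holes up to
`se_diameter_px^2` pixels. The fill is bounded on purpose: a genuinely
unstained interior, i.e. a dead core absent from the green channel, is a
real region of the slice and must survive; only the small specks closing
cannot bridge are treated as defects. The channel masks intersect into the
three regions; shares are areas over the union area.

Two conventions required a decision:

* **Live-ratio denominator.** "Living area over total area" is read with
  total = the union of stained areas and living = solely green, matching
  the three-region decomposition; `live_includes_overlap = TRUE` switches
  to counting doubly stained area as living. Whether unstained enclosed
  pixels belong to "total area" remains the open point; the union
  convention is documented, not asserted as the only reading.
* **Signal-free channels.** Otsu applied to a channel containing only
  sensor noise invents a foreground. `analyze_slice()` treats a channel
  whose Otsu classes separate by fewer than 4 pooled within-class standard
  deviations as unstained (empty mask).

Over a 5 x 5 grid of core/overlap geometries with 5% noise the mean
absolute share error is well below 0.05, and channel swap exchanges live
and dead shares exactly.

## Pulse-shape flow cytometry

An in-flow scanning cytometer records each particle's forward scatter
(FSC), sideward scatter (SSC) and green/red fluorescence (FLG/FLR) as a
profile against position. The generator models a pellet as a projected
sphere: scatter proportional to the chord $2\sqrt{R^2-x^2}$ of total
material, FLG proportional to the projected viable outer shell, FLR to the
projected dead core, FSC clipped at the instrument saturation level,
baseline 50 mV, optional Gaussian noise. One sample always falls exactly
at the particle centre.

Per-particle metrics (baselines estimated as the median of the first and
last three samples per channel and subtracted; all crossings linearly
interpolated):

* **Signal length** — distance between the first and last FSC samples
  above the 200 mV trigger; the particle diameter proxy.
* **Classification** — a *pellet* shows a saturated FSC core (>= 3
  consecutive samples at >= 99% of saturation) *and* signal length
  > 80 um; otherwise *large* (> 80 um) or *small*.
* **Compactness** — SSC full width at half maximum over signal length.
  For a homogeneous projected sphere the half-maximum sits at
  $x = \pm R\sqrt{3}/2$, so compactness is $\sqrt{3}/2 \approx 0.866$ — a
  built-in oracle the acceptance checks re-derive across diameters.
* **FDA viable layer** — $0.5 \cdot (A_{FLG}/A_{FSC}) \cdot L$ with
  trapezoidal areas over the extent, FSC as recorded (clipped). Under the
  chord model without saturation this equals
  $R\,(1-(1-t/R)^2)\,(g_{FLG}/g_{FSC})$ for shell thickness $t$ — the
  square arises because chord integrals are projected *areas*; a volume
  reading would give a cube law, but that is not what chord profiles
  integrate to, so the square law is the model-consistent closed form used
  in validation.
* **PI viable layer** — the dead core is delimited by FLR exceeding 0.3 of
  its own maximum; the summed length of those sub-intervals (a union, in
  case noise fragments the core) is subtracted:
  $0.5\,(L - \ell_{>0.3})$, floored at zero. The printed form of this
  estimator subtracts a length from the dimensionless 1; the implementation
  uses the dimensional repair above, which restores the intended "viable
  layer as simplified radius" and keeps the viability factor in [0, 1].
  The threshold rule recovers the core diameter exactly only for
  plateau-shaped FLR; for sphere-projected FLR it reads the chord at 30%
  of peak, a deterministic 4.6% underestimate of the core. The generator
  therefore offers `flr_shape = "slab"` (plateau with a one-sample-spacing
  edge ramp) for validating the estimator on its own terms.
* **Viability factor** — $2 \cdot vl / L$, in [0, 1]; FDA-based by
  default, `layer = "pi"` switches.
* **Autofluorescence factor** — $A_{FLG}/A_{FSC}$ on unstained runs; green
  autofluorescence tracks intracellular pigment, making the factor a
  candidate productivity indicator.

`summarize_population()` restricts summaries to pellets, flags samples
with fewer than 50 pellets, mirrors the instrument's 500-um size exclusion
as an optional filter, and flags particles whose FLR/FLG area ratio
deviates more than 3.5 scaled MADs from the run median — the spectral
overlap control used when hardware compensation is unavailable.

## Kinetics and statistics

`specific_productivity()` computes $q_P = (1/X)\,dP/dt$ (mg per g biomass
per day) with central differences on interior points and one-sided ends;
how the original daily data were differentiated is not recorded anywhere,
and central differences are the symmetric default. Points with zero
biomass are flagged `NA` rather than infinite. Because early samples
divide measurement noise by a near-zero inoculum biomass, summary tables
report the q_P peak over the established-biomass phase (X at or above half
its maximum).

`anova_oneway()` is the classical fixed-effects one-way ANOVA with
unequal-n sums of squares and the p-value from the F survival function;
groups under two observations are rejected outright (single observations
invite type II errors). `compare_conditions_per_day()` applies it day by
day, reporting skipped and degenerate days with reasons instead of
failing; no multiple-testing correction is applied across days — the
original per-day comparisons applied none — and the output records that.
Under the null the per-day test holds its 5% size within binomial error
(re-measured over 500 replicates in the acceptance checks).

## Cultivation model

`generate_cultivation_series()` uses logistic biomass growth (defaults:
carrying capacity 3 g/L, rate 3 /d from a 0.06 g/L inoculum — growth
essentially complete by day 2 on 4 g/L glucose), glucose coupled through a
0.75 g/g yield, and a delayed truncated-logistic product rise starting at
day 3.5 toward `P_max` (38 mg/L default, ~95 mg/L emulating a glass-bead
supplemented culture). Noise is per-channel Gaussian, clipped at zero.

## The demonstration workflow

`run_demo()` reproduces the comparison design end to end: two conditions —
`no_beads` (large, more eccentric, less viable pellets, low titre) and
`beads` (smaller, rounder, more viable, high titre) — across ten simulated
days, one brightfield field (900 x 700 px, 20 pellets), one stained slice,
60 stained and 25 unstained pulse profiles per condition and day, plus one
cultivation series per condition. These problem sizes keep a full run
around a quarter minute while leaving every per-day ANOVA well powered;
all of them are configuration fields. Every stage seed derives
deterministically from the master seed, so a repeated run is byte-identical
file for file; the manifest records the package version, a configuration
hash and per-stage warnings.

## Numerical choices and degenerate inputs

* Crossing and FWHM computations interpolate linearly between samples;
  positions are um throughout.
* Boundary tracing uses Moore neighbourhood with the repeated-first-
  transition stopping rule; single-pixel regions get the square perimeter.
* Otsu on a constant channel, ANOVA with zero within- and between-group
  variance, empty mask unions, FSC never crossing the trigger, flat SSC:
  all raise explicit errors rather than returning numbers.
* Watershed on an empty mask returns zero objects; filters log removal
  counts.
* All generators restore the caller's RNG state.

## Limitations

The image generator renders smooth elliptical cores with stochastic
coronas — no true hyphal texture, no optical point-spread function, no
out-of-focus light, no touching pellets (cores are non-overlapping by
construction, so the watershed's neck-splitting is exercised by dedicated
fixtures rather than by the generated fields). The pulse model assumes
spherical, radially layered pellets and a linear position axis. Passing
recovery tests on these models demonstrates the correctness of the
measurement code, not robustness to every artefact of real micrographs
(air bubbles, glass beads, debris) — the optional bright-object and
size-exclusion filters exist for such data but default off. Viability
factors from slices and from pulse profiles measure different physical
quantities (area shares of one equatorial slice vs volume-weighted
fluorescence of whole pellets); they need not coincide, and the demo
reproduces that divergence.
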
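---
title: "Motility metrics, random-walk classification and the synthetic track simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motility metrics, random-walk classification and the synthetic track simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmotility)
```

## The problem

Intravital two-photon imaging of tumors yields per-cell trajectory tables:
one row per cell per timepoint, with positions in micrometres and times in
minutes, typically sampled every 0.5 min for 10–15 min. The scientific
questions — are cytotoxic T cells scanning the tumor or arrested on
targets, does a treatment mobilise tumor-infiltrating immunocytes, do cells
move diffusively or directionally — are answered through a small set of
per-track statistics and one cohort-level curve. This package implements
those statistics, the group comparisons applied to them, and a synthetic
cohort simulator so every stage can be verified end to end without any
imaging data.

## Per-track statistics

For a track with positions $x_1,\dots,x_n$ at times $t_1<\dots<t_n$:

* **Instantaneous velocity** of step $i$:
  $v_i = \lVert x_{i+1}-x_i\rVert / (t_{i+1}-t_i)$ (µm/min).
* **Mean velocity**: path length $\sum_i \lVert x_{i+1}-x_i\rVert$ divided
  by the duration $t_n-t_1$. At uniform sampling this equals the arithmetic
  mean of the instantaneous velocities — an identity the test suite asserts
  on random tracks.
* **Arrest coefficient**: the percentage of track time spent in steps with
  $v_i$ strictly below 2 µm/min. Each step is weighted by its own
  $\Delta t$, which makes the definition well behaved under irregular
  sampling. The threshold is a tunable argument (`arrest_threshold`,
  default 2 µm/min, the conventional value for T cells).
* **Confinement ratio**: maximum displacement from the track's *first*
  position divided by path length; near 1 for ballistic motion, near 0 for
  confined motion. Trajectory plots in this field align tracks on their
  starting positions, which fixes the displacement origin convention. For
  a zero-path track the ratio is 0/0; it is reported as `NA` and excluded
  from cohort summaries with a logged count, because silently reporting 0
  would bias cohort means downward.
* **Immotile**: mean velocity strictly below 2 µm/min
  (`immotile_threshold`).

Cohort summaries treat each cell as one observation and report mean, SD
and SEM per metric; figure-style reporting conventions use mean ± SD for
cell-level metrics and mean ± SEM for field-level counts, so both are
always emitted with explicit column names.

Tracks may be 2-D or 3-D. Acquisition z-stacks are thin (tens of µm)
relative to lateral fields, and displayed analyses are planar, so all
metric functions project 3-D tracks to the xy-plane by default
(`project_2d = TRUE`); the flag makes the 3-D alternative a one-argument
change.

## Mean displacement versus √time and the random-walk criterion

For each elapsed time $k\,\Delta t$ on the common grid, the cohort mean
displacement $\mathrm{MD}(t)$ averages, over the cells still observed at
that elapsed time, the distance of each cell from its own first position.
Cells contribute only while observed; nothing is imputed, and the per-point
cell count is recorded (it is non-increasing). For an isotropic random walk
$\mathrm{MD}(t)\propto\sqrt{t}$, so the curve is fitted by ordinary least
squares against $\sqrt{t}$ and the population is classed as random-walking
when $R^2 > 0.95$.

Numerical choices, all surfaced as arguments:

* The fit uses a **free intercept**: that is the conventional default for
  a "linear fit" and what the usual $R^2$ presumes; slope, intercept and
  $R^2$ are all reported, so a through-origin variant is recoverable.
* The $t=0$ point has $\mathrm{MD}=0$ by construction and is excluded so
  it cannot anchor the fit artificially.
* Grid points supported by fewer than `min_cells_per_point` cells
  (default 5) are dropped, guarding the noisy late times where short
  tracks have dropped out. Fewer than 3 usable points is an error, not a
  silent fit.
* A fully saturated curve (zero variance in MD) would make $R^2$ 0/0; it
  is defined as 0 and classed non-random-walk, which matches the physical
  reading of a plateau.

A deliberately narrow scope: this is the displacement-from-origin curve,
not a full mean-squared-displacement analysis over all lag pairs, and no
anomalous-diffusion exponent is fitted. Note one property of the criterion
itself, visible in the regression fixtures: a purely ballistic cohort
(MD linear in $t$, hence convex in $\sqrt t$) can still exceed
$R^2 = 0.95$ over a short recording; the criterion separates diffusive
from *confined* motion much more sharply than from directed motion.

## The synthetic cohort simulator

`simulate_trackset()` generates cohorts with the statistical structure the
analysis assumes; it is a statistical emulator, not an agent-based model
of immunology. Four motion models operate per frame: `random_walk`
(independent uniform direction each frame; constant or i.i.d. uniform step
length), `confined` (each frame the cell relaxes a fraction `tether`
toward its start before stepping), `directed` (random walk plus constant
drift), and `stop_and_go` (two-state Markov chain over per-frame speeds
with random directions, started from its stationary distribution).
Defaults mirror the emulated recordings: frame interval 0.5 min, track
durations of 10–15 min (21–31 frames). Step directions are uniform on the
circle, or on the sphere with `dim = 3`.

Reproducibility is by construction: each simulate call derives one
sub-stream per track by counter from the config seed, so the same seed
gives identical output and track `i` does not depend on how many tracks
follow it.

### Regime presets and their calibration

`preset_regime()` encodes the published motility regimes (adoptive CTLs by
day and region, endogenous TIIs by day and by treatment group, endogenous
GFP T cells) with each regime's reported mean velocity, arrest
coefficient, confinement ratio and cohort size. Calibration follows a
fixed convention:

* A regime with only a reported mean velocity $v$ uses a constant-step
  random walk with step $v\,\Delta t$, whose cohort mean velocity is $v$
  exactly.
* A regime that also reports an arrest coefficient $q\%$ uses
  `stop_and_go` with i.i.d. per-frame occupancy: stop speed 0, go speed
  $v/(1-q/100)$, transition probabilities chosen so each frame is arrested
  independently with probability $q/100$. Expected mean velocity and
  expected arrest coefficient then equal the reported pair analytically.
* The three reported statistics jointly over-determine these one- and
  two-parameter models, so the achieved confinement ratio is whatever the
  calibrated model produces (documented via `attr(cfg, "expected")`
  against the measured cohort). Matching all three would require a
  persistent-motion parameter the reported numbers cannot identify.

Two registry values are not reported in the source figures and were fixed
once as package choices: the parenchymal day-6 cohort size (set to 118,
the reported parenchymal cohort size from day 3) and the endogenous GFP
T-cell cohort sizes (set to 200, a typical pooled intravital cohort).

What passing the recovery tests shows — and does not show: simulated
cohorts reproduce the reported mean velocities within 5% (exactly, for
constant-step presets) and arrest coefficients within 3 percentage points
at the printed cohort sizes. Real intravital data additionally contain
persistence, cell–cell heterogeneity beyond the two-state mixture,
tracking gaps and drift; none of those are emulated, so agreement here
validates the *metric implementations*, not any biological model.

## Point patterns, density and the ring profile

`simulate_point_pattern()` draws independent Poisson counts per
compartment — tumor-disc interior, a boundary annulus, and the remaining
field — with user intensities in cells/mm², uniformly within each
compartment, emulating the peri-tumoral accumulation geometry seen in
large-field images. `cell_density()` is exact count/area arithmetic with
the conventional field areas (0.18, 0.40, 12 mm²) bundled as named
constants, and `phenotype_fraction()` is a percentage of a reference
category set.

`radial_ring_profile()` bins points by signed distance to the tumor
boundary (negative inside). Bin areas for disc geometry are the annulus
areas clipped to the imaging field, computed by 1-D integration of clipped
chord heights (relative tolerance ~1e-10); polygon boundaries use exact
point-to-segment distances with ray-casting sign and deterministic grid
quadrature (400×400 cells) for the areas. Densities are computed with the
same areas that are reported, so total count is conserved across bins by
construction — an invariant the tests exercise. The **ring index** (first
exterior bin density over overall interior density, `Inf` when the
interior is empty) is this package's construct for quantifying a
peri-tumoral band; it is labelled as such in outputs and has no published
reference value. Which bin counts as "the ring" is the documented default
`[0, bin_width)` just outside the boundary.

## Group statistics

`compare_groups()` applies the two-group two-tailed unpaired t-test, or
Kruskal–Wallis (mid-ranks, tie-corrected — motility data contain ties at
zero speed) followed by Dunn's pairwise z-tests for three or more groups.
Dunn's multiplicity adjustment defaults to Bonferroni over all pairs —
the common Prism convention, since post-hoc reports rarely say more — and
is configurable (`none`, `bonferroni`, `holm`). Significance bands are
`*`/`**`/`***` at 0.05/0.01/0.001. The module exposes the tests; it does
not prescribe per-timepoint versus pooled invocation for growth curves,
which is a study-design choice.

## Bench formulas

`cytotoxicity_percent()` is the background-corrected kill fraction
$100\,(e-s)/(1-s)$ on 0–1 dead fractions (the CLI accepts percentages and
divides by 100); a negative value — experimental kill below spontaneous —
is reported as-is with a warning rather than clamped. `tumor_volume()` is
the caliper formula $LWH/2$ in mm³.

## Problem sizes and determinism in the shipped checks

The test-suite simulations use cohorts of 118–3000 tracks of 21–31 frames
and Monte-Carlo panels of 5–20 seeds; these sizes put the stochastic
checks 2–3 standard errors inside their tolerances while keeping the whole
suite under a minute on one CPU. The triangle-inequality and bound
invariants run over 10⁴ random tracks. All stochastic tests fix seeds;
simulator determinism (same seed, identical bytes) is itself under test.

## Known limitations

* The emulator has no persistent random walk and no chemotactic drift
  toward the boundary; directed motion is a constant global drift.
* Confinement-ratio calibration is not attempted (see above), so preset
  cohorts should not be used as references for that statistic.
* Irregularly sampled cohorts must be resampled by the caller before
  mean-displacement analysis; only per-track metrics handle irregular
  sampling natively.
* Polygon ring profiles trade exact areas for grid quadrature; with the
  default grid, areas are accurate to roughly one part in 10³, adequate
  for ring indices but not for sub-percent area work.
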
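---
title: "Canopy kite morphometrics for hemp trials: models, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy kite morphometrics for hemp trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hempkite)
```

`hempkite` implements the quantitative backbone of a morphometric analysis
of field-grown cannabinoid hemp (*Cannabis sativa*) hybrid trials: a
two-dimensional "kite" summary of canopy architecture, model-II allometric
regression, growth and disease statistics, half-sib quantitative genetics,
biomass and cannabinoid yield arithmetic, archetypal classification of
canopy form, and per-plant trait extraction from aerial imagery products.
A synthetic trial generator reproduces the statistical structure of such a
trial so that every stage can be exercised, and its estimators validated,
without field data. This vignette explains the models, the tunable
parameters, and the numerical decisions, in that order.

## The kite model of canopy architecture

A plant's canopy is summarised by four field measurements, all in cm:
plant height `HT`, maximum canopy diameter `MCD`, the height `MCDH` at
which that diameter occurs, and trunk length `TRKL` from the ground to the
first branch. The kite is the quadrilateral with vertices at the first
branch point $(0, \mathrm{TRKL})$, the apex $(0, \mathrm{HT})$, and the two
lateral extremes $(\pm \mathrm{MCD}/2, \mathrm{MCDH})$; the bare trunk is
excluded. With lower leg $a = \mathrm{MCDH} - \mathrm{TRKL}$, upper leg
$b = \mathrm{HT} - \mathrm{MCDH}$ and half-width $w = \mathrm{MCD}/2$:

- area $A = (a + b)\,w$ (reported in m²),
- perimeter $P = 2(h_l + h_u)$ with $h_l = \sqrt{w^2 + a^2}$,
  $h_u = \sqrt{w^2 + b^2}$ (m),
- circularity $C = 4\pi A / P^2$, a dimensionless compactness in
  $(0, \pi/4]$,
- hypotenuse ratio $\mathrm{KHR} = h_u / h_l$,
- branch angle $\mathrm{KBA} = \arctan(w/a)$, measured from the vertical
  stem axis using the lower kite triangle.

The branch-angle convention (from the stem axis, not from the hypotenuse's
complement) is the one that reproduces the observed trait means and makes
circularity maximal at 45°: for symmetric kites ($h_l = h_u$), $C$ is
unimodal in KBA with its maximum $\pi/4 \approx 0.785$ exactly at 45°, the
square kite. Kites flatter or more columnar than that are less circular,
which is what makes $C$ a useful one-number shape descriptor.

```{r kite}
k <- build_kite(ht = 157.7, mcd = 125.9, mcdh = 85.9, trkl = 12.2)
k
```

Two derived quantities need a volume. The kite's solid of revolution about
the stem axis is a bicone, $V = \frac{\pi}{3} w^2 (a + b)$; canopy density
is wet leaf mass divided by $V$ (kg m⁻³). The bicone is a modelling choice:
the quantity is defined geometrically rather than printed as a formula in
the trait tables we emulate, and the bicone is the unique solid consistent
with deriving it from the same three measurements. It is isolated in
`kite_volume()` so an alternative solid can be substituted.

Similarly, primary stem volume `VOL` is modelled as a **cone**,
$\frac{1}{3}\pi (\mathrm{DIA}/2)^2 \mathrm{HT}$: at the trait-table means
(DIA 4.44 cm, HT 157.7 cm) the cone gives 814 cm³, consistent with the
reported mean of 888 cm³ once the positive diameter–height covariance is
accounted for, while a cylinder (2441 cm³) is excluded by a factor of
nearly 3. The middle-leaflet "pointed oval" area uses the parabolic-lens
constant $\frac{2}{3} L W$, which reproduces the reported leaflet-area mean
within 1.5%; the constant is an argument (`pointed_oval_area(..., constant=)`)
because the exact convention is not fixed by the source material.

## Model-II allometry

Allometric scaling relations are fitted on $\log_{10}$ scales with
regression methods that treat both variables as error-prone.
`model2_regress()` implements OLS, the major axis (MA, leading eigenvector
of the covariance), the standardized major axis (SMA,
$\mathrm{sign}(r)\, s_y/s_x$), and the **ranged major axis** (RMA): both
variables are standardized by their min–max ranges, an MA line is fitted in
the standardized space, and the slope is back-transformed by
$\mathrm{range}(y)/\mathrm{range}(x)$. RMA is the default throughout
because it is the method used in the analyses we reproduce. On error-free
power-law data all four methods coincide; under symmetric proportional
noise on both log axes RMA recovers the generating exponent while OLS is
attenuated toward zero — both facts are property-tested.

The reported slope CI uses the standard large-sample slope-variance
formulation based on $\sqrt{(1-r^2)/(n-2)}$; at the trial sizes used here
(n ≥ 300) the difference between method-specific CI variants is
negligible.

## Growth, phenology, disease

Weekly height series are smoothed with cubic smoothing splines
(`stats::smooth.spline`, default `spar = 0.35`, matching the smoothing
used by the original growth-rate analysis; a target effective-df option is
retained for sensitivity). The derivative is evaluated on a 50-point grid
over the observed days; the maximum growth rate and its day are read off
the grid, and the mean rate is the endpoint slope. For a logistic curve of
rate $r$ and asymptote $K$ the analytic maximum is $rK/4$ at the
inflection; weekly sampling recovers it within 5% in tests. An optional
restriction of the maximum to the log-linear window (3-point rolling
log-linear fits with $R^2 > 0.95$) approximates derivative extraction from
the log-linear part of the curve; it is off by default because the
windowing heuristic is our own reconstruction.

Pre-terminal flowering day partitions plants into early (< 50 DAP),
mid (50–70 DAP, both ends closed — the printed class boundaries are
ambiguous, and the closed convention is declared here once) and late
(> 70 DAP). Family segregation patterns are summarised descriptively by
the nearest simple ratio among all-early, all-late, 1:1, 2:1, 3:1 by
chi-square distance; this is reporting, not testing.

Powdery-mildew severity (0–100% canopy area, assessed at 71, 86 and
97 DAP) is summarised by the absolute AUDPC, the trapezoidal integral of
severity over days, bounded by $100 \times (t_{last} - t_{first}) = 2600$
%·days for these dates. Relative AUDPC (divided by that bound) is an
option.

## Variance components and half-sib heritability

For each trait, a one-way random-effects decomposition across
common-parent families yields $\sigma^2_F$ (among families) and
$\sigma^2_\varepsilon$ (within). The primary estimator is the closed-form
method of moments with the unbalanced-design coefficient
$n_0 = (N - \sum n_i^2/N)/(k-1)$; REML via `lme4` is available as a
cross-check and agrees to $10^{-5}$ on balanced data with interior
estimates. Under the half-sib assumption the additive variance is
$4\sigma^2_F$, so

$$h^2 = \frac{4\,\sigma^2_F}{\sigma^2_F + \sigma^2_\varepsilon}.$$

The multiplier is applied to all families alike (including selfed ones, as
in the trial design we emulate); a full-sib multiplier of 2 is available
for sensitivity. Negative moment estimates are clamped to zero and
flagged; the ratio is capped at 1 for per-trait reporting, with the
uncapped value also returned — recovery simulations average the uncapped
ratio, because capping before averaging introduces a truncation bias of
roughly −0.04 at a true $h^2$ of 0.85 with 23 families. Heritability of
stem diameter is estimated on the $\log_{10}$ scale, matching the
log-scale allometric role of that trait; at the trial's CV (0.23) the raw-
and log-scale estimates differ by less than 0.01.

## Yield models

The packaged wet-to-dry calibration (34 harvested calibration plants)
predicts whole-plant dry biomass and dry stripped floral biomass from wet
biomass with fixed linear coefficients and residual standard deviations
(`reference_biomass_calibration()`); predictions are clamped at zero.
Total-potential cannabinoid percentages combine neutral and acid forms as
$\mathrm{total} = \mathrm{neutral} + f \cdot \mathrm{acid}$ with
decarboxylation factors $f = 0.877$ (pentyl series) and $0.867$
(propyl/varin series) from molar-mass ratios; both are arguments.
Cannabinoid yield per plant is the summed totals times dry stripped floral
biomass. Predictor selection uses bidirectional stepwise AIC
(`stats::step`, criterion $n \log(\mathrm{RSS}/n) + 2(k+1)$ up to an
additive constant that cannot change selections), and the selected model's
$R^2$ is decomposed by **LMG relative importance**: predictor $j$'s share
is its sequential $R^2$ increase averaged over all $p!$ orderings, computed
exactly via subset enumeration with combinatorial weights ($p \le 12$).
Shares are nonnegative and sum to the model $R^2$ to $10^{-9}$; bootstrap
percentile CIs (1000 case resamples) use a Bonferroni-adjusted level
$1 - 0.05/p$.

## Archetypal analysis of canopy form

Canopy form is classified on two dimensionless ratios, MCD/HT and
MCDH/HT. Archetypal analysis approximates the data as convex combinations
of $k$ archetypes that are themselves convex combinations of data points:
minimise $\|X - A B X\|_F^2$ with the rows of $A$ ($n \times k$) and $B$
($k \times n$) on the probability simplex. The solver alternates:

1. **A-step** — each plant's simplex weights are the exact
   simplex-constrained projection onto the current archetypes, computed by
   enumerating all $2^k - 1$ supports of the KKT system (vectorised over
   plants; exact for the $k \le 10$ used here).
2. **B-step** — the unconstrained optimal archetypes
   $(A^\top A)^{-1} A^\top X$ are mapped back into the data's convex hull
   by nonnegative least squares with a sum-to-one augmentation
   (Lawson–Hanson in normal-equation form, with a small ridge so
   passive-set solves stay full rank).

Each of `nrep` restarts (default 5) initialises from a seeded
furthest-point sample of the data. Convergence is a relative rss change
below $10^{-8}$ or 500 iterations; because the B-step is not strictly
monotone, the incumbent best iterate is tracked and returned, and a
sustained failure to improve it (10 iterations) also terminates. Hard
assignment is by the largest weight, ties to the lowest archetype index —
the assignment rule is our choice, stated here. The scree over
$k = 1{:}10$ reports an advisory elbow by maximum second difference; on
noisy real-shaped data that heuristic is genuinely ambiguous between the
large early drops and the flattening point, which is why `k = 4` is a
parameter, not an inference.

## Aerial trait extraction

The aerial module consumes reconstructed products — an RGB raster, a
5-band multispectral raster (B, G, R, RedEdge, NIR) and a 3-D point cloud
sharing one ground coordinate frame (rasters as in-memory arrays with a
geotransform; clouds as `x, y, z` tables with plain-text I/O). The
pipeline is: excess green ($2G - R - B$) → Otsu binarisation (256-bin
histogram, smallest argmax on ties) → 8-connected component labelling
(minimum blob 50 px) → centroids as plant centres; RANSAC ground plane
(3-point samples, 0.05 m inlier distance, 500 seeded iterations, total
least squares refit on inliers); per-plant canopy metrics inside a
1.83 m × 1.22 m bounding box — height as the **99th percentile** of point
heights above the plane (robust to stray points; the percentile is an
argument), projected area as occupied 0.05 m grid cells, volume as the sum
of cell-maximum heights times cell area; and seven vegetation indices
(NDVI, GNDVI, GCI, EVI, OSAVI, MSAVI2, MNLI, standard published forms)
averaged over a 0.28 m radius circle at each centre, with zero-denominator
pixels excluded and counted. Touching canopies merge into one component —
a stated limitation, exercised in tests.

## The synthetic trial generator

`simulate_trial()` is the package's test bed: 23 families × 15 progeny
with a major-gene flowering segregation (family patterns all-early,
all-late, ~1:1, ~2:1 mixed 5/8/6/4 so the early fraction ≈ 0.46 puts the
mean pre-terminal flowering day near 59 DAP; class means N(42, 3²) and
N(75, 6²) are calibrated inventions consistent with the observed range
28–85 DAP). Basal stem diameter is the lognormal root latent (mean
4.44 cm, CV 0.23) — mirroring the conclusion that stem diameter is the
best single predictor — and every size trait derives from it:
$\mathrm{HT} \propto \mathrm{DIA}^{0.65}$,
$\mathrm{WBM} \propto \mathrm{DIA}^{1.7}$, and a leafing-intensity cascade
(leaf mass $\propto \mathrm{LI}^{-0.71}$, specific petiole area
$\propto \mathrm{LI}^{2.08}$).

Noise is placed **symmetrically and proportionally on both log axes**
around the shared latent, which makes RMA consistent for the generating
exponent; the single noise ratio is set from the biomass–diameter fit
quality ($R^2 = 0.78$, giving $\lambda^2 = 1/\sqrt{0.78} - 1$), so the
height–diameter pair inherits the same $R^2$ — its own fit quality is not
independently constrained. Family effects enter the diameter latent with
$\sigma^2_F = h^2 \sigma^2_P / 4$ at the configured $h^2$ (default 0.85);
derived traits inherit family structure through the cascade. Disease
severity couples linearly to flowering day with slope and noise set so the
AUDPC–flowering correlation is ≈ −0.54; biomass passes through the
reference calibration with its stated residual noise; cannabinoid totals
are lognormal around CBD-dominant means with a 95% acid fraction.

What the generator does **not** emulate: spatial field effects, G×E,
measurement censoring, lodging, genuine multi-gene flowering epistasis,
inflorescence structure in the scenes, or radiometric noise in the
multispectral bands. Passing recovery tests therefore demonstrates that
the estimators are correct under the stated statistical structure — not
that field data meet that structure.

`simulate_scene()` plants cone-like canopy point clusters on a grid
(1.8 m between rows, 1.2 m within) over a rough ground plane
(sd 0.005 m), with green-vs-soil RGB contrast and NIR-elevated vegetation
in five bands. Canopy points are uniform in height between 5% and 100% of
plant height so the 99th-percentile height estimator reads essentially the
true height.

## Problem sizes and reproducibility

The shipped analyses and tests use: full trials of 345 plants; 50
replicate trials for exponent recovery and 100 for heritability recovery
(the 100-replicate mean of the $h^2$ estimator carries a standard error of
about 0.027, which should be kept in mind when reading single runs);
scenes of 24–40 plants at 0.04 m ground sampling distance. All generators
are pure functions of (config, seed); one master seed fans out to
independent per-module streams, and `run_pipeline()` writes a manifest
(seed, config, file checksums) sufficient to reproduce a run bit-for-bit.

## Known limitations

- The kite is symmetric by construction; strongly asymmetric canopies are
  out of scope.
- MoM variance components can be clamped at zero for low-heritability
  traits in small trials; the clamp is flagged rather than hidden.
- Exact LMG enumeration stops at $p = 12$ predictors.
- The archetype solver's restarts make the optimum reproducible under a
  fixed seed but, as with all alternating schemes, global optimality is
  not guaranteed.
- Touching plants merge in the aerial segmentation; the trial spacing
  keeps canopies separated in the default scenes.
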
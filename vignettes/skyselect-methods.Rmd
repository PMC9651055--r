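---
title: "Methods: scoring and modelling free-selection sky-as-nature data"
author: "skyselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and modelling free-selection sky-as-nature data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skyselect)
```

## The problem

In image-based free-selection experiments, participants view outdoor scenes
and click circular regions they consider "nature", then rate each scene on
visual-analogue scales.  The scientific question is how scene composition —
in particular the visible amount of sky and its condition — shapes both the
explicit selection of sky as nature and the judged naturalness of the whole
scene.  The analysis needs four ingredients, which are this package's four
analysis modules plus a simulator:

1. a **scene catalog**: per-pixel semantic segmentation of every stimulus
   and the derived composition covariates;
2. a **selection score** turning free clicks into a per-label quantity;
3. **quality-control rules** for implausible click behaviour;
4. a **statistical stage**: validation tests and a stepwise ladder of
   crossed random-intercept mixed models.

Because behavioural raw data of this kind are typically not redistributable,
the package ships a **synthetic-data generator** with a fully known
generating model.  Every downstream stage is exercised, and its statistical
operating characteristics measured, on data whose ground truth is known.

## Scene catalog

Scenes are represented as `label_mask` objects: integer matrices over a
closed ten-label vocabulary (`trees, sky, grass, water, rocks, sand,
vegetation, snow, manmade, background`), with `background` holding
unclassified pixels.  Masks come from three sources: LabelMe-style polygon
JSON (`parse_labelme()` + `rasterize()`), indexed raster PNGs with a legend
(`read_label_mask_png()`), or the generator.

Geometry conventions are fixed and exactly testable: 0-based pixel indices,
origin top-left; a pixel belongs to a polygon iff its centre
`(ix + 0.5, iy + 0.5)` is inside under the even-odd rule; overlapping
polygons are painted in file order (later shapes win), the LabelMe
convention.  The production rasterizer is a scanline fill with a half-open
vertex rule; the test suite checks it pixel-for-pixel against an
independently coded per-pixel ray-cast on random polygons.

`quantify_labels()` converts a mask into the scene's semantic vector — the
percentage of the surface covered by each label.  The denominator is the
total pixel count *including background*, so percentages always sum to 100;
treating background as excluded would be the main defensible alternative,
and is deliberately not the default because it makes the conservation
invariant unconditional.  Derived covariates follow the field's composites:
`pct_greenery = grass + trees + vegetation` exactly, and `pct_nature` sums
every label except `manmade` and `background`.  Whether sky itself counts
toward nature is study-specific, so it is an explicit flag
(`include_sky`, default `TRUE`).

Metadata levels are normalized on entry: weather `clear` is stored as
`blue`, seasons `spring`/`summer` collapse to `spring_summer` (models treat
them as one level), and unknown levels are an error listing what is
accepted.  The vocabulary is closed at ten names; an alias map on the
parser admits data annotated under other spellings.

## The EDB selection score

For one (participant, image) presentation with clicks $n = 1, 2, \dots$ and
semantic label $x$:

$$\mathrm{Score}^{EDB}_x \;=\; \sum_n \frac{D_x(n)}{B_x} \times 100,$$

where $D_x(n)$ is the number of pixels of label $x$ inside click $n$'s
selection disc and $B_x$ the number of pixels of label $x$ in the whole
image.  The content-based semantic vector (CBSV) collects these scores over
all labels, one row per presentation (`build_cbsv()`).

Numerical choices:

* **Disc membership** is pixel-centre Euclidean distance $\le$ radius
  (experimental radius: 150 px on a 1500 × 750 canvas); discs are clipped
  at image edges rather than rejected.
* **Clicks are summed without pixel de-duplication.**  Overlapping discs can
  therefore push a score above 100.  This is the faithful reading of the
  score: the downstream QC rule removes sky scores *over 100* as extreme
  behaviour, which can only arise under per-click summation — a union-based
  score is bounded by 100 and the rule would be vacuous.
* **Absent labels** ($B_x = 0$) score 0 and carry an `absent` flag, so a
  structural zero (no sky on the image) stays distinguishable from a true
  zero selection.

The implementation is checked against brute-force per-pixel enumeration on
hundreds of random mask/click cases (counts are integers; the single
floating step is the ratio, compared at 1e-9), and property tests cover
additivity over clicks, the ≤ 100 bound for pairwise-disjoint discs, and
equivariance under label bijections.

## Quality control

Three rules, applied in a fixed order, each only ever removing rows:

1. **Click outliers**: rows with more than 20 clicks ("above 20" read
   strictly; a row at exactly 20 is retained).
2. **Flagged images**: an explicit, configuration-supplied id list (the
   image-level anomaly criterion in such studies is qualitative, so the
   package does not invent a quantitative one; the default list is empty).
3. **Sky scores**: rows with sky EDB > 100 (strict) and sky absolute zeros
   are removed — *for the sky stream only*.  Other labels keep their zeros
   and over-100 values, which is why per-label summaries can show maxima
   above 100 for other streams.  Each removed zero is logged as
   `absent_sky` when the scene has under 2% sky coverage, else as
   `true_zero_selection`.

A row violating several rules is counted once, under the first rule.  The
report conserves counts (`survivors + removals = input`), and the pipeline
is idempotent.

## Statistical stage

Distributional diagnostics use the one-sample Kolmogorov–Smirnov test
against a normal with estimated parameters (the estimation caveat is
attached to the result) and the Levene test (mean-centred by default;
median-centring gives Brown–Forsythe).  Group comparisons use the Welch
one-way ANOVA — the form with fractional denominator df, appropriate under
variance heterogeneity — with classical $\eta^2$ and Bonferroni pairwise
Welch t post hocs; and the Kruskal–Wallis test with midrank tie correction,
followed by Dunn's post hoc test.  Dunn's z statistics are computed from
the mean-rank formula with tie-corrected variance and Bonferroni
$m = k(k-1)/2$; this is hand-implemented (no installed package provides it)
and tested against a direct evaluation of the defining formula.  Spearman
correlations use midranks with pairwise-complete observations; a constant
column yields a flagged `NA`, never a silent 0.

### Mixed models

`fit_mixed_model()` fits crossed random intercepts for participant and
image with `lme4`.  Design choices:

* **Family.**  Gaussian with identity link is the default; a Gamma log-link
  option exists for strictly positive skewed outcomes.  The family used is
  recorded in every fit object.
* **ML, not REML**, everywhere: the ladder compares fixed-effect
  structures by likelihood-ratio test, which requires ML.
* **Coefficient p-values** are Wald z (normal approximation), the
  convention in GLMM reporting; they are approximate in small samples.
* **Reference levels**: environment `Urban`, horizon `Low`, weather
  `blue`, season `spring_summer`, so contrasts read as
  "High vs Low horizon" etc.
* A rank-deficient fixed design is an error naming the aliased columns;
  non-convergence and degenerate (zero residual variance) fits are flagged
  in the result, not raised.

Marginal and conditional $R^2$ follow the variance-component
decomposition: with $\sigma^2_f$ the variance of the fixed-effect linear
predictor over the data, $\sigma^2_p, \sigma^2_i$ the intercept variances
and $\sigma^2_e$ the residual variance,

$$R^2_{marginal} = \frac{\sigma^2_f}{\sigma^2_f + \sigma^2_p + \sigma^2_i +
\sigma^2_e}, \qquad
R^2_{conditional} = \frac{\sigma^2_f + \sigma^2_p + \sigma^2_i}
{\sigma^2_f + \sigma^2_p + \sigma^2_i + \sigma^2_e}.$$

`run_model_ladder()` fits an ordered list of specifications, optionally on
row subsets (e.g. presentations where both trees and sky were present),
compares each step to its named predecessor by AIC and LRT when the row
sets coincide, and marks the AIC-preferred step within each group of
comparable fits.  `default_sky_ladder()` encodes the canonical sequence for
the sky selection score (environment → + horizon → horizon alone →
+ weather → interaction → + season → weather × season);
`default_naturalness_ladder()` the selection-score models for naturalness.

## The synthetic generator

The generator reproduces the study's *structure* — a 4 (environment type) ×
3 (horizon) × 2 (vantage) factorial over 48 environments, 288 images,
96-trial per-participant schedules balanced at 8 trials per
(environment-type × horizon) cell, with each participant seeing one horizon
condition per environment × vantage slot — and plausible *marginals*:

* **Scenes.**  A top sky band occupies the target sky fraction (defaults
  per horizon: Low 0.41, Medium 0.19, High 0.04, matching the reported
  stimulus means; per-image fractions are drawn with per-horizon SDs
  0.23/0.13/0.044, matching the reported spread, truncated to [0, 1]).
  The below-horizon region is tiled with contiguous label patches grown
  from random Voronoi seeds whose label shares follow a per-environment
  composition.  Scene records are quantified from the emitted mask, never
  from the targets.  The analysis consumes only label identities and
  areas, so no photorealism is attempted.
* **Clicks.**  Counts are Poisson, truncated to 0–20, with environment
  means Urban 2, SomeUrban 4, SomeNature 5, Nature 6 (the reported
  selection-task means).  Each click targets a label with probability
  proportional to affinity × availability and lands on a uniformly chosen
  pixel of that label.  The distributional forms are conventions — the
  source experiments report only means and SDs — and are therefore
  configuration, not reconstruction.
* **Ratings.**  Linear fixed effects of scene covariates plus participant
  and image random intercepts (SDs 10 and 8 scale units by default) and
  residual noise (SD 12), *clipped* to the scale bounds (naturalness
  0–100, others −50..50).  Clipping rather than resampling reproduces the
  boundary pile-up typical of visual-analogue scales.  Default
  coefficients (e.g. naturalness = 15 + 0.65 × pct_nature) were chosen
  once to give realistic rating ranges and effect sizes.

Ground truth (profiles, rating model, image effects, seed) is retained in
the bundle; the same seed regenerates a bundle identically.

What passing tests on this generator do **not** show: real scenes have
spatially structured, correlated label layouts and real participants have
serial dependencies, attention drift and idiosyncratic strategies; none of
these are modelled.  The simulation validates the *pipeline arithmetic* and
the *statistical machinery* (calibration, recovery), not human behaviour.

## Operating characteristics measured in the test suite

The test suite measures, at fixed seeds:

* slope recovery for the crossed design (40 participants × 48 images,
  intercept SDs 5/5, residual SD 10, 100 replicates): mean bias under 10%
  and Wald 95% interval coverage within [90%, 98%];
* type-I error of the LRT (400-row crossed null fits) and of the
  Kruskal–Wallis test at α = 0.05, inside the exact binomial 95% band over
  200 null replicates;
* ladder recovery: with a true horizon effect and no environment effect,
  the AIC-preferred model includes horizon in over 80% of 50 replicates.

## Problem sizes and the acceptance script

`scripts/acceptance.R` (run as
`Rscript scripts/acceptance.R --seed N --out results/acceptance.json`)
recomputes the design arithmetic at the full stimulus scale and runs the
complete pipeline — generation, scoring, QC, validation statistics, the sky
ladder — on the package's demonstration scale: 24 participants on a
300 × 150 px canvas with the selection radius scaled accordingly (30 px).
This scale keeps a desk run under a minute while preserving the factorial
structure and the calibrated marginals; the full 105-participant,
1500 × 750 px configuration is a parameter change.

## Known limitations

* The image-level "extreme behaviour" flag is configuration-driven; the
  package does not attempt to infer which images would have been flagged.
* Wald z coefficient tests and the ML-based LRT are asymptotic;
  small-sample df corrections (Satterthwaite, Kenward–Roger) are not
  implemented.
* The Gamma option uses the Laplace approximation (adaptive quadrature is
  unavailable for crossed random effects), and variance-component
  $R^2$ is reported for Gaussian fits only.
* K-S normality p-values with estimated parameters are conservative; the
  result object says so.
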
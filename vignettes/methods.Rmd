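---
title: "Measuring and modeling glyph complexity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and modeling glyph complexity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, why the
numerical choices are what they are, and what the synthetic-data tests do
and do not establish about real corpora.

## The scientific questions

Characters of the world's scripts differ widely in visual complexity, and
complexity has measurable costs: complex shapes are slower to recognize,
easier to confuse, and more effortful to produce. The package implements
the measurement and inference layers for four questions:

1. **Size**: do scripts with larger graph inventories (more characters to
   keep apart) have more complex characters?
2. **Homogeneity**: how much of the variance in character complexity is
   explained by the script a character belongs to, versus its script
   family or its writing-system type?
3. **Evolutionary change**: are recently invented (idiosyncratic) scripts
   more complex than old ones, and do characters simplify when a script
   branches off from its ancestor?
4. **Order**: is complexity concentrated in the half of a character that
   is read first (left in left-to-right scripts, right in right-to-left
   scripts)?

Because cross-cultural observations are not independent (related scripts
inherit shape from common ancestors — Galton's problem), all inference
runs through mixed models with script, family, or ancestor random
intercepts rather than script-level regressions.

## Complexity metrics

### Perimetric complexity

For a binary image with summed boundary-contour length $P$ and foreground
area $A$ (pixels),

$$C = \frac{P^2}{4\pi A}.$$

$P$ includes the outer contour of every connected component *and* the
contour of every hole. $C$ is dimensionless and scale-free in the
continuum; a disk uniquely minimizes it at 1 (isoperimetric inequality),
an axis-aligned square gives $16s^2/(4\pi s^2) = 4/\pi \approx 1.273$,
and an annulus with radii $R > r$ gives $(R+r)/(R-r)$. These closed forms
are the package's calibration suite.

**Perimeter estimation.** Counting boundary pixel edges overestimates the
length of diagonal and curved boundaries by up to $\sqrt{2}$ and fails
the disk calibration badly (a digitized disk would measure $C \approx
1.27$). The package instead traces sub-pixel contours with marching
squares (`grDevices::contourLines` at level 0.5 on the zero-padded mask)
and then smooths each closed contour along its arc with a circular
Gaussian window whose standard deviation grows with contour length,
$\sigma = \sqrt{L}/10$ vertices. The window choice matters:

* A *fixed* window leaves an orientation-dependent staircase excess of
  roughly 1% that does not shrink as shapes grow, so the discretization
  error of a disk plateaus instead of converging.
* A window growing like $\sqrt{L}$ makes the staircase residual decay
  while the curvature-induced shrinkage it causes is $O(1/L)$; both
  vanish with size, giving true scale convergence (disk error 0.010 at
  $r=25$ down to 0.0002 at $r=200$) while corners of polygonal shapes are
  still rounded only locally (square error stays within 2%).

The divisor 10 was fixed once against the analytic suite (disk, square,
annulus, and sub-pixel placement robustness) before any corpus work; it
is a property of the estimator, not a tunable of the science.

Area is the raw foreground pixel count. Foreground touching the canvas
border is closed along the border and flagged with a warning, since the
cut edge then contributes to $P$.

### Algorithmic complexity

AC is the byte count of a losslessly compressed, canonical vector
rendering of the image: marching-squares contours, translated to the
drawing's own origin, coordinates rounded to 0.1 px, each closed path
rotated to start at its lexicographically smallest vertex, paths sorted,
serialized as decimal text, DEFLATE-compressed (`memCompress`, fixed
level). Three properties matter downstream, and all are tested:

* **Determinism**: identical pixels give identical bytes, across runs
  and platforms.
* **Monotonicity with structure**: adding a disjoint stroke strictly
  increases AC (checked over 100 random glyph pairs).
* **Translation invariance**: exact under whole-pixel shifts, because
  coordinates are origin-normalized.

AC values are comparable only *within* one serialization scheme; absolute
byte counts from other toolchains (different vectorizers, containers or
compression levels) live on a different scale. Mirror images serialize
with opposite contour orientation and may differ by a few percent of
their size; the null-calibration test verifies this does not bias
left/right differentials on random (non-mirror-paired) corpora.

Both metrics operate on the binary foreground mask; the black-on-white
versus white-on-black conventions of particular toolchains are
abstracted away because both measures are color-symmetric given the mask.

## Raster standardization

Fonts vary in size and line thickness, which both leak into complexity
measures. The pipeline therefore standardizes each script:

1. **Trim** to the tight foreground bounding box.
2. **Resize** every image of a script by *one shared ratio*, chosen so
   the script's largest trimmed image fits a 490 x 490 box; this removes
   between-script size variation while preserving within-script
   variation. Dimensions are rounded half away from zero and clamped to
   490 (deterministic across platforms); the glyph is centered on a
   fresh 500 x 500 canvas. Centering is a declared choice — alignment
   does not affect either metric, but it makes the half-split well
   defined.
3. **Homogenize line thickness**: thinning to an approximate medial axis
   (Zhang–Suen), pruning, then dilation with a half-width-2 box, giving
   a uniform 5 px stroke.

**Pruning semantics.** A *branch* is a skeleton path from a degree-1
pixel to the nearest junction; branches shorter than 35 px (the default
`prune_len`) are removed iteratively until stable, because thinning
ribbon-like strokes sprouts short spurs at corners and stroke ends that
are artifacts, not marks. Junction-free components are *kept* whatever
their length: a short isolated component is a genuine mark (a dot, a
diacritic-like element), not a thinning artifact. Pixel classification
uses the crossing number (0-to-1 transitions around the 8-neighborhood)
rather than raw neighbor counts, which misclassify diagonal contacts
along thin paths. The exact pruning rule of reference skeleton
implementations is generally unpublished; this one is declared and
directly unit-tested (a 10 px spur on an L-shape is removed, the L
survives; a 9 px bar comes out as the 5 px dilation of its axis).

**Rendering** is optional and abstracted behind a rasterizer closure:
`renderScriptGlyphs(rasterizer, codepoints)` drives any
`f(codepoint, point_size)` with the shared-point-size rule — start at 60,
re-render the *whole script* 5 points smaller whenever any glyph
overflows the canvas, stop when everything fits; missing codepoints
become missing-symbol markers that feed the per-script `n_missing`
inclusion rule (scripts with more than 5 missing symbols are excluded).

## Halves and differentials

Standardized 500-wide characters are cut at the midline (columns 1–250
and 251–500, no pixel lost or duplicated — the printed half sizes 250 x
500 and padded 300 x 500 are asserted exactly), each half padded with 50
background columns on its cut side, and re-measured. Cutting creates a
new artificial contour along the cut; padding keeps it away from the
image border. Perimetric complexity is inherently more sensitive to this
artificial contour than algorithmic complexity, which is exactly why the
suite includes the discrepancy analysis below.

Per character and metric:

* $\Delta_{FL}$ = first-half minus last-half complexity, where *first*
  is the left half of a left-to-right script and the right half of a
  right-to-left script. By construction $\Delta_{FL} = \Delta_{LR}$ for
  LR scripts and $-\Delta_{LR}$ for RL scripts; this sign law is tested
  as an exact identity over a 1,000-glyph corpus.
* $D$ = $z(\mathrm{PC}) - z(\mathrm{AC})$ per half, z-scored over the
  full population of analyzed halves (no grouping), diagnosing
  metric-specific laterality bias.

**Blank halves**: a blank half has no perimetric complexity (recorded
`NA`, dropped from PC differential analyses — logged) but a well-defined
algorithmic complexity (the blank-canvas baseline), so it stays in AC
analyses. This asymmetric policy minimizes data loss while never
inventing a PC value. Vertically written, boustrophedon, and
uncertain-direction scripts are excluded from all order analyses.

## Inference layer

* `fitRandomIntercept()` wraps `lmerTest::lmer`: REML estimates,
  Wald 95% intervals, Satterthwaite approximate df. Singular fits are
  flagged, with the offending variance component reported as 0.
* `deltaAIC()` refits both models with ML (`lme4::refitML`) and returns
  AIC(null) − AIC(test): positive favors the test model; a useless
  predictor costs about 2.
* `intraclassCorrelation()` is $\sigma^2_b / (\sigma^2_b + \sigma^2_w)$
  from a one-way random-intercept REML fit — on raw values for PC and
  log-transformed values for AC (byte counts are right-skewed and
  convergence behaves better on the log scale).
* `ancestryDifferentials()` subtracts each ancestor's mean complexity
  from each descendant's, then averages per ancestor *before* testing, so
  prolific ancestors do not dominate; the ancestor-averaged values go
  into the JZS test, and the pair-level values into a random-intercept
  model controlling for ancestor.
* `jzsBayesFactor()` computes the one-sample JZS Bayes factor by
  quadrature of the Zellner–Siow g-mixture integral (Cauchy prior on the
  standardized effect as a scale mixture of normals); the default prior
  scale is $\sqrt{2}/2$, the conventional "medium" default of this test
  family. The unit tests check it against an *independent* formulation —
  direct integration of the noncentral-t likelihood against the Cauchy
  prior — to within 1% on a $(t, n)$ grid, and its limits (null favored
  at $t=0$; BF $\to 0$ as $|t|$ grows; monotone between).
* `orderModels()` fits the order/laterality suite for one metric:
  intercept-only $\Delta_{FL}$ (family/script nesting), $\Delta_{FL}$
  with directionality, the order-versus-side model comparison on
  half-level data (ΔAIC), the discrepancy model with side and order
  fixed effects, and the $\Delta_{LR}$ model with directionality. For
  the invention-hypothesis follow-up, where the grouping structure of
  the reference analysis is ambiguous, both variants (with and without
  family) are available through the `random` argument of
  `fitRandomIntercept()` directly.

A sensitivity option re-runs size models excluding scripts with 200 or
more characters (`excludeLargeScripts()`), since the size effect is known
to hinge on a few very large logosyllabic systems.

## The synthetic corpus generator

`generatorSpec()` fixes the study conditions; `generateCorpus()` realizes
them reproducibly from one seed. Stroke counts follow a hierarchical
log-normal model,

$$\log n_{ij} = \log m_{t(i)} + s_i + \varepsilon_{ij},$$

with type means $m_t$ (defaults 3–9 strokes from alphabets to
logosyllabaries, bracketing hand-count norms for real scripts), script
effects $s_i \sim N(0, 0.25^2)$, and character noise
$\varepsilon_{ij} \sim N(0, 0.35^2)$. Glyphs are drawn as straight or
arc strokes at the standardized 5 px thickness (so they can bypass or
pass through `skeletonStandardize` equivalently — both paths are
tested); each stroke lands in the reading-order first half with
probability `first_half_share` (0.5 = the symmetric null). The default
directionality mix is 78% LR / 22% RL, matching the balance of
horizontally written scripts in real inventories. Within each family the
first script is the ancestor of its siblings, and `delta_drift` shifts
descendants' log stroke counts (0 = no change at branching). Every
latent quantity is emitted in a truth sidecar (`truth.json`) so recovery
tests never re-derive ground truth from generator internals.

**What the generator does and does not emulate.** It reproduces the
*statistical* structure the analyses assume — hierarchical complexity
variance, directionality, within-character asymmetry, ancestry — with
known truth, which is exactly what parameter-recovery and calibration
tests need. It does not produce typographically plausible shapes,
connected glyphs, stroke-orientation anisotropy, or the extreme inventory
sizes of logographic systems; passing tests therefore validate the
pipeline's correctness and calibration, not any empirical claim about
real scripts. Real-corpus effect sizes (regression coefficients, ICC
percentages, Bayes factors) depend on the fonts and inventories used and
are not reproduced here.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale corpora chosen as the smallest
sizes at which each property is statistically decidable: the sign law and
concordance on 560–1,000 glyphs; order-effect recovery on 320 glyphs at
`first_half_share = 0.60`; type-I calibration of the $\Delta_{FL}$
intercept over 200 replicate corpora of 8 scripts x 6 characters at the
symmetric share (rejection rate checked against the nominal 5% within
Monte-Carlo error); ICC recovery at 50 groups x 20 and, in the
acceptance script, 200 x 10. The ICC(type) > ICC(script) recovery uses
3 types x 8 scripts per family with zero script-level variance, where
the ordering is robustly identified.

Other fixed choices: binarization of grayscale inputs at 50% of the
dynamic range; the 250/251 cut column (an even 500 splits cleanly; no
pixel duplication); padding uses the background color of the processed
stage; quadrature tolerance $10^{-10}$ for the Bayes factor;
`integrate()` on $(0, \infty)$ for the g-mixture. PC on padded (not
unpadded) halves, matching the geometry in which the artificial cut
contour is kept away from the border.

## Known limitations

* AC byte counts are serialization-specific; only within-package
  comparisons are meaningful, and mirror images are not exactly
  AC-invariant (a few percent; unbiased over random corpora).
* The perimeter estimator's adaptive smoothing slightly rounds true
  corners (square measured ~1.25 vs 4/pi ~ 1.273); for glyph-scale
  strokes this is negligible relative to between-character variation.
* Thinning is Zhang–Suen, an approximation to the exact medial axis;
  skeletons of ribbon strokes are faithful, but very thick blobs lose
  interior detail by design.
* The generator's inventory sizes are constant per corpus, so the
  size-effect regression on synthetic corpora is a structural smoke test
  (it runs, with the size column dropped as rank-deficient when
  constant) rather than a recovery test; size-effect recovery is tested
  on simulated numeric data instead.
* Mixed models on small synthetic corpora are frequently singular
  (script-level variance estimated at zero); fits are flagged rather
  than hidden.
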
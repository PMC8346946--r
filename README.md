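# glyphmetry

Visual complexity of writing-system characters, measured and modeled in R.

Scripts — sets of graphic characters such as Latin, Arabic or Brahmi — vary
enormously in how visually complex their characters are. This package
implements a complete, testable pipeline for asking what drives that
variation: does complexity track the number of characters a script has to
keep distinct (its graph inventory size)? Is it set mostly by the writing
system's type (alphabet, abjad, abugida, syllabary, logosyllabary,
featural)? Do characters simplify when scripts branch off from their
ancestors? And is complexity concentrated in the half of the character a
reader meets first, as reading-order accounts of letter perception
predict?

It is written for quantitative students of writing systems and cultural
evolution who have per-character binary images (rendered from fonts or
digitized) plus a script-level inventory table, and for methodologists who
want the measurement layer — the two complexity metrics and the raster
standardization — on its own.

## The measures and models

**Perimetric complexity.** For a binary image with total boundary contour
length *P* (outside contours of all components plus the contours of all
holes) and foreground area *A*,

    C = P^2 / (4 pi A).

A filled disk minimizes C at 1; thin, fragmented, or holed shapes score
higher. The boundary is traced at sub-pixel resolution (marching squares
with arc-length-adaptive smoothing), so the analytic values for simple
shapes are met within a few percent: a disk measures 1.001, a square
1.251 (4/pi = 1.273), an annulus with radii 150/50 measures 2.001
(exactly (R+r)/(R−r) = 2).

**Algorithmic complexity.** The image is vectorized to a canonical
closed-path outline (coordinates to 0.1 px, fixed path order) and the
serialized vector file is DEFLATE-compressed; AC is the compressed byte
count — a proxy for description length. The two metrics are strongly
rank-correlated on any corpus with real structural variation.

**Standardization.** Rasters are trimmed, resized per script so the
largest character fits a 490-px box (one shared ratio preserves
within-script size variation), re-centered on a 500x500 canvas, and
brought to a uniform ~5 px stroke: medial-axis thinning, pruning of
skeleton branches shorter than 35 px, dilation with a half-width-2 box.

**Halves.** Each standardized character is cut at the vertical midline
into two 250x500 halves, padded on the cut side to 300x500, and measured
again. Per character and metric the pipeline derives the first-minus-last
differential (first = left in left-to-right scripts, right in
right-to-left scripts), the left-minus-right differential, and a
discrepancy score z(PC) − z(AC) per half.

**Inference.** Random-intercept mixed models (REML, Satterthwaite df,
ML refits for AIC comparison) for the size and invention hypotheses;
intraclass correlations for the homogeneity question; ancestor-averaged
complexity differentials with a JZS Bayesian one-sample t-test (Cauchy
prior, scale sqrt(2)/2, computed by quadrature) for branching-out events;
and the order/laterality regression suite for the reading-order
hypothesis.

A seeded synthetic-corpus generator (`generateCorpus()`) emits inventories,
character tables and glyph images with controlled hierarchical structure
— type-level stroke-count means, script effects, character noise, a
directionality mix, an adjustable share of strokes in the reading-order
first half, and ancestry drift — so every stage of the pipeline is
testable without fonts or downloads.

## Worked example

```r
library(glyphmetry)

# a synthetic corpus: 28 scripts in 7 families, 20 characters each,
# with 60% of strokes in the reading-order first half
spec <- generatorSpec(first_half_share = 0.60, seed = 2)
corpus <- generateCorpus(spec)

measures <- measureGlyphs(corpus$glyphs)
metricConcordance(measures)
#> [1] 0.9766304

tabs <- halvesTable(corpus$glyphs, corpus$inventory)
om <- orderModels(tabs, "ac")
fixedEffects(om$intercept)
#>             estimate ci_lower ci_upper       df        t           p
#> (Intercept) 663.7946 365.2858 962.3035 6.000004 4.358375 0.004778901
```

The Spearman correlation of 0.98 says the two complexity metrics rank
these characters almost identically. The positive, significant intercept
(~664 bytes, t = 4.36) is the first-half advantage in algorithmic
complexity: with 60% of strokes placed in the half read first, first
halves compress to systematically more bytes than last halves, exactly
the signature the order analysis is built to detect. At
`first_half_share = 0.5` the same intercept is null-calibrated (the test
suite checks its type-I rate over 200 replicate corpora).

`runPipeline(pipelineConfig(...))` chains synthesis (or loading),
standardization, measurement, half-splitting and analysis from a single
seeded configuration and writes tidy CSV tables plus a JSON manifest with
row counts at every filter.

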
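Package: glyphmetry
Title: Visual Complexity of Writing-System Characters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the visual complexity of binary character images from
    writing systems and tests hypotheses about its distribution across and
    within scripts. Implements perimetric complexity (squared total contour
    length over 4*pi times foreground area, estimated by sub-pixel contour
    tracing) and algorithmic complexity (byte size of a losslessly
    compressed canonical vector outline); a raster standardization pipeline
    (trimming, per-script adaptive resizing, line-thickness homogenization
    by thinning, branch pruning and dilation); vertical half-splitting with
    inner-side padding and reading-order complexity differentials; and the
    inferential layer: nested random-intercept mixed models with AIC
    comparison, intraclass correlations, ancestor-descendant differentials
    with a JZS Bayesian one-sample t-test, and the order/laterality
    regression suite. A synthetic corpus generator with controlled
    hierarchical effects makes every stage testable without fonts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'corpus.R'
    'thinning.R'
    'imaging.R'
    'complexity.R'
    'halves.R'
    'stats-mixed.R'
    'stats-bayes.R'
    'synthetic.R'
    'pipeline.R'
    'glyphmetry-package.R'
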
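test_that("vertical split is an exact partition of the canvas", {
  set.seed(5)
  g <- generateGlyph(4, 0.5, "LR")
  halves <- splitVertical(g)
  expect_identical(dim(halves$left), c(250L, 500L))
  expect_identical(dim(halves$right), c(250L, 500L))
  expect_identical(
    foregroundCount(halves$left) + foregroundCount(halves$right),
    foregroundCount(g)
  )
  expect_identical(rbind(glyphPixels(halves$left), glyphPixels(halves$right)),
                   glyphPixels(g))
  # glyph entirely left of the cut -> blank right half
  gl <- generateGlyph(2, 1.0, "LR")
  expect_identical(foregroundCount(splitVertical(gl)$right), 0L)
  expect_error(splitVertical(GlyphImage(matrix(FALSE, 300, 500))), "500")
})

test_that("a vertically symmetric glyph splits into mirror-image halves", {
  px <- matrix(FALSE, 500, 500)
  px[101:400, 248:252] <- TRUE   # x-extent symmetric about the 250|251 cut
  px[249:252, 101:400] <- TRUE
  halves <- splitVertical(GlyphImage(px, stage = "skeleton-standardized"))
  expect_identical(glyphPixels(halves$left),
                   glyphPixels(halves$right)[250:1, ])
})

test_that("inner padding lands on the cut side and makes 300x500 halves", {
  px <- matrix(FALSE, 500, 500)
  px[40:460, 240:260] <- TRUE
  g <- GlyphImage(px, stage = "skeleton-standardized")
  halves <- splitVertical(g)
  pl <- padInner(halves$left, "left")
  pr <- padInner(halves$right, "right")
  expect_identical(dim(pl), c(300L, 500L))
  expect_identical(dim(pr), c(300L, 500L))
  # left half: padding occupies columns 251-300 (blank)
  expect_identical(sum(glyphPixels(pl)[251:300, ]), 0L)
  expect_true(any(glyphPixels(pl)[1:250, ]))
  # right half: padding occupies columns 1-50
  expect_identical(sum(glyphPixels(pr)[1:50, ]), 0L)
  expect_true(any(glyphPixels(pr)[51:300, ]))
  expect_error(padInner(pl, "left"), "250")
})

test_that("unpadding and rejoining reconstructs the original bit-exactly", {
  set.seed(6)
  for (i in 1:5) {
    g <- generateGlyph(sample(1:6, 1L), runif(1), sample(c("LR", "RL"), 1L))
    pair <- halfPair(g, "LR")
    expect_identical(glyphPixels(rejoinHalves(pair)), glyphPixels(g))
  }
})

test_that("half complexities handle symmetry, blanks and the half-disk value", {
  # symmetric cross: equal halves within contour discretization
  px <- matrix(FALSE, 500, 500)
  px[101:400, 248:252] <- TRUE
  px[249:252, 101:400] <- TRUE   # mirror-symmetric about the cut
  h <- halfComplexities(halfPair(GlyphImage(px,
    stage = "skeleton-standardized"), "LR"))
  expect_equal(h$C[1L], h$C[2L], tolerance = 0.01)
  # mirror-image halves serialize with opposite contour orientation, so
  # their compressed sizes agree only within a few bytes
  expect_lte(abs(h$AC[1L] - h$AC[2L]) / h$AC[1L], 0.08)
  expect_identical(h$order, c("first", "last"))

  # glyph fully in the left half: blank right gets NA PC, baseline AC
  gl <- generateGlyph(2, 1.0, "LR", seed = 8)
  hb <- halfComplexities(halfPair(gl, "LR"))
  expect_true(is.na(hb$C[2L]))
  expect_identical(hb$AC[2L], as.numeric(acBaseline(300L, 500L)))

  # disk centered on the cut: each half is analytically a half-disk,
  # C = (pi*r + 2r)^2 / (4*pi*(pi*r^2/2)) = (pi+2)^2 / (2*pi^2)
  r <- 150
  d <- outer(1:500, 1:500, function(i, j) sqrt((i - 250.5)^2 + (j - 250)^2))
  disk <- GlyphImage(d <= r, stage = "skeleton-standardized")
  hd <- halfComplexities(halfPair(disk, "LR"), metrics = "pc")
  expect_equal(hd$C[1L], (pi + 2)^2 / (2 * pi^2), tolerance = 0.05 / 1.34)
  expect_equal(hd$C[2L], (pi + 2)^2 / (2 * pi^2), tolerance = 0.05 / 1.34)
})

test_that("the first-last differential follows reading order by definition", {
  expect_identical(firstLastDifferential(10, 6, "LR"), 4)
  expect_identical(firstLastDifferential(10, 6, "RL"), -4)
  expect_identical(firstLastDifferential(c(10, 10), c(6, 6), c("LR", "RL")),
                   c(4, -4))
  expect_error(firstLastDifferential(1, 2, "other"), "directionality")
})

test_that("discrepancy scores are centered z-differences", {
  h <- data.frame(
    C = c(1, 2, 3, 4, 5, 6),
    AC = c(10, 20, 30, 40, 50, 60),
    side = rep(c("left", "right"), 3L)
  )
  # identical rank and scale after z-normalization -> D = 0 everywhere
  d <- discrepancyScores(h)
  expect_equal(d$D, rep(0, 6))
  # inflating right-half PC by a constant shifts D right over left
  h2 <- h
  h2$C[h2$side == "right"] <- h2$C[h2$side == "right"] + 2
  d2 <- discrepancyScores(h2)
  expect_gt(mean(d2$D[d2$side == "right"]), mean(d2$D[d2$side == "left"]))
  expect_equal(mean(d2$D), 0)
  h3 <- h
  h3$AC <- 5
  expect_error(discrepancyScores(h3), "zero variance")
})

test_that("sign law: first-last equals signed left-right per directionality", {
  spec <- generatorSpec(n_families = 2L, scripts_per_family = 3L,
                        chars_per_script = 5L, share_LR = 0.5, seed = 17L)
  corpus <- generateCorpus(spec)
  tabs <- suppressMessages(halvesTable(corpus$glyphs, corpus$inventory))
  ch <- tabs$characters
  lr <- ch$directionality == "LR"
  expect_identical(ch$dFL_ac[lr], ch$dLR_ac[lr])
  expect_identical(ch$dFL_ac[!lr], -ch$dLR_ac[!lr])
  ok <- !is.na(ch$dFL_pc)
  expect_identical(ch$dFL_pc[ok & lr], ch$dLR_pc[ok & lr])
  expect_identical(ch$dFL_pc[ok & !lr], -ch$dLR_pc[ok & !lr])
})

test_that("mirroring an LR corpus and relabeling RL preserves first-last AC", {
  set.seed(23)
  diffs_lr <- numeric(0)
  diffs_rl <- numeric(0)
  for (i in 1:15) {
    g <- generateGlyph(sample(2:5, 1L), 0.7, "LR")
    mirrored <- GlyphImage(glyphPixels(g)[500:1, ],
                           stage = "skeleton-standardized")
    h1 <- halfComplexities(halfPair(g, "LR"), metrics = "ac")
    h2 <- halfComplexities(halfPair(mirrored, "RL"), metrics = "ac")
    diffs_lr <- c(diffs_lr, h1$AC[h1$order == "first"] -
                    h1$AC[h1$order == "last"])
    diffs_rl <- c(diffs_rl, h2$AC[h2$order == "first"] -
                    h2$AC[h2$order == "last"])
  }
  # serialization of mirrored contours differs slightly; the distribution
  # of first-minus-last differentials is preserved
  expect_gt(stats::cor(diffs_lr, diffs_rl), 0.99)
  expect_lt(abs(mean(diffs_lr - diffs_rl)), 0.05 * stats::sd(diffs_lr))
})
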
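test_that("trim returns the tight bounding box and is idempotent", {
  px <- matrix(FALSE, 500, 500)
  px[201:300, 101:140] <- TRUE  # 100 x 40 block
  tr <- trimGlyph(GlyphImage(px))
  expect_identical(dim(tr), c(100L, 40L))
  expect_true(all(glyphPixels(tr)))
  expect_identical(glyphStage(tr), "trimmed")
  # already tight -> unchanged
  again <- trimGlyph(tr)
  expect_identical(glyphPixels(again), glyphPixels(tr))
  expect_error(trimGlyph(GlyphImage(matrix(FALSE, 5, 5))), "blank")
})

test_that("the per-script resize ratio comes from the largest dimension", {
  g <- function(w, h) GlyphImage(matrix(TRUE, w, h), stage = "trimmed")
  expect_equal(scriptResizeRatio(list(g(700, 300))), 0.7)
  expect_equal(scriptResizeRatio(list(g(490, 490))), 1.0)
  expect_equal(scriptResizeRatio(list(g(100, 50), g(980, 10), g(200, 200))),
               0.5)
  expect_error(scriptResizeRatio(list()), "no images")
})

test_that("resize preserves aspect ratio and centers on the 500 canvas", {
  g <- GlyphImage(matrix(TRUE, 700, 300), stage = "trimmed")
  rz <- resizeAndCenter(g, 0.7)
  expect_identical(dim(rz), c(500L, 500L))
  expect_identical(glyphStage(rz), "resized")
  px <- glyphPixels(rz)
  xr <- range(which(rowSums(px) > 0))
  yr <- range(which(colSums(px) > 0))
  expect_identical(diff(xr) + 1L, 490L)
  expect_identical(diff(yr) + 1L, 210L)
  # centered within a pixel
  expect_lte(abs((xr[1L] - 1L) - (500L - xr[2L])), 1L)
  expect_lte(abs((yr[1L] - 1L) - (500L - yr[2L])), 1L)

  # ratio 1 on an already-fitting image keeps its size
  g2 <- GlyphImage(matrix(TRUE, 490, 490), stage = "trimmed")
  rz2 <- resizeAndCenter(g2, 1.0)
  expect_identical(sum(glyphPixels(rz2)), 490L * 490L)

  # a shared ratio preserves relative sizes within the script
  big <- GlyphImage(matrix(TRUE, 600, 100), stage = "trimmed")
  small <- GlyphImage(matrix(TRUE, 300, 100), stage = "trimmed")
  ratio <- scriptResizeRatio(list(big, small))
  wb <- diff(range(which(rowSums(glyphPixels(resizeAndCenter(big, ratio))) > 0))) + 1L
  ws <- diff(range(which(rowSums(glyphPixels(resizeAndCenter(small, ratio))) > 0))) + 1L
  expect_equal(wb / ws, 2, tolerance = 0.01)

  expect_error(resizeAndCenter(g, 1.2), "beyond")
})

test_that("skeleton standardization reduces a thick bar to a 5-px stroke", {
  px <- matrix(FALSE, 500, 500)
  px[100:400, 246:254] <- TRUE  # 9-px-thick bar
  out <- skeletonStandardize(GlyphImage(px, stage = "resized"))
  expect_identical(glyphStage(out), "skeleton-standardized")
  opx <- glyphPixels(out)
  # compare against the directly constructed dilated medial axis
  axis <- matrix(FALSE, 500, 500)
  axis[100:400, 250] <- TRUE
  expected <- glyphmetry:::.boxDilate(axis, 2L)
  iou <- sum(opx & expected) / sum(opx | expected)
  expect_gt(iou, 0.9)
  # uniform 5-px thickness across the glyph
  expect_equal(range(colSums(opx[, colSums(opx) > 0])), c(296, 296))
  expect_equal(unique(rowSums(opx[rowSums(opx) > 0, , drop = FALSE])), 5)
})

test_that("pruning removes short junction branches but keeps open components", {
  sk <- matrix(FALSE, 160, 160)
  sk[20, 20:120] <- TRUE        # L shape: both arms > 35 px from the spur
  sk[20:100, 120] <- TRUE
  sk[21:30, 70] <- TRUE         # 10-px spur artifact
  pr <- glyphmetry:::.pruneBranches(sk, 35)
  expect_false(any(pr[21:30, 70]))
  expect_true(all(pr[20, 20:120]))
  expect_true(all(pr[20:100, 120]))
  # a junction-free component shorter than the threshold is kept
  sk2 <- matrix(FALSE, 100, 100)
  sk2[10:20, 50] <- TRUE
  expect_identical(glyphmetry:::.pruneBranches(sk2, 35), sk2)
})

test_that("standardized output has near-constant stroke thickness", {
  set.seed(21)
  g <- generateGlyph(4, 0.5, "LR")
  raw <- GlyphImage(glyphPixels(g), stage = "raw")
  std <- standardizeScript(list(raw), skeletonize = TRUE)[[1L]]
  d <- glyphmetry:::.chessboardDistance(glyphPixels(std))
  frac <- mean(d[glyphPixels(std)] <= 3L)  # dilation_radius + 1
  expect_gte(frac, 0.95)
})

test_that("standardization is deterministic: same bytes in, same bytes out", {
  px <- matrix(FALSE, 500, 500)
  px[150:350, 200:320] <- TRUE
  px[220:280, 100:400] <- TRUE
  g <- GlyphImage(px, stage = "resized")
  a <- skeletonStandardize(g)
  b <- skeletonStandardize(g)
  expect_identical(glyphPixels(a), glyphPixels(b))
})

test_that("adaptive point size re-renders the whole script until it fits", {
  # mock rasterizer: glyph side scales linearly with point size
  rast <- function(cp, ps) {
    if (cp == "MISS") return(NULL)
    need <- if (cp == "BIG") 520 else 200
    size <- round(need * ps / 60)
    m <- matrix(FALSE, 500, 500)
    lo <- max(1L, 250L - size %/% 2L)
    hi <- min(500L, lo + size - 1L)
    m[lo:hi, lo:hi] <- TRUE
    g <- GlyphImage(m)
    attr(g, "overflow") <- size > 500
    g
  }
  res <- renderScriptGlyphs(rast, c("A1", "BIG", "MISS"), script = "Test")
  expect_identical(res$point_size, 55)  # one decrement needed
  expect_identical(res$n_missing, 1L)
  expect_null(res$glyphs[["MISS"]])
  expect_identical(scriptCode(res$glyphs[["A1"]]), "Test")

  # everything fits at the starting size -> no fallback
  res2 <- renderScriptGlyphs(rast, "A1")
  expect_identical(res2$point_size, 60)

  # rasterizer that never fits -> error at point size 0
  always_big <- function(cp, ps) {
    g <- GlyphImage(matrix(TRUE, 500, 500))
    attr(g, "overflow") <- TRUE
    g
  }
  expect_error(renderScriptGlyphs(always_big, "A1"), "point size reached 0")
})

test_that("glyph images round-trip through PBM and PNG byte-exactly", {
  set.seed(4)
  g <- generateGlyph(3, 0.5, "LR")
  g@script <- "Aaaa"
  g@codepoint <- "4001"
  d <- tempfile()
  dir.create(d)
  for (fmt in c("pbm", "png")) {
    p <- file.path(d, paste0("Aaaa_4001.", fmt))
    writeGlyph(g, p)
    back <- readGlyph(p, stage = "skeleton-standardized")
    expect_identical(glyphPixels(back), glyphPixels(g))
    expect_identical(scriptCode(back), "Aaaa")
    expect_identical(codepointId(back), "4001")
  }
  dirload <- readGlyphDir(d)
  expect_identical(length(dirload), 2L)  # same glyph in both formats
})
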
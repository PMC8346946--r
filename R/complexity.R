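# Sub-pixel boundary contours of a binary mask.
#
# The mask is padded with background so that shapes touching the canvas
# border still yield closed contours (the canvas edge acts as boundary),
# then traced with marching squares at the 0.5 level. Each closed
# contour is optionally smoothed along its arc with a circular Gaussian
# window whose scale grows with contour length (sigma = sqrt(L) / 10):
# this removes the pixel-scale staircase excess while the induced
# curvature shrinkage stays O(1/L), so the perimeter estimate converges
# as shapes grow.
.CONTOUR_PAD <- 6L
.CONTOUR_SMOOTH_DIV <- 10

.circularGaussSmooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0.2 || n < 5L) return(x)
  kh <- min(n %/% 2L, max(2L, ceiling(3 * sigma)))
  k <- exp(-((-kh:kh)^2) / (2 * sigma^2))
  k <- k / sum(k)
  xx <- c(x[(n - kh + 1L):n], x, x[1:kh])
  as.numeric(stats::filter(xx, k)[(kh + 1L):(kh + n)])
}

.polyLength <- function(x, y) sum(sqrt(diff(x)^2 + diff(y)^2))

# Returns a list of contours: each has x, y (sub-pixel vertices in padded
# coordinates) and closed (logical).
.traceContours <- function(px) {
  pad <- .CONTOUR_PAD
  z <- matrix(0, nrow(px) + 2L * pad, ncol(px) + 2L * pad)
  z[pad + seq_len(nrow(px)), pad + seq_len(ncol(px))] <- px * 1
  cl <- grDevices::contourLines(
    x = seq_len(nrow(z)), y = seq_len(ncol(z)), z = z, levels = 0.5
  )
  lapply(cl, function(c1) {
    n <- length(c1$x)
    closed <- abs(c1$x[1L] - c1$x[n]) < 1e-9 && abs(c1$y[1L] - c1$y[n]) < 1e-9
    list(x = c1$x, y = c1$y, closed = closed)
  })
}

.contourPerimeter <- function(contours) {
  tot <- 0
  for (c1 in contours) {
    x <- c1$x
    y <- c1$y
    if (c1$closed) {
      n <- length(x)
      x <- x[-n]
      y <- y[-n]
      l_raw <- .polyLength(c(x, x[1L]), c(y, y[1L]))
      sigma <- sqrt(l_raw) / .CONTOUR_SMOOTH_DIV
      x <- .circularGaussSmooth(x, sigma)
      y <- .circularGaussSmooth(y, sigma)
      x <- c(x, x[1L])
      y <- c(y, y[1L])
    }
    tot <- tot + .polyLength(x, y)
  }
  tot
}

#' Perimetric complexity of a binary image
#'
#' C = P^2 / (4 pi A): the squared total length of the inside and
#' outside boundary contours P, divided by the foreground area A and by
#' 4 pi. A filled disk minimizes C at 1; thin, elongated, fragmented or
#' holed shapes score higher. P sums the sub-pixel lengths of the outer
#' contours of every connected component and of every hole.
#'
#' Foreground touching the canvas border is closed along the border
#' (with a warning): the canvas edge acts as part of the boundary.
#'
#' @param glyph a [GlyphImage-class] (or logical/0-1 matrix) with at
#'   least one foreground pixel.
#' @return a [ComplexityResult-class] with P, A and C filled (AC is NA).
#' @examples
#' d <- outer(1:220, 1:220, function(i, j) (i - 110)^2 + (j - 110)^2 <= 100^2)
#' perimetricComplexity(GlyphImage(d)) # C close to 1
#' @export
perimetricComplexity <- function(glyph) {
  px <- if (is(glyph, "GlyphImage")) glyph@pixels else glyph
  stopifnot(is.matrix(px))
  if (is.numeric(px)) storage.mode(px) <- "logical"
  if (!any(px)) stop("perimetricComplexity: blank image")
  if (any(px[1L, ]) || any(px[nrow(px), ]) || any(px[, 1L]) ||
      any(px[, ncol(px)])) {
    warning("foreground touches the canvas border; contour closed along the border")
  }
  A <- sum(px)
  P <- .contourPerimeter(.traceContours(px))
  .ComplexityResult(P = P, A = A, C = P^2 / (4 * pi * A))
}

# Canonical vector serialization: closed paths from marching squares,
# coordinates translated to the drawing's own origin and rounded to
# 0.1 px, each path rotated to start at its lexicographically smallest
# vertex, paths sorted; the byte stream is the decimal text of the path
# list. Deterministic across runs and platforms, and invariant under
# whole-pixel translation of the drawing.
.canonicalVector <- function(px) {
  contours <- .traceContours(px)
  if (length(contours)) {
    x0 <- min(vapply(contours, function(c1) min(c1$x), numeric(1L)))
    y0 <- min(vapply(contours, function(c1) min(c1$y), numeric(1L)))
  } else {
    x0 <- y0 <- 0
  }
  paths <- vapply(contours, function(c1) {
    x <- round((c1$x - x0) * 10) / 10
    y <- round((c1$y - y0) * 10) / 10
    n <- length(x)
    if (c1$closed && n > 1L) {
      x <- x[-n]
      y <- y[-n]
      key <- order(x, y)[1L]
      idx <- c(key:length(x), if (key > 1L) 1:(key - 1L))
      x <- x[idx]
      y <- y[idx]
    }
    paste(sprintf("%.1f,%.1f", x, y), collapse = " ")
  }, character(1L))
  paste(sort(paths), collapse = "\n")
}

#' Algorithmic complexity of a binary image
#'
#' The image is vectorized to a canonical closed-path outline
#' representation (sub-pixel contours, coordinates rounded to 0.1 px,
#' fixed path order), and the serialized vector file is losslessly
#' DEFLATE-compressed; AC is the compressed byte count. A blank canvas
#' yields the baseline byte count, the smallest possible value.
#'
#' @param glyph a [GlyphImage-class] or logical/0-1 matrix (blank
#'   allowed).
#' @return integer byte count.
#' @export
algorithmicComplexity <- function(glyph) {
  px <- if (is(glyph, "GlyphImage")) glyph@pixels else glyph
  stopifnot(is.matrix(px))
  if (is.numeric(px)) storage.mode(px) <- "logical"
  ser <- .canonicalVector(px)
  length(memCompress(charToRaw(ser), type = "gzip"))
}

#' Baseline algorithmic complexity of a blank canvas
#'
#' @param width,height canvas dimensions (defaults 500x500).
#' @return integer byte count of the compressed empty vector file.
#' @export
acBaseline <- function(width = 500L, height = 500L) {
  algorithmicComplexity(matrix(FALSE, width, height))
}

#' Measure both complexity metrics for one glyph
#'
#' @param glyph a [GlyphImage-class].
#' @return a [ComplexityResult-class] with P, A, C and AC filled.
#' @export
glyphComplexity <- function(glyph) {
  pc <- perimetricComplexity(glyph)
  .ComplexityResult(P = pc@P, A = pc@A, C = pc@C,
      AC = as.numeric(algorithmicComplexity(glyph)))
}

#' Measure a list of glyphs into a tidy table
#'
#' @param glyphs list of [GlyphImage-class].
#' @param metrics character subset of \code{c("pc", "ac")}.
#' @return data.frame with columns script, codepoint, P, A, C, AC.
#' @export
measureGlyphs <- function(glyphs, metrics = c("pc", "ac")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  rows <- lapply(glyphs, function(g) {
    P <- A <- C <- AC <- NA_real_
    if ("pc" %in% metrics) {
      r <- perimetricComplexity(g)
      P <- r@P
      A <- r@A
      C <- r@C
    }
    if ("ac" %in% metrics) AC <- as.numeric(algorithmicComplexity(g))
    data.frame(script = g@script, codepoint = g@codepoint,
               P = P, A = A, C = C, AC = AC, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank concordance of the two complexity metrics
#'
#' Spearman rank correlation of perimetric vs. algorithmic complexity
#' across characters.
#'
#' @param measures data.frame with columns \code{C} and \code{AC} (as
#'   from [measureGlyphs()]).
#' @return Spearman's rho.
#' @export
metricConcordance <- function(measures) {
  stopifnot(all(c("C", "AC") %in% names(measures)))
  ok <- stats::complete.cases(measures[, c("C", "AC")])
  x <- measures$C[ok]
  y <- measures$AC[ok]
  if (length(x) < 3L) stop("metricConcordance: need at least 3 characters")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("metricConcordance: a metric is constant; rank correlation undefined")
  }
  stats::cor(x, y, method = "spearman")
}
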
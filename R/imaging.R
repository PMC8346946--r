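#' Trim a glyph to its foreground bounding box
#'
#' @param glyph a [GlyphImage-class] with at least one foreground pixel.
#' @return the tight bounding-box crop, stage \code{"trimmed"}.
#' @export
trimGlyph <- function(glyph) {
  stopifnot(is(glyph, "GlyphImage"))
  px <- glyph@pixels
  if (!any(px)) stop("trimGlyph: blank image")
  xr <- range(which(rowSums(px) > 0))
  yr <- range(which(colSums(px) > 0))
  GlyphImage(px[xr[1L]:xr[2L], yr[1L]:yr[2L], drop = FALSE],
             stage = "trimmed", script = glyph@script,
             codepoint = glyph@codepoint)
}

#' Per-script resize ratio
#'
#' One ratio per script: how much the script's largest trimmed image must
#' be scaled for its largest dimension to fit a 490 by 490 pixel square.
#' Applying the same ratio to every image of the script standardizes size
#' between scripts while preserving the size variation within a script.
#'
#' @param glyphs list of trimmed [GlyphImage-class] objects (one script).
#' @return scalar ratio (490 / largest dimension over all images).
#' @export
scriptResizeRatio <- function(glyphs) {
  if (length(glyphs) == 0L) stop("scriptResizeRatio: no images")
  maxdim <- max(vapply(glyphs, function(g) max(dim(g@pixels)), numeric(1L)))
  .FIT_BOX / maxdim
}

.roundHalfAway <- function(x) floor(x + 0.5)

#' Resize a trimmed glyph and center it on the 500x500 canvas
#'
#' Nearest-neighbor scaling by a common per-script ratio, aspect ratio
#' preserved (each dimension rounded half away from zero, clamped to
#' 490), then centered on a fresh 500 by 500 background canvas.
#'
#' @param glyph trimmed [GlyphImage-class].
#' @param ratio scalar from [scriptResizeRatio()].
#' @return [GlyphImage-class] at stage \code{"resized"} (500x500).
#' @export
resizeAndCenter <- function(glyph, ratio) {
  stopifnot(is(glyph, "GlyphImage"), ratio > 0)
  px <- glyph@pixels
  w <- nrow(px)
  h <- ncol(px)
  if (max(w, h) * ratio > .FIT_BOX + 1) {
    stop(sprintf(
      "resizeAndCenter: ratio %.4f would scale %dx%d beyond the %d-px fit box",
      ratio, w, h, .FIT_BOX
    ))
  }
  w2 <- min(.FIT_BOX, max(1L, .roundHalfAway(w * ratio)))
  h2 <- min(.FIT_BOX, max(1L, .roundHalfAway(h * ratio)))
  sx <- pmin(w, pmax(1L, ceiling((seq_len(w2) - 0.5) * w / w2)))
  sy <- pmin(h, pmax(1L, ceiling((seq_len(h2) - 0.5) * h / h2)))
  small <- px[sx, sy, drop = FALSE]
  canvas <- matrix(FALSE, .CANVAS, .CANVAS)
  ox <- (.CANVAS - w2) %/% 2L
  oy <- (.CANVAS - h2) %/% 2L
  canvas[ox + seq_len(w2), oy + seq_len(h2)] <- small
  GlyphImage(canvas, stage = "resized", script = glyph@script,
             codepoint = glyph@codepoint)
}

#' Homogenize line thickness by thinning, pruning and dilation
#'
#' Reduces the glyph to its (approximate) medial-axis skeleton, removes
#' skeleton branches shorter than \code{prune_len} pixels (artifacts of
#' thinning), and dilates the cleaned skeleton with a square structuring
#' element of half-width \code{dilation_radius}, yielding a uniform
#' stroke thickness of \code{2 * dilation_radius + 1} pixels.
#'
#' A "branch" is the skeleton path from an endpoint (degree-1 pixel) to
#' the nearest junction (degree >= 3); pruning is applied iteratively
#' until stable. Whole components with no junction are kept whatever
#' their length: they are genuine marks, not thinning artifacts.
#'
#' @param glyph [GlyphImage-class] at stage \code{"resized"}.
#' @param prune_len minimum branch length kept, default 35 pixels.
#' @param dilation_radius half-width of the square dilation element,
#'   default 2.
#' @return [GlyphImage-class] at stage \code{"skeleton-standardized"}.
#' @export
skeletonStandardize <- function(glyph, prune_len = 35, dilation_radius = 2L) {
  stopifnot(is(glyph, "GlyphImage"))
  if (glyph@stage != "resized") {
    stop("skeletonStandardize expects a glyph at stage 'resized', got '",
         glyph@stage, "'")
  }
  if (prune_len < 0) stop("prune_len must be >= 0")
  sk <- .thin(glyph@pixels)
  sk <- .pruneBranches(sk, prune_len)
  if (!any(sk)) {
    stop(sprintf(
      "skeletonStandardize: empty skeleton after pruning (script=%s codepoint=%s); the glyph may be smaller than prune_len=%s",
      glyph@script, glyph@codepoint, format(prune_len)
    ))
  }
  out <- .boxDilate(sk, as.integer(dilation_radius))
  GlyphImage(out, stage = "skeleton-standardized", script = glyph@script,
             codepoint = glyph@codepoint)
}

#' Standardize all glyphs of one script
#'
#' Convenience wrapper running trim, the shared per-script resize, and
#' line-thickness homogenization over a script's glyph list.
#'
#' @param glyphs list of [GlyphImage-class] (any raw/trimmed stage).
#' @param prune_len,dilation_radius passed to [skeletonStandardize()].
#' @param skeletonize if \code{FALSE}, stop after resizing (useful for
#'   inputs already drawn at the target stroke thickness).
#' @return list of standardized [GlyphImage-class] objects.
#' @export
standardizeScript <- function(glyphs, prune_len = 35, dilation_radius = 2L,
                              skeletonize = TRUE) {
  trimmed <- lapply(glyphs, trimGlyph)
  ratio <- scriptResizeRatio(trimmed)
  resized <- lapply(trimmed, resizeAndCenter, ratio = ratio)
  if (!skeletonize) {
    return(resized)
  }
  lapply(resized, skeletonStandardize, prune_len = prune_len,
         dilation_radius = dilation_radius)
}

#' Render all glyphs of a script with an adaptive point size
#'
#' Drives an externally supplied rasterizer with the shared-point-size
#' rule: start at \code{point_size} and, whenever any glyph of the script
#' overflows the 500x500 canvas, re-render the whole script 5 points
#' smaller, until everything fits. A rasterizer is a function
#' \code{f(codepoint, point_size)} returning a raw-stage
#' [GlyphImage-class] (500x500), or \code{NULL} when the font lacks the
#' codepoint. Overflow is signalled either by an \code{"overflow"}
#' attribute on the returned glyph or by foreground touching the canvas
#' border.
#'
#' @param rasterizer function(codepoint, point_size) -> GlyphImage or
#'   NULL.
#' @param codepoints character vector of codepoint identifiers.
#' @param point_size starting point size, default 60.
#' @param step decrement on overflow, default 5.
#' @param script optional script tag stamped on the results.
#' @return list with \code{glyphs} (named list, missing codepoints NULL),
#'   \code{point_size} (final shared size), \code{n_missing}.
#' @export
renderScriptGlyphs <- function(rasterizer, codepoints, point_size = 60,
                               step = 5, script = NA_character_) {
  stopifnot(is.function(rasterizer), length(codepoints) >= 1L)
  ps <- point_size
  repeat {
    if (ps <= 0) {
      stop("renderScriptGlyphs: point size reached 0 without fitting the canvas")
    }
    glyphs <- lapply(codepoints, function(cp) rasterizer(cp, ps))
    names(glyphs) <- codepoints
    overflow <- vapply(glyphs, function(g) {
      if (is.null(g)) return(FALSE)
      if (isTRUE(attr(g, "overflow"))) return(TRUE)
      px <- g@pixels
      any(px[1L, ]) || any(px[nrow(px), ]) || any(px[, 1L]) || any(px[, ncol(px)])
    }, logical(1L))
    if (!any(overflow)) break
    ps <- ps - step
  }
  for (cp in codepoints) {
    if (!is.null(glyphs[[cp]])) {
      glyphs[[cp]]@script <- as.character(script)
      glyphs[[cp]]@codepoint <- cp
    }
  }
  list(
    glyphs = glyphs,
    point_size = ps,
    n_missing = sum(vapply(glyphs, is.null, logical(1L)))
  )
}
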
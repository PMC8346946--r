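#' @import methods
NULL

.GLYPH_STAGES <- c("raw", "trimmed", "resized", "skeleton-standardized")
.CANVAS <- 500L
.HALF_WIDTH <- 250L
.PADDED_WIDTH <- 300L
.FIT_BOX <- 490L

#' GlyphImage: a binary raster of one character
#'
#' The central image container of the package. Pixels are stored as a
#' logical matrix with \code{TRUE} marking the character (foreground);
#' rows index x (horizontal position, left to right) and columns index y
#' (vertical position). The \code{stage} slot records where in the
#' standardization pipeline the image sits; at the \code{resized} and
#' \code{skeleton-standardized} stages the canvas is exactly 500 by 500
#' pixels.
#'
#' @slot pixels logical matrix, \code{TRUE} = foreground.
#' @slot stage character, one of \code{"raw"}, \code{"trimmed"},
#'   \code{"resized"}, \code{"skeleton-standardized"}.
#' @slot script character, ISO 15924 script tag (may be \code{NA}).
#' @slot codepoint character, hexadecimal codepoint identifier (may be
#'   \code{NA}).
#'
#' @seealso [GlyphImage()] for the user constructor, [trimGlyph()],
#'   [resizeAndCenter()], [skeletonStandardize()].
#' @export
setClass("GlyphImage",
  representation(
    pixels = "matrix",
    stage = "character",
    script = "character",
    codepoint = "character"
  ),
  prototype(
    pixels = matrix(FALSE, 0, 0),
    stage = "raw",
    script = NA_character_,
    codepoint = NA_character_
  )
)

setValidity("GlyphImage", function(object) {
  msg <- character()
  if (!is.logical(object@pixels)) {
    msg <- c(msg, "pixels must be a logical matrix")
  }
  if (length(object@stage) != 1L || !object@stage %in% .GLYPH_STAGES) {
    msg <- c(msg, sprintf(
      "stage must be one of: %s", paste(.GLYPH_STAGES, collapse = ", ")
    ))
  }
  if (length(object@stage) == 1L &&
      object@stage %in% c("resized", "skeleton-standardized")) {
    d <- dim(object@pixels)
    # full canvas, or a (possibly padded) vertical half of it
    if (d[2L] != .CANVAS ||
        !d[1L] %in% c(.CANVAS, .HALF_WIDTH, .PADDED_WIDTH)) {
      msg <- c(msg, sprintf(
        "stage '%s' requires a %d-px-tall canvas %d, %d or %d px wide, got %d x %d",
        object@stage, .CANVAS, .CANVAS, .HALF_WIDTH, .PADDED_WIDTH,
        d[1L], d[2L]
      ))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GlyphImage
#'
#' @param pixels a logical or 0/1 numeric matrix; \code{TRUE}/1 is
#'   foreground (the character). Rows are x (columns of the picture),
#'   columns are y.
#' @param stage pipeline stage label.
#' @param script optional ISO 15924 tag.
#' @param codepoint optional hexadecimal identifier.
#' @return a [GlyphImage-class] object.
#' @examples
#' g <- GlyphImage(matrix(c(0, 1, 1, 0), 2, 2))
#' foregroundCount(g)
#' @export
GlyphImage <- function(pixels, stage = "raw", script = NA_character_,
                       codepoint = NA_character_) {
  if (is.numeric(pixels)) {
    storage.mode(pixels) <- "logical"
  }
  new("GlyphImage",
    pixels = pixels, stage = stage,
    script = as.character(script), codepoint = as.character(codepoint)
  )
}

setMethod("show", "GlyphImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "GlyphImage %dx%d [%s] script=%s codepoint=%s fg=%d\n",
    d[1L], d[2L], object@stage, object@script, object@codepoint,
    sum(object@pixels)
  ))
})

#' @describeIn GlyphImage-class image dimensions (width, height)
#' @param x a GlyphImage
#' @export
setMethod("dim", "GlyphImage", function(x) dim(x@pixels))

#' ComplexityResult: both complexity measures for one image
#'
#' Perimetric complexity C = P^2 / (4 pi A), where P is the summed
#' sub-pixel length of all boundary contours (component outlines plus hole
#' outlines) and A the foreground area in pixels; a disk minimizes C at 1.
#' Algorithmic complexity AC is the byte count of the losslessly
#' compressed canonical vector outline of the image. Slots not computed
#' are NA.
#'
#' @slot P numeric, total contour length (pixels).
#' @slot A numeric, foreground area (pixels^2).
#' @slot C numeric, perimetric complexity (dimensionless).
#' @slot AC numeric, algorithmic complexity (bytes).
#' @export
setClass("ComplexityResult",
  representation(P = "numeric", A = "numeric", C = "numeric", AC = "numeric"),
  prototype(P = NA_real_, A = NA_real_, C = NA_real_, AC = NA_real_)
)

setValidity("ComplexityResult", function(object) {
  msg <- character()
  for (s in c("P", "A", "C", "AC")) {
    if (length(slot(object, s)) != 1L) {
      msg <- c(msg, sprintf("%s must be a scalar", s))
    }
  }
  if (isTRUE(object@P <= 0)) msg <- c(msg, "P must be positive")
  if (isTRUE(object@A <= 0)) msg <- c(msg, "A must be positive")
  if (length(msg)) msg else TRUE
})

# internal constructor: a slot named C would partially match new()'s
# Class argument, so slots are assigned explicitly
.ComplexityResult <- function(P = NA_real_, A = NA_real_, C = NA_real_,
                              AC = NA_real_) {
  out <- new("ComplexityResult")
  out@P <- as.numeric(P)
  out@A <- as.numeric(A)
  out@C <- as.numeric(C)
  out@AC <- as.numeric(AC)
  validObject(out)
  out
}

setMethod("show", "ComplexityResult", function(object) {
  cat(sprintf(
    "ComplexityResult: C=%.4f (P=%.2f, A=%.0f), AC=%s bytes\n",
    object@C, object@P, object@A,
    if (is.na(object@AC)) "NA" else format(object@AC)
  ))
})

#' HalfPair: the two padded halves of one character
#'
#' A 500x500 standardized character split at column 250 into a left and a
#' right 250x500 half, each padded with 50 background columns on the cut
#' ("inner") side to 300x500. Which half is "first" in reading order is
#' decided by the script's directionality (left for left-to-right scripts,
#' right for right-to-left scripts).
#'
#' @slot left,right [GlyphImage-class] padded halves (300x500).
#' @slot directionality character, \code{"LR"} or \code{"RL"}.
#' @slot script,codepoint provenance labels.
#' @export
setClass("HalfPair",
  representation(
    left = "GlyphImage", right = "GlyphImage",
    directionality = "character",
    script = "character", codepoint = "character"
  )
)

setValidity("HalfPair", function(object) {
  msg <- character()
  for (s in c("left", "right")) {
    d <- dim(slot(object, s)@pixels)
    if (!identical(as.integer(d), c(.PADDED_WIDTH, .CANVAS))) {
      msg <- c(msg, sprintf(
        "%s half must be %d x %d, got %d x %d",
        s, .PADDED_WIDTH, .CANVAS, d[1L], d[2L]
      ))
    }
  }
  if (!object@directionality %in% c("LR", "RL", NA_character_)) {
    msg <- c(msg, "directionality must be 'LR', 'RL' or NA")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HalfPair", function(object) {
  cat(sprintf(
    "HalfPair [%s] script=%s codepoint=%s fg(left)=%d fg(right)=%d\n",
    object@directionality, object@script, object@codepoint,
    sum(object@left@pixels), sum(object@right@pixels)
  ))
})

#' ModelFit: one random-intercept linear mixed model
#'
#' Wraps a REML (or ML) fit with the quantities the analyses report:
#' fixed-effect estimates with 95% confidence intervals and
#' Satterthwaite-approximate degrees of freedom, variance components per
#' grouping level, log-likelihood and AIC.
#'
#' @slot formula the model formula.
#' @slot coefficients data.frame with columns estimate, ci_lower,
#'   ci_upper, df, t, p.
#' @slot varcomp named numeric, variance components (residual included as
#'   \code{"Residual"}).
#' @slot logLik,AIC numeric scalars.
#' @slot method character, \code{"REML"} or \code{"ML"}.
#' @slot singular logical, whether the fit is singular (some variance
#'   component estimated at zero).
#' @slot fit the underlying \code{lmerModLmerTest} object.
#' @export
setClass("ModelFit",
  representation(
    formula = "ANY", coefficients = "data.frame", varcomp = "numeric",
    logLik = "numeric", AIC = "numeric", method = "character",
    singular = "logical", fit = "ANY"
  )
)

setValidity("ModelFit", function(object) {
  msg <- character()
  if (any(object@varcomp < 0)) msg <- c(msg, "variance components must be >= 0")
  if (!is.finite(object@AIC)) msg <- c(msg, "AIC must be finite")
  if (!object@method %in% c("REML", "ML")) {
    msg <- c(msg, "method must be 'REML' or 'ML'")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf(
    "ModelFit (%s%s): %s\n", object@method,
    if (object@singular) ", singular" else "",
    deparse(object@formula)
  ))
  cat(sprintf("  AIC = %.2f, logLik = %.2f\n", object@AIC, object@logLik))
  print(round(object@coefficients, 4))
  cat("  Variance components:\n")
  print(round(object@varcomp, 4))
})

#' BayesTestResult: JZS Bayesian one-sample t-test
#'
#' Bayes factor in favor of the null (mean = 0) against an alternative
#' with a Cauchy prior of scale \code{r} on the standardized effect size.
#'
#' @slot BF_null numeric, Bayes factor for the null (> 1 favors the null).
#' @slot t numeric, the classical one-sample t statistic.
#' @slot n numeric, sample size.
#' @slot prior_scale numeric, Cauchy prior scale.
#' @export
setClass("BayesTestResult",
  representation(
    BF_null = "numeric", t = "numeric", n = "numeric", prior_scale = "numeric"
  )
)

setValidity("BayesTestResult", function(object) {
  if (length(object@BF_null) != 1L || !is.finite(object@BF_null) ||
      object@BF_null <= 0) {
    "BF_null must be a positive finite scalar"
  } else {
    TRUE
  }
})

setMethod("show", "BayesTestResult", function(object) {
  cat(sprintf(
    "JZS one-sample t-test: BF_null = %.3f (t = %.3f, n = %d, r = %.3f)\n",
    object@BF_null, object@t, as.integer(object@n), object@prior_scale
  ))
})
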
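#' Accessors for glyphmetry S4 objects
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("glyphPixels", function(x) standardGeneric("glyphPixels"))

#' @rdname accessors
#' @export
setMethod("glyphPixels", "GlyphImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("glyphStage", function(x) standardGeneric("glyphStage"))

#' @rdname accessors
#' @export
setMethod("glyphStage", "GlyphImage", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("scriptCode", function(x) standardGeneric("scriptCode"))

#' @rdname accessors
#' @export
setMethod("scriptCode", "GlyphImage", function(x) x@script)

#' @rdname accessors
#' @export
setGeneric("codepointId", function(x) standardGeneric("codepointId"))

#' @rdname accessors
#' @export
setMethod("codepointId", "GlyphImage", function(x) x@codepoint)

#' @rdname accessors
#' @export
setGeneric("foregroundCount", function(x) standardGeneric("foregroundCount"))

#' @rdname accessors
#' @export
setMethod("foregroundCount", "GlyphImage", function(x) sum(x@pixels))

#' @rdname accessors
#' @export
setGeneric("leftHalf", function(x) standardGeneric("leftHalf"))

#' @rdname accessors
#' @export
setMethod("leftHalf", "HalfPair", function(x) x@left)

#' @rdname accessors
#' @export
setGeneric("rightHalf", function(x) standardGeneric("rightHalf"))

#' @rdname accessors
#' @export
setMethod("rightHalf", "HalfPair", function(x) x@right)

#' @rdname accessors
#' @export
setGeneric("bayesFactorNull", function(x) standardGeneric("bayesFactorNull"))

#' @rdname accessors
#' @export
setMethod("bayesFactorNull", "BayesTestResult", function(x) x@BF_null)

#' @rdname accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname accessors
#' @export
setMethod("fixedEffects", "ModelFit", function(x) x@coefficients)

#' @rdname accessors
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))

#' @rdname accessors
#' @export
setMethod("varianceComponents", "ModelFit", function(x) x@varcomp)

#' @rdname accessors
#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' @rdname accessors
#' @export
setMethod("modelAIC", "ModelFit", function(x) x@AIC)

#' @rdname accessors
#' @export
setGeneric("isSingular", function(x) standardGeneric("isSingular"))

#' @rdname accessors
#' @export
setMethod("isSingular", "ModelFit", function(x) x@singular)
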
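#' @title Accessor generics
#' @description Accessors for the core classes; user code should use these
#'   rather than reaching into slots.
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("imageDpi", function(x) standardGeneric("imageDpi"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("foreground", function(x) standardGeneric("foreground"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname accessors
#' @export
setGeneric("touchesBorder", function(x) standardGeneric("touchesBorder"))

#' @rdname accessors
#' @export
setGeneric("perImageThresholds",
    function(x) standardGeneric("perImageThresholds"))

#' @rdname accessors
#' @export
setGeneric("batchMean", function(x) standardGeneric("batchMean"))

#' @rdname accessors
#' @export
setMethod("pixels", "RasterImage", function(x) x@pixels)

#' @rdname accessors
#' @export
setMethod("imageDpi", "RasterImage", function(x) x@dpi)

#' @rdname accessors
#' @export
setMethod("imageId", "RasterImage", function(x) x@imageId)

#' @rdname accessors
#' @export
setMethod("imageId", "BinaryMask", function(x) x@imageId)

#' @rdname accessors
#' @export
setMethod("imageId", "ComponentLabeling", function(x) x@imageId)

#' @rdname accessors
#' @export
setMethod("foreground", "BinaryMask", function(x) x@fg)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "ComponentLabeling", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("nComponents", "ComponentLabeling", function(x) x@nComponents)

#' @rdname accessors
#' @export
setMethod("touchesBorder", "ComponentLabeling", function(x) x@touchesBorder)

#' @rdname accessors
#' @export
setMethod("perImageThresholds", "ThresholdSet", function(x) x@perImage)

#' @rdname accessors
#' @export
setMethod("batchMean", "ThresholdSet", function(x) x@batchMean)

#' @describeIn accessors dimensions of the pixel grid.
#' @export
setMethod("dim", "RasterImage", function(x) dim(x@pixels))

#' @describeIn accessors dimensions of the mask.
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@fg))

setMethod("show", "RasterImage", function(object) {
    d <- dim(object@pixels)
    cat(sprintf("RasterImage '%s': %d x %d px, %.0f dpi, range [%d, %d]\n",
        object@imageId, d[1L], d[2L], object@dpi,
        min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryMask", function(object) {
    d <- dim(object@fg)
    cat(sprintf("BinaryMask '%s': %d x %d px, %d foreground px (%.1f%%)\n",
        object@imageId, d[1L], d[2L], sum(object@fg),
        100 * mean(object@fg)))
})

setMethod("show", "ComponentLabeling", function(object) {
    cat(sprintf(
        "ComponentLabeling '%s': %d components, %d touching the border\n",
        object@imageId, object@nComponents, sum(object@touchesBorder)))
})

setMethod("show", "ThresholdSet", function(object) {
    nd <- sum(is.na(object@perImage))
    cat(sprintf(
        "ThresholdSet: %d image(s) (%d undefined), batch mean %.3f\n",
        length(object@perImage), nd, object@batchMean))
})

setMethod("show", "HeritabilityResult", function(object) {
    cat(sprintf("HeritabilityResult for '%s'\n", object@trait))
    cat(sprintf("  MS_M = %.4g (df %g), MS_E = %.4g (df %g), n0 = %.4g\n",
        object@msM, object@dfM, object@msE, object@dfE, object@n0))
    cat(sprintf("  V_A = %.4g, V_E = %.4g (V_E_method=%s), H2 = %.3f\n",
        object@vA, object@vE, object@veMethod, object@h2))
})

setMethod("show", "FieldSpec", function(object) {
    cat(sprintf(
        paste0("FieldSpec: %d x %d px @ %.0f dpi; %d singles, %d pairs, ",
               "%d scratches, %d debris; seed %s\n"),
        object@height, object@width, object@dpi, object@nSingles,
        object@nPairs, object@nScratches, object@nDebris,
        sprintf("%.2f x %.2f mm", object@majorMm, object@minorMm)))
})
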
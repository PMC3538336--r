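#' @import methods
NULL

#' RasterImage: an 8-bit grayscale scanner image with resolution metadata
#'
#' The unit of input for the pipeline: a matrix of integer intensities in
#' \[0, 255\] together with the acquisition resolution in dots per inch and
#' a source identifier. Seeds are assumed dark on a light background.
#'
#' @slot pixels integer matrix of intensities in \[0, 255\]; rows are image
#'   rows (y), columns are image columns (x).
#' @slot dpi positive scalar, dots per inch of the scan.
#' @slot imageId character scalar identifying the source image.
#'
#' @seealso [loadImage()], [binarize()]
#' @export
setClass("RasterImage",
    representation(pixels = "matrix", dpi = "numeric", imageId = "character"))

setValidity("RasterImage", function(object) {
    p <- object@pixels
    if (!is.numeric(p) || length(dim(p)) != 2L)
        return("pixels must be a 2-D numeric matrix")
    if (nrow(p) < 1L || ncol(p) < 1L)
        return("pixels must have at least one row and one column")
    if (anyNA(p) || any(p < 0) || any(p > 255))
        return("all intensities must lie in [0, 255]")
    if (any(p != floor(p)))
        return("intensities must be integral (8-bit)")
    if (length(object@dpi) != 1L || is.na(object@dpi) || object@dpi <= 0)
        return("dpi must be a single positive number")
    if (length(object@imageId) != 1L || is.na(object@imageId))
        return("imageId must be a single string")
    TRUE
})

#' BinaryMask: a foreground/background segmentation of a RasterImage
#'
#' @slot fg logical matrix, TRUE for foreground (seed) pixels; same
#'   dimensions as the source image.
#' @slot imageId character scalar, identifier of the source image.
#'
#' @seealso [binarize()], [labelComponents()]
#' @export
setClass("BinaryMask",
    representation(fg = "matrix", imageId = "character"))

setValidity("BinaryMask", function(object) {
    if (!is.logical(object@fg) || length(dim(object@fg)) != 2L)
        return("fg must be a 2-D logical matrix")
    if (anyNA(object@fg))
        return("fg must not contain NA")
    TRUE
})

#' ComponentLabeling: 8-connected components of a binary mask
#'
#' Each maximal set of 8-connected foreground pixels receives a positive
#' integer label; background pixels are 0. Labels are assigned in row-major
#' order of each component's first pixel. `touchesBorder` records, per
#' component, whether any of its pixels lies on the image boundary, so that
#' seeds truncated by the scan edge can be excluded downstream.
#'
#' @slot labels integer matrix, 0 = background, k = pixels of component k.
#' @slot nComponents integer, number of components.
#' @slot touchesBorder logical vector of length `nComponents`.
#' @slot imageId character scalar.
#'
#' @seealso [labelComponents()], [measureComponents()]
#' @export
setClass("ComponentLabeling",
    representation(labels = "matrix", nComponents = "integer",
                   touchesBorder = "logical", imageId = "character"))

setValidity("ComponentLabeling", function(object) {
    if (!is.integer(object@labels))
        return("labels must be an integer matrix")
    n <- object@nComponents
    if (length(n) != 1L || is.na(n) || n < 0L)
        return("nComponents must be a single nonnegative integer")
    if (length(object@touchesBorder) != n)
        return("touchesBorder must have one entry per component")
    if (n > 0L && max(object@labels) != n)
        return("labels must run 1..nComponents")
    TRUE
})

#' ThresholdSet: per-image Otsu thresholds and their batch mean
#'
#' Scanner batches vary in background level and seed count, so no single
#' per-image threshold is reliable; instead each image's Otsu threshold is
#' computed, undefined results (degenerate histograms) are dropped, and the
#' arithmetic mean of the remainder binarizes every image in the batch.
#'
#' @slot perImage named numeric vector of per-image thresholds in
#'   \[0, 255\]; `NA` marks images whose histogram admitted no split.
#' @slot batchMean numeric scalar, mean of the defined thresholds.
#'
#' @seealso [otsuThreshold()], [batchThreshold()], [writeThresholdSet()]
#' @export
setClass("ThresholdSet",
    representation(perImage = "numeric", batchMean = "numeric"))

setValidity("ThresholdSet", function(object) {
    def <- object@perImage[!is.na(object@perImage)]
    if (length(def) == 0L)
        return("at least one per-image threshold must be defined")
    if (any(def < 0) || any(def > 255))
        return("thresholds must lie in [0, 255]")
    if (abs(object@batchMean - mean(def)) > 1e-9)
        return("batchMean must equal the mean of the defined thresholds")
    TRUE
})

#' HeritabilityResult: one-way ANOVA variance components for one trait
#'
#' Holds the mean squares and degrees of freedom of a one-way (line)
#' ANOVA, the unbalanced-design effective group size n0, the
#' moment-estimated between-line genetic variance V_A, the environmental
#' variance V_E (by the configured estimator), and broad-sense
#' heritability H2 = V_A / (V_A + V_E).
#'
#' @slot trait character, trait name.
#' @slot msM,msE numeric, model (between-line) and error (within-line)
#'   mean squares.
#' @slot dfM,dfE numeric, degrees of freedom (lines - 1; N - lines).
#' @slot n0 numeric, effective per-line group size
#'   (N - sum(n_i^2)/N) / (a - 1).
#' @slot vA numeric, max(0, (msM - msE) / n0).
#' @slot vE numeric, environmental variance per `veMethod`.
#' @slot h2 numeric in \[0, 1\].
#' @slot veMethod character, how vE was obtained (default "MS_E").
#'
#' @seealso [varianceComponents()], [heritability()]
#' @export
setClass("HeritabilityResult",
    representation(trait = "character", msM = "numeric", msE = "numeric",
                   dfM = "numeric", dfE = "numeric", n0 = "numeric",
                   vA = "numeric", vE = "numeric", h2 = "numeric",
                   veMethod = "character"))

setValidity("HeritabilityResult", function(object) {
    if (object@vA < 0) return("vA must be nonnegative (floored at zero)")
    if (!is.na(object@h2) && (object@h2 < 0 || object@h2 > 1))
        return("h2 must lie in [0, 1]")
    TRUE
})

#' FieldSpec: parameters of a synthetic seed-field image
#'
#' Describes a scanner-like field of dark elliptical seeds on a light
#' noisy background: canvas size and resolution, object counts (isolated
#' seeds, touching pairs, scratches, debris), the seed axis-length
#' distributions in millimetres, the intensity model, and the RNG seed
#' that makes rendering deterministic.
#'
#' @slot height,width integer, canvas size in pixels.
#' @slot dpi numeric, simulated scan resolution.
#' @slot nSingles,nPairs,nScratches,nDebris integer object counts.
#' @slot majorMm,minorMm numeric, mean seed major/minor axis in mm.
#' @slot axisCv numeric, coefficient of variation of the axis lengths.
#' @slot fgMean,bgMean numeric, seed and background mean intensities
#'   (seeds dark: fgMean < bgMean).
#' @slot noiseSd numeric, Gaussian intensity noise standard deviation.
#' @slot rngSeed integer.
#'
#' @seealso [fieldSpec()], [renderField()]
#' @export
setClass("FieldSpec",
    representation(height = "integer", width = "integer", dpi = "numeric",
                   nSingles = "integer", nPairs = "integer",
                   nScratches = "integer", nDebris = "integer",
                   majorMm = "numeric", minorMm = "numeric",
                   axisCv = "numeric", fgMean = "numeric",
                   bgMean = "numeric", noiseSd = "numeric",
                   rngSeed = "integer"))

setValidity("FieldSpec", function(object) {
    if (object@height < 1L || object@width < 1L)
        return("canvas must be at least 1x1")
    if (object@dpi <= 0) return("dpi must be positive")
    cnt <- c(object@nSingles, object@nPairs, object@nScratches,
             object@nDebris)
    if (any(cnt < 0L)) return("object counts must be nonnegative")
    ints <- c(object@fgMean, object@bgMean)
    if (any(ints < 0) || any(ints > 255))
        return("intensities must lie in [0, 255]")
    if (object@bgMean <= object@fgMean)
        return("background must be lighter than foreground (dark seeds)")
    if (object@majorMm < object@minorMm)
        return("majorMm must be >= minorMm")
    if (object@noiseSd < 0) return("noiseSd must be nonnegative")
    TRUE
})
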
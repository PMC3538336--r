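#' Otsu threshold of an 8-bit image
#'
#' Picks the integer threshold t in \[0, 255\] maximizing the between-class
#' variance of the 256-bin intensity histogram split into \{intensity < t\}
#' versus \{intensity >= t\} — the convention matching [binarize()], where
#' foreground is strictly below the threshold. If several thresholds attain
#' the maximum, the lowest is returned (deterministic, and conservative in
#' the sense of a smaller foreground). If the histogram occupies a single
#' bin no split exists — an image with very few (or no) seeds can produce
#' this — and `NA` is returned so batch averaging can skip the image.
#'
#' @param image a [RasterImage-class], or an integer matrix/vector of
#'   intensities in \[0, 255\].
#' @return integer threshold in \[1, 255\], or `NA` if undefined.
#' @seealso [batchThreshold()], [binarize()]
#' @export
otsuThreshold <- function(image) {
    v <- if (is(image, "RasterImage")) pixels(image) else image
    h <- tabulate(as.integer(v) + 1L, nbins = 256L)
    n <- sum(h)
    if (sum(h > 0L) < 2L) return(NA_integer_)
    lev <- 0:255
    # for threshold t = 1..255: class0 = {0..t-1}, class1 = {t..255}
    w0 <- cumsum(h)[1:255]
    s0 <- cumsum(h * lev)[1:255]
    w1 <- n - w0
    valid <- w0 > 0 & w1 > 0
    mu0 <- s0 / w0
    mu1 <- (sum(h * lev) - s0) / w1
    bcv <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
    bcv[!valid] <- -Inf
    as.integer(which.max(bcv))   # lowest argmax; thresholds are 1..255
}

#' Pool per-image Otsu thresholds into a batch threshold
#'
#' Averages the defined per-image thresholds into the single batch mean
#' used to binarize every image in the batch; undefined (`NA`) entries are
#' excluded from the mean, with a warning naming them.
#'
#' @param thresholds numeric vector of per-image thresholds, `NA` for
#'   images whose histogram admitted no split; names (if any) are taken as
#'   image ids.
#' @return a [ThresholdSet-class].
#' @export
batchThreshold <- function(thresholds) {
    ids <- names(thresholds)
    thresholds <- as.numeric(thresholds)
    names(thresholds) <- if (is.null(ids))
        sprintf("image%03d", seq_along(thresholds)) else ids
    und <- is.na(thresholds)
    if (all(und))
        stop("no image yielded a defined Otsu threshold; supply a manual ",
             "threshold for this batch")
    if (any(und))
        warning("excluded ", sum(und), " undefined threshold(s) from the ",
                "batch mean: ", paste(names(thresholds)[und],
                collapse = ", "))
    new("ThresholdSet", perImage = thresholds,
        batchMean = mean(thresholds[!und]))
}

#' Binarize an image at a threshold
#'
#' With the default polarity, a pixel is foreground iff its intensity is
#' strictly below the threshold: seeds are dark on the light scanner
#' background, and after binarization they are the black pixels that
#' component labeling operates on. Set `darkForeground = FALSE` for
#' inverted media (light objects on dark background).
#'
#' @param image a [RasterImage-class].
#' @param threshold numeric in \[0, 255\].
#' @param darkForeground logical; default `TRUE`.
#' @return a [BinaryMask-class] with the image's dimensions.
#' @export
binarize <- function(image, threshold, darkForeground = TRUE) {
    stopifnot(is(image, "RasterImage"),
              threshold >= 0, threshold <= 255)
    p <- pixels(image)
    fg <- if (darkForeground) p < threshold else p > threshold
    new("BinaryMask", fg = fg, imageId = imageId(image))
}

#' Label the 8-connected foreground components of a mask
#'
#' Finds all maximal sets of foreground pixels connected under
#' 8-adjacency (diagonal contact joins). Labels are assigned in row-major
#' order of each component's first pixel. Components with a pixel on the
#' image boundary are flagged `touchesBorder`, since a seed truncated by
#' the scan edge yields biased measurements.
#'
#' @param mask a [BinaryMask-class], or a logical matrix.
#' @return a [ComponentLabeling-class]; an empty mask yields zero
#'   components.
#' @seealso [measureComponents()]
#' @export
labelComponents <- function(mask) {
    if (is(mask, "BinaryMask")) {
        fg <- foreground(mask)
        id <- imageId(mask)
    } else {
        stopifnot(is.logical(mask), length(dim(mask)) == 2L)
        fg <- mask
        id <- "mask"
    }
    lab <- .label_cc8(fg)
    n <- max(lab)
    tb <- logical(n)
    if (n > 0L) {
        border <- unique(c(lab[1L, ], lab[nrow(lab), ],
                           lab[, 1L], lab[, ncol(lab)]))
        tb[border[border > 0L]] <- TRUE
    }
    new("ComponentLabeling", labels = lab, nComponents = as.integer(n),
        touchesBorder = tb, imageId = id)
}

#' Pixel coordinates of one labeled component
#'
#' @param labeling a [ComponentLabeling-class].
#' @param label component label (1-based).
#' @return two-column integer matrix of (row, col) positions.
#' @export
componentPixels <- function(labeling, label) {
    stopifnot(is(labeling, "ComponentLabeling"),
              label >= 1L, label <= nComponents(labeling))
    which(labelMatrix(labeling) == label, arr.ind = TRUE)
}

#' Store or reload a batch ThresholdSet as a JSON sidecar
#'
#' A batch threshold is an acquisition-level quantity worth keeping next
#' to the images, so a later run (or a subset rerun) binarizes with the
#' same value.
#'
#' @param x a [ThresholdSet-class].
#' @param path JSON file path.
#' @return `writeThresholdSet`: `path`, invisibly. `readThresholdSet`: the
#'   reloaded [ThresholdSet-class].
#' @export
writeThresholdSet <- function(x, path) {
    stopifnot(is(x, "ThresholdSet"))
    jsonlite::write_json(
        list(per_image = as.list(x@perImage), batch_mean = x@batchMean),
        path, auto_unbox = TRUE, digits = NA, na = "null")
    invisible(path)
}

#' @rdname writeThresholdSet
#' @export
readThresholdSet <- function(path) {
    j <- jsonlite::read_json(path)
    per <- vapply(j$per_image,
                  function(v) if (is.null(v)) NA_real_ else as.numeric(v),
                  numeric(1))
    new("ThresholdSet", perImage = per, batchMean = as.numeric(j$batch_mean))
}
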
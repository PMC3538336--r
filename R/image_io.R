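#' Construct a RasterImage from a pixel matrix
#'
#' @param pixels numeric matrix of intensities in \[0, 255\] (integral
#'   values).
#' @param dpi positive scalar, scan resolution in dots per inch.
#' @param imageId identifier string; defaults to `"image"`.
#' @return a [RasterImage-class] object.
#' @examples
#' img <- RasterImage(matrix(c(0L, 128L, 64L, 255L), 2, 2), dpi = 3200)
#' dim(img)
#' @export
RasterImage <- function(pixels, dpi, imageId = "image") {
    d <- dim(pixels)
    px <- matrix(as.integer(round(pixels)), d[1L], d[2L])
    new("RasterImage", pixels = px, dpi = as.numeric(dpi),
        imageId = as.character(imageId))
}

## BT.601 luma weights, the common grayscale conversion for scanned media
.LUMA <- c(0.299, 0.587, 0.114)

#' Load a scanner image from a PNG or TIFF file
#'
#' Reads an 8-bit grayscale raster; RGB inputs are converted to grayscale
#' by standard luminance weighting (with a warning), and 16-bit inputs are
#' rescaled to 8 bits (with a warning). The resolution is taken from the
#' file's metadata (PNG pHYs chunk, TIFF resolution tags) unless
#' `dpiOverride` is supplied, which always wins; with neither, loading
#' fails, because every downstream physical unit depends on it.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @param dpiOverride optional positive scalar overriding file metadata.
#' @param imageId identifier; defaults to the file name without extension.
#' @return a [RasterImage-class].
#' @seealso [saveImage()], [pxToMm()]
#' @export
loadImage <- function(path, dpiOverride = NULL, imageId = NULL) {
    if (!file.exists(path))
        stop("cannot read image file: ", path)
    ext <- tolower(tools::file_ext(path))
    dpiMeta <- NA_real_
    if (ext == "png") {
        arr <- tryCatch(png::readPNG(path, info = TRUE),
                        error = function(e)
                            stop("corrupt or unreadable PNG: ", path))
        info <- attr(arr, "info")
        if (!is.null(info$dpi)) dpiMeta <- mean(info$dpi)
        if (!is.null(info$bit.depth) && info$bit.depth > 8L)
            warning(sprintf("%d-bit input rescaled to 8-bit: %s",
                            info$bit.depth, path))
    } else if (ext %in% c("tif", "tiff")) {
        arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
                        error = function(e)
                            stop("corrupt or unreadable TIFF: ", path))
        at <- attributes(arr)
        if (!is.null(at$x.resolution)) {
            unit <- if (is.null(at$resolution.unit)) "inch"
                    else at$resolution.unit
            dpiMeta <- switch(unit,
                cm = at$x.resolution * 2.54,
                at$x.resolution)
        }
        if (!is.null(at$bits.per.sample) && at$bits.per.sample > 8L)
            warning(sprintf("%d-bit input rescaled to 8-bit: %s",
                            at$bits.per.sample, path))
    } else {
        stop("unsupported image format '", ext, "': ", path)
    }
    if (length(dim(arr)) == 3L) {
        nch <- dim(arr)[3L]
        if (nch >= 3L) {
            warning("color input converted to grayscale by luminance ",
                    "weighting: ", path)
            arr <- .LUMA[1L] * arr[, , 1L] + .LUMA[2L] * arr[, , 2L] +
                   .LUMA[3L] * arr[, , 3L]
        } else {
            arr <- arr[, , 1L]   # gray + alpha: drop alpha
        }
    }
    dpi <- if (!is.null(dpiOverride)) {
        if (dpiOverride <= 0) stop("dpiOverride must be positive")
        dpiOverride
    } else if (!is.na(dpiMeta) && dpiMeta > 0) {
        # PNG stores pixels-per-metre, so a 3200 dpi scan reads back as
        # 3199.993; snap to the integer dpi the scanner was set to
        if (abs(dpiMeta - round(dpiMeta)) < 0.05)
            dpiMeta <- round(dpiMeta)
        dpiMeta
    } else {
        stop("no resolution metadata in ", path,
             " and no dpiOverride given; the dpi is required to convert ",
             "pixel measurements to millimetres")
    }
    if (is.null(imageId))
        imageId <- tools::file_path_sans_ext(basename(path))
    RasterImage(round(arr * 255), dpi = dpi, imageId = imageId)
}

#' Save a RasterImage to a PNG (with dpi metadata) or TIFF file
#'
#' @param image a [RasterImage-class].
#' @param path output path; format chosen by extension (`.png` carries the
#'   dpi in its pHYs chunk; TIFF output does not embed resolution, so
#'   reloading it needs a `dpiOverride`).
#' @return `path`, invisibly.
#' @export
saveImage <- function(image, path) {
    stopifnot(is(image, "RasterImage"))
    ext <- tolower(tools::file_ext(path))
    m <- pixels(image) / 255
    if (ext == "png") {
        png::writePNG(m, path, dpi = imageDpi(image))
    } else if (ext %in% c("tif", "tiff")) {
        tiff::writeTIFF(m, path, bits.per.sample = 8L)
    } else {
        stop("unsupported output format: ", ext)
    }
    invisible(path)
}

#' Convert a pixel length to millimetres
#'
#' @param lengthPx nonnegative length in pixels.
#' @param dpi positive scan resolution in dots per inch.
#' @return `lengthPx * 25.4 / dpi`, in mm.
#' @examples
#' pxToMm(3200, 3200)   # one inch of pixels = 25.4 mm
#' @export
pxToMm <- function(lengthPx, dpi) {
    if (any(dpi <= 0)) stop("dpi must be positive")
    lengthPx * 25.4 / dpi
}

#' Convert a pixel area to square millimetres
#'
#' @param areaPx nonnegative area in pixels.
#' @inheritParams pxToMm
#' @return `areaPx * (25.4 / dpi)^2`, in mm^2.
#' @examples
#' pxAreaToMm2(3200^2, 3200)   # one square inch = 645.16 mm^2
#' @export
pxAreaToMm2 <- function(areaPx, dpi) {
    if (any(dpi <= 0)) stop("dpi must be positive")
    areaPx * (25.4 / dpi)^2
}
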
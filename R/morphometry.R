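#' Measure area and moment-equivalent ellipse axes of labeled components
#'
#' For each component, the area is its exact pixel count and the major and
#' minor axes are those of the ellipse with the same normalized second
#' central moments as the pixel set: the 2x2 covariance matrix of the
#' pixel-center coordinates (population form, divide by n) with 1/12 added
#' to each diagonal term to account for the unit extent of a pixel; with
#' eigenvalues lambda1 >= lambda2, major = 4*sqrt(lambda1) and
#' minor = 4*sqrt(lambda2). A single pixel therefore measures
#' 4/sqrt(12) ~ 1.155 px on both axes, and a filled disk of radius r
#' measures 2r. Orientation is the angle of the principal eigenvector
#' relative to the row (y) axis pointing down the image, in
#' (-pi/2, pi/2].
#'
#' @param labeling a [ComponentLabeling-class].
#' @return data.frame with one row per component: `label`, `area_px`,
#'   `major_px`, `minor_px`, `centroid_row`, `centroid_col`,
#'   `orientation`, `touches_border`.
#' @seealso [modelArea()], [filterComponents()]
#' @export
measureComponents <- function(labeling) {
    stopifnot(is(labeling, "ComponentLabeling"))
    n <- nComponents(labeling)
    if (n == 0L)
        return(data.frame(label = integer(), area_px = integer(),
                          major_px = numeric(), minor_px = numeric(),
                          centroid_row = numeric(),
                          centroid_col = numeric(),
                          orientation = numeric(),
                          touches_border = logical()))
    lab <- labelMatrix(labeling)
    idx <- which(lab > 0L)
    l <- lab[idx]
    nr <- nrow(lab)
    r <- ((idx - 1L) %% nr) + 1L
    c_ <- ((idx - 1L) %/% nr) + 1L
    area <- tabulate(l, nbins = n)
    sr <- rowsum(as.numeric(r), l)[, 1L]
    sc <- rowsum(as.numeric(c_), l)[, 1L]
    mr <- sr / area
    mc <- sc / area
    # central second moments with the +1/12 pixel-extent correction
    vrr <- rowsum(as.numeric(r)^2, l)[, 1L] / area - mr^2 + 1 / 12
    vcc <- rowsum(as.numeric(c_)^2, l)[, 1L] / area - mc^2 + 1 / 12
    vrc <- rowsum(as.numeric(r) * c_, l)[, 1L] / area - mr * mc
    tr <- vrr + vcc
    disc <- sqrt(pmax(0, (vrr - vcc)^2 + 4 * vrc^2))
    l1 <- (tr + disc) / 2
    l2 <- (tr - disc) / 2
    theta <- atan2(2 * vrc, vrr - vcc) / 2
    data.frame(label = seq_len(n), area_px = area,
               major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(pmax(0, l2)),
               centroid_row = mr, centroid_col = mc,
               orientation = theta,
               touches_border = touchesBorder(labeling))
}

#' Ellipse-model area from the measured axes
#'
#' The area the component would have if it were a filled ellipse with the
#' measured major and minor axes: `pi * major * minor / 4`. For a genuine
#' single seed this agrees closely with the pixel count; for a pair of
#' touching seeds or irregular debris it does not, which is what the
#' first filtering stage exploits.
#'
#' @param majorPx,minorPx positive axis lengths in pixels
#'   (major >= minor).
#' @return modeled area in square pixels.
#' @export
modelArea <- function(majorPx, minorPx) {
    if (any(majorPx <= 0) || any(minorPx <= 0))
        stop("axis lengths must be positive")
    pi * majorPx * minorPx / 4
}

#' Ellipse-consistency filter (stage one)
#'
#' Keeps a component iff its pixel-count area agrees with the area of its
#' moment-equivalent ellipse to within a relative tolerance:
#' `|area_px - modelArea| / modelArea <= tol`. Touching seed pairs and
#' much debris are far from elliptical and fail; a clean single seed at
#' typical scan scales deviates by well under 3%, so the default
#' tolerance of 0.10 leaves a wide margin on both sides.
#'
#' @param areaPx measured pixel count(s).
#' @param majorPx,minorPx measured axis length(s).
#' @param tol positive relative tolerance; default 0.10.
#' @return logical: `TRUE` = pass (keep).
#' @export
ellipseConsistency <- function(areaPx, majorPx, minorPx, tol = 0.10) {
    stopifnot(tol > 0)
    m <- modelArea(majorPx, minorPx)
    abs(areaPx - m) / m <= tol
}

#' Aspect-ratio filter (stage two)
#'
#' Rejects components whose major axis is more than `maxRatio` times the
#' minor axis; the bound is inclusive (a ratio of exactly `maxRatio` is
#' kept). The default 2.5 removes elongated artifacts such as scratches
#' in the Petri plate, which can pass the ellipse test because a thin
#' rectangle is close to its moment-equivalent ellipse in area.
#'
#' @param majorPx,minorPx measured axis length(s).
#' @param maxRatio positive ratio bound; default 2.5.
#' @return logical: `TRUE` = pass (keep).
#' @export
aspectFilter <- function(majorPx, minorPx, maxRatio = 2.5) {
    stopifnot(maxRatio > 0)
    majorPx / minorPx <= maxRatio
}

#' Filter measured components into audited seed records
#'
#' Applies, in order, the optional border exclusion, the
#' ellipse-consistency test, and the aspect-ratio test, and converts
#' pixel measurements to millimetres. Every input component yields an
#' output row — rejected components are kept with `accepted = FALSE` and
#' per-stage flags — so a run is fully auditable.
#'
#' @param measures data.frame from [measureComponents()].
#' @param dpi positive scan resolution.
#' @param imageId source image identifier recorded in each row.
#' @param tol ellipse-consistency relative tolerance; default 0.10.
#' @param maxRatio aspect-ratio bound; default 2.5.
#' @param excludeBorder if `TRUE` (default), components touching the
#'   image border fail `passed_border`.
#' @return data.frame of seed records: `image_id`, `label`,
#'   `centroid_row`, `centroid_col`, `area_px`, `major_px`, `minor_px`,
#'   `area_mm2`, `major_mm`, `minor_mm`, `passed_border`,
#'   `passed_ellipse`, `passed_aspect`, `accepted`.
#' @export
filterComponents <- function(measures, dpi, imageId = "image",
                             tol = 0.10, maxRatio = 2.5,
                             excludeBorder = TRUE) {
    if (nrow(measures) == 0L) {
        out <- data.frame(image_id = character(), label = integer(),
                          centroid_row = numeric(),
                          centroid_col = numeric(),
                          area_px = integer(), major_px = numeric(),
                          minor_px = numeric(), area_mm2 = numeric(),
                          major_mm = numeric(), minor_mm = numeric(),
                          passed_border = logical(),
                          passed_ellipse = logical(),
                          passed_aspect = logical(),
                          accepted = logical())
        return(out)
    }
    pb <- if (excludeBorder) !measures$touches_border
          else rep(TRUE, nrow(measures))
    pe <- ellipseConsistency(measures$area_px, measures$major_px,
                             measures$minor_px, tol = tol)
    pa <- aspectFilter(measures$major_px, measures$minor_px,
                       maxRatio = maxRatio)
    data.frame(image_id = imageId, label = measures$label,
               centroid_row = measures$centroid_row,
               centroid_col = measures$centroid_col,
               area_px = measures$area_px,
               major_px = measures$major_px,
               minor_px = measures$minor_px,
               area_mm2 = pxAreaToMm2(measures$area_px, dpi),
               major_mm = pxToMm(measures$major_px, dpi),
               minor_mm = pxToMm(measures$minor_px, dpi),
               passed_border = pb, passed_ellipse = pe,
               passed_aspect = pa, accepted = pb & pe & pa)
}

#' Measure and filter one image at a given threshold
#'
#' Convenience wrapper running binarize -> label -> measure -> filter for
#' a single image, typically at the batch-mean threshold.
#'
#' @param image a [RasterImage-class].
#' @param threshold binarization threshold in \[0, 255\].
#' @inheritParams filterComponents
#' @param darkForeground passed to [binarize()].
#' @return a seed-record data.frame (see [filterComponents()]).
#' @export
measureImage <- function(image, threshold, tol = 0.10, maxRatio = 2.5,
                         excludeBorder = TRUE, darkForeground = TRUE) {
    labeling <- labelComponents(binarize(image, threshold,
                                         darkForeground = darkForeground))
    filterComponents(measureComponents(labeling), dpi = imageDpi(image),
                     imageId = imageId(image), tol = tol,
                     maxRatio = maxRatio, excludeBorder = excludeBorder)
}

#' Write seed records to a per-image CSV
#'
#' @param records seed-record data.frame from [filterComponents()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSeedRecords <- function(records, path) {
    utils::write.csv(records, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSeedRecords
#' @export
readSeedRecords <- function(path) {
    utils::read.csv(path, stringsAsFactors = FALSE)
}
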
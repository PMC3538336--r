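#' Construct a FieldSpec for the synthetic seed-field generator
#'
#' Defaults emulate a flatbed reflective scan of Arabidopsis-scale seeds:
#' a 3200-dpi field of dark (mean intensity 60) ellipses of about
#' 0.55 x 0.30 mm (5% coefficient of variation on each axis) on a light
#' (mean 220) background with Gaussian noise (sd 8), plus the three
#' artifact classes the filters must reject — touching seed pairs,
#' plate scratches, and small fibrous debris.
#'
#' @param height,width canvas size in pixels.
#' @param dpi simulated scan resolution (dots per inch).
#' @param nSingles,nPairs,nScratches,nDebris object counts.
#' @param majorMm,minorMm mean seed axis lengths in millimetres.
#' @param axisCv coefficient of variation of the sampled axis lengths.
#' @param fgMean,bgMean seed and background mean intensities.
#' @param noiseSd Gaussian intensity noise sd.
#' @param rngSeed integer seed making rendering deterministic.
#' @return a [FieldSpec-class].
#' @seealso [renderField()]
#' @export
fieldSpec <- function(height = 2048L, width = 2048L, dpi = 3200,
                      nSingles = 50L, nPairs = 10L, nScratches = 5L,
                      nDebris = 10L, majorMm = 0.55, minorMm = 0.30,
                      axisCv = 0.05, fgMean = 60, bgMean = 220,
                      noiseSd = 8, rngSeed = 1L) {
    new("FieldSpec", height = as.integer(height), width = as.integer(width),
        dpi = as.numeric(dpi), nSingles = as.integer(nSingles),
        nPairs = as.integer(nPairs), nScratches = as.integer(nScratches),
        nDebris = as.integer(nDebris), majorMm = as.numeric(majorMm),
        minorMm = as.numeric(minorMm), axisCv = as.numeric(axisCv),
        fgMean = as.numeric(fgMean), bgMean = as.numeric(bgMean),
        noiseSd = as.numeric(noiseSd), rngSeed = as.integer(rngSeed))
}

## run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(),
                        inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## subpixel coverage of a primitive over its bounding box, by 4x4
## supersampling; `inside(y, x)` tests point membership (vectorized)
.coverageBox <- function(rows, cols, inside) {
    s <- 4L
    off <- (seq_len(s) - 0.5) / s - 0.5
    cov <- matrix(0, length(rows), length(cols))
    for (oy in off) for (ox in off) {
        y <- matrix(rows + oy, length(rows), length(cols))
        x <- matrix(rep(cols + ox, each = length(rows)),
                    length(rows), length(cols))
        cov <- cov + inside(y, x)
    }
    cov / (s * s)
}

## paint one primitive into the field-wide coverage matrix (max-combine)
.paint <- function(cov, H, W, cy, cx, rad, inside) {
    r0 <- max(1L, floor(cy - rad)); r1 <- min(H, ceiling(cy + rad))
    c0 <- max(1L, floor(cx - rad)); c1 <- min(W, ceiling(cx + rad))
    if (r0 > r1 || c0 > c1) return(cov)
    rows <- r0:r1; cols <- c0:c1
    block <- .coverageBox(rows, cols, inside)
    cov[rows, cols] <- pmax(cov[rows, cols], block)
    cov
}

.insideEllipse <- function(cy, cx, A, B, theta) {
    ct <- cos(theta); st <- sin(theta)
    function(y, x) {
        dy <- y - cy; dx <- x - cx
        u <- dy * ct + dx * st     # along major axis
        v <- -dy * st + dx * ct
        (u / A)^2 + (v / B)^2 <= 1
    }
}

.insideRect <- function(cy, cx, halfLen, halfWid, theta) {
    ct <- cos(theta); st <- sin(theta)
    function(y, x) {
        dy <- y - cy; dx <- x - cx
        u <- dy * ct + dx * st
        v <- -dy * st + dx * ct
        abs(u) <= halfLen & abs(v) <= halfWid
    }
}

#' Render a synthetic seed field with per-object ground truth
#'
#' Draws anti-aliased (coverage-weighted) dark objects on a light noisy
#' background, deterministically for a given `rngSeed`:
#' \describe{
#'   \item{singles}{isolated filled ellipses — the only objects a correct
#'     pipeline accepts; placed so that no two objects approach within a
#'     guard margin and none touches the border.}
#'   \item{touching pairs}{two ellipses joined at an oblique contact
#'     angle (60–90 degrees between major axes), merging into one
#'     8-connected component whose pixel area falls well short of its
#'     moment-ellipse area.}
#'   \item{scratches}{thin rectangles at least 5x longer than wide,
#'     near-elliptical in area but far beyond the 2.5 aspect bound.}
#'   \item{debris}{small crosses of two thin fibres (area under a
#'     quarter of the median seed area), strongly non-elliptical.}
#' }
#' Placement is by rejection sampling on bounding circles; impossible
#' densities raise an error suggesting a larger canvas.
#'
#' @param spec a [FieldSpec-class].
#' @param keepCoverage if `TRUE`, also return the noiseless coverage
#'   matrix (1 = fully inside an object), useful as pixel-level ground
#'   truth.
#' @return list with `image` (a [RasterImage-class]), `truth` (a
#'   data.frame with one row per rendered primitive: `object_id`, `part`,
#'   `kind`, `center_row`, `center_col`, `semi_major_px`,
#'   `semi_minor_px`, `theta`, `expected_accepted`), and optionally
#'   `coverage`.
#' @export
renderField <- function(spec, keepCoverage = FALSE) {
    stopifnot(is(spec, "FieldSpec"))
    .withSeed(spec@rngSeed, {
        H <- spec@height; W <- spec@width
        pxPerMm <- spec@dpi / 25.4
        Amu <- spec@majorMm * pxPerMm / 2   # mean semi-axes in px
        Bmu <- spec@minorMm * pxPerMm / 2
        cov <- matrix(0, H, W)
        placed <- matrix(numeric(0), ncol = 3)   # cy, cx, radius
        margin <- 6
        borderPad <- 4
        place <- function(rad) {
            for (k in 1:500) {
                cy <- runif(1, rad + borderPad, H - rad - borderPad)
                cx <- runif(1, rad + borderPad, W - rad - borderPad)
                if (nrow(placed) == 0L ||
                    all(sqrt((placed[, 1] - cy)^2 +
                             (placed[, 2] - cx)^2) >
                        placed[, 3] + rad + margin)) {
                    placed <<- rbind(placed, c(cy, cx, rad))
                    return(c(cy, cx))
                }
            }
            stop("could not place all objects without overlap; use a ",
                 "larger canvas or fewer objects")
        }
        sampleAxes <- function() {
            A <- stats::rnorm(1, Amu, spec@axisCv * Amu)
            B <- stats::rnorm(1, Bmu, spec@axisCv * Bmu)
            A <- max(A, 3); B <- max(B, 2)
            c(max(A, B), min(A, B))
        }
        truth <- list()
        oid <- 0L
        addTruth <- function(part, kind, cy, cx, A, B, th, acc) {
            truth[[length(truth) + 1L]] <<- data.frame(
                object_id = oid, part = part, kind = kind,
                center_row = cy, center_col = cx, semi_major_px = A,
                semi_minor_px = B, theta = th, expected_accepted = acc)
        }
        for (i in seq_len(spec@nScratches)) {
            len <- runif(1, 1.2, 2.0) * pxPerMm
            wid <- runif(1, 2.5, 4)
            th <- runif(1, 0, pi)
            p <- place(len / 2)
            cov <- .paint(cov, H, W, p[1], p[2], len / 2 + 1,
                          .insideRect(p[1], p[2], len / 2, wid / 2, th))
            oid <- oid + 1L
            addTruth(1L, "scratch", p[1], p[2], len / 2, wid / 2, th,
                     FALSE)
        }
        for (i in seq_len(spec@nPairs)) {
            a1 <- sampleAxes(); a2 <- sampleAxes()
            th1 <- runif(1, 0, pi)
            # oblique contact: second seed's axis 60-90 degrees off the
            # first's, centers pulled together so the outlines merge
            phi <- sample(c(-1, 1), 1) * runif(1, pi / 3, pi / 2)
            th2 <- th1 + phi
            ext2 <- sqrt((a2[1] * cos(phi))^2 + (a2[2] * sin(phi))^2)
            d <- 0.92 * (a1[1] + ext2)
            rad <- d / 2 + max(a1[1], a2[1])
            p <- place(rad)
            c1 <- p - c(cos(th1), sin(th1)) * d / 2
            c2 <- p + c(cos(th1), sin(th1)) * d / 2
            cov <- .paint(cov, H, W, c1[1], c1[2], a1[1] + 1,
                          .insideEllipse(c1[1], c1[2], a1[1], a1[2], th1))
            cov <- .paint(cov, H, W, c2[1], c2[2], a2[1] + 1,
                          .insideEllipse(c2[1], c2[2], a2[1], a2[2], th2))
            oid <- oid + 1L
            addTruth(1L, "touching_pair", c1[1], c1[2], a1[1], a1[2],
                     th1, FALSE)
            addTruth(2L, "touching_pair", c2[1], c2[2], a2[1], a2[2],
                     th2, FALSE)
        }
        for (i in seq_len(spec@nSingles)) {
            ax <- sampleAxes(); A <- ax[1]; B <- ax[2]
            th <- runif(1, 0, pi)
            p <- place(A)
            cov <- .paint(cov, H, W, p[1], p[2], A + 1,
                          .insideEllipse(p[1], p[2], A, B, th))
            oid <- oid + 1L
            addTruth(1L, "single", p[1], p[2], A, B, th, TRUE)
        }
        for (i in seq_len(spec@nDebris)) {
            len <- runif(1, 0.10, 0.16) * pxPerMm
            wid <- runif(1, 2, 3)
            th <- runif(1, 0, pi)
            th2 <- th + pi / 2 + runif(1, -pi / 9, pi / 9)
            p <- place(len / 2 + 2)
            cov <- .paint(cov, H, W, p[1], p[2], len / 2 + 1,
                          .insideRect(p[1], p[2], len / 2, wid / 2, th))
            cov <- .paint(cov, H, W, p[1], p[2], len / 2 + 1,
                          .insideRect(p[1], p[2], len / 2, wid / 2, th2))
            oid <- oid + 1L
            addTruth(1L, "debris", p[1], p[2], len / 2, wid / 2, th,
                     FALSE)
        }
        img <- spec@bgMean + cov * (spec@fgMean - spec@bgMean)
        if (spec@noiseSd > 0)
            img <- img + stats::rnorm(length(img), 0, spec@noiseSd)
        img <- round(pmin(255, pmax(0, img)))
        truth <- if (length(truth)) do.call(rbind, truth) else
            data.frame(object_id = integer(), part = integer(),
                       kind = character(), center_row = numeric(),
                       center_col = numeric(), semi_major_px = numeric(),
                       semi_minor_px = numeric(), theta = numeric(),
                       expected_accepted = logical())
        out <- list(image = RasterImage(matrix(img, H, W), dpi = spec@dpi,
                                        imageId = sprintf("synth-%d",
                                                          spec@rngSeed)),
                    truth = truth)
        if (keepCoverage) out$coverage <- matrix(cov, H, W)
        out
    })
}

#' Write a rendered field to disk (PNG + ground-truth manifest)
#'
#' @param field list from [renderField()].
#' @param dir output directory (created if needed).
#' @param name base file name; defaults to the image id.
#' @return character vector of the two paths written, invisibly.
#' @export
writeField <- function(field, dir, name = NULL) {
    if (is.null(name)) name <- imageId(field$image)
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pngPath <- file.path(dir, paste0(name, ".png"))
    csvPath <- file.path(dir, paste0(name, "_truth.csv"))
    saveImage(field$image, pngPath)
    utils::write.csv(field$truth, csvPath, row.names = FALSE)
    invisible(c(pngPath, csvPath))
}

#' Simulate a per-seed trait population with known variance components
#'
#' Draws y_ij = mu + g_i + e_ij with line effects
#' g_i ~ Normal(0, vATrue) and within-line deviations
#' e_ij ~ Normal(0, vWTrue) — the statistical structure the one-way
#' ANOVA heritability estimator assumes. Deterministic given `rngSeed`.
#'
#' @param aLines number of lines.
#' @param nPerLine seeds per line (scalar or vector of length `aLines`).
#' @param mu trait grand mean.
#' @param vATrue between-line (genetic) variance.
#' @param vWTrue within-line (environmental) variance.
#' @param rngSeed integer seed.
#' @return data.frame with columns `line_id`, `value`.
#' @seealso [varianceComponents()]
#' @export
samplePopulation <- function(aLines, nPerLine, mu, vATrue, vWTrue,
                             rngSeed = 1L) {
    stopifnot(aLines >= 1L, all(nPerLine >= 1L), vATrue >= 0, vWTrue >= 0)
    if (length(nPerLine) == 1L) nPerLine <- rep(nPerLine, aLines)
    stopifnot(length(nPerLine) == aLines)
    .withSeed(rngSeed, {
        g <- stats::rnorm(aLines, 0, sqrt(vATrue))
        line <- rep(seq_len(aLines), nPerLine)
        e <- stats::rnorm(sum(nPerLine), 0, sqrt(vWTrue))
        data.frame(line_id = sprintf("L%03d", line),
                   value = mu + g[line] + e)
    })
}
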
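test_that("a single pixel measures by the pixel-extent correction alone", {
    m <- matrix(FALSE, 3, 3)
    m[2, 2] <- TRUE
    res <- measurePixelSet(m)
    expect_equal(res$area_px, 1L)
    expect_equal(res$major_px, 4 * sqrt(1 / 12), tolerance = 1e-12)
    expect_equal(res$minor_px, res$major_px)
})

test_that("a digital disk measures close to its analytic circle", {
    r <- 20
    res <- measurePixelSet(digitalDisk(r))
    expect_lt(abs(res$area_px - pi * r^2) / (pi * r^2), 0.02)
    expect_lt(abs(res$major_px - 2 * r) / (2 * r), 0.02)
    expect_lt(abs(res$minor_px - 2 * r) / (2 * r), 0.02)
    expect_lt((res$major_px - res$minor_px) / res$major_px, 0.01)
})

test_that("a digital ellipse recovers its analytic axes", {
    res <- measurePixelSet(digitalEllipse(30, 15))
    expect_lt(abs(res$major_px - 60) / 60, 0.03)
    expect_lt(abs(res$minor_px - 30) / 30, 0.03)
    # and its modeled ellipse area agrees with its pixel count
    expect_lt(abs(res$area_px - modelArea(res$major_px, res$minor_px)) /
              modelArea(res$major_px, res$minor_px), 0.03)
})

test_that("model area follows the ellipse formula", {
    expect_equal(modelArea(2, 2), pi)
    expect_equal(modelArea(60, 30), 450 * pi)
    expect_error(modelArea(0, 10), "positive")
    r <- 20
    disk <- measurePixelSet(digitalDisk(r))
    expect_lt(abs(disk$area_px - modelArea(disk$major_px, disk$minor_px)) /
              modelArea(disk$major_px, disk$minor_px), 0.03)
})

test_that("ellipse consistency passes singles and fails touching pairs", {
    single <- measurePixelSet(digitalEllipse(30, 15))
    expect_true(ellipseConsistency(single$area_px, single$major_px,
                                   single$minor_px, tol = 0.10))
    # two ellipses, centers 62 px apart along the shared major axis,
    # measured as one pixel set: a dumbbell whose pixel count falls well
    # below its fitted-ellipse area
    u <- digitalEllipse(30, 15, pad = 40, centerOffset = c(0, -31)) |
         digitalEllipse(30, 15, pad = 40, centerOffset = c(0, 31))
    pair <- measurePixelSet(u)
    expect_false(ellipseConsistency(pair$area_px, pair$major_px,
                                    pair$minor_px, tol = 0.10))
    # vacuous limit: any tolerance large enough passes everything
    expect_true(ellipseConsistency(pair$area_px, pair$major_px,
                                   pair$minor_px, tol = 1e9))
})

test_that("the aspect filter keeps ratio <= 2.5 and rejects beyond it", {
    expect_false(aspectFilter(52, 20))        # ratio 2.6
    expect_true(aspectFilter(30, 30))         # ratio 1
    expect_true(aspectFilter(50, 20))         # exactly 2.5 is kept
    expect_true(aspectFilter(52, 20, maxRatio = 3))
})

test_that("filterComponents audits every component and accepts only seeds", {
    empty <- filterComponents(measureComponents(
        labelComponents(matrix(FALSE, 4, 4))), dpi = 3200)
    expect_equal(nrow(empty), 0L)

    # one perfect ellipse + one touching pair + one 200x3 scratch
    canvas <- matrix(FALSE, 300, 560)
    canvas <- paintEllipse(canvas, 70, 55, 30, 15)
    # touching pair at an oblique contact, merged into one component
    canvas <- paintEllipse(canvas, 220, 120, 30, 15, theta = 0)
    canvas <- paintEllipse(canvas, 220, 162, 30, 15, theta = pi / 2)
    canvas[140:142, 300:499] <- TRUE           # 3 x 200 scratch line
    rec <- filterComponents(measureComponents(labelComponents(canvas)),
                            dpi = 3200)
    expect_equal(nrow(rec), 3L)
    expect_equal(sum(rec$accepted), 1L)
    expect_identical(rec$accepted,
                     rec$passed_border & rec$passed_ellipse &
                     rec$passed_aspect)
    # unit conversions recorded alongside pixel values
    expect_equal(rec$area_mm2, pxAreaToMm2(rec$area_px, 3200))
    expect_equal(rec$major_mm, pxToMm(rec$major_px, 3200))

    # idempotence: re-filtering the same measures yields identical flags
    rec2 <- filterComponents(measureComponents(labelComponents(canvas)),
                             dpi = 3200)
    expect_identical(rec, rec2)
})

test_that("border-touching components are excluded by default, kept on demand", {
    m <- matrix(FALSE, 20, 20)
    m[1:4, 1:4] <- TRUE   # square block on the image corner
    meas <- measureComponents(labelComponents(m))
    withB <- filterComponents(meas, dpi = 3200, excludeBorder = TRUE)
    noB <- filterComponents(meas, dpi = 3200, excludeBorder = FALSE)
    expect_false(any(withB$passed_border))
    expect_true(all(noB$passed_border))
})

test_that("measurement is exactly equivariant under 90-degree rotation", {
    set.seed(3)
    fg <- digitalEllipse(25, 12)
    rot <- t(fg)[ncol(fg):1, , drop = FALSE]
    a <- measurePixelSet(fg)
    b <- measurePixelSet(rot)
    expect_equal(a$area_px, b$area_px)
    expect_equal(a$major_px, b$major_px, tolerance = 1e-9)
    expect_equal(a$minor_px, b$minor_px, tolerance = 1e-9)
})

test_that("loosening tolerances never decreases the accepted count", {
    set.seed(21)
    f <- renderField(smallFieldSpec(rngSeed = 21L))
    meas <- measureComponents(labelComponents(binarize(f$image,
        otsuThreshold(f$image))))
    prev <- -1L
    for (tol in c(0.02, 0.05, 0.10, 0.25, 1)) {
        n <- sum(filterComponents(meas, dpi = 3200, tol = tol)$accepted)
        expect_gte(n, prev)
        prev <- n
    }
    prev <- -1L
    for (mr in c(1.2, 1.8, 2.5, 4, 10)) {
        n <- sum(filterComponents(meas, dpi = 3200,
                                  maxRatio = mr)$accepted)
        expect_gte(n, prev)
        prev <- n
    }
})

test_that("major >= minor holds for every measured component", {
    set.seed(31)
    fg <- matrix(runif(100 * 100) < 0.35, 100, 100)
    meas <- measureComponents(labelComponents(fg))
    expect_true(all(meas$major_px >= meas$minor_px))
    expect_true(all(meas$minor_px > 0))
    expect_equal(meas$area_px, tabulate(labelMatrix(labelComponents(fg)),
                                        nrow(meas)))
})
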
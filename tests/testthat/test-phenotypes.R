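mkRecords <- function(line, area, rep = NA) {
    data.frame(line_id = line, replicate_id = rep, accepted = TRUE,
               area_mm2 = area, major_mm = 2 * sqrt(area),
               minor_mm = sqrt(area))
}

test_that("line means are plain arithmetic over accepted seeds", {
    lm <- lineMeans(mkRecords("L1", c(0.10, 0.12, 0.14)))
    expect_equal(lm$mean_area_mm2, 0.12)
    expect_equal(lm$n_seeds, 3L)
    one <- lineMeans(mkRecords("L1", 0.2))
    expect_equal(one$mean_area_mm2, 0.2)
    expect_equal(one$sd_area_mm2, 0)
    # rejected records never contribute
    rec <- mkRecords(c("L1", "L1"), c(0.1, 9))
    rec$accepted[2] <- FALSE
    expect_equal(lineMeans(rec)$mean_area_mm2, 0.1)
})

test_that("line mean of a large sample recovers the simulated center", {
    set.seed(17)
    n <- 1000
    rec <- mkRecords("L1", rnorm(n, 0.12, 0.01))
    lm <- lineMeans(rec)
    se <- 0.01 / sqrt(n)
    expect_lt(abs(lm$mean_area_mm2 - 0.12), 3 * se)
    expect_equal(lm$n_seeds, n)
})

test_that("replicate averaging is unweighted at the replicate level", {
    ph <- data.frame(line_id = "L1", replicate_id = c("r1", "r2"),
                     n_seeds = c(10L, 1000L),
                     mean_area_mm2 = c(0.10, 0.14),
                     mean_major_mm = c(0.5, 0.7),
                     mean_minor_mm = c(0.3, 0.4))
    fin <- replicateAverage(ph)
    expect_equal(fin$area, 0.12)            # not the pooled mean
    expect_equal(fin$n_replicates, 2L)
    pooled <- replicateAverage(ph, mode = "pooled")
    expect_equal(pooled$area,
                 (10 * 0.10 + 1000 * 0.14) / 1010)
    # single replicate and k identical replicates are identities
    expect_equal(replicateAverage(ph[1, ])$area, 0.10)
    same <- ph; same$mean_area_mm2 <- 0.11
    expect_equal(replicateAverage(same)$area, 0.11)
})

test_that("variance components match a hand-worked ANOVA", {
    vals <- c(1, 2, 3, 4, 5, 6)
    line <- rep(c("A", "B"), each = 3)
    r <- varianceComponents(vals, line)
    o <- oracleAnova(vals, line)
    expect_equal(r@msM, o$msM)
    expect_equal(r@msE, o$msE)
    expect_equal(r@dfM, o$dfM)
    expect_equal(r@dfE, o$dfE)
    expect_equal(r@n0, 3)                        # balanced design
    expect_equal(r@vA, max(0, (o$msM - o$msE) / 3))
})

test_that("ANOVA identity and unbalanced n0 hold on random designs", {
    set.seed(23)
    for (k in 1:5) {
        a <- sample(3:12, 1)
        ni <- sample(2:15, a, replace = TRUE)
        line <- rep(sprintf("L%02d", seq_len(a)), ni)
        vals <- rnorm(sum(ni), 10, 2)
        r <- varianceComponents(vals, line)
        o <- oracleAnova(vals, line)
        # total SS decomposes exactly
        sst <- sum((vals - mean(vals))^2)
        expect_equal(o$sst, sst, tolerance = 1e-10)
        expect_equal(r@msM, o$msM)
        expect_equal(r@msE, o$msE)
        N <- sum(ni)
        expect_equal(r@n0, (N - sum(ni^2) / N) / (a - 1))
    }
    # balanced: n0 equals the common group size exactly
    line <- rep(letters[1:8], each = 7)
    r <- varianceComponents(rnorm(56), line)
    expect_equal(r@n0, 7)
})

test_that("161 lines give model df 160, and degenerate inputs error", {
    set.seed(2)
    line <- rep(sprintf("RIL%03d", 1:161), each = 2)
    r <- varianceComponents(rnorm(322), line)
    expect_equal(r@dfM, 160)
    expect_equal(r@dfE, 322 - 161)
    expect_error(varianceComponents(1:5, rep("A", 5)), "two lines")
    z <- suppressWarnings(   # constant data: the F-test itself degenerates
        varianceComponents(rep(1, 20), rep(letters[1:4], each = 5)))
    expect_equal(z@msM, 0)
    expect_equal(z@vA, 0)
})

test_that("vA is floored at zero when MS_M < MS_E", {
    # within-line spread huge, line effects nil: moment estimate can go
    # negative and must be clipped
    set.seed(4)
    vals <- rnorm(40, 0, 5)
    vals[1:20] <- vals[1:20] - mean(vals[1:20])
    vals[21:40] <- vals[21:40] - mean(vals[21:40])   # force MS_M ~ 0
    r <- varianceComponents(vals, rep(c("A", "B"), each = 20))
    expect_gte(r@vA, 0)
})

test_that("heritability is the variance-component ratio with guards", {
    expect_equal(round(heritability(2.60e-4, 9.78e-5), 3), 0.727)
    expect_equal(round(heritability(5.10e-5, 1.98e-4), 3), 0.205)
    expect_equal(heritability(0.3, 0), 1)
    expect_error(heritability(0, 0), "undefined")
    expect_error(heritability(-1, 1), "nonnegative")
})

test_that("heritability is invariant to rescaling the trait", {
    set.seed(9)
    vals <- rnorm(120, 5, 1) + rep(rnorm(12, 0, 1), each = 10)
    line <- rep(sprintf("L%02d", 1:12), each = 10)
    h1 <- varianceComponents(vals, line)@h2
    h2 <- varianceComponents(vals * 37.5, line)@h2
    expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("the heritability report covers the three traits with labels", {
    set.seed(12)
    n <- 30
    seeds <- data.frame(line_id = rep(c("A", "B", "C"), each = n),
                        area_mm2 = rnorm(3 * n, 0.12, 0.01),
                        major_mm = rnorm(3 * n, 0.55, 0.03),
                        minor_mm = rnorm(3 * n, 0.30, 0.02))
    rep <- heritabilityReport(seeds)
    expect_equal(rep$trait, c("area", "major_axis", "minor_axis"))
    expect_true(all(rep$V_E_method == "MS_E"))
    expect_true(all(rep$H2 >= 0 & rep$H2 <= 1))
    # supplied V_E overrides the MS_E estimator
    rep2 <- heritabilityReport(seeds, vE = list(area = 1e-4))
    expect_equal(rep2$V_E_method[1], "supplied")
    expect_equal(rep2$V_E[1], 1e-4)
})

test_that("phenotype export is sorted, typed, and round-trips", {
    fin <- data.frame(line_id = c("L2", "L1", "L3"),
                      area = c(0.12, 0.11, 0.13),
                      major_axis = c(0.55, 0.54, 0.56),
                      minor_axis = c(0.30, 0.29, 0.31),
                      n_seeds = c(100L, 200L, 300L),
                      n_replicates = c(2L, 2L, 1L))
    path <- withr::local_tempfile(fileext = ".csv")
    exportPhenotypes(fin, path)
    back <- read.csv(path)
    expect_equal(back$line_id, c("L1", "L2", "L3"))
    expect_equal(back$area, c(0.11, 0.12, 0.13), tolerance = 1e-6)
    expect_equal(nrow(back), 3L)
    expect_error(exportPhenotypes(fin, "/no/such/dir/x.csv"), "write")
})
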
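# Independent reference implementations and fixture builders used to
# cross-check the package. These deliberately share no code with the
# package internals.

# exhaustive Otsu: loop over all 256 candidate thresholds, computing the
# between-class variance of {intensity < t} vs {intensity >= t} directly
oracleOtsu <- function(v) {
    h <- tabulate(as.integer(v) + 1L, nbins = 256L)
    n <- sum(h)
    best <- NA_integer_
    bestVar <- -Inf
    for (t in 1:255) {
        w0 <- sum(h[1:t])
        w1 <- n - w0
        if (w0 == 0L || w1 == 0L) next
        mu0 <- sum((0:(t - 1)) * h[1:t]) / w0
        mu1 <- sum((t:255) * h[(t + 1):256]) / w1
        bc <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
        if (bc > bestVar) {   # strict: keeps the lowest argmax
            bestVar <- bc
            best <- t
        }
    }
    best
}

# reference 8-connected labeling by iterative minimum-label propagation:
# give every foreground pixel a unique label, then repeatedly replace each
# label by the minimum over its 8-neighborhood until a fixed point
oracleLabel <- function(fg) {
    nr <- nrow(fg)
    nc <- ncol(fg)
    lab <- matrix(Inf, nr + 2L, nc + 2L)
    core <- matrix(Inf, nr, nc)
    core[fg] <- seq_len(sum(fg))
    lab[2:(nr + 1L), 2:(nc + 1L)] <- core
    repeat {
        m <- lab[2:(nr + 1L), 2:(nc + 1L)]
        for (dy in -1:1) for (dx in -1:1) {
            m <- pmin(m, lab[(2 + dy):(nr + 1L + dy),
                             (2 + dx):(nc + 1L + dx)])
        }
        m[!fg] <- Inf
        if (identical(m, lab[2:(nr + 1L), 2:(nc + 1L)])) break
        lab[2:(nr + 1L), 2:(nc + 1L)] <- m
    }
    out <- matrix(0L, nr, nc)
    fin <- lab[2:(nr + 1L), 2:(nc + 1L)]
    out[fg] <- as.integer(fin[fg])
    out
}

# relabel a label matrix by first occurrence in a fixed (column-major)
# scan so two labelings can be compared up to renaming
canonLabels <- function(lab) {
    idx <- which(lab > 0L)
    out <- matrix(0L, nrow(lab), ncol(lab))
    out[idx] <- match(lab[idx], unique(lab[idx]))
    out
}

# hand-worked one-way ANOVA sums of squares
oracleAnova <- function(values, line) {
    line <- as.character(line)
    gm <- mean(values)
    grp <- split(values, line)
    ssb <- sum(vapply(grp, function(x) length(x) * (mean(x) - gm)^2,
                      numeric(1)))
    ssw <- sum(vapply(grp, function(x) sum((x - mean(x))^2), numeric(1)))
    a <- length(grp)
    N <- length(values)
    list(msM = ssb / (a - 1), msE = ssw / (N - a),
         dfM = a - 1, dfE = N - a, sst = ssb + ssw)
}

# pixel-set fixtures: logical masks of digital shapes on a padded canvas
digitalDisk <- function(r, pad = 3L) {
    n <- 2L * (ceiling(r) + pad) + 1L
    c0 <- ceiling(r) + pad + 1L
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    (rows - c0)^2 + (cols - c0)^2 <= r^2
}

digitalEllipse <- function(a, b, pad = 3L, centerOffset = c(0, 0)) {
    # axis-aligned: semi-major a along columns, semi-minor b along rows
    n <- 2L * (ceiling(a) + pad) + 1L
    cy <- ceiling(a) + pad + 1L + centerOffset[1]
    cx <- ceiling(a) + pad + 1L + centerOffset[2]
    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    ((cols - cx) / a)^2 + ((rows - cy) / b)^2 <= 1
}

# draw a rotated ellipse onto an existing logical canvas
paintEllipse <- function(canvas, cy, cx, a, b, theta = 0) {
    rows <- matrix(seq_len(nrow(canvas)), nrow(canvas), ncol(canvas))
    cols <- matrix(seq_len(ncol(canvas)), nrow(canvas), ncol(canvas),
                   byrow = TRUE)
    u <- (cols - cx) * cos(theta) + (rows - cy) * sin(theta)
    v <- -(cols - cx) * sin(theta) + (rows - cy) * cos(theta)
    canvas | ((u / a)^2 + (v / b)^2 <= 1)
}

# measure an arbitrary pixel set as a single component
measurePixelSet <- function(fg) {
    lab <- matrix(0L, nrow(fg), ncol(fg))
    lab[fg] <- 1L
    labeling <- new("ComponentLabeling", labels = lab, nComponents = 1L,
                    touchesBorder = FALSE, imageId = "fixture")
    measureComponents(labeling)
}

# small synthetic field used by fast pipeline tests
smallFieldSpec <- function(rngSeed = 1L, ...) {
    fieldSpec(height = 640L, width = 640L, nSingles = 6L, nPairs = 2L,
              nScratches = 1L, nDebris = 2L, rngSeed = rngSeed, ...)
}
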
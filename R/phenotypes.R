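#' Per-line (and per-replicate) trait means from accepted seed records
#'
#' Groups accepted seed records by line (and replicate, when present) and
#' computes the arithmetic mean and standard deviation of the three
#' traits, with the seed count. Groups that end up empty after the
#' accepted-filter are skipped with a warning.
#'
#' @param records seed-record data.frame (see [filterComponents()]) with
#'   additional columns `line_id` and optionally `replicate_id`; only
#'   rows with `accepted == TRUE` contribute.
#' @return data.frame with one row per line (x replicate): `line_id`,
#'   `replicate_id` (`NA` when absent), `n_seeds`, `mean_area_mm2`,
#'   `mean_major_mm`, `mean_minor_mm`, `sd_area_mm2`, `sd_major_mm`,
#'   `sd_minor_mm`.
#' @seealso [replicateAverage()]
#' @export
lineMeans <- function(records) {
    stopifnot("line_id" %in% names(records))
    if (!"replicate_id" %in% names(records))
        records$replicate_id <- NA
    if ("accepted" %in% names(records)) {
        allKeys <- unique(records[c("line_id", "replicate_id")])
        records <- records[records$accepted, , drop = FALSE]
        kept <- unique(records[c("line_id", "replicate_id")])
        nDropped <- nrow(allKeys) - nrow(kept)
        if (nDropped > 0L)
            warning(nDropped, " line/replicate group(s) had no accepted ",
                    "records and were skipped")
    }
    if (nrow(records) == 0L) {
        warning("no accepted records; returning empty table")
        return(data.frame(line_id = character(),
                          replicate_id = character(),
                          n_seeds = integer(), mean_area_mm2 = numeric(),
                          mean_major_mm = numeric(),
                          mean_minor_mm = numeric(),
                          sd_area_mm2 = numeric(), sd_major_mm = numeric(),
                          sd_minor_mm = numeric()))
    }
    repKey <- ifelse(is.na(records$replicate_id), "",
                     as.character(records$replicate_id))
    key <- paste(records$line_id, repKey, sep = "\r")
    grp <- split(records, key)
    res <- do.call(rbind, lapply(grp, function(g) {
        sdz <- function(x) if (length(x) > 1L) stats::sd(x) else 0
        data.frame(line_id = g$line_id[1L],
                   replicate_id = g$replicate_id[1L],
                   n_seeds = nrow(g),
                   mean_area_mm2 = mean(g$area_mm2),
                   mean_major_mm = mean(g$major_mm),
                   mean_minor_mm = mean(g$minor_mm),
                   sd_area_mm2 = sdz(g$area_mm2),
                   sd_major_mm = sdz(g$major_mm),
                   sd_minor_mm = sdz(g$minor_mm))
    }))
    rownames(res) <- NULL
    res
}

#' Final per-line phenotype values by replicate averaging
#'
#' The final value for a line is the unweighted mean of its replicate
#' means — each replicate (one mother plant's scan) counts equally, no
#' matter how many seeds it contributed. Set `mode = "pooled"` to instead
#' pool all accepted seeds of a line and take one grand mean (weighting
#' replicates by seed count).
#'
#' @param phenos data.frame from [lineMeans()].
#' @param mode `"replicate-mean"` (default) or `"pooled"`.
#' @return data.frame with one row per line: `line_id`, `area`,
#'   `major_axis`, `minor_axis` (mm-scale trait values), `n_seeds`
#'   (total), `n_replicates`.
#' @export
replicateAverage <- function(phenos, mode = c("replicate-mean", "pooled")) {
    mode <- match.arg(mode)
    stopifnot(nrow(phenos) >= 1L)
    grp <- split(phenos, phenos$line_id)
    res <- do.call(rbind, lapply(grp, function(g) {
        if (mode == "replicate-mean") {
            data.frame(line_id = g$line_id[1L],
                       area = mean(g$mean_area_mm2),
                       major_axis = mean(g$mean_major_mm),
                       minor_axis = mean(g$mean_minor_mm),
                       n_seeds = sum(g$n_seeds),
                       n_replicates = nrow(g))
        } else {
            w <- g$n_seeds / sum(g$n_seeds)
            data.frame(line_id = g$line_id[1L],
                       area = sum(w * g$mean_area_mm2),
                       major_axis = sum(w * g$mean_major_mm),
                       minor_axis = sum(w * g$mean_minor_mm),
                       n_seeds = sum(g$n_seeds),
                       n_replicates = nrow(g))
        }
    }))
    res <- res[order(res$line_id), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' One-way ANOVA variance components for a per-seed trait
#'
#' Fits the one-way random-effects model y_ij = mu + g_i + e_ij with
#' lines as the grouping factor, by the standard ANOVA identities:
#' MS_M is the between-line mean square, MS_E the within-line mean
#' square, and the between-line (genetic) variance component is
#' estimated by the method of moments as
#' `V_A = max(0, (MS_M - MS_E) / n0)`, where
#' `n0 = (N - sum(n_i^2)/N) / (a - 1)` is the effective per-line group
#' size of an unbalanced design (for a balanced design n0 equals the
#' common group size). Negative moment estimates are floored at zero.
#' The environmental variance defaults to the within-line mean square
#' (`veMethod = "MS_E"`); a known V_E can be supplied instead via `vE`,
#' in which case `veMethod` is reported as `"supplied"`.
#'
#' @param values numeric vector of per-seed trait values.
#' @param line factor (or coercible) of line identifiers, same length.
#' @param trait trait name recorded in the result.
#' @param vE optional known environmental variance overriding the MS_E
#'   estimator.
#' @return a [HeritabilityResult-class].
#' @seealso [heritability()]
#' @export
varianceComponents <- function(values, line, trait = "trait", vE = NULL) {
    line <- factor(line)
    if (nlevels(line) < 2L)
        stop("at least two lines are required")
    if (anyNA(values)) stop("values must not contain NA")
    ni <- table(line)
    if (any(ni == 0L)) stop("every line must have at least one value")
    N <- length(values)
    a <- nlevels(line)
    if (N - a < 1L)
        stop("need more observations than lines to estimate MS_E")
    av <- stats::anova(stats::aov(values ~ line))
    msM <- av[["Mean Sq"]][1L]
    msE <- av[["Mean Sq"]][2L]
    dfM <- av[["Df"]][1L]
    dfE <- av[["Df"]][2L]
    n0 <- (N - sum(ni^2) / N) / (a - 1)
    vA <- max(0, (msM - msE) / n0)
    veMethod <- if (is.null(vE)) "MS_E" else "supplied"
    if (is.null(vE)) vE <- msE
    h2 <- if (vA + vE > 0) vA / (vA + vE) else NA_real_
    new("HeritabilityResult", trait = trait, msM = msM, msE = msE,
        dfM = as.numeric(dfM), dfE = as.numeric(dfE), n0 = n0,
        vA = vA, vE = vE, h2 = h2, veMethod = veMethod)
}

#' Broad-sense heritability from variance components
#'
#' `H2 = V_A / (V_A + V_E)`: the fraction of phenotypic variance
#' attributable to genetic differences among lines.
#'
#' @param vA nonnegative genetic variance.
#' @param vE nonnegative environmental variance.
#' @return H2 in \[0, 1\].
#' @examples
#' heritability(2.60e-4, 9.78e-5)   # ~0.727
#' @export
heritability <- function(vA, vE) {
    if (any(vA < 0) || any(vE < 0))
        stop("variance components must be nonnegative")
    if (any(vA + vE == 0))
        stop("H2 is undefined when both components are zero")
    vA / (vA + vE)
}

#' Heritability report table for the three seed traits
#'
#' Runs [varianceComponents()] on each trait of a per-seed table and
#' formats the results as one row per trait, H2 rounded to three
#' decimals.
#'
#' @param seeds data.frame with columns `line_id`, `area_mm2`,
#'   `major_mm`, `minor_mm` (one row per seed).
#' @param vE optional named list/vector of known environmental variances
#'   per trait.
#' @return data.frame with columns `trait`, `MS_M`, `MS_E`, `df_M`,
#'   `df_E`, `n0`, `V_A`, `V_E`, `V_E_method`, `H2`.
#' @export
heritabilityReport <- function(seeds, vE = NULL) {
    traits <- c(area = "area_mm2", major_axis = "major_mm",
                minor_axis = "minor_mm")
    rows <- lapply(names(traits), function(tr) {
        col <- traits[[tr]]
        veTr <- if (!is.null(vE) && !is.null(vE[[tr]])) vE[[tr]] else NULL
        r <- varianceComponents(seeds[[col]], seeds$line_id, trait = tr,
                                vE = veTr)
        data.frame(trait = r@trait, MS_M = r@msM, MS_E = r@msE,
                   df_M = r@dfM, df_E = r@dfE, n0 = r@n0, V_A = r@vA,
                   V_E = r@vE, V_E_method = r@veMethod,
                   H2 = round(r@h2, 3))
    })
    do.call(rbind, rows)
}

#' Export final line phenotypes as a CSV for QTL mapping
#'
#' One row per line, sorted by `line_id`, with the trait columns named
#' so the block can be pasted into a standard QTL cross file.
#'
#' @param finalValues data.frame from [replicateAverage()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
exportPhenotypes <- function(finalValues, path) {
    stopifnot(nrow(finalValues) >= 1L)
    out <- finalValues[order(finalValues$line_id),
                       c("line_id", "area", "major_axis", "minor_axis",
                         "n_seeds", "n_replicates")]
    ok <- tryCatch({
        utils::write.csv(out, path, row.names = FALSE)
        TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("cannot write phenotype table to ", path)
    invisible(path)
}
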
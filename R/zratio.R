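#' @include AllGenerics.R
NULL

.asIntensityMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, 1L) else as.matrix(x)
}

.asZMatrix <- function(x) {
    if (is(x, "ZScoreExperiment")) zValues(x)
    else if (is(x, "SummarizedExperiment")) assay(x, 1L)
    else as.matrix(x)
}

#' Global normalization of array intensities
#'
#' Rescales every sample (column) so that its total intensity equals the mean
#' of all sample totals. Within-sample structure is preserved exactly; only a
#' per-column scale factor \eqn{\bar S / S_j} is applied, where \eqn{S_j} is
#' the column total.
#'
#' @param x an \linkS4class{IntensityExperiment} or a numeric gene x sample
#'   matrix with nonnegative entries.
#' @return an object of the same type with equalized column totals.
#' @examples
#' m <- matrix(c(4, 6, 10, 20), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' colSums(globalNormalize(m))
#' @export
globalNormalize <- function(x) {
    v <- .asIntensityMatrix(x)
    totals <- colSums(v)
    if (any(totals <= 0)) {
        bad <- colnames(v)[totals <= 0]
        stop("sample(s) with non-positive total intensity: ",
             paste(bad, collapse = ", "))
    }
    factor <- mean(totals) / totals
    out <- sweep(v, 2, factor, `*`)
    if (is(x, "IntensityExperiment")) {
        assay(x, "intensity") <- out
        x
    } else out
}

#' Per-array log10 Z-scoring
#'
#' Intensities are floored at \code{floor}, transformed to log10 and
#' standardized within each array (column): \eqn{z = (\log_{10} x - \mu_j) /
#' \sigma_j} with the population standard deviation (divide by \eqn{n}).
#'
#' @param x an \linkS4class{IntensityExperiment} or intensity matrix.
#' @param floor intensities below this value are clipped to it before the log
#'   (default 1), so zeros never reach the transform.
#' @return a \linkS4class{ZScoreExperiment} (or plain matrix for matrix
#'   input); provenance (log base, sd convention, floor) is in
#'   \code{metadata()}.
#' @examples
#' m <- matrix(c(10, 100, 1000), ncol = 1,
#'             dimnames = list(paste0("g", 1:3), "s1"))
#' # logZscore needs >= 2 distinct values; z of {1,2,3} is {-1,0,1}
#' zValues(logZscore(IntensityExperiment(cbind(m, m * 2),
#'                   genotype = c("control", "case"))))
#' @export
logZscore <- function(x, floor = 1) {
    v <- .asIntensityMatrix(x)
    v[v < floor] <- floor
    lg <- log10(v)
    mu <- colMeans(lg)
    sdp <- sqrt(colMeans(sweep(lg, 2, mu)^2))
    if (any(sdp == 0)) {
        bad <- colnames(lg)[sdp == 0]
        stop("constant column(s) after log transform: ",
             paste(bad, collapse = ", "))
    }
    z <- sweep(sweep(lg, 2, mu), 2, sdp, `/`)
    if (is(x, "SummarizedExperiment")) {
        se <- SummarizedExperiment(assays = list(z = z), colData = colData(x))
        out <- new("ZScoreExperiment", se)
        metadata(out)$provenance <- list(log = "log10",
                                         sd = "population",
                                         floor = floor)
        out
    } else z
}

.resolveGroups <- function(z, groupA, groupB) {
    cols <- colnames(z)
    idx <- function(g) {
        if (is.character(g)) {
            if (!all(g %in% cols)) stop("unknown sample(s): ",
                                        paste(setdiff(g, cols), collapse = ", "))
            match(g, cols)
        } else as.integer(g)
    }
    a <- idx(groupA); b <- idx(groupB)
    if (!length(a) || !length(b)) stop("groups must be non-empty")
    if (length(intersect(a, b))) stop("groups must be disjoint")
    list(a = a, b = b)
}

#' Z-ratio between two sample groups
#'
#' For each gene, the difference of group-mean Z-scores \eqn{d_g = \bar
#' z_A(g) - \bar z_B(g)} is divided by the standard deviation (sample
#' convention, \eqn{n-1}) of the \eqn{d} vector across all genes, yielding a
#' standardized fold-change surrogate: the change of a gene in units of
#' standard deviation of the average change of all genes. The returned vector
#' therefore has (sample) standard deviation 1; a degenerate all-constant
#' \eqn{d} returns zeros rather than dividing by zero.
#'
#' @param z a \linkS4class{ZScoreExperiment} or Z-score matrix.
#' @param groupA,groupB disjoint character or integer column selections
#'   (condition A minus condition B).
#' @return named numeric vector of per-gene Z-ratios.
#' @examples
#' zm <- matrix(c(1, 0, -1, 0, 0, 0), ncol = 2,
#'              dimnames = list(paste0("g", 1:3), c("a", "b")))
#' zRatio(zm, "a", "b")
#' @export
zRatio <- function(z, groupA, groupB) {
    zm <- .asZMatrix(z)
    g <- .resolveGroups(zm, groupA, groupB)
    d <- rowMeans(zm[, g$a, drop = FALSE]) - rowMeans(zm[, g$b, drop = FALSE])
    s <- stats::sd(d)
    if (is.na(s) || s == 0) {
        d[] <- 0
        return(d)
    }
    d / s
}

#' Two-group Z-test on replicate Z-scores
#'
#' Per gene, tests reproducibility of the difference between the two groups
#' of replicate arrays: \eqn{T = (\bar z_A - \bar z_B) / \sqrt{s_A^2/n_A +
#' s_B^2/n_B}} (sample variances), referred two-sided to a reference
#' distribution. The classical Z-test (\code{ref = "normal"}, the default)
#' refers \eqn{T} to the standard normal; with the handful of replicates
#' typical of these designs that reference is anti-conservative, and
#' \code{ref = "t"} refers \eqn{T} to Student's t with \eqn{n_A + n_B - 2}
#' degrees of freedom instead (exact for equal-variance groups).
#'
#' @inheritParams zRatio
#' @param ref \code{"normal"} (classical Z-test) or \code{"t"} (small-sample
#'   reference).
#' @return named numeric vector of two-sided p-values.
#' @examples
#' zm <- cbind(a1 = c(1, 0), a2 = c(1.2, 0.1),
#'             b1 = c(-1, 0), b2 = c(-0.8, -0.1))
#' zTest(zm, c("a1", "a2"), c("b1", "b2"))
#' @export
zTest <- function(z, groupA, groupB, ref = c("normal", "t")) {
    ref <- match.arg(ref)
    zm <- .asZMatrix(z)
    g <- .resolveGroups(zm, groupA, groupB)
    if (length(g$a) < 2L || length(g$b) < 2L)
        stop("each group needs >= 2 samples to estimate a variance")
    za <- zm[, g$a, drop = FALSE]; zb <- zm[, g$b, drop = FALSE]
    na <- ncol(za); nb <- ncol(zb)
    ma <- rowMeans(za); mb <- rowMeans(zb)
    va <- rowSums((za - ma)^2) / (na - 1)
    vb <- rowSums((zb - mb)^2) / (nb - 1)
    se <- sqrt(va / na + vb / nb)
    stat <- (ma - mb) / se
    stat[se == 0 & (ma - mb) == 0] <- 0   # identical constant groups
    p <- if (ref == "normal") 2 * stats::pnorm(-abs(stat))
         else 2 * stats::pt(-abs(stat), df = na + nb - 2)
    p[se == 0 & abs(ma - mb) > 0] <- 0
    p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, mapped back to input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as input.
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhFdr <- function(p) {
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1] and be non-missing")
    stats::p.adjust(p, method = "BH")
}

#' Significance calls from Z-ratio, Z-test and FDR gates
#'
#' Default rule: a gene is significant when (|Z-ratio| >= \code{zrThreshold}
#' OR p < \code{pThreshold}) AND q < \code{fdrThreshold}; the call is
#' \code{"up"} or \code{"down"} by the Z-ratio sign, \code{"ns"} otherwise.
#' Each gate can be disabled; disabling both the Z-ratio and p gates leaves
#' only the FDR gate.
#'
#' @param records data.frame with columns \code{z_ratio}, \code{p_value},
#'   \code{q_value}.
#' @param zrThreshold absolute Z-ratio threshold (default 1.5).
#' @param pThreshold Z-test p threshold (default 0.05).
#' @param fdrThreshold FDR threshold (default 0.05).
#' @param useZRatio,useP,useFdr logical gate switches.
#' @return \code{records} with a \code{call} factor column
#'   (\code{up}/\code{down}/\code{ns}).
#' @examples
#' callSignificance(data.frame(gene_id = "g1", z_ratio = 2,
#'                             p_value = 0.001, q_value = 0.01))
#' @export
callSignificance <- function(records, zrThreshold = 1.5, pThreshold = 0.05,
                             fdrThreshold = 0.05, useZRatio = TRUE,
                             useP = TRUE, useFdr = TRUE) {
    stopifnot(all(c("z_ratio", "p_value", "q_value") %in% colnames(records)))
    zr <- records$z_ratio; p <- records$p_value; q <- records$q_value
    gates <- list()
    if (useZRatio) gates$zr <- abs(zr) >= zrThreshold
    if (useP) gates$p <- p < pThreshold
    primary <- if (length(gates)) Reduce(`|`, gates) else rep(TRUE, length(zr))
    pass <- primary & (!useFdr | q < fdrThreshold)
    call <- ifelse(pass & zr > 0, "up", ifelse(pass & zr < 0, "down", "ns"))
    records$call <- factor(call, levels = c("up", "down", "ns"))
    records
}

#' Full Z-ratio differential-expression analysis
#'
#' Runs global normalization, per-array log10 Z-scoring, the Z-ratio and
#' Z-test statistics for case versus control, Benjamini-Hochberg adjustment
#' and the threshold-based significance call.
#'
#' @param x an \linkS4class{IntensityExperiment} whose \code{colData$genotype}
#'   distinguishes the groups.
#' @param caseLevel,controlLevel genotype labels of condition A and B.
#' @param floor intensity floor before the log transform.
#' @param ref reference distribution for \code{\link{zTest}}.
#' @param ... thresholds and gate switches passed to
#'   \code{\link{callSignificance}}.
#' @return data.frame with columns \code{gene_id}, \code{z_ratio},
#'   \code{p_value}, \code{q_value}, \code{call}.
#' @examples
#' sim <- simulateExpressionStudy(200, deFraction = 0.05, effect = 3, seed = 1)
#' head(runDifferentialExpression(sim$experiment))
#' @export
runDifferentialExpression <- function(x, caseLevel = "case",
                                      controlLevel = "control",
                                      floor = 1, ref = "normal", ...) {
    stopifnot(is(x, "IntensityExperiment"))
    geno <- colData(x)$genotype
    a <- colnames(x)[geno == caseLevel]
    b <- colnames(x)[geno == controlLevel]
    if (!length(a) || !length(b))
        stop("genotype levels '", caseLevel, "'/'", controlLevel,
             "' not both present")
    zs <- logZscore(globalNormalize(x), floor = floor)
    tab <- data.frame(gene_id = rownames(x),
                      z_ratio = zRatio(zs, a, b),
                      p_value = zTest(zs, a, b, ref = ref),
                      row.names = NULL)
    tab$q_value <- bhFdr(tab$p_value)
    callSignificance(tab, ...)
}
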
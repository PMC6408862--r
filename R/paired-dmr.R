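## Per-CpG paired t statistics on smoothed levels, p/q conversion, and
## candidate DMR detection.

#' Per-CpG paired t statistics
#'
#' For each CpG computes the per-mother difference of smoothed levels
#' d_k = CR_k - NF_k, the mean difference, and a t statistic whose
#' denominator uses a floored standard deviation: per-site sds are floored
#' at the genome-wide \code{floorQuantile} quantile of all per-site sds,
#' the same variance-stabilisation device ("local correction") the
#' BSmooth t-statistic uses. Two-tailed p-values come from the t
#' distribution with (pairs - 1) degrees of freedom (5 for a six-pair
#' design); q-values by Benjamini-Hochberg.
#'
#' If the genome-wide floor itself is 0 (all differences identical), sites
#' with sd 0 get t = 0.
#'
#' @param me MethylExperiment with a "smooth" assay.
#' @param floorQuantile quantile of per-site sds used as the floor
#'   (default 0.75).
#' @return data.frame: scaffold, position, meanDiff, sd (floored), t, df,
#'   p, q.
#' @export
pairedTStats <- function(me, floorQuantile = 0.75) {
    pid <- pairIndex(me)
    n <- length(pid$mothers)
    if (n < 2L) stop("need at least 2 pairs")
    s <- smoothedLevels(me)
    d <- s[, pid$cr, drop = FALSE] - s[, pid$nf, drop = FALSE]
    mbar <- rowMeans(d)
    sdRaw <- sqrt(rowSums((d - mbar)^2) / (n - 1L))
    floor <- stats::quantile(sdRaw, floorQuantile, na.rm = TRUE,
                             names = FALSE)
    sdF <- pmax(sdRaw, floor)
    tv <- ifelse(sdF == 0, 0, mbar / (sdF / sqrt(n)))
    p <- 2 * stats::pt(-abs(tv), df = n - 1L)
    gr <- SummarizedExperiment::rowRanges(me)
    data.frame(scaffold = as.character(GenomicRanges::seqnames(gr)),
               position = GenomicRanges::start(gr),
               meanDiff = mbar, sd = sdF, t = tv, df = n - 1L,
               p = p, q = pToQ(p), row.names = NULL)
}

#' Convert p-values to q-values
#'
#' \code{method = "BH"} is the Benjamini-Hochberg step-up; \code{"storey"}
#' scales BH by an estimate of the null proportion pi0 obtained with the
#' smoother method (natural cubic spline of pi0(lambda) over a lambda
#' grid, evaluated at the largest lambda), or by a user-supplied
#' \code{pi0}.
#'
#' @param p p-values in [0,1]; NA is an error.
#' @param method "BH" or "storey".
#' @param pi0 optional null-proportion override for "storey".
#' @return q-values, same length and order as \code{p}.
#' @export
pToQ <- function(p, method = c("BH", "storey"), pi0 = NULL) {
    method <- match.arg(method)
    if (anyNA(p)) stop("NA p-values")
    stopifnot(all(p >= 0 & p <= 1))
    q <- stats::p.adjust(p, method = "BH")
    if (method == "storey") {
        if (is.null(pi0)) pi0 <- estimatePi0(p)
        q <- pmin(q * pi0, 1)
    }
    q
}

# pi0 by the smoother method: pi0(lambda) = #{p > lambda} / (m (1-lambda)),
# spline-smoothed, taken at the largest lambda, clamped to (0, 1]
estimatePi0 <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
    m <- length(p)
    pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                   numeric(1))
    if (length(unique(pi0l)) < 4L) return(min(1, max(pi0l[1L], 1e-8)))
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
    min(max(pi0, 1e-8), 1)
}

#' Find candidate DMRs
#'
#' Maximal runs of consecutive CpGs whose t statistics all exceed the
#' symmetric cutoff with a common sign (t > tCut hyper, t < -tCut hypo).
#' A run is broken by a sub-threshold site, a sign change, a scaffold
#' change, or a gap larger than \code{maxGapBp} between consecutive member
#' CpGs. Region coordinates are 1-based inclusive, first to last member
#' CpG; the region mean difference is the mean of member per-CpG mean
#' differences.
#'
#' @param stats data.frame from \code{\link{pairedTStats}} (sites sorted).
#' @param tCut symmetric t cutoff (default 4.6).
#' @param maxGapBp maximum within-region gap (default 300).
#' @param siteFdr per-CpG q-value threshold used only to annotate each
#'   region with its count of FDR-significant member CpGs (default 0.05).
#' @return GRanges with mcols direction, nCpG, meanDiff, tMean, nSigCpG,
#'   members (IntegerList of row indices into \code{stats}).
#' @export
findCandidateRegions <- function(stats, tCut = 4.6, maxGapBp = 300,
                                 siteFdr = 0.05) {
    stopifnot(tCut > 0)
    sgn <- ifelse(stats$t > tCut, 1L, ifelse(stats$t < -tCut, -1L, 0L))
    keep <- sgn != 0L
    if (!any(keep)) return(emptyRegions())
    idx <- which(keep)
    newRun <- c(TRUE,
        sgn[idx[-1L]] != sgn[idx[-length(idx)]] |
        stats$scaffold[idx[-1L]] != stats$scaffold[idx[-length(idx)]] |
        diff(idx) != 1L |
        diff(stats$position[idx]) > maxGapBp)
    runId <- cumsum(newRun)
    members <- unname(split(idx, runId))
    first <- vapply(members, `[`, integer(1), 1L)
    last <- vapply(members, function(i) i[length(i)], integer(1))
    gr <- GenomicRanges::GRanges(stats$scaffold[first],
        IRanges::IRanges(stats$position[first], stats$position[last]))
    gr$direction <- ifelse(sgn[first] > 0L, "hyper", "hypo")
    gr$nCpG <- lengths(members)
    gr$meanDiff <- vapply(members, function(i) mean(stats$meanDiff[i]),
                          numeric(1))
    gr$tMean <- vapply(members, function(i) mean(stats$t[i]), numeric(1))
    gr$nSigCpG <- vapply(members, function(i)
        sum(stats$q[i] < siteFdr), integer(1))
    gr$members <- IRanges::IntegerList(members)
    gr
}

emptyRegions <- function() {
    gr <- GenomicRanges::GRanges()
    gr$direction <- character(0)
    gr$nCpG <- integer(0)
    gr$meanDiff <- numeric(0)
    gr$tMean <- numeric(0)
    gr$nSigCpG <- integer(0)
    gr$members <- IRanges::IntegerList()
    gr
}

#' Filter candidate DMRs
#'
#' Keeps regions with at least \code{minCpgs} member CpGs and an absolute
#' region mean difference strictly greater than \code{minAbsMeanDiff}.
#' Optionally (off by default, matching the narrative selection by
#' t-cutoffs) additionally requires at least \code{minSigCpgs} member
#' CpGs with q below the per-site FDR threshold.
#'
#' @param regions GRanges from \code{\link{findCandidateRegions}}.
#' @param minCpgs minimum member CpGs (default 3).
#' @param minAbsMeanDiff strict lower bound on |region mean difference|
#'   (default 0.1).
#' @param minSigCpgs if > 0, require this many FDR-significant member
#'   CpGs (default 0, i.e. off).
#' @return the filtered GRanges.
#' @export
filterCandidates <- function(regions, minCpgs = 3L, minAbsMeanDiff = 0.1,
                             minSigCpgs = 0L) {
    keep <- regions$nCpG >= minCpgs &
        abs(regions$meanDiff) > minAbsMeanDiff
    if (minSigCpgs > 0L) keep <- keep & regions$nSigCpG >= minSigCpgs
    regions[keep]
}
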
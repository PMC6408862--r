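#' Smoother configuration
#'
#' Parameters of the BSmooth-style local-likelihood smoother. The
#' published defaults of the cited approach are adopted: windows of at
#' least 70 CpGs and at least 1000 bp, tricube kernel, local polynomial of
#' degree 2. Test fixtures and desk-scale synthetic runs use smaller
#' windows (e.g. 5 CpGs / 100 bp) scaled to the simulated CpG spacing.
#'
#' @param minCpgs minimum CpGs per window (default 70).
#' @param minWindowBp minimum window span in bp (default 1000).
#' @param degree local polynomial degree, 0 or 2 (default 2).
#' @param maxGapBp split scaffolds into independent smoothing clusters at
#'   gaps larger than this (default 1e8, i.e. one cluster per scaffold).
#' @return a classed list of smoother settings.
#' @export
smootherConfig <- function(minCpgs = 70L, minWindowBp = 1000,
                           degree = 2L, maxGapBp = 1e8) {
    stopifnot(minCpgs >= 1L, minWindowBp > 0, degree %in% c(0L, 2L))
    structure(list(minCpgs = as.integer(minCpgs),
                   minWindowBp = as.numeric(minWindowBp),
                   degree = as.integer(degree),
                   maxGapBp = as.numeric(maxGapBp)),
              class = "smootherConfig")
}

#' Smooth one replicate on one scaffold
#'
#' Weighted local polynomial fit of the raw methylation proportions: for
#' each CpG the window is the smallest symmetric neighbourhood holding at
#' least \code{minCpgs} CpGs and spanning at least \code{minWindowBp} bp;
#' weights are tricube(distance/halfwidth) x coverage; the fitted value at
#' the centre is clipped to [0,1]. Zero-coverage sites contribute no
#' weight but still receive a fitted value. If the scaffold holds fewer
#' CpGs than \code{minCpgs}, the window is the whole scaffold (with a
#' warning).
#'
#' @param pos sorted 1-based positions.
#' @param meth,cov methylated counts and total coverage per site.
#' @param config a \code{\link{smootherConfig}}.
#' @return numeric vector of smoothed levels (NA only where the whole
#'   window has zero coverage).
#' @export
smoothReplicate <- function(pos, meth, cov, config = smootherConfig()) {
    stopifnot(length(pos) == length(meth), length(pos) == length(cov),
              !is.unsorted(pos))
    if (length(pos) == 0L) return(numeric(0))
    if (length(pos) < config$minCpgs)
        warning("scaffold has fewer CpGs (", length(pos),
                ") than the window minimum (", config$minCpgs,
                "); using the whole scaffold")
    smooth_scaffold_cpp(as.numeric(pos), as.numeric(meth), as.numeric(cov),
                        config$minCpgs, config$minWindowBp, config$degree)
}

#' Smooth all replicates of a MethylExperiment
#'
#' Applies \code{\link{smoothReplicate}} per replicate per scaffold (and
#' per smoothing cluster when \code{maxGapBp} splits a scaffold) and
#' stores the result as the "smooth" assay. Deterministic.
#'
#' @param me MethylExperiment.
#' @param config a \code{\link{smootherConfig}}.
#' @return \code{me} with a "smooth" assay added.
#' @export
smoothMatrix <- function(me, config = smootherConfig()) {
    gr <- SummarizedExperiment::rowRanges(me)
    sc <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    m <- methCounts(me); cov <- methCoverage(me)
    out <- matrix(NA_real_, nrow(me), ncol(me),
                  dimnames = dimnames(m))
    for (s in unique(sc)) {
        i <- which(sc == s)
        p <- pos[i]
        brk <- cumsum(c(1L, as.integer(diff(p) > config$maxGapBp)))
        for (cl in split(i, brk)) {
            if (length(cl) < config$minCpgs)
                warning("smoothing cluster on ", s, " has fewer CpGs (",
                        length(cl), ") than the window minimum (",
                        config$minCpgs, "); using the whole cluster")
            for (j in seq_len(ncol(me)))
                out[cl, j] <- suppressWarnings(
                    smoothReplicate(pos[cl], m[cl, j], cov[cl, j], config))
        }
    }
    SummarizedExperiment::assay(me, "smooth", withDimnames = FALSE) <- out
    me
}
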
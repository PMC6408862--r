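## Region p-value validation: autocorrelation of per-CpG p-values,
## Stouffer-Liptak-Kechris combination, BH across regions, and the final
## intersection with the filtered candidates.

#' Estimate the autocorrelation of per-CpG p-values
#'
#' Transforms p to z = qnorm(1 - p) and, for each distance bin, computes
#' the Pearson correlation over all same-scaffold site pairs whose
#' separation falls in the bin. Bins with fewer than \code{minPairs}
#' pairs, or with a constant z series, get rho = 0 (reported in the
#' table).
#'
#' @param stats data.frame with scaffold, position, p (sites sorted).
#' @param binWidth bp per lag bin (default 50).
#' @param maxLag largest lag considered (default 500).
#' @param minPairs minimum pairs per bin (default 10).
#' @return data.frame: lagLo, lagHi (1-based inclusive bp bounds), rho,
#'   nPairs.
#' @export
estimateAcf <- function(stats, binWidth = 50, maxLag = 500,
                        minPairs = 10L) {
    stopifnot(nrow(stats) >= 2L)
    z <- zFromP(stats$p)
    nb <- ceiling(maxLag / binWidth)
    sx <- vector("list", nb); sy <- vector("list", nb)
    scafs <- split(seq_len(nrow(stats)), stats$scaffold)
    for (i in scafs) {
        pos <- stats$position[i]
        n <- length(i)
        for (k in seq_len(n - 1L)) {
            d <- pos[-seq_len(k)] - pos[seq_len(n - k)]
            inRange <- d <= maxLag
            if (!any(inRange)) break
            b <- pmin(ceiling(d[inRange] / binWidth), nb)
            b[b < 1L] <- 1L
            ii <- which(inRange)
            for (bb in unique(b)) {
                sel <- ii[b == bb]
                sx[[bb]] <- c(sx[[bb]], z[i][sel])
                sy[[bb]] <- c(sy[[bb]], z[i][sel + k])
            }
        }
    }
    rho <- numeric(nb); np <- integer(nb)
    for (bb in seq_len(nb)) {
        np[bb] <- length(sx[[bb]])
        if (np[bb] < minPairs ||
            stats::sd(sx[[bb]]) == 0 || stats::sd(sy[[bb]]) == 0) {
            rho[bb] <- 0
        } else {
            rho[bb] <- stats::cor(sx[[bb]], sy[[bb]])
        }
    }
    data.frame(lagLo = (seq_len(nb) - 1L) * binWidth + 1L,
               lagHi = seq_len(nb) * binWidth,
               rho = rho, nPairs = np)
}

# upper-tail z transform (small p -> large z) with machine-safe clamping
# of p in {0, 1}; qnorm's upper-tail form keeps precision for tiny p
zFromP <- function(p) {
    nClamp <- sum(p <= 0 | p >= 1)
    if (nClamp)
        message(nClamp, " p-value(s) clamped away from {0,1}")
    stats::qnorm(pmin(pmax(p, 1e-300), 1 - 1e-16), lower.tail = FALSE)
}

# rho for a site-pair distance from the ACF table: the bin containing the
# distance; beyond the last bin 0; negative estimates clipped to 0 so the
# combination stays conservative
rhoLookup <- function(d, acf) {
    ## bins are (lagLo - 1, lagHi], matching the estimator's ceiling rule
    b <- findInterval(d, c(acf$lagLo[1L] - 1L, acf$lagHi),
                      left.open = TRUE)
    r <- ifelse(b >= 1L & b <= nrow(acf),
                acf$rho[pmin(pmax(b, 1L), nrow(acf))], 0)
    pmax(r, 0)
}

#' Stouffer-Liptak(-Kechris) combination of correlated p-values
#'
#' z_i = qnorm(1 - p_i); combined z = sum(z) / sqrt(n + 2 * sum_{i<j}
#' rho_ij); combined p = 1 - pnorm(z). With all rho = 0 this is the
#' classic Stouffer combination. p-values of exactly 0 or 1 are clamped to
#' machine-safe values (with a message).
#'
#' @param p member p-values.
#' @param rho either a symmetric correlation matrix (diagonal ignored) or
#'   a single number recycled to every pair; entries are clipped to >= 0.
#' @return the combined p-value.
#' @export
stoufferLiptak <- function(p, rho = 0) {
    n <- length(p)
    stopifnot(n >= 1L)
    z <- zFromP(p)
    if (is.matrix(rho)) {
        stopifnot(nrow(rho) == n, ncol(rho) == n)
        sumRho <- sum(pmax(rho[upper.tri(rho)], 0))
    } else {
        sumRho <- max(rho, 0) * n * (n - 1) / 2
    }
    zc <- sum(z) / sqrt(n + 2 * sumRho)
    stats::pnorm(zc, lower.tail = FALSE)
}

#' Combine per-CpG p-values over candidate regions
#'
#' Assigns every (unfiltered) candidate region a Stouffer-Liptak combined
#' p-value using pairwise correlations looked up from the ACF model by
#' member-pair distance, then applies Benjamini-Hochberg across all
#' combined p-values.
#'
#' @param regions candidate GRanges (the unfiltered set) with a
#'   \code{members} mcol indexing into \code{stats}.
#' @param stats per-CpG data.frame with position and p.
#' @param acf ACF table from \code{\link{estimateAcf}}.
#' @return \code{regions} with mcols \code{combinedP} and
#'   \code{correctedP} added.
#' @export
combineRegions <- function(regions, stats, acf) {
    cp <- rep(NA_real_, length(regions))
    for (r in seq_along(regions)) {
        i <- regions$members[[r]]
        if (length(i) == 0L) {
            warning("region ", r, " has no member p-values; skipped")
            next
        }
        pos <- stats$position[i]
        if (length(i) == 1L) {
            cp[r] <- stoufferLiptak(stats$p[i], 0)
        } else {
            dmat <- abs(outer(pos, pos, "-"))
            rmat <- matrix(rhoLookup(dmat, acf), length(i))
            cp[r] <- stoufferLiptak(stats$p[i], rmat)
        }
    }
    regions$combinedP <- cp
    regions$correctedP <- NA_real_
    ok <- !is.na(cp)
    regions$correctedP[ok] <- stats::p.adjust(cp[ok], method = "BH")
    regions
}

#' Finalize the DMR set
#'
#' The final DMRs are the filtered candidates whose interval matches a
#' combined region with corrected (BH) p-value below \code{alpha}.
#'
#' @param combined GRanges from \code{\link{combineRegions}} (all
#'   candidates).
#' @param filtered GRanges from \code{\link{filterCandidates}}.
#' @param alpha FDR threshold (default 0.05).
#' @return GRanges of final DMRs carrying direction, nCpG, meanDiff,
#'   combinedP, correctedP.
#' @export
finalizeDmrs <- function(combined, filtered, alpha = 0.05) {
    if (length(filtered) == 0L) {
        out <- combined[0L]
        return(out)
    }
    keyC <- paste(as.character(GenomicRanges::seqnames(combined)),
                  GenomicRanges::start(combined),
                  GenomicRanges::end(combined))
    keyF <- paste(as.character(GenomicRanges::seqnames(filtered)),
                  GenomicRanges::start(filtered),
                  GenomicRanges::end(filtered))
    i <- match(keyF, keyC)
    if (anyNA(i))
        stop("filtered candidate absent from the combined set")
    out <- combined[i]
    out[!is.na(out$correctedP) & out$correctedP < alpha]
}

#' Standalone peak finder over per-CpG p-values
#'
#' Off the main path (the pipeline defines regions by the t-statistic
#' candidates): identifies runs of low p-values by seeding at
#' p < \code{seedP} and extending to neighbouring CpGs with
#' p < \code{extendP} within \code{maxGapBp}.
#'
#' @param stats per-CpG data.frame with scaffold, position, p.
#' @param seedP seed threshold (default 0.01).
#' @param extendP extension threshold (default 0.05).
#' @param maxGapBp maximum gap between members (default 300).
#' @return GRanges with nCpG and members.
#' @export
findPeakRegions <- function(stats, seedP = 0.01, extendP = 0.05,
                            maxGapBp = 300) {
    ext <- stats$p < extendP
    if (!any(ext)) return(emptyRegions()[, c("nCpG", "members")])
    idx <- which(ext)
    newRun <- c(TRUE,
        stats$scaffold[idx[-1L]] != stats$scaffold[idx[-length(idx)]] |
        diff(stats$position[idx]) > maxGapBp)
    members <- unname(split(idx, cumsum(newRun)))
    hasSeed <- vapply(members, function(i) any(stats$p[i] < seedP),
                      logical(1))
    members <- members[hasSeed]
    if (!length(members)) return(emptyRegions()[, c("nCpG", "members")])
    first <- vapply(members, `[`, integer(1), 1L)
    last <- vapply(members, function(i) i[length(i)], integer(1))
    gr <- GenomicRanges::GRanges(stats$scaffold[first],
        IRanges::IRanges(stats$position[first], stats$position[last]))
    gr$nCpG <- lengths(members)
    gr$members <- IRanges::IntegerList(members)
    gr
}
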
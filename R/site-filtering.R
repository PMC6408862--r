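## Pre-statistics filters: non-conversion read filtering, GATK-style
## variant hard filtering, polymorphic-CpG masking, the coverage rule, and
## the global-methylation summary with its paired t-test.

#' Remove bisulphite-unconverted reads
#'
#' A read whose call string contains any methylated non-CpG call ('X' CHG
#' or 'H' CHH) is discarded entirely: CHH/CHG methylation is negligible in
#' the organisms this pipeline targets, so such calls mark a read that
#' escaped bisulphite conversion. The per-replicate report gives the
#' fraction of reads removed and the non-CpG percent methylated before
#' filtering; 100 minus that figure is the bisulphite conversion
#' efficiency.
#'
#' @param reads data.table with columns read_id, replicate, scaffold, pos,
#'   call (Bismark extractor alphabet z/Z, x/X, h/H).
#' @return list with \code{reads} (retained rows) and \code{report}
#'   (per-replicate: nReads, nRemoved, pctRemoved, nonCpgPctMeth,
#'   conversionEfficiency).
#' @export
filterNonconvertedReads <- function(reads) {
    reads <- data.table::as.data.table(reads)
    bad <- grepl("[^zZxXhH]", reads$call)
    if (any(bad))
        stop("unknown call symbol in read ",
             reads$read_id[which(bad)[1L]])
    nH <- nchar(gsub("[^HX]", "", reads$call))
    nh <- nchar(gsub("[^hx]", "", reads$call))
    drop <- nH > 0L
    rep_ <- reads$replicate
    agg <- function(x) tapply(x, rep_, sum)
    nReads <- as.vector(table(rep_))
    repNames <- names(table(rep_))
    nRemoved <- as.vector(tapply(drop, rep_, sum))
    totH <- as.vector(agg(nH)); totAll <- as.vector(agg(nH + nh))
    nonCpg <- 100 * totH / pmax(totAll, 1L)
    report <- data.frame(replicate = repNames, nReads = nReads,
        nRemoved = nRemoved, pctRemoved = 100 * nRemoved / nReads,
        nonCpgPctMeth = nonCpg, conversionEfficiency = 100 - nonCpg,
        stringsAsFactors = FALSE)
    list(reads = reads[!drop], report = report)
}

#' Rebuild the call matrix from a read-level table
#'
#' Counts the CpG call (exactly one z/Z per read) per site and replicate.
#' Typically applied to the output of
#' \code{\link{filterNonconvertedReads}} to obtain post-filter counts.
#'
#' @param reads read-level call table.
#' @param metadata data.frame: replicate, mother, treatment.
#' @param sites optional GRanges of sites to report (zero counts where no
#'   read remains); default: the sites present in \code{reads}.
#' @return A \linkS4class{MethylExperiment}.
#' @export
callMatrixFromReads <- function(reads, metadata, sites = NULL) {
    reads <- data.table::as.data.table(reads)
    reads[, methCall := grepl("Z", call, fixed = TRUE)]
    cnt <- reads[, list(meth = sum(methCall), unmeth = sum(!methCall)),
                 by = c("replicate", "scaffold", "pos")]
    recs <- lapply(split(cnt, cnt$replicate), function(d)
        data.table::data.table(scaffold = d$scaffold, position = d$pos,
            strand = "+", meth = as.integer(d$meth),
            unmeth = as.integer(d$unmeth)))
    recs <- recs[metadata$replicate]
    names(recs) <- metadata$replicate
    empty <- vapply(recs, is.null, logical(1))
    recs[empty] <- list(data.table::data.table(scaffold = character(0),
        position = integer(0), strand = character(0), meth = integer(0),
        unmeth = integer(0)))
    me <- assembleMatrix(recs, metadata)
    if (!is.null(sites)) {
        hit <- GenomicRanges::findOverlaps(sites,
            SummarizedExperiment::rowRanges(me), ignore.strand = TRUE)
        n <- length(sites); k <- ncol(me)
        meth <- matrix(0L, n, k); unmeth <- matrix(0L, n, k)
        meth[S4Vectors::queryHits(hit), ] <-
            methCounts(me)[S4Vectors::subjectHits(hit), ]
        unmeth[S4Vectors::queryHits(hit), ] <-
            unmethCounts(me)[S4Vectors::subjectHits(hit), ]
        me <- MethylExperiment(GenomicRanges::granges(sites), meth, unmeth,
            mother = metadata$mother, treatment = metadata$treatment,
            replicateNames = metadata$replicate)
    }
    me
}

#' GATK-style hard filtering of variants
#'
#' A variant fails if any annotation violates its bound: QD below
#' \code{qdMin}, FS above \code{fsMax}, MQ below \code{mqMin}, MQRankSum
#' below \code{mqRankSumMin}, or ReadPosRankSum below
#' \code{readPosRankSumMin}. A missing annotation does not fail that
#' criterion (GATK-consistent; set \code{strict = TRUE} to fail on
#' missing).
#'
#' @param variants GRanges from \code{\link{readVariants}}.
#' @param qdMin,fsMax,mqMin,mqRankSumMin,readPosRankSumMin thresholds
#'   (defaults: 2, 60, 40, -12.5, -8).
#' @param strict treat a missing annotation as failing.
#' @return the passing subset of \code{variants}.
#' @export
hardFilterVariants <- function(variants, qdMin = 2, fsMax = 60, mqMin = 40,
                               mqRankSumMin = -12.5,
                               readPosRankSumMin = -8.0, strict = FALSE) {
    mc <- S4Vectors::mcols(variants)
    crit <- function(x, failWhen) {
        f <- failWhen(x)
        f[is.na(x)] <- strict
        f
    }
    fails <- crit(mc$QD, function(x) x < qdMin) |
        crit(mc$FS, function(x) x > fsMax) |
        crit(mc$MQ, function(x) x < mqMin) |
        crit(mc$MQRankSum, function(x) x < mqRankSumMin) |
        crit(mc$ReadPosRankSum, function(x) x < readPosRankSumMin)
    nAllMissing <- sum(is.na(mc$QD) & is.na(mc$FS) & is.na(mc$MQ) &
                       is.na(mc$MQRankSum) & is.na(mc$ReadPosRankSum))
    if (nAllMissing && !strict)
        message(nAllMissing,
                " variant(s) with no hard-filter annotations passed through")
    variants[!fails]
}

#' Mask polymorphic CpG sites
#'
#' Removes a CpG site when a passing SNP can mimic a methylation signal
#' there: a C/T polymorphism at the cytosine position (the T allele reads
#' as an unmethylated C), or - because reverse-strand reads report the
#' complementary G - a G/A polymorphism at the position immediately after
#' the cytosine (the G of the CpG dinucleotide). The G-side rule can be
#' disabled with \code{gMask = FALSE}.
#'
#' @param me MethylExperiment.
#' @param variants passing variants (after
#'   \code{\link{hardFilterVariants}}).
#' @param gMask also mask on G/A SNPs at the G of the dinucleotide.
#' @return list with \code{me} (filtered) and \code{nRemoved},
#'   \code{fracRemoved}.
#' @export
maskPolymorphicCpgs <- function(me, variants, gMask = TRUE) {
    gr <- SummarizedExperiment::rowRanges(me)
    sc <- as.character(GenomicRanges::seqnames(gr))
    pos <- GenomicRanges::start(gr)
    vsc <- as.character(GenomicRanges::seqnames(variants))
    vpos <- GenomicRanges::start(variants)
    ct <- variants$ref == "C" & variants$alt == "T"
    ga <- variants$ref == "G" & variants$alt == "A"
    bad <- paste(sc, pos) %in% paste(vsc[ct], vpos[ct])
    if (gMask)
        bad <- bad | paste(sc, pos + 1L) %in% paste(vsc[ga], vpos[ga])
    out <- me[!bad, ]
    list(me = out, nRemoved = sum(bad),
         fracRemoved = if (length(bad)) mean(bad) else 0)
}

#' Coverage rule
#'
#' Keeps a site iff at least \code{minReplicates} replicates in each
#' treatment arm have coverage of at least \code{minReads} reads (default:
#' two replicates with six or more reads in both NF and CR).
#'
#' @param me MethylExperiment.
#' @param minReads minimum reads per replicate (default 6).
#' @param minReplicates minimum qualifying replicates per treatment
#'   (default 2).
#' @return the filtered MethylExperiment.
#' @export
applyCoverageRule <- function(me, minReads = 6L, minReplicates = 2L) {
    stopifnot(minReads >= 1L, minReplicates >= 1L)
    cov <- methCoverage(me)
    tr <- treatment(me)
    okNF <- rowSums(cov[, tr == "NF", drop = FALSE] >= minReads) >=
        minReplicates
    okCR <- rowSums(cov[, tr == "CR", drop = FALSE] >= minReads) >=
        minReplicates
    me[okNF & okCR, ]
}

#' Global methylation summary with paired t-test
#'
#' Per-replicate global CpG methylation (100 x total methylated / total
#' calls) and a paired two-tailed t-test of the per-mother CR - NF
#' differences (df = pairs - 1).
#'
#' @param me paired MethylExperiment.
#' @return list with \code{perReplicate} (data.frame replicate, mother,
#'   treatment, globalPct), \code{t}, \code{df}, \code{p}.
#' @export
globalMethylation <- function(me) {
    pid <- pairIndex(me)
    if (length(pid$mothers) < 2L)
        stop("paired t-test needs at least 2 mother pairs")
    m <- colSums(methCounts(me)); cov <- colSums(methCoverage(me))
    pct <- 100 * m / cov
    d <- pct[pid$cr] - pct[pid$nf]
    n <- length(d)
    sdd <- stats::sd(d)
    if (sdd == 0) {
        tv <- 0; p <- 1
    } else {
        tv <- mean(d) / (sdd / sqrt(n))
        p <- 2 * stats::pt(-abs(tv), df = n - 1L)
    }
    list(perReplicate = data.frame(replicate = colnames(me),
            mother = mother(me), treatment = treatment(me),
            globalPct = pct, row.names = NULL),
         t = tv, df = n - 1L, p = p)
}
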
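#' Construct a MethylExperiment
#'
#' Low-level constructor; most users will obtain a
#' \linkS4class{MethylExperiment} from \code{\link{assembleMatrix}} or the
#' synthetic-data generator.
#'
#' @param sites GRanges of CpG sites (width 1, 1-based cytosine position).
#' @param meth,unmeth integer matrices, sites x replicates.
#' @param mother integer-like vector of mother ids, one per replicate.
#' @param treatment character vector, "NF" or "CR", one per replicate.
#' @param replicateNames optional column names.
#' @param paired enforce the one-NF/one-CR-per-mother pairing at validity.
#' @return A \linkS4class{MethylExperiment}.
#' @examples
#' gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(c(10, 50), width = 1),
#'                              strand = "+")
#' me <- MethylExperiment(gr, meth = matrix(0:3, 2), unmeth = matrix(5L, 2, 2),
#'                        mother = c(1, 1), treatment = c("NF", "CR"))
#' methLevel(me)
#' @export
MethylExperiment <- function(sites, meth, unmeth, mother, treatment,
                             replicateNames = NULL, paired = TRUE) {
    meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
    stopifnot(length(sites) == nrow(meth), all(dim(meth) == dim(unmeth)),
              length(mother) == ncol(meth), length(treatment) == ncol(meth))
    if (is.null(replicateNames))
        replicateNames <- paste0("M", mother, "_", treatment)
    colnames(meth) <- colnames(unmeth) <- replicateNames
    cd <- S4Vectors::DataFrame(mother = as.integer(mother),
                               treatment = as.character(treatment),
                               row.names = replicateNames)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(meth = meth, unmeth = unmeth),
        rowRanges = sites, colData = cd)
    new("MethylExperiment", se, paired = paired)
}

#' Accessors for MethylExperiment
#'
#' \code{methCounts}/\code{unmethCounts} return the raw count matrices;
#' \code{methCoverage} their sum; \code{methLevel} the raw per-site
#' methylation proportion (NA where coverage is zero);
#' \code{smoothedLevels} the smoothed levels (after
#' \code{\link{smoothMatrix}}); \code{mother} and \code{treatment} the
#' design metadata.
#'
#' @param x a \linkS4class{MethylExperiment}.
#' @return matrices (sites x replicates) or per-replicate vectors.
#' @name methCounts
#' @aliases methCounts,MethylExperiment-method
NULL

#' @rdname methCounts
#' @export
setMethod("methCounts", "MethylExperiment", function(x)
    SummarizedExperiment::assay(x, "meth"))

#' @rdname methCounts
#' @export
setMethod("unmethCounts", "MethylExperiment", function(x)
    SummarizedExperiment::assay(x, "unmeth"))

#' @rdname methCounts
#' @export
setMethod("methCoverage", "MethylExperiment", function(x)
    SummarizedExperiment::assay(x, "meth") +
    SummarizedExperiment::assay(x, "unmeth"))

#' @rdname methCounts
#' @export
setMethod("methLevel", "MethylExperiment", function(x) {
    m <- methCounts(x); cov <- methCoverage(x)
    out <- m / cov
    out[cov == 0] <- NA_real_
    out
})

#' @rdname methCounts
#' @export
setMethod("smoothedLevels", "MethylExperiment", function(x) {
    if (!"smooth" %in% SummarizedExperiment::assayNames(x))
        stop("no 'smooth' assay: run smoothMatrix() first")
    SummarizedExperiment::assay(x, "smooth")
})

#' @rdname methCounts
#' @export
setMethod("mother", "MethylExperiment", function(x)
    SummarizedExperiment::colData(x)$mother)

#' @rdname methCounts
#' @export
setMethod("treatment", "MethylExperiment", function(x)
    SummarizedExperiment::colData(x)$treatment)

#' @describeIn MethylExperiment compact display
#' @param object a MethylExperiment
#' @export
setMethod("show", "MethylExperiment", function(object) {
    cat("MethylExperiment:", nrow(object), "CpG sites x",
        ncol(object), "replicates\n")
    tr <- table(treatment(object))
    cat("  design:", paste(names(tr), tr, sep = "=", collapse = ", "),
        if (isTRUE(object@paired)) "(paired by mother)" else "", "\n")
    cat("  assays:",
        paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
    cov <- methCoverage(object)
    cat(sprintf("  mean coverage: %.2f\n", mean(cov)))
    invisible(NULL)
})

# order rows by (scaffold lexicographic, position); stable and total
orderSites <- function(gr) {
    order(as.character(GenomicRanges::seqnames(gr)),
          GenomicRanges::start(gr))
}

# pairing helper: columns of NF and CR replicates matched by mother id,
# mothers sorted increasing
pairIndex <- function(me) {
    mo <- mother(me); tr <- treatment(me)
    mothers <- sort(unique(mo))
    nf <- vapply(mothers, function(k) which(mo == k & tr == "NF")[1L],
                 integer(1))
    cr <- vapply(mothers, function(k) which(mo == k & tr == "CR")[1L],
                 integer(1))
    if (anyNA(nf) || anyNA(cr))
        stop("unpaired design: every mother needs one NF and one CR replicate")
    list(mothers = mothers, nf = nf, cr = cr)
}
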
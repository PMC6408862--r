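#' @import methods
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

#' MethylExperiment: per-CpG methylation calls across replicates
#'
#' A thin extension of
#' \linkS4class{RangedSummarizedExperiment} holding per-CpG methylated and
#' unmethylated read counts for a set of WGBS replicates, together with the
#' design metadata a paired analysis needs: which mother each replicate
#' derives from and which treatment arm (\code{"NF"} normal food,
#' \code{"CR"} calorie restricted) it belongs to.
#'
#' Assays:
#' \describe{
#'   \item{\code{meth}}{integer matrix, methylated read counts.}
#'   \item{\code{unmeth}}{integer matrix, unmethylated read counts.}
#'   \item{\code{smooth}}{(optional, added by \code{\link{smoothMatrix}})
#'     smoothed methylation levels in [0,1].}
#' }
#'
#' Rows are CpG sites (a \code{GRanges}, 1-based, width 1, the cytosine of
#' the CpG on the reported strand), sorted by (scaffold, position).
#' Columns are replicates; \code{colData} must contain \code{mother}
#' (integer-like id) and \code{treatment} (\code{"NF"}/\code{"CR"}).
#'
#' @slot paired logical; when TRUE, validity additionally requires exactly
#'   one NF and one CR replicate per mother id.
#'
#' @seealso \code{\link{assembleMatrix}}, \code{\link{methCounts}},
#'   \code{\link{smoothMatrix}}
#' @exportClass MethylExperiment
setClass("MethylExperiment",
    contains = "RangedSummarizedExperiment",
    slots = c(paired = "logical"),
    prototype = prototype(paired = TRUE))

setValidity("MethylExperiment", function(object) {
    msg <- character()
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("meth", "unmeth") %in% an))
        msg <- c(msg, "assays 'meth' and 'unmeth' are required")
    else {
        m <- SummarizedExperiment::assay(object, "meth")
        u <- SummarizedExperiment::assay(object, "unmeth")
        if (any(m < 0, na.rm = TRUE) || any(u < 0, na.rm = TRUE))
            msg <- c(msg, "counts must be non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("mother", "treatment") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'mother' and 'treatment'")
    else {
        if (!all(cd$treatment %in% c("NF", "CR")))
            msg <- c(msg, "treatment must be 'NF' or 'CR'")
        if (isTRUE(object@paired) && nrow(cd) > 0L) {
            tab <- table(cd$mother, cd$treatment)
            if (!all(dim(tab) == c(length(unique(cd$mother)), 2L)) ||
                !all(tab == 1L))
                msg <- c(msg,
                    "paired design requires exactly one NF and one CR replicate per mother")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SimulationConfig: stated world of the synthetic WGBS generator
#'
#' Parameters of the synthetic methylome generator. Defaults describe a
#' sparse "mosaic" invertebrate methylome: global CpG methylation below 1\%
#' concentrated in clusters of consecutive exonic CpGs, 6 mother-paired
#' replicate pairs, ~10x coverage, ~3\% bisulphite conversion failure, and
#' planted DMRs with mean-difference effects of 0.10-0.35 spanning 3-20
#' CpGs, 35\% of them hypermethylated under CR.
#'
#' @slot nScaffolds number of scaffolds.
#' @slot scaffoldLength length of each scaffold in bp.
#' @slot nGenes total number of genes placed across scaffolds.
#' @slot exonsPerGene integer range (min, max) of exons per gene.
#' @slot cpgDensity CpGs per kbp (genome average).
#' @slot exonCpgEnrichment relative CpG density in exons versus elsewhere
#'   (mosaic methylomes retain CpGs in methylated gene bodies).
#' @slot fracMethylatedSites proportion of gene-body CpGs that belong to
#'   highly methylated clusters.
#' @slot clusterWidth integer range of CpGs per methylated cluster.
#' @slot highBetaParams,lowBetaParams shape pairs of the Beta distributions
#'   from which per-site baseline methylation levels are drawn for sites in
#'   methylated clusters and background sites respectively.
#' @slot nPairs number of mother pairs (each contributes one NF and one CR
#'   replicate).
#' @slot coverageMean mean reads per site per replicate.
#' @slot coverageModel "poisson" or "nbinom".
#' @slot coverageDispersion size parameter of the negative binomial.
#' @slot motherSd sd of the mother random effect on the logit scale.
#' @slot nDmrs number of planted DMRs.
#' @slot dmrEffect range of |mean difference| effects on the proportion
#'   scale.
#' @slot dmrWidth integer range of CpGs per planted DMR.
#' @slot fracHyper proportion of planted DMRs hypermethylated under CR.
#' @slot conversionFailureRate probability that a read is bisulphite
#'   unconverted.
#' @slot nSnps number of CpG sites confounded by a planted C/T (or G/A)
#'   polymorphism.
#' @slot seed integer RNG seed.
#'
#' @seealso \code{\link{simulationConfig}}
#' @exportClass SimulationConfig
setClass("SimulationConfig", slots = c(
    nScaffolds = "integer",
    scaffoldLength = "integer",
    nGenes = "integer",
    exonsPerGene = "integer",
    cpgDensity = "numeric",
    exonCpgEnrichment = "numeric",
    fracMethylatedSites = "numeric",
    clusterWidth = "integer",
    highBetaParams = "numeric",
    lowBetaParams = "numeric",
    nPairs = "integer",
    coverageMean = "numeric",
    coverageModel = "character",
    coverageDispersion = "numeric",
    motherSd = "numeric",
    nDmrs = "integer",
    dmrEffect = "numeric",
    dmrWidth = "integer",
    fracHyper = "numeric",
    conversionFailureRate = "numeric",
    nSnps = "integer",
    seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msg <- character()
    chkProp <- function(x, nm) {
        if (any(x < 0 | x > 1)) sprintf("%s must be in [0,1]", nm) else NULL
    }
    msg <- c(msg,
        chkProp(object@fracMethylatedSites, "fracMethylatedSites"),
        chkProp(object@fracHyper, "fracHyper"),
        chkProp(object@conversionFailureRate, "conversionFailureRate"))
    if (object@nPairs < 2L) msg <- c(msg, "nPairs must be >= 2")
    if (min(object@dmrWidth) < 1L) msg <- c(msg, "dmrWidth must be >= 1")
    if (min(object@clusterWidth) < 1L) msg <- c(msg, "clusterWidth must be >= 1")
    if (object@nScaffolds < 1L) msg <- c(msg, "nScaffolds must be >= 1")
    if (object@scaffoldLength < 100L) msg <- c(msg, "scaffoldLength too small")
    if (any(object@dmrEffect < 0 | object@dmrEffect > 1))
        msg <- c(msg, "dmrEffect must be in [0,1]")
    if (!object@coverageModel %in% c("poisson", "nbinom"))
        msg <- c(msg, "coverageModel must be 'poisson' or 'nbinom'")
    if (length(msg)) msg else TRUE
})

#' SimulationTruth: ground truth of a synthetic dataset
#'
#' Everything the generator knows that the pipeline must rediscover:
#' planted DMR intervals with direction and effect size, planted SNP
#' positions, and the per-site per-replicate true methylation levels.
#'
#' @slot genome list with elements \code{scaffolds} (data.frame name,
#'   length), \code{genes} (GRanges with gene ids), \code{exons} (GRanges
#'   with gene id and exon index), \code{cpgs} (GRanges of CpG sites with a
#'   genic/exonic/intergenic flag and cluster membership).
#' @slot dmrs GRanges of planted DMRs with \code{direction}
#'   (hyper/hypo in CR), \code{effect} (planted |mean difference|) and
#'   \code{nCpG}.
#' @slot snps GRanges of planted polymorphisms (ref/alt in mcols); the
#'   affected CpG site position is in \code{cpgPos}.
#' @slot baseLevel numeric, per-CpG baseline methylation level.
#' @slot trueLevel matrix, per-CpG x replicate true methylation level
#'   (after mother effect, treatment effect and SNP confounding).
#'
#' @exportClass SimulationTruth
setClass("SimulationTruth", slots = c(
    genome = "list",
    dmrs = "GRanges",
    snps = "GRanges",
    baseLevel = "numeric",
    trueLevel = "matrix"))

setValidity("SimulationTruth", function(object) {
    msg <- character()
    if (length(object@dmrs) > 1L) {
        ov <- GenomicRanges::findOverlaps(object@dmrs, object@dmrs)
        if (length(ov) > length(object@dmrs))
            msg <- c(msg, "planted DMR intervals must be disjoint")
    }
    if (length(msg)) msg else TRUE
})
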
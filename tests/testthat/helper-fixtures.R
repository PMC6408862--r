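# shared in-code fixtures

# tiny paired experiment built by hand
toyMe <- function(nSites = 6L, nPairs = 2L, meth = NULL, unmeth = NULL,
                  positions = NULL, scaffold = "sc1") {
    nRep <- 2L * nPairs
    if (is.null(positions)) positions <- seq(100L, by = 50L,
                                             length.out = nSites)
    if (is.null(meth)) meth <- matrix(3L, nSites, nRep)
    if (is.null(unmeth)) unmeth <- matrix(7L, nSites, nRep)
    gr <- GenomicRanges::GRanges(scaffold,
        IRanges::IRanges(positions, width = 1L), strand = "+")
    MethylExperiment(gr, meth, unmeth,
        mother = rep(seq_len(nPairs), each = 2L),
        treatment = rep(c("NF", "CR"), nPairs))
}

# attach a smoothed assay directly (for t-stat tests)
withSmooth <- function(me, smooth) {
    SummarizedExperiment::assay(me, "smooth", withDimnames = FALSE) <-
        smooth
    me
}

# small simulation config that runs in well under a second
tinyConfig <- function(...) {
    defaults <- list(nScaffolds = 1L, scaffoldLength = 100000L,
        nGenes = 8L, nDmrs = 3L, dmrWidth = c(3L, 6L), nSnps = 10L,
        seed = 42L)
    do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

# independent tricube weight for smoothing oracles
tricube <- function(u) ifelse(abs(u) < 1, (1 - abs(u)^3)^3, 0)
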
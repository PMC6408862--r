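#' Configure the synthetic WGBS generator
#'
#' Builds a \linkS4class{SimulationConfig} describing the stated world the
#' generator emulates: a sparse mosaic methylome in which a small fraction
#' of gene-body CpGs sit in highly methylated clusters against a near-zero
#' background, sequenced at ~10x in a mother-paired two-arm design with
#' ~3\% bisulphite conversion failure.
#'
#' With the defaults, the analytic expectation of global CpG methylation is
#' below 1\% (the mixture of the high and low Beta components weighted by
#' the realized fraction of cluster sites), matching the 0.7-0.9\% range
#' typical of *Daphnia*-like invertebrate methylomes.
#'
#' @param nScaffolds,scaffoldLength,nGenes,exonsPerGene,cpgDensity genome
#'   layout; \code{cpgDensity} is CpGs per kbp averaged over the scaffold.
#' @param exonCpgEnrichment relative CpG density in exons versus the rest
#'   of the scaffold (default 3; mosaic methylomes keep CpGs in the
#'   methylated gene bodies while the unmethylated background decays).
#' @param fracMethylatedSites proportion of gene-body CpGs assigned to
#'   highly methylated clusters.
#' @param clusterWidth CpGs per methylated cluster (range; the field's
#'   reported clusters run from 3 to 20 CpGs, averaging about six).
#' @param highBetaParams,lowBetaParams Beta shape pairs for baseline levels
#'   of cluster and background sites.
#' @param nPairs mother pairs (default 6, i.e. 12 replicates).
#' @param coverageMean,coverageModel,coverageDispersion read-depth model.
#' @param motherSd sd of the per-mother random effect (logit scale).
#' @param nDmrs,dmrEffect,dmrWidth,fracHyper planted-DMR plan; effects are
#'   mean differences on the proportion scale, 35\% hyper / 65\% hypo under
#'   CR by default.
#' @param conversionFailureRate probability a read escapes bisulphite
#'   conversion (default 0.03).
#' @param nSnps CpG sites confounded by a planted C/T or G/A polymorphism.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nScaffolds = 1, scaffoldLength = 50000L,
#'                         nGenes = 4L, nDmrs = 2L, seed = 7)
#' @export
simulationConfig <- function(nScaffolds = 2L, scaffoldLength = 500000L,
        nGenes = 60L, exonsPerGene = c(4L, 8L), cpgDensity = 20,
        exonCpgEnrichment = 3, fracMethylatedSites = 0.008,
        clusterWidth = c(3L, 20L),
        highBetaParams = c(6, 2), lowBetaParams = c(0.05, 25),
        nPairs = 6L, coverageMean = 10, coverageModel = "poisson",
        coverageDispersion = 5, motherSd = 0.3,
        nDmrs = 10L, dmrEffect = c(0.10, 0.35), dmrWidth = c(3L, 20L),
        fracHyper = 0.35, conversionFailureRate = 0.03,
        nSnps = 50L, seed = 1L) {
    new("SimulationConfig",
        nScaffolds = as.integer(nScaffolds),
        scaffoldLength = as.integer(scaffoldLength),
        nGenes = as.integer(nGenes),
        exonsPerGene = as.integer(exonsPerGene),
        cpgDensity = as.numeric(cpgDensity),
        exonCpgEnrichment = as.numeric(exonCpgEnrichment),
        fracMethylatedSites = as.numeric(fracMethylatedSites),
        clusterWidth = as.integer(clusterWidth),
        highBetaParams = as.numeric(highBetaParams),
        lowBetaParams = as.numeric(lowBetaParams),
        nPairs = as.integer(nPairs),
        coverageMean = as.numeric(coverageMean),
        coverageModel = coverageModel,
        coverageDispersion = as.numeric(coverageDispersion),
        motherSd = as.numeric(motherSd),
        nDmrs = as.integer(nDmrs),
        dmrEffect = as.numeric(dmrEffect),
        dmrWidth = as.integer(dmrWidth),
        fracHyper = as.numeric(fracHyper),
        conversionFailureRate = as.numeric(conversionFailureRate),
        nSnps = as.integer(nSnps),
        seed = as.integer(seed))
}

#' Build the synthetic genome model
#'
#' Lays out scaffolds, non-overlapping genes with ordered exons, CpG
#' positions, and the methylated-cluster structure (runs of consecutive
#' exonic CpGs destined to be highly methylated) that gives the methylome
#' its mosaic character.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return list with \code{scaffolds} (data.frame: name, length),
#'   \code{genes} (GRanges, mcols gene, nExons), \code{exons} (GRanges,
#'   mcols gene, exonIndex in transcription order, nExons), \code{cpgs}
#'   (GRanges of all CpG sites with flags \code{isGenic},
#'   \code{isExonic} and \code{clusterId}, NA outside clusters).
#' @export
buildGenomeModel <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)
    scaffolds <- data.frame(
        name = sprintf("scaffold%02d", seq_len(config@nScaffolds)),
        length = rep(config@scaffoldLength, config@nScaffolds),
        stringsAsFactors = FALSE)

    genesPer <- diff(round(seq(0, config@nGenes,
                               length.out = config@nScaffolds + 1L)))
    geneList <- list(); exonList <- list(); cpgList <- list()
    geneCounter <- 0L
    for (s in seq_len(config@nScaffolds)) {
        sc <- scaffolds$name[s]; len <- scaffolds$length[s]
        ## genes laid left to right with random gaps
        ng <- genesPer[s]
        exStartsAll <- integer(0); exEndsAll <- integer(0)
        if (ng > 0L) {
            cursor <- 1L
            gstart <- integer(ng); gend <- integer(ng)
            exStarts <- list(); exEnds <- list(); exGene <- list()
            nExonsVec <- integer(ng)
            for (g in seq_len(ng)) {
                nEx <- sample(seq(config@exonsPerGene[1],
                                  config@exonsPerGene[2]), 1L)
                exLen <- sample(150:350, nEx, replace = TRUE)
                inLen <- if (nEx > 1L)
                    sample(300:800, nEx - 1L, replace = TRUE) else integer(0)
                span <- sum(exLen) + sum(inLen)
                gap <- sample(500:3000, 1L)
                st <- cursor + gap
                if (st + span - 1L > len)
                    stop("configuration error: scaffold '", sc,
                         "' too short for ", ng, " genes")
                es <- st + cumsum(c(0L, exLen[-nEx] + inLen))
                ee <- es + exLen - 1L
                gstart[g] <- st; gend[g] <- st + span - 1L
                exStarts[[g]] <- es; exEnds[[g]] <- ee
                exGene[[g]] <- rep(g + geneCounter, nEx)
                nExonsVec[g] <- nEx
                cursor <- gend[g]
            }
            strands <- sample(c("+", "-"), ng, replace = TRUE)
            ids <- sprintf("gene%04d", geneCounter + seq_len(ng))
            gr <- GenomicRanges::GRanges(sc,
                IRanges::IRanges(gstart, gend), strand = strands)
            gr$gene <- ids; gr$nExons <- nExonsVec
            geneList[[s]] <- gr
            nExAll <- lengths(exStarts)
            exStrand <- rep(strands, nExAll)
            ex <- GenomicRanges::GRanges(sc,
                IRanges::IRanges(unlist(exStarts), unlist(exEnds)),
                strand = exStrand)
            ex$gene <- rep(ids, nExAll)
            ## exon index in transcription order: genomic order on +,
            ## reversed on -
            idxGenomic <- unlist(lapply(nExAll, seq_len))
            ex$exonIndex <- ifelse(exStrand == "+", idxGenomic,
                rep(nExAll, nExAll) - idxGenomic + 1L)
            ex$nExons <- rep(nExonsVec, nExAll)
            exonList[[s]] <- ex
            geneCounter <- geneCounter + ng
            exStartsAll <- unlist(exStarts); exEndsAll <- unlist(exEnds)
        }

        ## CpG positions: average density cpgDensity, relative density
        ## exonCpgEnrichment-fold higher inside exons
        nCpg <- round(config@cpgDensity * len / 1000)
        isEx <- logical(len)
        if (length(exStartsAll))
            isEx[unlist(Map(seq.int, exStartsAll, exEndsAll))] <- TRUE
        exBp <- sum(isEx)
        wEx <- exBp * config@exonCpgEnrichment
        wBg <- len - exBp
        nEx <- round(nCpg * wEx / (wEx + wBg))
        nEx <- min(nEx, exBp)
        nBg <- min(nCpg - nEx, len - exBp)
        exPos <- which(isEx); bgPos <- which(!isEx)
        pos <- sort(c(if (nEx > 0L) sample(exPos, nEx),
                      if (nBg > 0L) sample(bgPos, nBg)))
        pos <- pos[pos < len]
        cpgList[[s]] <- GenomicRanges::GRanges(sc,
            IRanges::IRanges(pos, width = 1L), strand = "+")
    }
    genes <- if (length(geneList)) suppressWarnings(do.call(c, geneList))
             else GenomicRanges::GRanges()
    exons <- if (length(exonList)) suppressWarnings(do.call(c, exonList))
             else GenomicRanges::GRanges()
    cpgs <- suppressWarnings(do.call(c, cpgList))
    cpgs <- cpgs[orderSites(cpgs)]
    cpgs$isGenic <- IRanges::overlapsAny(cpgs, genes, ignore.strand = TRUE)
    cpgs$isExonic <- IRanges::overlapsAny(cpgs, exons, ignore.strand = TRUE)
    cpgs$clusterId <- NA_integer_

    ## methylated clusters: runs of consecutive exonic CpGs
    nGenic <- sum(cpgs$isGenic)
    target <- round(config@fracMethylatedSites * nGenic)
    if (target > 0L && sum(cpgs$isExonic) > 0L) {
        exIdx <- which(cpgs$isExonic)
        ## consecutive runs of exonic CpGs (consecutive in the global site
        ## ordering, so a cluster stays within one exon-dense stretch)
        runs <- split(exIdx, cumsum(c(1L, diff(exIdx) != 1L)))
        runs <- runs[lengths(runs) >= config@clusterWidth[1]]
        nHigh <- 0L; cl <- 0L; tries <- 0L
        runPool <- sample(length(runs))
        while (nHigh < target && tries < length(runPool)) {
            tries <- tries + 1L
            r <- runs[[runPool[tries]]]
            if (any(!is.na(cpgs$clusterId[r]))) next
            w <- min(sample(seq(config@clusterWidth[1],
                                config@clusterWidth[2]), 1L), length(r))
            st <- if (length(r) > w) sample(length(r) - w + 1L, 1L) else 1L
            sel <- r[st:(st + w - 1L)]
            cl <- cl + 1L
            cpgs$clusterId[sel] <- cl
            nHigh <- nHigh + w
        }
    }
    list(scaffolds = scaffolds, genes = genes, exons = exons, cpgs = cpgs)
}

#' Plant differentially methylated regions and confounding SNPs
#'
#' Draws per-site baseline methylation levels (high Beta inside clusters,
#' low Beta elsewhere), selects disjoint exonic clusters to host the
#' planted DMRs, assigns directions (~\code{fracHyper} hypermethylated
#' under CR) and effect sizes, and plants C/T (or G/A on the reverse
#' strand) polymorphisms at non-DMR CpG sites.
#'
#' The treatment effect is an additive shift on the proportion scale,
#' clipped to [0,1] after the shift; hypomethylated DMRs therefore need a
#' methylated host, which placing them in high clusters guarantees.
#'
#' @param genome output of \code{\link{buildGenomeModel}}.
#' @param config the \linkS4class{SimulationConfig} used to build it.
#' @return A \linkS4class{SimulationTruth} (trueLevel filled in later by
#'   \code{\link{simulateCounts}}).
#' @export
plantDmrs <- function(genome, config) {
    set.seed(config@seed + 1L)
    cpgs <- genome$cpgs
    base <- numeric(length(cpgs))
    isHigh <- !is.na(cpgs$clusterId)
    base[isHigh] <- stats::rbeta(sum(isHigh), config@highBetaParams[1],
                                 config@highBetaParams[2])
    base[!isHigh] <- stats::rbeta(sum(!isHigh), config@lowBetaParams[1],
                                  config@lowBetaParams[2])

    dmrs <- GenomicRanges::GRanges()
    memberIdx <- list()
    if (config@nDmrs > 0L) {
        ## hosts: maximal runs of consecutive exonic CpGs (one DMR per
        ## run); members are (re)drawn from the high component so hypo
        ## effects always have a methylated host
        exIdx <- which(cpgs$isExonic)
        sameScaf <- as.character(GenomicRanges::seqnames(cpgs))
        runs <- split(exIdx, cumsum(c(1L,
            (diff(exIdx) != 1L) |
            (sameScaf[exIdx[-1L]] != sameScaf[exIdx[-length(exIdx)]]))))
        widths <- sample(seq(config@dmrWidth[1], config@dmrWidth[2]),
                         config@nDmrs, replace = TRUE)
        ok <- FALSE
        for (try in seq_len(100L)) {
            capOrder <- order(-widths)   # place widest first
            pool <- runs[sample(length(runs))]
            used <- logical(length(pool))
            assign <- vector("list", config@nDmrs)
            feasible <- TRUE
            for (d in capOrder) {
                hit <- which(!used & lengths(pool) >= widths[d])
                if (!length(hit)) { feasible <- FALSE; break }
                used[hit[1L]] <- TRUE
                r <- pool[[hit[1L]]]
                st <- if (length(r) > widths[d])
                    sample(length(r) - widths[d] + 1L, 1L) else 1L
                assign[[d]] <- r[st:(st + widths[d] - 1L)]
            }
            if (feasible) { ok <- TRUE; break }
            widths <- sample(seq(config@dmrWidth[1], config@dmrWidth[2]),
                             config@nDmrs, replace = TRUE)
        }
        if (!ok)
            stop("infeasible DMR placement: fewer than ", config@nDmrs,
                 " disjoint exonic CpG runs of width >= ",
                 config@dmrWidth[1], " available")
        memberIdx <- assign
        ## DMR members become a methylated cluster
        nextCl <- max(c(0L, cpgs$clusterId), na.rm = TRUE)
        for (d in seq_along(assign)) {
            cpgs$clusterId[assign[[d]]] <- nextCl + d
            base[assign[[d]]] <- stats::rbeta(length(assign[[d]]),
                config@highBetaParams[1], config@highBetaParams[2])
        }
        nHyper <- round(config@fracHyper * config@nDmrs)
        direction <- sample(c(rep("hyper", nHyper),
                              rep("hypo", config@nDmrs - nHyper)))
        effect <- stats::runif(config@nDmrs, config@dmrEffect[1],
                               config@dmrEffect[2])
        dmrs <- GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(cpgs))[
                vapply(assign, `[`, integer(1), 1L)],
            IRanges::IRanges(
                start = vapply(assign, function(i)
                    GenomicRanges::start(cpgs)[i[1L]], integer(1)),
                end = vapply(assign, function(i)
                    GenomicRanges::start(cpgs)[i[length(i)]], integer(1))))
        dmrs$direction <- direction
        dmrs$effect <- effect
        dmrs$nCpG <- lengths(assign)
        dmrs$members <- IRanges::IntegerList(assign)
        o <- orderSites(dmrs)
        dmrs <- dmrs[o]
        memberIdx <- memberIdx[o]
    }

    snps <- GenomicRanges::GRanges()
    if (config@nSnps > 0L) {
        inDmr <- unique(unlist(memberIdx))
        eligible <- setdiff(seq_along(cpgs), inDmr)
        pick <- sort(sample(eligible, min(config@nSnps, length(eligible))))
        onG <- stats::runif(length(pick)) < 0.5
        cpgPos <- GenomicRanges::start(cpgs)[pick]
        snpPos <- ifelse(onG, cpgPos + 1L, cpgPos)
        snps <- GenomicRanges::GRanges(
            as.character(GenomicRanges::seqnames(cpgs))[pick],
            IRanges::IRanges(snpPos, width = 1L))
        snps$ref <- ifelse(onG, "G", "C")
        snps$alt <- ifelse(onG, "A", "T")
        snps$cpgPos <- cpgPos
        snps$QD <- round(stats::runif(length(pick), 10, 35), 2)
        snps$FS <- round(stats::runif(length(pick), 0, 10), 2)
        snps$MQ <- 60
        snps$MQRankSum <- round(stats::runif(length(pick), -1, 1), 2)
        snps$ReadPosRankSum <- round(stats::runif(length(pick), -1, 1), 2)
    }
    genome$cpgs <- cpgs
    new("SimulationTruth", genome = genome, dmrs = dmrs, snps = snps,
        baseLevel = base,
        trueLevel = matrix(numeric(0), nrow = 0, ncol = 0))
}

#' Simulate methylation call counts (and optionally read-level calls)
#'
#' Per site and replicate, coverage is drawn from the configured model and
#' methylated counts from a Binomial at the replicate's true level, where
#' level = logistic(logit(baseline) + mother effect) with the planted
#' treatment shift added on the proportion scale for CR replicates and a
#' halving at C/T-confounded sites (the alternate allele always reads as
#' unmethylated). A fraction \code{conversionFailureRate} of reads is
#' emitted unconverted: every cytosine on such a read calls methylated,
#' including its CHH/CHG positions, inflating the raw counts exactly as
#' conversion failure does in real libraries.
#'
#' @param truth a \linkS4class{SimulationTruth} from \code{\link{plantDmrs}}.
#' @param config the matching \linkS4class{SimulationConfig}.
#' @param readLevel also emit the read-level call table (one row per read:
#'   replicate, scaffold, start, call string in the Bismark extractor
#'   alphabet, z/Z CpG, x/X CHG, h/H CHH, lower case unmethylated).
#' @return list with \code{me} (a \linkS4class{MethylExperiment} whose
#'   counts include unconverted reads, i.e. the pre-filter calls),
#'   \code{reads} (data.table or NULL) and \code{truth} (with
#'   \code{trueLevel} filled in).
#' @export
simulateCounts <- function(truth, config, readLevel = TRUE) {
    set.seed(config@seed + 2L)
    cpgs <- truth@genome$cpgs
    nSite <- length(cpgs)
    nRep <- 2L * config@nPairs
    mothers <- rep(seq_len(config@nPairs), each = 2L)
    treat <- rep(c("NF", "CR"), config@nPairs)
    ## per-site mother random effect, shared by both replicates of a
    ## mother: epiallelic variation between maternal lines at each locus,
    ## which cancels exactly in the paired differences
    mEff <- matrix(stats::rnorm(nSite * config@nPairs, 0, config@motherSd),
                   nSite, config@nPairs)

    b <- pmin(pmax(truth@baseLevel, 1e-6), 1 - 1e-6)
    lv <- matrix(0, nSite, nRep)
    shift <- numeric(nSite)
    if (length(truth@dmrs)) {
        mem <- truth@dmrs$members
        dirSign <- ifelse(truth@dmrs$direction == "hyper", 1, -1)
        for (d in seq_along(truth@dmrs))
            shift[mem[[d]]] <- dirSign[d] * truth@dmrs$effect[d]
    }
    confounded <- integer(0)
    if (length(truth@snps)) {
        hit <- match(paste(as.character(GenomicRanges::seqnames(truth@snps)),
                           truth@snps$cpgPos),
                     paste(as.character(GenomicRanges::seqnames(cpgs)),
                           GenomicRanges::start(cpgs)))
        confounded <- hit[!is.na(hit)]
    }
    for (r in seq_len(nRep)) {
        l <- stats::plogis(stats::qlogis(b) + mEff[, mothers[r]])
        if (treat[r] == "CR") l <- pmin(pmax(l + shift, 0), 1)
        if (length(confounded)) l[confounded] <- l[confounded] / 2
        lv[, r] <- l
    }

    covv <- if (config@coverageModel == "poisson") {
        matrix(stats::rpois(nSite * nRep, config@coverageMean), nSite, nRep)
    } else {
        matrix(stats::rnbinom(nSite * nRep, mu = config@coverageMean,
                              size = config@coverageDispersion), nSite, nRep)
    }
    f <- config@conversionFailureRate
    unconv <- matrix(stats::rbinom(nSite * nRep, as.vector(covv), f),
                     nSite, nRep)
    methConv <- matrix(stats::rbinom(nSite * nRep,
                                     as.vector(covv - unconv),
                                     as.vector(lv)), nSite, nRep)
    meth <- methConv + unconv
    unmeth <- covv - meth
    repNames <- paste0("M", mothers, "_", treat)
    me <- MethylExperiment(GenomicRanges::granges(cpgs), meth, unmeth,
                           mother = mothers, treatment = treat,
                           replicateNames = repNames)

    reads <- NULL
    if (readLevel) {
        sc <- as.character(GenomicRanges::seqnames(cpgs))
        pos <- GenomicRanges::start(cpgs)
        blocks <- list()
        for (r in seq_len(nRep)) {
            nU <- unconv[, r]; nM <- methConv[, r]
            nZ <- covv[, r] - nU - nM
            counts <- c(nU, nM, nZ)
            kind <- rep(rep(c("U", "M", "Z"), each = nSite), counts)
            i <- rep(rep(seq_len(nSite), 3L), counts)
            n <- length(i)
            if (!n) next
            nH <- sample(1:3, n, replace = TRUE)
            nX <- sample(1:3, n, replace = TRUE)
            cpgCall <- ifelse(kind == "Z", "z", "Z")
            hCall <- ifelse(kind == "U", "H", "h")
            xCall <- ifelse(kind == "U", "X", "x")
            blocks[[r]] <- data.table::data.table(
                replicate = repNames[r], scaffold = sc[i], pos = pos[i],
                call = paste0(cpgCall, strrep(hCall, nH), strrep(xCall, nX)))
        }
        reads <- data.table::rbindlist(blocks)
        data.table::setorder(reads, replicate, scaffold, pos)
        reads[, read_id := sprintf("read%08d", .I)]
        data.table::setcolorder(reads,
            c("read_id", "replicate", "scaffold", "pos", "call"))
    }
    truth@trueLevel <- lv
    colnames(truth@trueLevel) <- repNames
    list(me = me, reads = reads, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the on-disk artifacts of a simulated experiment: one Bismark-style
#' cytosine report per replicate, the read-level call table, a GFF3 gene
#' and exon annotation, a minimal VCF v4.2 of the planted SNPs (QD, FS,
#' MQ, MQRankSum, ReadPosRankSum INFO keys), a pairing table, and the
#' ground-truth tables (planted DMRs as TSV and BED, planted SNP sites,
#' per-replicate true levels). Everything round-trips losslessly through
#' the package readers.
#'
#' @param me MethylExperiment from \code{\link{simulateCounts}}.
#' @param truth matching \linkS4class{SimulationTruth}.
#' @param dir output directory, created if absent.
#' @param reads optional read-level call table.
#' @return named list of the written paths, invisibly.
#' @export
emitDataset <- function(me, truth, dir, reads = NULL) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    ok <- file.access(dir, 2) == 0
    if (!ok) stop("directory not writable: ", dir)
    paths <- list()
    for (j in seq_len(ncol(me))) {
        p <- file.path(dir, paste0(colnames(me)[j], ".CpG_report.txt"))
        writeCytosineReport(me, j, p)
        paths[[colnames(me)[j]]] <- p
    }
    paths$pairing <- file.path(dir, "pairing.tsv")
    utils::write.table(
        data.frame(replicate = colnames(me), mother = mother(me),
                   treatment = treatment(me)),
        paths$pairing, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(reads)) {
        paths$reads <- file.path(dir, "reads.tsv")
        data.table::fwrite(reads, paths$reads, sep = "\t")
    }
    ## annotation as GFF3
    paths$annotation <- file.path(dir, "genes.gff3")
    g <- truth@genome$genes
    e <- truth@genome$exons
    ga <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
        IRanges::IRanges(GenomicRanges::start(g), GenomicRanges::end(g)),
        strand = GenomicRanges::strand(g))
    ga$type <- "gene"; ga$ID <- g$gene
    ea <- GenomicRanges::GRanges(GenomicRanges::seqnames(e),
        IRanges::IRanges(GenomicRanges::start(e), GenomicRanges::end(e)),
        strand = GenomicRanges::strand(e))
    ea$type <- "exon"; ea$Parent <- e$gene
    ea$exon_number <- e$exonIndex
    rtracklayer::export(suppressWarnings(c(ga, ea)), paths$annotation,
                        format = "gff3")
    ## minimal VCF v4.2
    paths$vcf <- file.path(dir, "snps.vcf")
    writeMinimalVcf(truth@snps, truth@genome$scaffolds, paths$vcf)
    ## truth tables
    paths$truthDmrs <- file.path(dir, "truth_dmrs.tsv")
    d <- truth@dmrs
    utils::write.table(
        data.frame(scaffold = as.character(GenomicRanges::seqnames(d)),
                   start = GenomicRanges::start(d),
                   end = GenomicRanges::end(d),
                   direction = if (length(d)) d$direction else character(0),
                   effect = if (length(d)) d$effect else numeric(0),
                   nCpG = if (length(d)) d$nCpG else integer(0)),
        paths$truthDmrs, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truthDmrsBed <- file.path(dir, "truth_dmrs.bed")
    writeRegions(d, paths$truthDmrsBed, format = "BED")
    paths$truthSnps <- file.path(dir, "truth_snps.tsv")
    s <- truth@snps
    utils::write.table(
        data.frame(scaffold = as.character(GenomicRanges::seqnames(s)),
                   pos = GenomicRanges::start(s),
                   ref = if (length(s)) s$ref else character(0),
                   alt = if (length(s)) s$alt else character(0),
                   cpgPos = if (length(s)) s$cpgPos else integer(0)),
        paths$truthSnps, sep = "\t", quote = FALSE, row.names = FALSE)
    paths$truthLevels <- file.path(dir, "truth_levels.tsv")
    cp <- truth@genome$cpgs
    data.table::fwrite(data.table::data.table(
        scaffold = as.character(GenomicRanges::seqnames(cp)),
        pos = GenomicRanges::start(cp),
        baseLevel = truth@baseLevel,
        truth@trueLevel), paths$truthLevels, sep = "\t")
    invisible(paths)
}

# hand-written minimal VCF v4.2 (records are simple SNVs; header declares
# the five hard-filter INFO keys so VariantAnnotation round-trips them)
writeMinimalVcf <- function(snps, scaffolds, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
        "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
        "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
        "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
        "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
        "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
        sprintf("##contig=<ID=%s,length=%d>", scaffolds$name,
                scaffolds$length),
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (length(snps)) {
        info <- sprintf("QD=%s;FS=%s;MQ=%s;MQRankSum=%s;ReadPosRankSum=%s",
                        snps$QD, snps$FS, snps$MQ, snps$MQRankSum,
                        snps$ReadPosRankSum)
        writeLines(sprintf("%s\t%d\t.\t%s\t%s\t50\tPASS\t%s",
            as.character(GenomicRanges::seqnames(snps)),
            GenomicRanges::start(snps), snps$ref, snps$alt, info), con)
    }
    invisible(path)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper chaining \code{\link{buildGenomeModel}},
#' \code{\link{plantDmrs}} and \code{\link{simulateCounts}}, optionally
#' writing everything to disk via \code{\link{emitDataset}}.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param dir optional output directory.
#' @param readLevel emit the read-level call table.
#' @return list(me, reads, truth, paths).
#' @export
simulateDataset <- function(config = simulationConfig(), dir = NULL,
                            readLevel = TRUE) {
    genome <- buildGenomeModel(config)
    truth <- plantDmrs(genome, config)
    sim <- simulateCounts(truth, config, readLevel = readLevel)
    sim$paths <- if (!is.null(dir))
        emitDataset(sim$me, sim$truth, dir, reads = sim$reads) else NULL
    sim
}
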
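## End-to-end orchestration: one config, stages in order, every
## intermediate written, counts logged at each filter stage.

#' Default pipeline configuration
#'
#' Returns the full configuration as a nested list with the package's
#' defaults filled in; write it with \code{\link{writePipelineConfig}} to
#' obtain an explicit, versionable parameter file (JSON).
#'
#' @param callFiles named character vector of per-replicate cytosine
#'   reports (names = replicate ids).
#' @param pairing data.frame replicate, mother, treatment.
#' @param annotationFile,vcfFile,readsFile,goMapFile,goParentsFile
#'   optional inputs; stages needing an absent input are skipped.
#' @param outDir output directory.
#' @param seed seed for the bootstrap stage.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(callFiles = character(0), pairing = NULL,
        annotationFile = NULL, vcfFile = NULL, readsFile = NULL,
        goMapFile = NULL, goParentsFile = NULL, outDir = "dmr_out",
        seed = 1L) {
    list(paths = list(callFiles = callFiles,
                      annotationFile = annotationFile,
                      vcfFile = vcfFile, readsFile = readsFile,
                      goMapFile = goMapFile,
                      goParentsFile = goParentsFile, outDir = outDir),
         pairing = pairing,
         filter = list(minReads = 6L, minReplicates = 2L, gMask = TRUE,
                       qdMin = 2, fsMax = 60, mqMin = 40,
                       mqRankSumMin = -12.5, readPosRankSumMin = -8.0),
         smoothing = list(minCpgs = 70L, minWindowBp = 1000,
                          degree = 2L, maxGapBp = 1e8),
         dmr = list(floorQuantile = 0.75, tCut = 4.6, maxGapBp = 300,
                    minCpgs = 3L, minAbsMeanDiff = 0.1, siteFdr = 0.05,
                    minSigCpgs = 0L),
         combine = list(binWidth = 50, maxLag = 500, alpha = 0.05),
         cluster = list(nBoot = 500L),
         enrich = list(alpha = 0.01, algorithm = "elim"),
         seed = as.integer(seed))
}

#' Write / read a pipeline configuration
#'
#' JSON round-trip of the nested configuration list, so every parameter
#' of a run is explicit on disk.
#'
#' @param config nested list from \code{\link{pipelineConfig}}.
#' @param path file path.
#' @return the path (write) or the configuration list (read).
#' @export
writePipelineConfig <- function(config, path) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
    invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
    if (!file.exists(path)) stop("no such config file: ", path)
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg$pairing <- as.data.frame(cfg$pairing)
    cfg
}

#' Run the full differential-methylation pipeline
#'
#' Stages, in order: read-level non-conversion filter (when a read table
#' is given) or cytosine-report import; variant hard filtering and
#' polymorphic-CpG masking (when a VCF is given); coverage rule; global
#' methylation summary with its paired t-test; BSmooth-style smoothing;
#' per-CpG paired t statistics; candidate regions; candidate filtering;
#' autocorrelation-aware region p-value combination and BH; final DMR
#' intersection; replicate clustering with bootstrap support; gene/exon
#' overlap and (when a GO map is given) term enrichment. Every
#' intermediate is written under \code{outDir} and a stage log records
#' site/read counts before and after each filter.
#'
#' @param config nested list from \code{\link{pipelineConfig}} or
#'   \code{\link{readPipelineConfig}}.
#' @param me optionally, an in-memory \linkS4class{MethylExperiment} to
#'   use instead of reading call files.
#' @param reads optionally, an in-memory read-level call table.
#' @return list with the filtered matrix, smoothed matrix, per-CpG stats,
#'   candidate/filtered/combined/final regions, clustering, overlaps,
#'   enrichment tables, global methylation summary, the stage log, and
#'   written paths.
#' @export
runPipeline <- function(config, me = NULL, reads = NULL) {
    outDir <- config$paths$outDir
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    log <- list()
    note <- function(stage, ...) {
        msg <- paste0(...)
        log[[length(log) + 1L]] <<- data.frame(stage = stage, note = msg)
        message("[", stage, "] ", msg)
    }

    pairing <- as.data.frame(config$pairing)

    ## --- input ---------------------------------------------------------
    if (is.null(reads) && !is.null(config$paths$readsFile))
        reads <- data.table::fread(config$paths$readsFile)
    if (!is.null(reads)) {
        fl <- filterNonconvertedReads(reads)
        note("reads", nrow(reads), " reads, ",
             sum(fl$report$nRemoved), " removed as unconverted (",
             sprintf("%.2f%%", 100 * sum(fl$report$nRemoved) / nrow(reads)),
             ")")
        utils::write.table(fl$report,
            file.path(outDir, "conversion_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        sites <- if (!is.null(me)) SummarizedExperiment::rowRanges(me)
                 else NULL
        me <- callMatrixFromReads(fl$reads, pairing, sites = sites)
    } else if (is.null(me)) {
        files <- config$paths$callFiles
        recs <- lapply(files, readCytosineReport)
        names(recs) <- names(files)
        me <- assembleMatrix(recs, pairing)
    }
    note("input", nrow(me), " CpG sites x ", ncol(me), " replicates")

    ## --- SNP masking ---------------------------------------------------
    if (!is.null(config$paths$vcfFile)) {
        v <- readVariants(config$paths$vcfFile)
        fcfg <- config$filter
        vp <- hardFilterVariants(v, qdMin = fcfg$qdMin, fsMax = fcfg$fsMax,
            mqMin = fcfg$mqMin, mqRankSumMin = fcfg$mqRankSumMin,
            readPosRankSumMin = fcfg$readPosRankSumMin)
        note("variants", length(v), " variants, ", length(vp),
             " pass hard filters")
        msk <- maskPolymorphicCpgs(me, vp, gMask = config$filter$gMask)
        note("snp_mask", msk$nRemoved, " polymorphic CpG sites removed (",
             sprintf("%.2f%%", 100 * msk$fracRemoved), ")")
        me <- msk$me
    }

    ## --- coverage rule -------------------------------------------------
    before <- nrow(me)
    me <- applyCoverageRule(me, config$filter$minReads,
                            config$filter$minReplicates)
    note("coverage", before, " -> ", nrow(me), " sites after coverage rule")

    glob <- globalMethylation(me)
    note("global", sprintf(
        "global CpG methylation %.3f-%.3f%%; paired t = %.3f, p = %.3g",
        min(glob$perReplicate$globalPct), max(glob$perReplicate$globalPct),
        glob$t, glob$p))

    ## --- smoothing + per-CpG stats ------------------------------------
    scfg <- config$smoothing
    me <- smoothMatrix(me, smootherConfig(scfg$minCpgs, scfg$minWindowBp,
                                          scfg$degree, scfg$maxGapBp))
    stats <- pairedTStats(me, config$dmr$floorQuantile)

    ## --- candidate regions --------------------------------------------
    dcfg <- config$dmr
    candidates <- findCandidateRegions(stats, tCut = dcfg$tCut,
        maxGapBp = dcfg$maxGapBp, siteFdr = dcfg$siteFdr)
    filtered <- filterCandidates(candidates, minCpgs = dcfg$minCpgs,
        minAbsMeanDiff = dcfg$minAbsMeanDiff,
        minSigCpgs = dcfg$minSigCpgs)
    note("dmr", length(candidates), " candidate regions; ",
         length(filtered), " pass the CpG-count and mean-difference filters")

    ## --- region combination -------------------------------------------
    final <- candidates[0L]
    combined <- candidates
    if (length(candidates) && nrow(stats) >= 2L) {
        acf <- estimateAcf(stats, binWidth = config$combine$binWidth,
                           maxLag = config$combine$maxLag)
        utils::write.table(acf, file.path(outDir, "acf.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        combined <- combineRegions(candidates, stats, acf)
        final <- finalizeDmrs(combined, filtered,
                              alpha = config$combine$alpha)
    }
    note("combine", length(final), " final DMRs at corrected p < ",
         config$combine$alpha)

    ## --- clustering ----------------------------------------------------
    clustering <- NULL
    cl <- tryCatch(bootstrapSupport(methLevel(me),
            nBoot = config$cluster$nBoot, seed = config$seed),
        error = function(e) {
            note("cluster", "skipped: ", conditionMessage(e)); NULL
        })
    if (!is.null(cl)) {
        clustering <- cl
        writeNewick(cl, file.path(outDir, "dendrogram.nwk"))
    }

    ## --- annotation + enrichment --------------------------------------
    overlaps <- NULL; enrichment <- NULL
    if (!is.null(config$paths$annotationFile)) {
        ann <- readGeneAnnotation(config$paths$annotationFile)
        overlaps <- overlapDmrsGenes(final, ann)
        if (!is.null(config$paths$goMapFile) &&
            !is.null(config$paths$goParentsFile)) {
            goMap <- utils::read.delim(config$paths$goMapFile,
                header = FALSE, col.names = c("gene", "term"))
            parents <- utils::read.delim(config$paths$goParentsFile,
                header = FALSE,
                col.names = c("term", "parent", "namespace"))
            universes <- buildUniverses(me, ann)
            enrichment <- list()
            for (dirn in c("hyper", "hypo"))
                for (u in names(universes))
                    enrichment[[paste(dirn, u, sep = ".")]] <-
                        fisherEnrichment(overlaps$geneSets[[dirn]],
                            universes[[u]], goMap, parents,
                            alpha = config$enrich$alpha,
                            algorithm = config$enrich$algorithm)
        }
    }

    ## --- outputs -------------------------------------------------------
    final <- attachOverlapColumns(final, overlaps)
    writeRegions(candidates, file.path(outDir, "candidates.bed"), "BED")
    writeRegions(candidates, file.path(outDir, "candidates.tsv"), "TSV")
    writeRegions(filtered, file.path(outDir, "filtered.tsv"), "TSV")
    writeRegions(final, file.path(outDir, "final_dmrs.bed"), "BED")
    writeRegions(final, file.path(outDir, "final_dmrs.tsv"), "TSV")
    utils::write.table(stats, file.path(outDir, "per_cpg_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- summarizeRun(final, overlaps$overlaps)
    writeLines(formatRunSummary(summary),
               file.path(outDir, "summary.txt"))
    logDf <- do.call(rbind, log)
    utils::write.table(logDf, file.path(outDir, "stage_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    list(me = me, global = glob, stats = stats, candidates = candidates,
         filtered = filtered, combined = combined, final = final,
         clustering = clustering, overlaps = overlaps,
         enrichment = enrichment, summary = summary, log = logDf,
         outDir = outDir)
}

# carry gene/exon annotations onto the final region table for TSV output
attachOverlapColumns <- function(final, overlaps) {
    if (is.null(overlaps) || length(final) == 0L) return(final)
    ov <- overlaps$overlaps
    key <- sprintf("%s:%d-%d",
        as.character(GenomicRanges::seqnames(final)),
        GenomicRanges::start(final), GenomicRanges::end(final))
    i <- match(key, ov$dmrKey)
    final$gene <- ov$gene[i]
    final$exon <- ov$exon[i]
    final$geneStrand <- ov$geneStrand[i]
    final$q <- final$correctedP
    final
}

#' Summarise a final DMR set
#'
#' Counts and integer-rounded percentages in the field's reporting style:
#' hyper/hypo split, gene-overlapping vs intergenic DMRs, exonic fraction
#' per direction, DMR length mean and range (length = end - start), and
#' CpGs per region mean and range.
#'
#' @param final GRanges of final DMRs (direction, nCpG mcols).
#' @param overlaps overlap data.frame from \code{\link{overlapDmrsGenes}}
#'   (or NULL: gene-related fields become NA).
#' @return list of counts and percentages.
#' @export
summarizeRun <- function(final, overlaps = NULL) {
    n <- length(final)
    if (n == 0L) {
        return(list(n = 0L, note = "empty DMR set",
            nHyper = 0L, nHypo = 0L, pctHyper = 0L, pctHypo = 0L,
            nIntergenic = NA_integer_, pctIntergenic = NA_integer_,
            exonicPct = c(hyper = NA_integer_, hypo = NA_integer_),
            lengthMean = NA_real_, lengthRange = c(NA_real_, NA_real_),
            cpgMean = NA_real_, cpgRange = c(NA_real_, NA_real_)))
    }
    nHyper <- sum(final$direction == "hyper")
    nHypo <- n - nHyper
    len <- GenomicRanges::end(final) - GenomicRanges::start(final)
    out <- list(n = n, nHyper = nHyper, nHypo = nHypo,
        pctHyper = as.integer(round(100 * nHyper / n)),
        pctHypo = as.integer(round(100 * nHypo / n)),
        lengthMean = mean(len), lengthRange = range(len),
        cpgMean = mean(final$nCpG), cpgRange = range(final$nCpG))
    if (!is.null(overlaps)) {
        key <- sprintf("%s:%d-%d",
            as.character(GenomicRanges::seqnames(final)),
            GenomicRanges::start(final), GenomicRanges::end(final))
        overlapped <- key %in% overlaps$dmrKey
        out$nIntergenic <- sum(!overlapped)
        out$pctIntergenic <- as.integer(round(100 * mean(!overlapped)))
        exonicPct <- c(hyper = NA_integer_, hypo = NA_integer_)
        for (dirn in c("hyper", "hypo")) {
            ovd <- overlaps[overlaps$direction == dirn, ]
            if (nrow(ovd))
                exonicPct[dirn] <- as.integer(round(
                    100 * sum(ovd$class %in% c("exonic", "mixed")) /
                        nrow(ovd)))
        }
        out$exonicPct <- exonicPct
    } else {
        out$nIntergenic <- NA_integer_
        out$pctIntergenic <- NA_integer_
        out$exonicPct <- c(hyper = NA_integer_, hypo = NA_integer_)
    }
    out
}

formatRunSummary <- function(s) {
    c(sprintf("final DMRs: %d", s$n),
      sprintf("hyper (CR): %d (%s%%)  hypo (CR): %d (%s%%)",
              s$nHyper, s$pctHyper, s$nHypo, s$pctHypo),
      sprintf("intergenic: %s (%s%%)", s$nIntergenic, s$pctIntergenic),
      sprintf("exonic among hyper: %s%%  among hypo: %s%%",
              s$exonicPct["hyper"], s$exonicPct["hypo"]),
      sprintf("DMR length (end - start): mean %.1f, range %s-%s",
              s$lengthMean, s$lengthRange[1], s$lengthRange[2]),
      sprintf("CpGs per region: mean %.1f, range %s-%s",
              s$cpgMean, s$cpgRange[1], s$cpgRange[2]))
}
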
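## DMR-to-gene annotation, gene universes, and Fisher-based GO term
## enrichment (classic and hierarchy-aware elim).

#' Overlap DMRs with genes and exons
#'
#' Interval intersection under the internal 1-based inclusive convention,
#' ignoring strand (methylation is reported strand-resolved but a DMR
#' belongs to a gene on either strand). Each overlap is classed
#' \code{exonic} (only exon sequence shared), \code{intronic} (only
#' intron) or \code{mixed} (both); the exon hit reports the first
#' (transcription-order) exon overlapped, as "i of n".
#'
#' @param dmrs GRanges of final DMRs.
#' @param annotation list(genes, exons) from
#'   \code{\link{readGeneAnnotation}} or the generator.
#' @return list with \code{overlaps} (data.frame: dmr id, gene, class,
#'   exon, geneStrand, direction) and \code{geneSets} (non-redundant gene
#'   id vectors per direction: hyper, hypo).
#' @export
overlapDmrsGenes <- function(dmrs, annotation) {
    genes <- annotation$genes; exons <- annotation$exons
    hits <- GenomicRanges::findOverlaps(dmrs, genes, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    n <- length(qh)
    cls <- character(n); exonLab <- character(n)
    for (i in seq_len(n)) {
        d <- dmrs[qh[i]]
        g <- genes[sh[i]]
        ex <- exons[exons$gene == g$gene]
        exHits <- GenomicRanges::findOverlaps(d, ex, ignore.strand = TRUE)
        exBp <- sum(GenomicRanges::width(GenomicRanges::pintersect(
            rep(d, length(S4Vectors::subjectHits(exHits))),
            ex[S4Vectors::subjectHits(exHits)], ignore.strand = TRUE)))
        dmrInGene <- GenomicRanges::pintersect(d, g, ignore.strand = TRUE)
        totBp <- sum(GenomicRanges::width(dmrInGene))
        hasExon <- length(exHits) > 0L
        hasIntron <- totBp > exBp
        cls[i] <- if (hasExon && hasIntron) "mixed"
                  else if (hasExon) "exonic" else "intronic"
        exonLab[i] <- if (hasExon) {
            first <- min(ex$exonIndex[S4Vectors::subjectHits(exHits)])
            sprintf("%d of %d", first, ex$nExons[1L])
        } else NA_character_
    }
    direction <- if (!is.null(dmrs$direction)) dmrs$direction[qh]
                 else rep(NA_character_, n)
    ov <- data.frame(dmr = qh,
        dmrKey = sprintf("%s:%d-%d",
            as.character(GenomicRanges::seqnames(dmrs))[qh],
            GenomicRanges::start(dmrs)[qh], GenomicRanges::end(dmrs)[qh]),
        gene = genes$gene[sh], class = cls, exon = exonLab,
        geneStrand = as.character(GenomicRanges::strand(genes))[sh],
        direction = direction, stringsAsFactors = FALSE)
    geneSets <- list(
        hyper = unique(ov$gene[ov$direction == "hyper"]),
        hypo = unique(ov$gene[ov$direction == "hypo"]))
    list(overlaps = ov, geneSets = geneSets)
}

#' Build the nested gene universes
#'
#' A CpG counts as methylated when its pooled (across replicates) raw
#' pre-smoothing methylated count exceeds zero; genes are then binned by
#' how many such CpGs they contain. Returns the three universes used for
#' enrichment: all genes, genes with >= 1 methylated CpG, genes with >= 3
#' (always nested).
#'
#' @param me MethylExperiment with raw (pre-smoothing) counts.
#' @param annotation list(genes, exons).
#' @param thresholds methylated-CpG count thresholds (default c(1, 3)).
#' @param perReplicate count a CpG as methylated only if methylated in at
#'   least one replicate considered separately (same as pooled for
#'   threshold "count > 0"; kept as an explicit flag for stricter
#'   variants).
#' @return named list of gene id vectors: \code{all}, then \code{geq<k>}
#'   per threshold.
#' @export
buildUniverses <- function(me, annotation, thresholds = c(1L, 3L),
                           perReplicate = FALSE) {
    pooled <- if (perReplicate)
        as.integer(rowSums(methCounts(me) > 0) > 0)
    else as.integer(rowSums(methCounts(me)) > 0)
    sites <- SummarizedExperiment::rowRanges(me)
    genes <- annotation$genes
    hits <- GenomicRanges::findOverlaps(sites, genes, ignore.strand = TRUE)
    cnt <- tapply(pooled[S4Vectors::queryHits(hits)],
                  genes$gene[S4Vectors::subjectHits(hits)], sum)
    methCount <- setNames(rep(0L, length(genes)), genes$gene)
    methCount[names(cnt)] <- as.integer(cnt)
    out <- list(all = genes$gene)
    for (k in thresholds)
        out[[paste0("geq", k)]] <- names(methCount)[methCount >= k]
    out
}

#' Propagate gene annotations up the GO hierarchy
#'
#' A gene annotated to a term is annotated to every ancestor of that
#' term.
#'
#' @param goMap data.frame (gene, term).
#' @param parents data.frame (term, parent); terms absent from the
#'   hierarchy are treated as root-attached (message).
#' @return list: gene id vectors per term, closed under ancestry.
#' @export
propagateAnnotations <- function(goMap, parents) {
    anc <- ancestorClosure(parents)
    known <- unique(c(parents$term, parents$parent))
    orphan <- setdiff(unique(goMap$term), known)
    if (length(orphan))
        message(length(orphan),
                " term(s) absent from the hierarchy treated as root-attached")
    genesByTerm <- split(goMap$gene, goMap$term)
    out <- genesByTerm
    for (tm in names(genesByTerm)) {
        for (a in anc[[tm]]) {
            out[[a]] <- c(out[[a]], genesByTerm[[tm]])
        }
    }
    lapply(out, unique)
}

# term -> all ancestors (transitive closure over the parent table)
ancestorClosure <- function(parents) {
    parentOf <- split(parents$parent, parents$term)
    terms <- unique(c(parents$term, parents$parent))
    anc <- list()
    getAnc <- function(tm, seen = character(0)) {
        if (!is.null(anc[[tm]])) return(anc[[tm]])
        ps <- setdiff(parentOf[[tm]], seen)
        res <- character(0)
        for (p in ps) res <- c(res, p, getAnc(p, c(seen, tm)))
        res <- unique(res)
        anc[[tm]] <<- res
        res
    }
    for (tm in terms) getAnc(tm)
    anc
}

#' Fisher-based GO term enrichment
#'
#' One-sided hypergeometric (Fisher) upper-tail test per term after
#' propagating annotations to ancestors. \code{algorithm = "elim"}
#' processes terms bottom-up and removes the genes of significantly
#' enriched child terms from their ancestors before testing them, so
#' general terms are not called significant merely because a specific
#' descendant is. No multiple-testing correction is applied (standard for
#' hierarchy-aware GO testing).
#'
#' @param interest gene ids of interest (e.g. DMR-overlapping genes).
#' @param universe gene id universe; interest is intersected with it.
#' @param goMap data.frame (gene, term), optionally a namespace column
#'   ("BP"/"MF").
#' @param parents data.frame (term, parent, namespace).
#' @param alpha significance level (default 0.01, used for reporting and
#'   for the elim cut).
#' @param algorithm "classic" or "elim".
#' @param minGenes skip terms with fewer universe genes (default 1).
#' @return data.frame: term, namespace, interestWithTerm, interestSize,
#'   universeWithTerm, universeSize, p, significant; sorted by p.
#' @export
fisherEnrichment <- function(interest, universe, goMap, parents,
                             alpha = 0.01,
                             algorithm = c("classic", "elim"),
                             minGenes = 1L) {
    algorithm <- match.arg(algorithm)
    interest <- intersect(interest, universe)
    genesByTerm <- propagateAnnotations(goMap, parents)
    genesByTerm <- lapply(genesByTerm, intersect, universe)
    genesByTerm <- genesByTerm[lengths(genesByTerm) >= minGenes]
    terms <- names(genesByTerm)
    N <- length(universe); K <- length(interest)
    ns <- termNamespace(terms, parents)

    testTerm <- function(gset) {
        nTerm <- length(gset)
        k <- length(intersect(gset, interest))
        p <- stats::phyper(k - 1L, nTerm, N - nTerm, K,
                           lower.tail = FALSE)
        c(k = k, n = nTerm, p = p)
    }

    if (algorithm == "classic") {
        res <- t(vapply(genesByTerm, testTerm, numeric(3)))
    } else {
        depth <- termDepth(terms, parents)
        anc <- ancestorClosure(parents)
        eliminated <- setNames(vector("list", length(terms)), terms)
        res <- matrix(NA_real_, length(terms), 3,
                      dimnames = list(terms, c("k", "n", "p")))
        for (tm in terms[order(-depth)]) {       # deepest first
            gset <- setdiff(genesByTerm[[tm]], eliminated[[tm]])
            res[tm, ] <- testTerm(gset)
            if (res[tm, "p"] < alpha) {
                for (a in intersect(anc[[tm]], terms))
                    eliminated[[a]] <- union(eliminated[[a]],
                                             genesByTerm[[tm]])
            }
        }
    }
    out <- data.frame(term = terms, namespace = ns,
        interestWithTerm = as.integer(res[, "k"]),
        interestSize = K,
        universeWithTerm = as.integer(res[, "n"]),
        universeSize = N,
        p = res[, "p"],
        significant = res[, "p"] < alpha,
        row.names = NULL, stringsAsFactors = FALSE)
    out[order(out$p, out$term), ]
}

termNamespace <- function(terms, parents) {
    if (!"namespace" %in% colnames(parents))
        return(rep(NA_character_, length(terms)))
    m <- c(stats::setNames(parents$namespace, parents$term),
           stats::setNames(parents$namespace, parents$parent))
    unname(m[terms])
}

# depth = longest path to a root (term with no parent)
termDepth <- function(terms, parents) {
    anc <- ancestorClosure(parents)
    vapply(terms, function(tm)
        length(anc[[tm]]), integer(1))
}
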
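## Readers and writers for every on-disk format the pipeline touches.
## Internal convention everywhere: coordinates are 1-based inclusive, a CpG
## site is the cytosine position on its reported strand, and site tables
## are sorted by (scaffold lexicographic, position numeric). BED output
## converts to 0-based half-open at the boundary and nowhere else.

#' Read a Bismark cytosine report
#'
#' Parses the 7-column cytosine-report TSV (chromosome, 1-based position,
#' strand, count methylated, count unmethylated, context, trinucleotide),
#' keeping only rows in the requested context. Gzipped input is accepted.
#'
#' @param path file path.
#' @param context context filter (default "CG").
#' @return data.table with columns scaffold, position, strand, meth,
#'   unmeth.
#' @export
readCytosineReport <- function(path, context = "CG") {
    if (!file.exists(path)) stop("no such file: ", path)
    emptyRec <- data.table::data.table(scaffold = character(0),
        position = integer(0), strand = character(0),
        meth = integer(0), unmeth = integer(0))
    if (file.size(path) == 0L) {
        warning("empty cytosine report: ", path)
        return(emptyRec)
    }
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = c(1, 3, 6, 7)))
    if (nrow(dt) == 0L) {
        warning("empty cytosine report: ", path)
        return(emptyRec)
    }
    if (ncol(dt) != 7L)
        stop("malformed cytosine report (", ncol(dt), " columns, 7 expected): ",
             path)
    data.table::setnames(dt, c("scaffold", "position", "strand", "meth",
                               "unmeth", "context", "tri"))
    bad <- which(!dt$strand %in% c("+", "-"))
    if (length(bad))
        stop("unknown strand symbol '", dt$strand[bad[1L]], "' at line ",
             bad[1L], " of ", path)
    bad <- which(is.na(dt$position) | is.na(dt$meth) | is.na(dt$unmeth) |
                 dt$meth < 0 | dt$unmeth < 0)
    if (length(bad))
        stop("malformed counts/position at line ", bad[1L], " of ", path)
    keep <- dt[["context"]] == context   # plain vector: no NSE capture
    out <- dt[keep, c("scaffold", "position", "strand", "meth", "unmeth")]
    out$position <- as.integer(out$position)
    out$meth <- as.integer(out$meth); out$unmeth <- as.integer(out$unmeth)
    out[]
}

#' Read a Bismark coverage file
#'
#' Parses the 6-column coverage TSV (chrom, start, end, percent
#' methylation, count methylated, count unmethylated). The percentage
#' column is ignored in favour of the counts but cross-checked (warning if
#' it disagrees by more than 0.1). Strand is unknown in this format and
#' reported as "*".
#'
#' @param path file path.
#' @return data.table with columns scaffold, position, strand, meth,
#'   unmeth.
#' @export
readCoverageFile <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    emptyRec <- data.table::data.table(scaffold = character(0),
        position = integer(0), strand = character(0),
        meth = integer(0), unmeth = integer(0))
    if (file.size(path) == 0L) {
        warning("empty coverage file: ", path)
        return(emptyRec)
    }
    dt <- data.table::fread(path, header = FALSE, sep = "\t",
                            colClasses = list(character = 1))
    if (nrow(dt) == 0L) {
        warning("empty coverage file: ", path)
        return(emptyRec)
    }
    if (ncol(dt) != 6L)
        stop("malformed coverage file (", ncol(dt), " columns, 6 expected): ",
             path)
    data.table::setnames(dt, c("scaffold", "start", "end", "pct", "meth",
                               "unmeth"))
    bad <- which(dt$start != dt$end)
    if (length(bad))
        stop("interval record at line ", bad[1L], " of ", path,
             " (start != end; CpG resolution expected)")
    cov <- dt$meth + dt$unmeth
    derived <- ifelse(cov > 0, 100 * dt$meth / cov, 0)
    off <- abs(derived - dt$pct) > 0.1
    if (any(off, na.rm = TRUE))
        warning(sum(off, na.rm = TRUE),
                " records whose % column disagrees with counts in ", path)
    data.table::data.table(scaffold = dt$scaffold,
        position = as.integer(dt$start), strand = "*",
        meth = as.integer(dt$meth), unmeth = as.integer(dt$unmeth))
}

#' Assemble per-replicate call tables into a MethylExperiment
#'
#' Takes one site table per replicate (as returned by
#' \code{\link{readCytosineReport}} or \code{\link{readCoverageFile}}) and
#' a pairing table, and builds the union-of-sites count matrices: a site
#' absent from a replicate gets counts (0, 0).
#'
#' @param records named list of per-replicate data.tables.
#' @param metadata data.frame with columns replicate, mother, treatment
#'   ("NF"/"CR"); rows must match \code{names(records)}.
#' @param paired enforce one NF + one CR per mother (error otherwise).
#' @param collapseStrands sum counts of a forward-strand C at position p
#'   with the reverse-strand C at p+1 into one dinucleotide site at p
#'   (off by default).
#' @return A \linkS4class{MethylExperiment}.
#' @export
assembleMatrix <- function(records, metadata, paired = TRUE,
                           collapseStrands = FALSE) {
    stopifnot(length(records) >= 1L,
              all(c("replicate", "mother", "treatment") %in%
                  colnames(metadata)))
    metadata <- as.data.frame(metadata)
    if (is.null(names(records)))
        names(records) <- metadata$replicate
    if (!setequal(names(records), metadata$replicate))
        stop("records and metadata name different replicates")
    metadata <- metadata[match(names(records), metadata$replicate), ]
    if (!all(c("NF", "CR") %in% metadata$treatment))
        stop("need at least one replicate per treatment")
    if (paired) {
        tab <- table(metadata$mother, metadata$treatment)
        if (!all(tab == 1L))
            stop("pairing error: every mother needs exactly one NF and one ",
                 "CR replicate (got mothers ",
                 paste(rownames(tab)[rowSums(tab != 1L) > 0],
                       collapse = ", "), ")")
    }
    recs <- lapply(records, function(r) {
        r <- data.table::as.data.table(r)
        if (collapseStrands) r <- collapseCpgStrands(r)
        key <- paste(r$scaffold, r$position, r$strand)
        if (anyDuplicated(key))
            stop("duplicate (scaffold, position, strand) within one replicate")
        r
    })
    allSites <- unique(data.table::rbindlist(
        lapply(recs, function(r) r[, c("scaffold", "position", "strand")])))
    data.table::setorder(allSites, scaffold, position)
    key <- paste(allSites$scaffold, allSites$position, allSites$strand)
    n <- nrow(allSites); k <- length(recs)
    meth <- matrix(0L, n, k); unmeth <- matrix(0L, n, k)
    for (j in seq_len(k)) {
        r <- recs[[j]]
        i <- match(paste(r$scaffold, r$position, r$strand), key)
        meth[i, j] <- r$meth
        unmeth[i, j] <- r$unmeth
    }
    sites <- GenomicRanges::GRanges(allSites$scaffold,
        IRanges::IRanges(allSites$position, width = 1L),
        strand = allSites$strand)
    MethylExperiment(sites, meth, unmeth, mother = metadata$mother,
                     treatment = metadata$treatment,
                     replicateNames = metadata$replicate, paired = paired)
}

# sum forward C at p with reverse C at p+1 into one site reported at p(+)
collapseCpgStrands <- function(r) {
    fwd <- r[r$strand %in% c("+", "*"), ]
    rev <- r[r$strand == "-", ]
    if (nrow(rev) == 0L) return(r)
    i <- match(paste(rev$scaffold, rev$position - 1L),
               paste(fwd$scaffold, fwd$position))
    hit <- !is.na(i)
    if (any(hit)) {
        fwd$meth[i[hit]] <- fwd$meth[i[hit]] + rev$meth[hit]
        fwd$unmeth[i[hit]] <- fwd$unmeth[i[hit]] + rev$unmeth[hit]
    }
    orphan <- rev[!hit, ]
    if (nrow(orphan)) {
        orphan$position <- orphan$position - 1L
        orphan$strand <- "+"
        fwd <- rbind(fwd, orphan)
    }
    data.table::setorder(fwd, scaffold, position)
    fwd
}

# per-replicate cytosine report writer (round-trips through
# readCytosineReport)
writeCytosineReport <- function(me, j, path) {
    gr <- SummarizedExperiment::rowRanges(me)
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "+"
    dt <- data.table::data.table(
        scaffold = as.character(GenomicRanges::seqnames(gr)),
        position = GenomicRanges::start(gr),
        strand = st,
        meth = methCounts(me)[, j],
        unmeth = unmethCounts(me)[, j],
        context = "CG", tri = "CGG")
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Read a gene/exon annotation (GFF3 or BED12)
#'
#' GFF3 input must carry \code{gene} features with an ID and \code{exon}
#' features with a Parent; BED12 blocks become exons. Exon indices are
#' assigned in transcription order (genomic order on +, reversed on -)
#' when not provided.
#'
#' @param path annotation file (format by extension).
#' @return list with \code{genes} (GRanges, mcols gene, nExons) and
#'   \code{exons} (GRanges, mcols gene, exonIndex, nExons).
#' @export
readGeneAnnotation <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path)
    if (grepl("\\.bed$", path, ignore.case = TRUE)) {
        genes <- gr
        genes$gene <- if (!is.null(gr$name)) gr$name
                      else sprintf("gene%04d", seq_along(gr))
        if (!is.null(gr$blocks)) {
            bl <- rtracklayer::blocks(gr)
            ex <- unlist(bl, use.names = FALSE)
            S4Vectors::mcols(ex) <- NULL
            ex$gene <- rep(genes$gene, lengths(bl))
        } else {
            ex <- genes
            ex$gene <- genes$gene
        }
    } else {
        genes <- gr[gr$type == "gene"]
        genes$gene <- genes$ID
        ex <- gr[gr$type == "exon"]
        ex$gene <- as.character(S4Vectors::unstrsplit(ex$Parent))
    }
    ## exon index in transcription order
    ord <- order(ex$gene, GenomicRanges::start(ex))
    ex <- ex[ord]
    perGene <- split(seq_along(ex), ex$gene)
    exonIndex <- integer(length(ex))
    nExons <- integer(length(ex))
    for (g in perGene) {
        n <- length(g)
        minus <- as.character(GenomicRanges::strand(ex[g[1L]])) == "-"
        exonIndex[g] <- if (minus) rev(seq_len(n)) else seq_len(n)
        nExons[g] <- n
    }
    ex$exonIndex <- exonIndex
    ex$nExons <- nExons
    genes$nExons <- as.integer(table(ex$gene)[genes$gene])
    list(genes = genes, exons = ex)
}

#' Read SNVs from a VCF
#'
#' Thin wrapper over \code{VariantAnnotation::readVcf} that keeps
#' single-nucleotide biallelic records only (indels and multiallelic
#' records are counted and dropped with a message) and extracts the five
#' GATK hard-filter annotations, NA where missing.
#'
#' @param path VCF file (plain or gzipped).
#' @return GRanges with mcols ref, alt, QD, FS, MQ, MQRankSum,
#'   ReadPosRankSum.
#' @export
readVariants <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(rr$REF)
    altL <- rr$ALT
    nAlt <- lengths(altL)
    alt <- rep(NA_character_, length(rr))
    alt[nAlt == 1L] <- as.character(unlist(altL[nAlt == 1L]))
    keep <- nAlt == 1L & nchar(ref) == 1L & nchar(alt) == 1L &
        ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
    nDropped <- sum(!keep)
    if (nDropped)
        message(nDropped,
                " non-SNV (indel/multiallelic) record(s) ignored in ", path)
    out <- GenomicRanges::granges(rr[keep])
    names(out) <- NULL
    out$ref <- ref[keep]
    out$alt <- alt[keep]
    inf <- VariantAnnotation::info(vcf)
    for (k in c("QD", "FS", "MQ", "MQRankSum", "ReadPosRankSum")) {
        v <- if (k %in% colnames(inf)) as.numeric(inf[[k]][keep])
             else rep(NA_real_, sum(keep))
        S4Vectors::mcols(out)[[k]] <- v
    }
    out
}

#' Write regions to BED or TSV
#'
#' BED6 output converts the internal 1-based inclusive intervals to
#' 0-based half-open starts; score is the region's combined or corrected
#' p-value when present. TSV output mirrors the field's reporting layout:
#' gene, genomic position, DMR coordinates, length (end - start),
#' condition in CR, number of sites, corrected p-value, exon, strand (gene
#' columns are filled when overlap annotations are attached to the input).
#'
#' @param regions GRanges with mcols such as direction, nCpG, meanDiff,
#'   p, q (any may be absent).
#' @param path output file.
#' @param format "BED" or "TSV".
#' @return path, invisibly.
#' @export
writeRegions <- function(regions, path, format = c("BED", "TSV")) {
    format <- match.arg(format)
    mc <- S4Vectors::mcols(regions)
    grab <- function(nm, default) {
        if (nm %in% colnames(mc)) mc[[nm]]
        else rep(default, length(regions))
    }
    if (format == "BED") {
        dt <- data.table::data.table(
            chrom = as.character(GenomicRanges::seqnames(regions)),
            start = GenomicRanges::start(regions) - 1L,   # 0-based half-open
            end = GenomicRanges::end(regions),
            name = sprintf("region%04d", seq_len(max(length(regions), 0L))),
            score = signif(grab("q", 0), 6),
            strand = rep(".", length(regions)))
        if (length(regions) == 0L)
            dt <- dt[0L]
        con <- file(path, "w")
        writeLines(paste0("#chrom\tstart\tend\tname\tscore\tstrand"), con)
        close(con)
        if (nrow(dt))
            data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                               append = TRUE)
    } else {
        dt <- data.table::data.table(
            gene = grab("gene", NA_character_),
            genomicPosition = grab("genePosition", NA_character_),
            DMR = sprintf("%s:%d-%d",
                as.character(GenomicRanges::seqnames(regions)),
                GenomicRanges::start(regions),
                GenomicRanges::end(regions)),
            length = GenomicRanges::end(regions) -
                GenomicRanges::start(regions),
            conditionInCR = grab("direction", NA_character_),
            nSites = grab("nCpG", NA_integer_),
            correctedP = grab("q", NA_real_),
            exon = grab("exon", NA_character_),
            strand = grab("geneStrand", NA_character_),
            meanDiff = grab("meanDiff", NA_real_),
            p = grab("p", NA_real_))
        if (length(regions) == 0L) dt <- dt[0L]
        data.table::fwrite(dt, path, sep = "\t")
    }
    invisible(path)
}

#' Export smoothed tracks as bedGraph
#'
#' One bedGraph per replicate, value = smoothed methylation level.
#'
#' @param me MethylExperiment with a "smooth" assay.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
writeSmoothedBedGraph <- function(me, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    s <- smoothedLevels(me)
    gr <- SummarizedExperiment::rowRanges(me)
    paths <- character(ncol(me))
    for (j in seq_len(ncol(me))) {
        paths[j] <- file.path(dir, paste0(colnames(me)[j], ".smooth.bedGraph"))
        dt <- data.table::data.table(
            chrom = as.character(GenomicRanges::seqnames(gr)),
            start = GenomicRanges::start(gr) - 1L,
            end = GenomicRanges::start(gr),
            value = round(s[, j], 6))
        data.table::fwrite(dt, paths[j], sep = "\t", col.names = FALSE)
    }
    invisible(paths)
}
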
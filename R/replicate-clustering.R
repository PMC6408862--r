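## Replicate clustering by genome-wide methylation: correlation distances,
## Ward.D2 dendrogram, bootstrap support over CpG sites.

#' Correlation-based replicate distances
#'
#' 1 - Pearson correlation of per-CpG methylation proportions, computed
#' pairwise over the sites covered in both replicates (zero-coverage cells
#' are missing, not zero).
#'
#' @param props sites x replicates matrix of methylation proportions with
#'   NA at uncovered cells (e.g. \code{methLevel(me)}).
#' @return symmetric distance matrix (zero diagonal, entries in [0,2]).
#' @export
correlationDistance <- function(props) {
    sds <- apply(props, 2, stats::sd, na.rm = TRUE)
    if (any(is.na(sds) | sds == 0))
        stop("zero-variance replicate(s): ",
             paste(colnames(props)[which(is.na(sds) | sds == 0)],
                   collapse = ", "))
    d <- 1 - stats::cor(props, use = "pairwise.complete.obs")
    diag(d) <- 0
    d
}

#' Ward.D2 dendrogram of replicates
#'
#' Agglomerative clustering with the Ward.D2 criterion (squared-distance
#' Lance-Williams update on unsquared input distances), as implemented by
#' \code{stats::hclust}.
#'
#' @param distances symmetric distance matrix or \code{dist}.
#' @return an \code{hclust} tree.
#' @export
wardD2Tree <- function(distances) {
    if (!inherits(distances, "dist")) distances <- stats::as.dist(distances)
    stats::hclust(distances, method = "ward.D2")
}

#' Bootstrap support for the replicate dendrogram
#'
#' Resamples CpG sites with replacement, rebuilds the Ward.D2 tree from
#' correlation distances on each resample, and scores every internal node
#' of the original tree by the fraction of bootstrap trees containing the
#' same leaf bipartition (bootstrap probability, BP). Input site order
#' does not affect the result: resampling happens on a canonical
#' (row-index) ordering of the matrix rows.
#'
#' @param props sites x replicates proportion matrix (NA = missing).
#' @param nBoot number of bootstrap resamples (the reference analysis used
#'   10,000; 500 suffices for well-separated structure).
#' @param seed RNG seed.
#' @return object of class \code{supportedDendrogram}: list with
#'   \code{hclust}, \code{phylo}, \code{bp} (named by internal node, root
#'   first), \code{nBoot}.
#' @export
bootstrapSupport <- function(props, nBoot = 500L, seed = 1L) {
    stopifnot(nBoot >= 1L)
    ref <- wardD2Tree(correlationDistance(props))
    refPhylo <- ape::as.phylo(ref)
    ## canonical row ordering (lexicographic by content) so the resampling
    ## stream, and therefore BP, is invariant to input site order
    props <- props[do.call(order,
        as.data.frame(unname(cbind(props)))), , drop = FALSE]
    set.seed(seed)
    n <- nrow(props)
    boots <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
        i <- sample.int(n, n, replace = TRUE)
        db <- tryCatch(correlationDistance(props[i, , drop = FALSE]),
                       error = function(e) NULL)
        if (is.null(db)) { boots[[b]] <- NA; next }
        boots[[b]] <- ape::as.phylo(wardD2Tree(db))
    }
    ok <- !vapply(boots, function(x) is.logical(x) && is.na(x[1L]),
                  logical(1))
    counts <- ape::prop.clades(refPhylo, boots[ok], rooted = FALSE)
    counts[is.na(counts)] <- 0L
    bp <- counts / sum(ok)
    structure(list(hclust = ref, phylo = refPhylo, bp = bp,
                   nBoot = as.integer(nBoot), nUsed = sum(ok)),
              class = "supportedDendrogram")
}

#' @export
print.supportedDendrogram <- function(x, ...) {
    cat("Ward.D2 replicate dendrogram,", length(x$phylo$tip.label),
        "replicates\n")
    cat("bootstrap support over", x$nUsed, "of", x$nBoot, "resamples:\n")
    print(round(x$bp, 3))
    invisible(x)
}

#' Bootstrap probability of each mother pair forming a cherry
#'
#' Convenience check of the mother-over-treatment structure: for every
#' mother id, the BP of the bipartition separating that mother's NF/CR
#' pair from all other replicates. Tip labels must follow the
#' \code{"M<mother>_<treatment>"} convention of the package constructors.
#'
#' @param sd a \code{supportedDendrogram}.
#' @return named numeric, BP per mother; NA when the pair is not a clade
#'   of the reference tree.
#' @export
motherPairSupport <- function(sd) {
    tips <- sd$phylo$tip.label
    mo <- sub("^M([0-9]+)_.*$", "\\1", tips)
    bp <- numeric(0)
    for (k in sort(unique(as.integer(mo)))) {
        pair <- which(mo == as.character(k))
        if (length(pair) != 2L) next
        node <- ape::getMRCA(sd$phylo, pair)
        desc <- unlist(ape::prop.part(sd$phylo)[node -
            length(tips)])
        if (length(desc) == 2L && setequal(desc, pair)) {
            bp[as.character(k)] <- sd$bp[node - length(tips)]
        } else {
            bp[as.character(k)] <- NA_real_
        }
    }
    bp
}

#' Export a supported dendrogram as Newick
#'
#' Internal nodes are labelled with their BP values.
#'
#' @param sd a \code{supportedDendrogram}.
#' @param path output file.
#' @return path, invisibly.
#' @export
writeNewick <- function(sd, path) {
    phy <- sd$phylo
    phy$node.label <- formatC(sd$bp, digits = 3, format = "f")
    ape::write.tree(phy, file = path)
    invisible(path)
}
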
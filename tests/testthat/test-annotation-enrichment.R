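# toy annotation: gene A (+, 3 exons), gene B (-, 2 exons)
toyAnnotation <- function() {
    genes <- GenomicRanges::GRanges("sc1",
        IRanges::IRanges(c(1000, 5000), c(2999, 6499)),
        strand = c("+", "-"))
    genes$gene <- c("geneA", "geneB")
    genes$nExons <- c(3L, 2L)
    exons <- GenomicRanges::GRanges("sc1",
        IRanges::IRanges(c(1000, 1800, 2600, 5000, 6000),
                         c(1199, 1999, 2999, 5399, 6499)),
        strand = c("+", "+", "+", "-", "-"))
    exons$gene <- c("geneA", "geneA", "geneA", "geneB", "geneB")
    exons$exonIndex <- c(1L, 2L, 3L, 2L, 1L)  # transcription order
    exons$nExons <- c(3L, 3L, 3L, 2L, 2L)
    list(genes = genes, exons = exons)
}

test_that("DMR-gene overlap classes and exon hits are correct", {
    ann <- toyAnnotation()
    dmrs <- GenomicRanges::GRanges("sc1", IRanges::IRanges(
        c(1850, 1900, 3500, 5100),
        c(1950, 2700, 3600, 5300)))
    dmrs$direction <- c("hyper", "hypo", "hyper", "hypo")
    ov <- overlapDmrsGenes(dmrs, ann)$overlaps
    ## DMR 1 inside exon 2 of geneA
    expect_equal(ov$class[ov$dmr == 1L], "exonic")
    expect_equal(ov$exon[ov$dmr == 1L], "2 of 3")
    ## DMR 2 spans exon/intron boundary -> mixed
    expect_equal(ov$class[ov$dmr == 2L], "mixed")
    ## DMR 3 is intergenic -> no record
    expect_false(3L %in% ov$dmr)
    ## DMR 4 hits the genomically-first exon of minus-strand geneB,
    ## which is exon 2 in transcription order
    expect_equal(ov$exon[ov$dmr == 4L], "2 of 2")
    expect_equal(ov$geneStrand[ov$dmr == 4L], "-")
    ## non-redundant gene sets per direction
    gs <- overlapDmrsGenes(dmrs, ann)$geneSets
    expect_equal(gs$hyper, "geneA")
    expect_setequal(gs$hypo, c("geneA", "geneB"))
})

test_that("a DMR within an intron is classed intronic", {
    ann <- toyAnnotation()
    d <- GenomicRanges::GRanges("sc1", IRanges::IRanges(2100, 2300))
    d$direction <- "hyper"
    ov <- overlapDmrsGenes(d, ann)$overlaps
    expect_equal(ov$class, "intronic")
    expect_true(is.na(ov$exon))
})

test_that("gene universes nest by methylated-CpG count", {
    ann <- toyAnnotation()
    ## 4 CpGs: two methylated in geneA, none in geneB, one intergenic
    gr <- GenomicRanges::GRanges("sc1",
        IRanges::IRanges(c(1100, 1850, 5100, 4000), width = 1L),
        strand = "+")
    meth <- matrix(c(2L, 1L, 0L, 5L), 4L, 2L)
    unmeth <- matrix(5L, 4L, 2L)
    me <- MethylExperiment(gr, meth, unmeth, mother = c(1L, 1L),
                           treatment = c("NF", "CR"))
    u <- buildUniverses(me, ann, thresholds = c(1L, 3L))
    expect_setequal(u$all, c("geneA", "geneB"))
    expect_equal(u$geq1, "geneA")         # 2 methylated CpGs
    expect_equal(u$geq3, character(0))
    expect_true(all(u$geq3 %in% u$geq1) && all(u$geq1 %in% u$all))
})

test_that("annotations propagate to every ancestor term", {
    parents <- data.frame(
        term = c("T2", "T3", "T4", "T5"),
        parent = c("T1", "T1", "T2", "T4"),
        namespace = "BP")
    goMap <- data.frame(gene = c("g1", "g2"), term = c("T5", "T3"))
    ann <- propagateAnnotations(goMap, parents)
    expect_setequal(ann$T5, "g1")
    expect_setequal(ann$T4, "g1")
    expect_setequal(ann$T2, "g1")
    expect_setequal(ann$T1, c("g1", "g2"))
    expect_setequal(ann$T3, "g2")
})

test_that("classic enrichment matches an explicit hypergeometric sum", {
    ## universe of 100 genes, 10 with the term; interest 10, 5 with it
    universe <- sprintf("g%03d", 1:100)
    withTerm <- universe[1:10]
    interest <- c(universe[1:5], universe[90:94])
    goMap <- data.frame(gene = withTerm, term = "T1")
    parents <- data.frame(term = "T1", parent = "root",
                          namespace = "MF")
    res <- fisherEnrichment(interest, universe, goMap, parents,
                            algorithm = "classic")
    ## enumeration oracle: P(X >= 5), X ~ Hypergeom(N=100, K=10, n=10)
    oracle <- sum(vapply(5:10, function(k)
        choose(10, k) * choose(90, 10 - k) / choose(100, 10),
        numeric(1)))
    r1 <- res[res$term == "T1", ]
    expect_equal(r1$p, oracle, tolerance = 1e-12)
    expect_equal(oracle, 1.6e-3, tolerance = 0.05)
    expect_equal(r1$interestWithTerm, 5L)
    expect_equal(r1$universeWithTerm, 10L)
    expect_true(r1$significant)

    ## interest = universe -> every p = 1
    resAll <- fisherEnrichment(universe, universe, goMap, parents,
                               algorithm = "classic")
    expect_true(all(resAll$p == 1))

    ## invariance to gene relabelling
    relab <- setNames(sprintf("x%03d", 1:100), universe)
    res2 <- fisherEnrichment(unname(relab[interest]),
        unname(relab[universe]),
        data.frame(gene = unname(relab[withTerm]), term = "T1"),
        parents, algorithm = "classic")
    expect_equal(res2$p, res$p)
})

test_that("elim removes significant children and otherwise equals classic", {
    universe <- sprintf("g%02d", 1:40)
    ## child term T2 strongly enriched; parent T1 only via T2's genes
    goMap <- data.frame(gene = universe[1:6], term = "T2")
    parents <- data.frame(term = "T2", parent = "T1", namespace = "BP")
    interest <- universe[1:6]
    classic <- fisherEnrichment(interest, universe, goMap, parents,
                                algorithm = "classic", alpha = 0.01)
    elim <- fisherEnrichment(interest, universe, goMap, parents,
                             algorithm = "elim", alpha = 0.01)
    ## classic flags both T2 and its ancestor; elim only the child
    expect_true(classic$significant[classic$term == "T1"])
    expect_true(elim$significant[elim$term == "T2"])
    expect_false(elim$significant[elim$term == "T1"])

    ## with no significant children, elim equals classic
    goMap2 <- data.frame(gene = universe[1:6], term = "T2")
    interest2 <- universe[c(1L, 20L, 30L)]      # weak overlap
    c2 <- fisherEnrichment(interest2, universe, goMap2, parents,
                           algorithm = "classic")
    e2 <- fisherEnrichment(interest2, universe, goMap2, parents,
                           algorithm = "elim")
    expect_equal(e2$p, c2$p)
})
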
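test_that("genome model respects bounds and is deterministic", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 10000L,
                            nGenes = 1L, exonsPerGene = c(2L, 3L),
                            cpgDensity = 20, nDmrs = 0L,
                            nSnps = 0L, seed = 3L)
    g <- buildGenomeModel(cfg)
    pos <- GenomicRanges::start(g$cpgs)
    expect_true(abs(length(pos) - 200L) <= 1L)
    expect_true(all(pos >= 1L & pos <= 10000L))
    expect_true(all(diff(pos) > 0L))            # strictly increasing
    expect_true(all(GenomicRanges::start(g$exons) >=
        rep(GenomicRanges::start(g$genes),
            table(g$exons$gene)[g$genes$gene])))

    g2 <- buildGenomeModel(cfg)
    expect_identical(GenomicRanges::start(g2$cpgs), pos)

    tooSmall <- simulationConfig(nScaffolds = 1L, scaffoldLength = 3000L,
                                 nGenes = 10L, seed = 3L)
    expect_error(buildGenomeModel(tooSmall), "too short")
})

test_that("with no methylated fraction the background mixture dominates", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 200000L,
        fracMethylatedSites = 0, nDmrs = 0L, nGenes = 10L, nSnps = 0L,
        seed = 9L)
    truth <- plantDmrs(buildGenomeModel(cfg), cfg)
    lowMean <- cfg@lowBetaParams[1] /
        (cfg@lowBetaParams[1] + cfg@lowBetaParams[2])
    expect_true(all(is.na(truth@genome$cpgs$clusterId)))
    expect_lt(abs(mean(truth@baseLevel) - lowMean), 0.002)
    expect_lt(mean(truth@baseLevel), 0.01)      # global under 1%
})

test_that("planted effects are additive on the proportion scale and clipped", {
    cfg <- tinyConfig(motherSd = 0, dmrEffect = c(0.2, 0.2),
                      conversionFailureRate = 0, nSnps = 0L)
    sim <- simulateDataset(cfg, readLevel = FALSE)
    truth <- sim$truth
    tr <- treatment(sim$me)
    b <- pmin(pmax(truth@baseLevel, 1e-6), 1 - 1e-6)
    for (d in seq_along(truth@dmrs)) {
        i <- truth@dmrs$members[[d]]
        sgn <- if (truth@dmrs$direction[d] == "hyper") 1 else -1
        expect_equal(truth@trueLevel[i, tr == "CR"],
                     matrix(pmin(pmax(b[i] + sgn * 0.2, 0), 1),
                            length(i), sum(tr == "CR")),
                     ignore_attr = TRUE, tolerance = 1e-12)
        expect_equal(truth@trueLevel[i, tr == "NF"],
                     matrix(b[i], length(i), sum(tr == "NF")),
                     ignore_attr = TRUE, tolerance = 1e-12)
    }
    ## explicit clipping: a high-baseline hyper site saturates at 1
    hyper <- truth@dmrs[truth@dmrs$direction == "hyper"]
    if (length(hyper)) {
        i <- unlist(hyper$members)
        sat <- b[i] >= 0.8
        if (any(sat))
            expect_true(all(truth@trueLevel[i[sat], tr == "CR"] == 1))
    }
    expect_true(all(truth@trueLevel >= 0 & truth@trueLevel <= 1))
})

test_that("no planted DMRs means identical arm means and empty truth", {
    cfg <- tinyConfig(nDmrs = 0L, motherSd = 0, nSnps = 0L)
    sim <- simulateDataset(cfg, readLevel = FALSE)
    expect_equal(length(sim$truth@dmrs), 0L)
    tr <- treatment(sim$me)
    expect_equal(sim$truth@trueLevel[, tr == "CR"],
                 sim$truth@trueLevel[, tr == "NF"], ignore_attr = TRUE)
})

test_that("coverage model hits its mean and the matrix dimensions fit", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 100000L,
        nGenes = 8L, coverageMean = 10, nDmrs = 0L, nSnps = 0L, seed = 4L)
    sim <- simulateDataset(cfg, readLevel = FALSE)   # ~2000 sites x 12
    expect_equal(ncol(sim$me), 12L)
    expect_lt(abs(mean(methCoverage(sim$me)) - 10), 0.5)
})

test_that("mother effects induce pair-dominant correlation", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 200000L,
        nGenes = 15L, motherSd = 2, nDmrs = 0L, nSnps = 0L, seed = 7L)
    sim <- simulateDataset(cfg, readLevel = FALSE)
    lv <- methLevel(sim$me)
    cc <- stats::cor(lv, use = "pairwise.complete.obs")
    mo <- mother(sim$me); tr <- treatment(sim$me)
    within <- mapply(function(k)
        cc[which(mo == k & tr == "NF"), which(mo == k & tr == "CR")],
        unique(mo))
    across <- c()
    for (t1 in c("NF", "CR")) {
        i <- which(tr == t1)
        m <- cc[i, i]
        across <- c(across, m[upper.tri(m)])
    }
    expect_gt(mean(within), mean(across))
})

test_that("conversion failure drives methylated non-CpG calls", {
    cfg <- tinyConfig(conversionFailureRate = 0)
    sim <- simulateDataset(cfg, readLevel = TRUE)
    expect_false(any(grepl("[HX]", sim$reads$call)))

    cfg2 <- tinyConfig(conversionFailureRate = 0.05)
    sim2 <- simulateDataset(cfg2, readLevel = TRUE)
    expect_true(any(grepl("[HX]", sim2$reads$call)))
    ## unconverted reads call every cytosine methylated, incl. the CpG
    unconv <- grepl("[HX]", sim2$reads$call)
    expect_true(all(grepl("Z", sim2$reads$call[unconv])))
})

test_that("emitted dataset round-trips and truth files are consistent", {
    cfg <- tinyConfig()
    d <- file.path(tempdir(), "simrt")
    sim <- simulateDataset(cfg, dir = d, readLevel = FALSE)
    meta <- data.frame(replicate = colnames(sim$me),
                       mother = mother(sim$me),
                       treatment = treatment(sim$me))
    recs <- lapply(meta$replicate, function(n)
        readCytosineReport(file.path(d, paste0(n, ".CpG_report.txt"))))
    names(recs) <- meta$replicate
    me2 <- assembleMatrix(recs, meta)
    expect_identical(unname(methCounts(me2)), unname(methCounts(sim$me)))
    expect_identical(unname(unmethCounts(me2)),
                     unname(unmethCounts(sim$me)))

    ## truth BED has one record per planted DMR
    bed <- readLines(file.path(d, "truth_dmrs.bed"))
    expect_equal(length(bed) - 1L, length(sim$truth@dmrs))

    ## every planted SNP appears in the VCF at its position
    v <- suppressMessages(readVariants(file.path(d, "snps.vcf")))
    expect_equal(length(v), length(sim$truth@snps))
    expect_setequal(GenomicRanges::start(v),
                    GenomicRanges::start(sim$truth@snps))

    ## annotation round-trips with transcription-order exon indices
    ann <- readGeneAnnotation(file.path(d, "genes.gff3"))
    expect_setequal(ann$genes$gene, sim$truth@genome$genes$gene)
    o1 <- order(ann$exons$gene, GenomicRanges::start(ann$exons))
    o2 <- order(sim$truth@genome$exons$gene,
                GenomicRanges::start(sim$truth@genome$exons))
    expect_equal(ann$exons$exonIndex[o1],
                 sim$truth@genome$exons$exonIndex[o2])

    ## byte-identical re-emission under the same config + seed
    d2 <- file.path(tempdir(), "simrt2")
    simulateDataset(cfg, dir = d2, readLevel = FALSE)
    f <- paste0(meta$replicate[1L], ".CpG_report.txt")
    expect_identical(readLines(file.path(d, f)),
                     readLines(file.path(d2, f)))
    expect_identical(readLines(file.path(d, "truth_dmrs.tsv")),
                     readLines(file.path(d2, "truth_dmrs.tsv")))
})

test_that("emitted global methylation matches the analytic mixture", {
    cfg <- simulationConfig(nDmrs = 0L, nSnps = 0L, seed = 13L)  # 2e4 CpGs
    sim <- simulateDataset(cfg, readLevel = FALSE)
    cp <- sim$truth@genome$cpgs
    nHigh <- sum(!is.na(cp$clusterId)); nTot <- length(cp)
    muHigh <- cfg@highBetaParams[1] / sum(cfg@highBetaParams)
    muLow <- cfg@lowBetaParams[1] / sum(cfg@lowBetaParams)
    mu <- (nHigh * muHigh + (nTot - nHigh) * muLow) / nTot
    f <- cfg@conversionFailureRate
    expected <- 100 * (mu + f * (1 - mu))       # unconverted reads inflate
    observed <- 100 * sum(methCounts(sim$me)) / sum(methCoverage(sim$me))
    expect_lt(abs(observed - expected), 0.2)
})

test_that("with no effects the paired design is exchangeable", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 100000L,
        nGenes = 8L, nDmrs = 0L, motherSd = 0, nSnps = 0L, seed = 17L)
    sim <- simulateDataset(cfg, readLevel = FALSE)
    lv <- methLevel(sim$me)
    mo <- mother(sim$me); tr <- treatment(sim$me)
    cr <- vapply(sort(unique(mo)), function(k)
        which(mo == k & tr == "CR"), integer(1))
    nf <- vapply(sort(unique(mo)), function(k)
        which(mo == k & tr == "NF"), integer(1))
    d <- lv[, cr] - lv[, nf]
    ok <- rowSums(is.na(d)) == 0 & rowSums(abs(d), na.rm = TRUE) > 0
    d <- d[ok, ][seq_len(500L), ]
    ## exact sign-flip permutation p per site; under exchangeability the
    ## rejection rate at alpha stays within alpha + 3 SE
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 6L)))
    obs <- abs(rowSums(d))
    perm <- abs(d %*% t(signs))
    p <- rowMeans(perm >= obs - 1e-12)
    alpha <- 0.05
    rate <- mean(p <= alpha)
    expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / nrow(d)))
})

test_that("infeasible DMR placement errors with the constraint named", {
    cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 30000L,
        nGenes = 2L, nDmrs = 50L, dmrWidth = c(10L, 12L), seed = 1L)
    expect_error(plantDmrs(buildGenomeModel(cfg), cfg), "exonic CpG runs")
})
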
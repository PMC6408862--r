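test_that("non-conversion filter drops reads with methylated CHH/CHG calls", {
    reads <- data.table::data.table(
        read_id = c("r1", "r2", "r3"),
        replicate = "a", scaffold = "sc1", pos = c(10L, 20L, 30L),
        call = c("zZz", "zHx", "Zhx"))
    fl <- filterNonconvertedReads(reads)
    expect_setequal(fl$reads$read_id, c("r1", "r3"))   # "zHx" removed

    bad <- data.table::data.table(read_id = "rX", replicate = "a",
        scaffold = "sc1", pos = 1L, call = "zQ")
    expect_error(filterNonconvertedReads(bad), "rX")
})

test_that("conversion report computes efficiency from non-CpG calls", {
    ## 100 reads; 97 converted reads with one unmethylated h each; 3
    ## unconverted reads with one methylated H each -> non-CpG 3%
    ## methylated, conversion efficiency 97%
    reads <- data.table::data.table(
        read_id = sprintf("r%03d", 1:100), replicate = "a",
        scaffold = "sc1", pos = seq_len(100L),
        call = c(rep("zh", 97L), rep("ZH", 3L)))
    fl <- filterNonconvertedReads(reads)
    expect_equal(fl$report$nRemoved, 3L)
    expect_equal(fl$report$pctRemoved, 3)
    expect_equal(fl$report$nonCpgPctMeth, 3)
    expect_equal(fl$report$conversionEfficiency, 97)
})

test_that("hard filters follow the GATK exclusion bounds", {
    mk <- function(QD = NA, FS = NA, MQ = NA, MQRankSum = NA,
                   ReadPosRankSum = NA) {
        gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(100, 100))
        gr$ref <- "C"; gr$alt <- "T"
        gr$QD <- QD; gr$FS <- FS; gr$MQ <- MQ
        gr$MQRankSum <- MQRankSum; gr$ReadPosRankSum <- ReadPosRankSum
        gr
    }
    pass <- mk(30, 10, 60, 0, 0)
    expect_equal(length(hardFilterVariants(pass)), 1L)
    expect_equal(length(hardFilterVariants(mk(1.5, 10, 60, 0, 0))), 0L)
    expect_equal(length(hardFilterVariants(mk(30, 70, 60, 0, 0))), 0L)
    expect_equal(length(hardFilterVariants(mk(30, 10, 30, 0, 0))), 0L)
    expect_equal(length(hardFilterVariants(mk(30, 10, 60, -13, 0))), 0L)
    expect_equal(length(hardFilterVariants(mk(30, 10, 60, 0, -9))), 0L)
    ## missing annotations pass (logged), unless strict
    allNa <- mk()
    expect_message(out <- hardFilterVariants(allNa), "no hard-filter")
    expect_equal(length(out), 1L)
    expect_equal(length(hardFilterVariants(allNa, strict = TRUE)), 0L)
})

test_that("polymorphic CpG masking handles both strands of the dinucleotide", {
    me <- toyMe(nSites = 4L, positions = c(100L, 200L, 300L, 400L))
    mkv <- function(pos, ref, alt) {
        gr <- GenomicRanges::GRanges("sc1", IRanges::IRanges(pos, pos))
        gr$ref <- ref; gr$alt <- alt
        gr$QD <- 30; gr$FS <- 1; gr$MQ <- 60
        gr$MQRankSum <- 0; gr$ReadPosRankSum <- 0
        gr
    }
    v <- c(mkv(100L, "C", "T"),     # C/T on the C -> mask site 100
           mkv(201L, "G", "A"),     # G/A on the G -> mask site 200
           mkv(350L, "A", "G"))     # elsewhere -> no effect
    msk <- maskPolymorphicCpgs(me, v)
    expect_equal(msk$nRemoved, 2L)
    expect_equal(GenomicRanges::start(
        SummarizedExperiment::rowRanges(msk$me)), c(300L, 400L))

    mskNoG <- maskPolymorphicCpgs(me, v, gMask = FALSE)
    expect_equal(mskNoG$nRemoved, 1L)
    expect_equal(GenomicRanges::start(
        SummarizedExperiment::rowRanges(mskNoG$me)), c(200L, 300L, 400L))
})

test_that("coverage rule needs two deep replicates in each arm", {
    ## 6 pairs: NF coverages [6,6,2,0,3,1], CR [7,9,0,0,0,0] -> kept
    covNF <- c(6, 6, 2, 0, 3, 1); covCR <- c(7, 9, 0, 0, 0, 0)
    cov <- as.integer(c(rbind(covNF, covCR)))
    me <- MethylExperiment(
        GenomicRanges::GRanges("sc1", IRanges::IRanges(100, 100), "+"),
        meth = matrix(0L, 1L, 12L), unmeth = matrix(cov, 1L),
        mother = rep(1:6, each = 2L), treatment = rep(c("NF", "CR"), 6L))
    expect_equal(nrow(applyCoverageRule(me)), 1L)

    covNF2 <- c(6, 5, 5, 5, 5, 5); covCR2 <- c(9, 9, 9, 9, 9, 9)
    me2 <- MethylExperiment(
        SummarizedExperiment::rowRanges(me), matrix(0L, 1L, 12L),
        matrix(as.integer(c(rbind(covNF2, covCR2))), 1L),
        mother = rep(1:6, each = 2L), treatment = rep(c("NF", "CR"), 6L))
    expect_equal(nrow(applyCoverageRule(me2)), 0L)  # one deep NF only

    me3 <- MethylExperiment(
        SummarizedExperiment::rowRanges(me), matrix(0L, 1L, 12L),
        matrix(0L, 1L, 12L),
        mother = rep(1:6, each = 2L), treatment = rep(c("NF", "CR"), 6L))
    expect_equal(nrow(applyCoverageRule(me3)), 0L)
})

test_that("masking and the coverage rule commute", {
    cfg <- tinyConfig()
    sim <- simulateDataset(cfg, readLevel = FALSE)
    v <- suppressMessages(hardFilterVariants(sim$truth@snps))
    a <- applyCoverageRule(maskPolymorphicCpgs(sim$me, v)$me)
    b <- maskPolymorphicCpgs(applyCoverageRule(sim$me), v)$me
    expect_identical(unname(methCounts(a)), unname(methCounts(b)))
    expect_equal(GenomicRanges::start(SummarizedExperiment::rowRanges(a)),
                 GenomicRanges::start(SummarizedExperiment::rowRanges(b)))
})

test_that("masking removes exactly the planted-SNP CpGs", {
    cfg <- tinyConfig()
    sim <- simulateDataset(cfg, readLevel = FALSE)
    v <- hardFilterVariants(sim$truth@snps)
    msk <- maskPolymorphicCpgs(sim$me, v)
    gone <- setdiff(
        GenomicRanges::start(SummarizedExperiment::rowRanges(sim$me)),
        GenomicRanges::start(SummarizedExperiment::rowRanges(msk$me)))
    expect_setequal(gone, sim$truth@snps$cpgPos)
})

test_that("global methylation summary matches the closed-form paired t", {
    ## per-1000-call percentages chosen to give differences (in %)
    ## d = 0.1, 0.2, 0.15, 0.05, 0.1, 0.1
    nfMeth <- rep(20L, 6L)
    crMeth <- c(22L, 24L, 23L, 21L, 22L, 22L)
    meth <- matrix(as.integer(c(rbind(nfMeth, crMeth))), 1L)
    unmeth <- matrix(2000L, 1L, 12L) - meth
    me <- MethylExperiment(
        GenomicRanges::GRanges("sc1", IRanges::IRanges(100, 100), "+"),
        meth, unmeth, mother = rep(1:6, each = 2L),
        treatment = rep(c("NF", "CR"), 6L))
    g <- globalMethylation(me)
    expect_equal(g$perReplicate$globalPct[1L], 1)   # 20 of 2000 calls
    d <- c(0.1, 0.2, 0.15, 0.05, 0.1, 0.1)
    tOracle <- mean(d) / (stats::sd(d) / sqrt(6))
    expect_equal(g$t, tOracle, tolerance = 1e-10)
    expect_equal(g$t, 5.534, tolerance = 1e-3)
    expect_equal(g$p, 2 * stats::pt(-tOracle, 5), tolerance = 1e-10)
    expect_equal(g$p, 0.0026, tolerance = 0.05)
    expect_equal(g$df, 5L)

    ## all differences zero -> p = 1
    me0 <- MethylExperiment(
        SummarizedExperiment::rowRanges(me),
        matrix(7L, 1L, 12L), matrix(993L, 1L, 12L),
        mother = rep(1:6, each = 2L), treatment = rep(c("NF", "CR"), 6L))
    g0 <- globalMethylation(me0)
    expect_equal(g0$perReplicate$globalPct[1L], 0.7)  # 7 of 1000
    expect_equal(g0$p, 1)
})

test_that("conversion filtering improves the global estimate monotonically", {
    for (s in c(31L, 32L)) {
        cfg <- simulationConfig(nScaffolds = 1L, scaffoldLength = 150000L,
            nGenes = 10L, nDmrs = 0L, nSnps = 0L,
            conversionFailureRate = 0.03, seed = s)
        sim <- simulateDataset(cfg, readLevel = TRUE)
        truth <- 100 * mean(sim$truth@trueLevel)
        pre <- 100 * sum(methCounts(sim$me)) / sum(methCoverage(sim$me))
        fl <- filterNonconvertedReads(sim$reads)
        meta <- data.frame(replicate = colnames(sim$me),
            mother = mother(sim$me), treatment = treatment(sim$me))
        post <- callMatrixFromReads(fl$reads, meta,
            sites = SummarizedExperiment::rowRanges(sim$me))
        postPct <- 100 * sum(methCounts(post)) / sum(methCoverage(post))
        expect_lt(abs(postPct - truth), abs(pre - truth))
    }
})
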
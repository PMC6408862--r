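test_that("per-CpG paired t matches the closed form and handles ties", {
    ## site 1 carries differences d; background sites carry tiny sds so
    ## the variance floor stays below the sample sd of d
    d <- c(0.1, 0.2, 0.15, 0.05, 0.1, 0.1)
    n <- 30L
    sm <- matrix(0.5, n, 12L)
    smNF <- sm; smCR <- sm
    smCR[1L, ] <- 0.5 + 0   # placeholder
    me <- toyMe(nSites = n, nPairs = 6L,
        meth = matrix(5L, n, 12L), unmeth = matrix(5L, n, 12L),
        positions = seq(100L, by = 50L, length.out = n))
    tr <- treatment(me); mo <- mother(me)
    smooth <- matrix(0.5, n, 12L)
    set.seed(5)
    smooth[2:n, ] <- 0.5 + matrix(rnorm((n - 1L) * 12L, 0, 1e-4),
                                  n - 1L)
    for (k in 1:6) smooth[1L, which(mo == k & tr == "CR")] <- 0.5 + d[k]
    me <- withSmooth(me, smooth)
    st <- pairedTStats(me, floorQuantile = 0.75)
    tOracle <- mean(d) / (sd(d) / sqrt(6))
    expect_equal(st$t[1L], tOracle, tolerance = 1e-10)
    expect_equal(st$t[1L], 5.534, tolerance = 1e-3)
    expect_equal(st$p[1L], 2 * pt(-tOracle, 5), tolerance = 1e-10)
    expect_equal(st$df[1L], 5L)
    expect_equal(st$meanDiff[1L], mean(d))

    ## all differences zero at a site with a zero floor -> t = 0, p = 1
    meZero <- withSmooth(me, matrix(0.5, n, 12L))
    stZero <- pairedTStats(meZero)
    expect_true(all(stZero$t == 0))
    expect_true(all(stZero$p == 1))
})

test_that("swapping treatment labels negates every t", {
    cfg <- tinyConfig()
    sim <- simulateDataset(cfg, readLevel = FALSE)
    me <- smoothMatrix(sim$me, smootherConfig(5L, 100))
    st <- pairedTStats(me)
    trSwap <- ifelse(treatment(me) == "NF", "CR", "NF")
    meSwap <- MethylExperiment(
        SummarizedExperiment::rowRanges(me),
        methCounts(me), unmethCounts(me),
        mother = mother(me), treatment = trSwap)
    meSwap <- withSmooth(meSwap, smoothedLevels(me))
    stSwap <- pairedTStats(meSwap)
    expect_equal(stSwap$t, -st$t, tolerance = 1e-12)
    expect_equal(stSwap$p, st$p, tolerance = 1e-12)
})

test_that("q-value conversion follows BH step-up, Storey scales by pi0", {
    expect_equal(pToQ(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4L))
    expect_equal(pToQ(rep(0.05, 7L)), rep(0.05, 7L))
    p <- c(0.001, 0.02, 0.04, 0.8)
    expect_equal(pToQ(p), c(0.004, 0.04, 0.04 * 4 / 3, 0.8))
    ## Storey with pi0 = 1 is exactly BH
    set.seed(6); pr <- runif(200)
    expect_equal(pToQ(pr, "storey", pi0 = 1), pToQ(pr))
    ## estimated pi0 is in (0, 1] and shrinks q
    expect_true(all(pToQ(pr, "storey") <= pToQ(pr) + 1e-12))
    expect_error(pToQ(c(0.1, NA)), "NA")
})

test_that("candidate regions follow run, sign, gap and scaffold breaks", {
    mkStats <- function(pos, t, scaffold = "sc1")
        data.frame(scaffold = scaffold, position = pos,
                   meanDiff = sign(t) * 0.2, sd = 0.05, t = t, df = 5L,
                   p = 2 * pt(-abs(t), 5),
                   q = 2 * pt(-abs(t), 5))
    ## single run of three
    r1 <- findCandidateRegions(mkStats(c(100L, 150L, 200L), c(5, 5, 5)))
    expect_equal(length(r1), 1L)
    expect_equal(r1$nCpG, 3L)
    expect_equal(GenomicRanges::start(r1), 100L)
    expect_equal(GenomicRanges::end(r1), 200L)
    expect_equal(r1$direction, "hyper")

    ## gap over 300 bp breaks the run
    r2 <- findCandidateRegions(mkStats(c(100L, 150L, 200L, 600L),
                                       c(5, 5, 5, 5)))
    expect_equal(length(r2), 2L)
    expect_equal(GenomicRanges::end(r2), c(200L, 600L))
    expect_equal(r2$nCpG, c(3L, 1L))

    ## sign change breaks the run
    r3 <- findCandidateRegions(mkStats(c(100L, 150L, 200L), c(5, -5, 5)))
    expect_equal(length(r3), 3L)
    expect_equal(r3$direction, c("hyper", "hypo", "hyper"))

    ## sub-threshold site breaks the run; |t| must exceed the cutoff
    r4 <- findCandidateRegions(mkStats(c(100L, 150L, 200L),
                                       c(5, 4.6, 5)))
    expect_equal(length(r4), 2L)

    ## scaffold change breaks the run even at small positional gaps
    st5 <- rbind(mkStats(c(100L, 150L), c(5, 5), "sc1"),
                 mkStats(c(180L, 220L), c(5, 5), "sc2"))
    r5 <- findCandidateRegions(st5)
    expect_equal(length(r5), 2L)
    expect_equal(as.character(GenomicRanges::seqnames(r5)),
                 c("sc1", "sc2"))

    ## every member satisfies the cutoff (assertable from stored indices)
    expect_true(all(vapply(seq_along(r5), function(i)
        all(abs(st5$t[r5$members[[i]]]) > 4.6), logical(1))))
})

test_that("candidate filtering applies the CpG and mean-difference rules", {
    gr <- GenomicRanges::GRanges("sc1",
        IRanges::IRanges(c(100, 500, 900, 1300), width = 50))
    gr$direction <- c("hyper", "hyper", "hypo", "hyper")
    gr$nCpG <- c(2L, 3L, 3L, 5L)
    gr$meanDiff <- c(0.3, 0.05, -0.15, 0.1)
    gr$nSigCpG <- c(2L, 3L, 0L, 5L)
    out <- filterCandidates(gr)
    ## 2 CpGs rejected; |0.05| rejected; 0.1 rejected (strictly greater)
    expect_equal(length(out), 1L)
    expect_equal(out$direction, "hypo")
    expect_equal(GenomicRanges::start(out), 900)
    ## optional per-site FDR composition
    expect_equal(length(filterCandidates(gr, minSigCpgs = 1L)), 0L)
})

test_that("label-swap antisymmetry holds end-to-end for regions", {
    cfg <- tinyConfig(dmrEffect = c(0.3, 0.3))
    sim <- simulateDataset(cfg, readLevel = FALSE)
    me <- smoothMatrix(sim$me, smootherConfig(5L, 100))
    st <- pairedTStats(me)
    cand <- findCandidateRegions(st)
    trSwap <- ifelse(treatment(me) == "NF", "CR", "NF")
    meSwap <- withSmooth(MethylExperiment(
        SummarizedExperiment::rowRanges(me), methCounts(me),
        unmethCounts(me), mother = mother(me), treatment = trSwap),
        smoothedLevels(me))
    candSwap <- findCandidateRegions(pairedTStats(meSwap))
    expect_equal(length(cand), length(candSwap))
    expect_equal(GenomicRanges::start(cand),
                 GenomicRanges::start(candSwap))
    expect_equal(cand$direction,
                 ifelse(candSwap$direction == "hyper", "hypo", "hyper"))
})
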
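test_that("timecourse generator is deterministic and honours degenerate configs", {
    cfg <- timecourseConfig(nGenes = 100, timepoints = c("t0", "t1", "t2"),
                            replicates = 2, dynamicFraction = 0.3, seed = 42)
    a <- simulateTimecourse(cfg)
    b <- simulateTimecourse(cfg)
    expect_identical(SummarizedExperiment::assay(a$experiment, "counts"),
                     SummarizedExperiment::assay(b$experiment, "counts"))
    expect_identical(a$truth$class, b$truth$class)

    flat <- simulateTimecourse(timecourseConfig(nGenes = 50,
        timepoints = c("t0", "t1"), dynamicFraction = 0, seed = 1))
    expect_true(all(flat$truth$class == "stable"))
    expect_true(all(flat$truth$effect == 0))

    expect_error(timecourseConfig(nGenes = 0), "invalid config")
    expect_error(timecourseConfig(replicates = 0), "invalid config")
    expect_error(timecourseConfig(dynamicFraction = 1.5), "invalid config")
    expect_error(timecourseConfig(timepoints = "only_one"), "invalid config")
})

test_that("truth table is internally consistent: effect zero iff stable", {
    sim <- simulateTimecourse(timecourseConfig(nGenes = 300,
        timepoints = c("a", "b", "c", "d"), dynamicFraction = c(0.4, 0.2, 0),
        seed = 9))
    expect_identical(sim$truth$effect == 0, sim$truth$class == "stable")
    # exact counts per transition: floor(frac * n)
    expect_equal(unname(colSums(sim$truth$class != "stable")),
                 c(120, 60, 0))
})

test_that("generated counts match NB moments at known parameters", {
    # base mean pinned at 100, phi = 0.1, 50 replicates of a flat design
    cfg <- timecourseConfig(nGenes = 5000, timepoints = c("t0", "t1"),
                            replicates = 50, dynamicFraction = 0,
                            baseMeanLogRange = log2(c(100, 100)),
                            dispersion = 0.1, librarySizeCV = 0, seed = 5)
    sim <- simulateTimecourse(cfg)
    cts <- SummarizedExperiment::assay(sim$experiment, "counts")
    t0 <- cts[, timepoints(sim$experiment) == "t0"]
    mu <- 100; phi <- 0.1
    expect_equal(mean(rowMeans(t0)), mu, tolerance = 0.01)
    expect_equal(mean(apply(t0, 1, var)), mu + phi * mu^2, tolerance = 0.03)
})

test_that("empirical log2 fold change converges to the configured effect", {
    cfg <- timecourseConfig(nGenes = 400, timepoints = c("t0", "t1"),
                            replicates = 30, dynamicFraction = 0.5,
                            lfcMagnitude = 2, librarySizeCV = 0,
                            baseMeanLogRange = c(6, 9), seed = 21)
    sim <- simulateTimecourse(cfg)
    cts <- SummarizedExperiment::assay(sim$experiment, "counts")
    tp <- timepoints(sim$experiment)
    lfc <- log2(rowMeans(cts[, tp == "t1"]) / rowMeans(cts[, tp == "t0"]))
    up <- sim$truth$class[, 1] == "up"
    down <- sim$truth$class[, 1] == "down"
    expect_equal(mean(lfc[up]), 2, tolerance = 0.05)
    expect_equal(mean(lfc[down]), -2, tolerance = 0.05)
})

test_that("paired series assigns exact shared/opposite counts", {
    sim <- simulateTimecourse(timecourseConfig(nGenes = 2500,
        timepoints = c("t0", "t1"), dynamicFraction = 0.8, seed = 2))
    nUp <- sum(sim$truth$class[, 1] == "up")        # 1000 up genes
    expect_equal(nUp, 1000)
    paired <- simulatePairedSeries(sim$truth, sharedUpFrac = 0.4,
                                   sharedDownFrac = 0.3, oppositeFrac = 0.1,
                                   seed = 3)
    asg <- paired$truth$assignment[, 1]
    up1 <- sim$truth$class[, 1] == "up"
    down1 <- sim$truth$class[, 1] == "down"
    expect_equal(sum(asg[up1] == "shared_up"), floor(0.4 * 1000))
    expect_equal(sum(asg[down1] == "shared_down"), floor(0.3 * 1000))
    expect_equal(sum(asg == "opposite"), floor(0.1 * 1000) * 2)
    expect_true(all(asg[!up1 & !down1] == "not_dynamic_in_first"))
    # shared genes carry the same-direction effect, opposite the negated one
    sharedUp <- names(asg)[asg == "shared_up"]
    expect_true(all(paired$truth$effect[sharedUp, 1] ==
                        sim$truth$effect[sharedUp, 1]))
    opp <- names(asg)[asg == "opposite"]
    expect_true(all(paired$truth$effect[opp, 1] ==
                        -sim$truth$effect[opp, 1]))
})

test_that("paired series boundary fractions behave", {
    sim <- simulateTimecourse(timecourseConfig(nGenes = 200,
        timepoints = c("t0", "t1"), dynamicFraction = 0.5, seed = 4))
    all1 <- simulatePairedSeries(sim$truth, 1, 1, 0, seed = 1)
    dyn <- sim$truth$class[, 1] != "stable"
    expect_identical(all1$truth$class[dyn, 1], sim$truth$class[dyn, 1])
    none <- simulatePairedSeries(sim$truth, 0, 0, 0, seed = 1)
    expect_true(all(none$truth$class[dyn, 1] == "stable"))
    expect_error(simulatePairedSeries(sim$truth, 0.8, 0.1, 0.4, seed = 1),
                 "invalid config")
    expect_error(simulatePairedSeries(sim$truth, -0.1, 0, 0, seed = 1),
                 "invalid config")
})

test_that("cell reference produces class-structured archetypes", {
    ref <- simulateCellReference(nClasses = 3, clustersPerClass = 2,
                                 cellsPerCluster = rep(10, 6), nGenes = 800,
                                 withinClassCorr = 0.9, seed = 6)
    r <- cor(t(ref$clusterArchetypes))
    same <- outer(ref$classTruth, ref$classTruth, "==")
    within <- mean(r[same & upper.tri(r)])
    between <- mean(r[!same & upper.tri(r)])
    expect_gt(within, 0.8)
    expect_lt(between, 0.3)
    expect_gt(within, between)

    # clusters_per_class = 1: cluster archetypes are the class archetypes
    ref1 <- simulateCellReference(nClasses = 2, clustersPerClass = 1,
                                  cellsPerCluster = c(5, 5), nGenes = 100,
                                  seed = 1)
    expect_equal(unname(ref1$clusterArchetypes),
                 unname(ref1$classArchetypes))
    expect_error(simulateCellReference(0, 1, c(5), 100), "invalid config")
    expect_error(simulateCellReference(2, 2, c(5, 5), 100), "invalid config")

    ref2 <- simulateCellReference(nClasses = 3, clustersPerClass = 2,
                                  cellsPerCluster = rep(10, 6), nGenes = 800,
                                  withinClassCorr = 0.9, seed = 6)
    expect_identical(ref$counts, ref2$counts)
})

test_that("bulk mixtures follow the weighted-sum definition exactly", {
    P <- matrix(runif(4 * 30, 0, 5), 4, 30,
                dimnames = list(paste0("c", 1:4), paste0("g", 1:30)))
    e2 <- simulateBulkMixture(P, c(0, 1, 0, 0), noiseSd = 0)
    expect_equal(unname(e2), unname(P[2, ]))
    expect_equal(unname(simulateBulkMixture(P, rep(0, 4), noiseSd = 0)),
                 rep(0, 30))
    w <- c(0.7, 0.2, 0.1, 0)
    expect_equal(unname(simulateBulkMixture(P, w, noiseSd = 0)),
                 as.numeric(0.7 * P[1, ] + 0.2 * P[2, ] + 0.1 * P[3, ]))
    expect_error(simulateBulkMixture(P, c(-1, 0, 0, 0)), "invalid config")
    expect_error(simulateBulkMixture(P, c(1, 1)), "invalid config")
})

test_that("peak universe honours gain/loss/proximal truth", {
    chrom <- c(chr1 = 2e6, chr2 = 1e6)
    set.seed(77)
    tss <- data.frame(gene = paste0("g", 1:40),
                      chrom = sample(names(chrom), 40, replace = TRUE),
                      position = floor(runif(40, 1e4, 9e5)), strand = "+")
    pu <- simulatePeakUniverse(chrom, c("t0", "t1", "t2"), nPeaks = 1000,
                               gainFrac = 0.2, lossFrac = 0.2,
                               proximalFrac = 0.3, tss = tss, seed = 8)
    expect_length(pu$truth[["t0->t1"]]$gained, 200)
    expect_length(pu$truth[["t0->t1"]]$lost, 200)
    expect_length(pu$truth[["t1->t2"]]$gained, 200)
    # non-overlapping within each set
    for (ps in pu$peakSets)
        expect_equal(sum(GenomicRanges::countOverlaps(ps, ps) > 1), 0)
    # frozen fractions mean all sets keep size 1000
    expect_equal(unname(lengths(pu$peakSets)), rep(1000L, 3))

    same <- simulatePeakUniverse(chrom, c("t0", "t1"), nPeaks = 100,
                                 gainFrac = 0, lossFrac = 0,
                                 proximalFrac = 0, tss = tss, seed = 1)
    expect_identical(grToDf(same$peakSets$t0), grToDf(same$peakSets$t1))

    prox <- simulatePeakUniverse(chrom, "t0", nPeaks = 100, gainFrac = 0,
                                 lossFrac = 0, proximalFrac = 1, tss = tss,
                                 seed = 2)$peakSets$t0
    mids <- floor((GenomicRanges::start(prox) - 1 +
                       GenomicRanges::end(prox)) / 2)
    d <- vapply(seq_along(prox), function(i)
        oracleNearestTssDist(as.character(
            GenomicRanges::seqnames(prox))[i], mids[i], tss), numeric(1))
    expect_true(all(d <= 2000))
})

test_that("peak placement fails loudly when the genome is saturated", {
    tiny <- c(chr1 = 1000)
    expect_error(simulatePeakUniverse(tiny, "t0", nPeaks = 50, gainFrac = 0,
                                      lossFrac = 0, proximalFrac = 0,
                                      tss = data.frame(gene = character(),
                                                       chrom = character(),
                                                       position = numeric()),
                                      seed = 1, peakWidth = 200),
                 "generation error")
})

test_that("score track is deterministic, covering, and supports constant mode", {
    chrom <- c(chrA = 5000, chrB = 2000)
    tr1 <- simulateScoreTrack(chrom, seed = 3)
    tr2 <- simulateScoreTrack(chrom, seed = 3)
    expect_identical(tr1$score, tr2$score)
    expect_identical(grToDf(tr1), grToDf(tr2))
    # full disjoint coverage per chromosome
    cov <- GenomicRanges::coverage(tr1)
    expect_true(all(vapply(names(chrom), function(ch)
        all(S4Vectors::runValue(cov[[ch]]) == 1), logical(1))))
    expect_true(all(tr1$score >= 0))

    const <- simulateScoreTrack(chrom, constant = 0.5)
    expect_true(all(const$score == 0.5))
    expect_equal(sum(GenomicRanges::width(const)), sum(chrom))
})
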
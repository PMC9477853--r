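refFixture <- function(seed = 3) {
    simulateCellReference(nClasses = 3, clustersPerClass = 2,
                          cellsPerCluster = c(10, 4, 7, 9, 12, 6),
                          nGenes = 600, withinClassCorr = 0.95, seed = seed)
}

test_that("cluster downsampling balances to the smallest cluster", {
    ref <- refFixture()
    bal <- downsampleClusters(ref$counts, ref$clusters, seed = 1)
    expect_true(all(table(bal$clusters) == 4))
    # deterministic for a fixed seed
    bal2 <- downsampleClusters(ref$counts, ref$clusters, seed = 1)
    expect_identical(colnames(bal$counts), colnames(bal2$counts))
    # already-balanced input passes through order-stable
    even <- downsampleClusters(bal$counts, bal$clusters, seed = 9)
    expect_identical(even$counts, bal$counts)
    expect_error(downsampleClusters(ref$counts[, 0], character(0), 1))
})

test_that("cluster profiles are per-gene means of depth-scaled log counts", {
    cts <- matrix(c(4, 0, 10, 2, 6, 8, 1, 3, 5), nrow = 3,
                  dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
    oneCell <- clusterProfiles(cts[, 1, drop = FALSE], "k1")
    depth <- colSums(cts)
    expect_equal(unname(oneCell[1, ]),
                 unname(log1p(cts[, 1] / (depth[1] / median(depth[1])))))

    twoSame <- clusterProfiles(cts[, c(1, 1)], c("k", "k"))
    expect_equal(unname(twoSame[1, ]), unname(log1p(cts[, 1])))

    prof <- clusterProfiles(cts, rep("k", 3))
    scaled <- sweep(cts, 2, depth / median(depth), "/")
    expect_equal(unname(prof[1, ]), unname(rowMeans(log1p(scaled))))
})

test_that("cluster merging recovers the generative classes", {
    ref <- refFixture(seed = 5)
    bal <- downsampleClusters(ref$counts, ref$clusters, seed = 2)
    prof <- clusterProfiles(bal$counts, bal$clusters)
    model <- mergeClusters(prof, nTopVar = 500, corrThreshold = 0.8)
    asg <- classAssignment(model)
    expect_equal(nrow(classProfiles(model)), 3)
    # merged classes match the generative truth up to label names
    expect_equal(length(unique(paste(asg, ref$classTruth[names(asg)]))), 3)

    # identical profiles merge into one class
    dup <- prof[c(1, 1), ]
    rownames(dup) <- c("a", "b")
    expect_equal(nrow(classProfiles(mergeClusters(dup, corrThreshold = 0.8))),
                 1)
    # a threshold above the max pairwise correlation keeps clusters apart
    rmax <- max(cor(t(prof))[upper.tri(diag(6))])
    sep <- mergeClusters(prof, corrThreshold = min(1, rmax + 1e-6))
    expect_equal(nrow(classProfiles(sep)), 6)
    expect_error(mergeClusters(prof, corrThreshold = 1.5), "corrThreshold")
})

test_that("NNLS fits satisfy KKT and match the active-set oracle", {
    set.seed(23)
    for (i in 1:30) {
        P <- matrix(runif(4 * 25, 0, 3), 4, 25,
                    dimnames = list(paste0("cl", 1:4), paste0("g", 1:25)))
        w <- round(runif(4, 0, 2), 2) * rbinom(4, 1, 0.7)
        bulk <- simulateBulkMixture(P, w, noiseSd = 0.05, seed = i)
        fit <- nnlsFit(bulk, P)
        got <- deconvWeights(fit)
        A <- t(P)
        expect_equal(unname(got), oracleNNLS(A, as.numeric(bulk)),
                     tolerance = 1e-6)
        # KKT: gradient non-negative at zero weights, ~zero at active ones
        grad <- as.numeric(t(A) %*% (A %*% got - as.numeric(bulk)))
        expect_true(all(grad[got == 0] >= -1e-6))
        expect_true(all(abs(grad[got > 1e-8]) <= 1e-6))
    }
})

test_that("NNLS edge cases: pure profile, zero bulk, scale equivariance", {
    ref <- refFixture()
    bal <- downsampleClusters(ref$counts, ref$clusters, seed = 1)
    model <- mergeClusters(clusterProfiles(bal$counts, bal$clusters),
                           nTopVar = 500, corrThreshold = 0.8)
    P <- classProfiles(model)
    pure <- nnlsFit(P[2, ], model)
    expect_equal(unname(deconvProportions(pure)[2]), 100, tolerance = 1e-6)
    expect_true(all(deconvProportions(pure)[-2] < 1e-6))

    zero <- nnlsFit(setNames(rep(0, ncol(P)), colnames(P)), model)
    expect_true(zero@degenerate)
    expect_true(all(deconvWeights(zero) == 0))

    mix <- simulateBulkMixture(P, c(0.5, 0.3, 0.2), noiseSd = 0)
    f1 <- nnlsFit(mix, model)
    f2 <- nnlsFit(mix * 7, model)
    expect_equal(deconvWeights(f2), 7 * deconvWeights(f1), tolerance = 1e-6)
    expect_equal(deconvProportions(f2), deconvProportions(f1),
                 tolerance = 1e-8)

    # permuting class order permutes weights identically
    perm <- c(3, 1, 2)
    f3 <- nnlsFit(mix, P[perm, ])
    expect_equal(unname(deconvWeights(f3)),
                 unname(deconvWeights(f1)[perm]), tolerance = 1e-8)
    expect_error(nnlsFit(setNames(1:3, c("x", "y", "z")), model), "shared")
})

test_that("two-stage deconvolution restricts stage 2 to cholinergic clusters", {
    ref <- refFixture(seed = 11)
    chol <- setNames(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                     sprintf("cluster%02d", 1:6))
    bal <- downsampleClusters(ref$counts, ref$clusters, seed = 4)
    model <- mergeClusters(clusterProfiles(bal$counts, bal$clusters),
                           nTopVar = 500, corrThreshold = 0.8)
    P <- classProfiles(model)
    asg <- classAssignment(model)
    cholClasses <- unique(asg[names(chol)[chol]])
    w <- setNames(rep(0, nrow(P)), rownames(P))
    w[cholClasses] <- c(0.7, 0.3)
    bulk <- simulateBulkMixture(P, w, noiseSd = 0.02, seed = 1)
    dec <- twoStageDeconvolve(bulk, ref$counts, ref$clusters, chol,
                              seed = 4, nTopVar = 500, bulkIsLog = TRUE)
    expect_equal(dec$stage1@stage, "all_classes")
    expect_equal(dec$stage2@stage, "cholinergic_only")
    # non-cholinergic classes get ~zero weight in stage 1
    nonChol <- setdiff(rownames(P), cholClasses)
    expect_lt(max(deconvProportions(dec$stage1)[nonChol]), 2)
    # stage 2 sees only cholinergic-derived classes
    expect_equal(nrow(classProfiles(dec$model2)), 2)
    expect_equal(sort(unname(deconvProportions(dec$stage2))),
                 c(30, 70), tolerance = 0.15)

    # all clusters cholinergic: stage 2 reproduces stage 1
    allChol <- setNames(rep(TRUE, 6), names(chol))
    dec2 <- twoStageDeconvolve(bulk, ref$counts, ref$clusters, allChol,
                               seed = 4, nTopVar = 500, bulkIsLog = TRUE)
    expect_equal(deconvWeights(dec2$stage2), deconvWeights(dec2$stage1))

    noChol <- setNames(rep(FALSE, 6), names(chol))
    expect_warning(dec3 <- twoStageDeconvolve(bulk, ref$counts, ref$clusters,
                                              noChol, seed = 4,
                                              nTopVar = 500,
                                              bulkIsLog = TRUE),
                   "no cholinergic")
    expect_null(dec3$stage2)
    expect_s4_class(dec3$stage1, "DeconvolutionResult")
})
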
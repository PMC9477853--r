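chromFixture <- c(chr1 = 1e6, chr2 = 6e5)

test_that("topPeaks keeps the n best scores with a positional tie-break", {
    set.seed(51)
    pk <- randomPeaks(50, chromFixture)
    expect_equal(length(topPeaks(pk, 50)), 50)
    expect_warning(allOf <- topPeaks(pk, 60), "exceeds")
    expect_equal(length(allOf), 50)

    top10 <- topPeaks(pk, 10)
    expect_equal(sort(top10$score, decreasing = TRUE),
                 sort(pk$score, decreasing = TRUE)[1:10])

    # ties at the cutoff: full-sort oracle with (score desc, chrom, start)
    tied <- randomPeaks(30, chromFixture)
    tied$score <- rep(c(10, 5), 15)
    got <- topPeaks(tied, 17)
    df <- grToDf(tied); df$score <- tied$score; df$name <- tied$name
    ord <- order(-df$score, df$chrom, df$start)
    expect_setequal(got$name, df$name[ord[1:17]])
    # output is coordinate-sorted
    expect_true(!is.unsorted(order(as.character(GenomicRanges::seqnames(got)),
                                   GenomicRanges::start(got))))
})

test_that("region exclusion drops any >=1 bp overlap and is idempotent", {
    set.seed(52)
    pk <- randomPeaks(100, chromFixture)
    expect_equal(length(excludeRegions(pk, GenomicRanges::GRanges())), 100)
    expect_equal(length(excludeRegions(pk, pk)), 0)

    for (i in 1:20) {
        a <- randomPeaks(60, chromFixture)
        b <- randomPeaks(40, chromFixture)
        got <- excludeRegions(a, b)
        da <- grToDf(a); db <- grToDf(b)
        keep <- !oracleOverlaps(da$chrom, da$start, da$end,
                                db$chrom, db$start, db$end)
        expect_equal(length(got), sum(keep))
        expect_setequal(got$name, a$name[keep])
        expect_identical(grToDf(excludeRegions(got, b)), grToDf(got))
    }
})

test_that("gain/loss subtraction is symmetric and matches generator truth", {
    set.seed(53)
    a <- randomPeaks(80, chromFixture)
    gl <- gainLoss(a, a, n = 100)
    expect_equal(length(gl$gained), 0)
    expect_equal(gl$percentGained, 0)
    expect_equal(gl$percentLost, 0)

    # fully disjoint sets: everything gained and lost
    left <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(seq(1, 10000, 500), width = 100),
        score = 1:20, name = paste0("L", 1:20))
    right <- GenomicRanges::shift(left, 250)
    right$name <- paste0("R", 1:20)
    gl2 <- gainLoss(left, right, n = 1000)
    expect_equal(gl2$percentGained, 100)
    expect_equal(gl2$percentLost, 100)

    b <- randomPeaks(70, chromFixture)
    fwd <- gainLoss(a, b, n = 1000)
    rev <- gainLoss(b, a, n = 1000)
    expect_identical(grToDf(fwd$gained), grToDf(rev$lost))
    expect_identical(grToDf(fwd$lost), grToDf(rev$gained))

    tss <- data.frame(gene = "g1", chrom = "chr1", position = 5e5)
    pu <- simulatePeakUniverse(chromFixture, c("e", "l"), nPeaks = 300,
                               gainFrac = 0.25, lossFrac = 0.25,
                               proximalFrac = 0, tss = tss, seed = 54)
    glT <- gainLoss(pu$peakSets$e, pu$peakSets$l, n = 1e5)
    expect_equal(glT$percentGained, pu$truth[["e->l"]]$percentGained)
    expect_equal(glT$percentLost, pu$truth[["e->l"]]$percentLost)
    expect_setequal(glT$gained$name, pu$truth[["e->l"]]$gained)
    expect_setequal(glT$lost$name, pu$truth[["e->l"]]$lost)
})

test_that("TSS proximity uses midpoint distance with an inclusive 2 kb cutoff", {
    tss <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr1"),
                      position = c(10000, 50000))
    mk <- function(mid0, w = 200)
        GenomicRanges::GRanges("chr1",
            IRanges::IRanges(mid0 - w / 2 + 1, mid0 + w / 2),
            score = 1, name = "p")
    atTss <- classifyTssProximity(mk(10000), tss)
    expect_equal(atTss$class, "proximal")
    expect_equal(atTss$distance, 0)
    expect_equal(classifyTssProximity(mk(12000), tss)$class, "proximal")
    expect_equal(classifyTssProximity(mk(12001), tss)$class, "distal")

    expect_warning(
        far <- classifyTssProximity(
            GenomicRanges::GRanges("chrUn", IRanges::IRanges(1, 100),
                                   score = 1, name = "x"), tss),
        "no TSS")
    expect_equal(far$class, "distal")

    set.seed(55)
    for (i in 1:20) {
        pk <- randomPeaks(50, chromFixture)
        ann <- data.frame(gene = paste0("g", 1:15),
                          chrom = sample(names(chromFixture), 15, TRUE),
                          position = floor(runif(15, 0, 5e5)))
        got <- classifyTssProximity(pk, ann)
        df <- grToDf(pk)
        mids <- floor((df$start + df$end) / 2)
        want <- vapply(seq_len(50), function(j)
            oracleNearestTssDist(df$chrom[j], mids[j], ann), numeric(1))
        expect_equal(got$distance, want)
        expect_equal(got$class, ifelse(want <= 2000, "proximal", "distal"))
    }
})

test_that("peaks-near-genes counts midpoints inside the window", {
    tss <- data.frame(gene = c("gA", "gB"), chrom = c("chr1", "chr2"),
                      position = c(100000, 200000))
    none <- GenomicRanges::GRanges()
    expect_equal(unname(peaksNearGenes(none, c("gA", "gB"), tss)), c(0, 0))
    one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(99901, 100100),
                                  score = 1, name = "p1")
    expect_equal(unname(peaksNearGenes(one, c("gA", "gB"), tss,
                                       window = 5000)), c(1, 0))
    expect_error(peaksNearGenes(one, c("gA", "missing"), tss), "missing")

    set.seed(56)
    for (i in 1:20) {
        pk <- randomPeaks(80, chromFixture)
        ann <- data.frame(gene = paste0("g", 1:10),
                          chrom = sample(names(chromFixture), 10, TRUE),
                          position = floor(runif(10, 0, 5e5)))
        win <- sample(c(1000, 20000, 50000), 1)
        got <- peaksNearGenes(pk, ann$gene, ann, window = win)
        df <- grToDf(pk)
        mids <- floor((df$start + df$end) / 2)
        want <- vapply(seq_len(10), function(j)
            sum(df$chrom == ann$chrom[j] &
                    abs(mids - ann$position[j]) <= win), integer(1))
        expect_equal(unname(got), want)
    }
})

test_that("peak-count comparison reproduces Welch's t-test", {
    x <- c(3, 3, 3); y <- c(3, 3, 3)
    same <- comparePeakCounts(x, y)
    expect_equal(unname(same["p"]), 1)
    expect_equal(unname(same["t"]), 0)

    big <- comparePeakCounts(rnorm(200, 10, 0.01), rnorm(200, 0, 0.01))
    expect_lt(unname(big["p"]), 1e-100)

    set.seed(57)
    for (i in 1:25) {
        g <- rpois(30, 6); l <- rpois(30, 4)
        got <- comparePeakCounts(g, l)
        want <- oracleWelch(g, l)
        expect_equal(unname(got["t"]), unname(want["t"]))
        expect_equal(unname(got["p"]), unname(want["p"]))
    }
    expect_error(comparePeakCounts(1, 2), "at least 2")
})

test_that("conservation averaging matches per-base expansion", {
    chrom <- c(chrA = 3000)
    track <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(c(1, 501, 1501), c(500, 1500, 3000)),
        score = c(0.2, 0.8, 0.4))
    regions <- GenomicRanges::GRanges("chrA",
        IRanges::IRanges(c(401, 1001, 2001, 1, 1451),
                         c(600, 1200, 2100, 3000, 1550)),
        score = 1, name = paste0("r", 1:5))
    got <- regionConservation(regions, track, chrom, backgroundN = 50,
                              backgroundLength = 100, seed = 5)
    df <- grToDf(regions)
    want <- vapply(seq_len(5), function(i)
        oracleTrackMean(df$chrom[i], df$start[i], df$end[i], track),
        numeric(1))
    expect_equal(got$regionMeans, want)
    expect_equal(got$foregroundMean, mean(want))

    const <- simulateScoreTrack(chrom, constant = 0.5)
    rc <- regionConservation(regions, const, chrom, backgroundN = 20,
                             seed = 2, backgroundLength = 200)
    expect_equal(rc$foregroundMean, 0.5)
    expect_equal(rc$backgroundMean, 0.5)
    expect_error(regionConservation(GenomicRanges::GRanges(), track, chrom),
                 "empty")
})
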
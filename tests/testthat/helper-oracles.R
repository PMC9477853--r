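# Independent brute-force oracles used across the suite. Each is a direct
# transcription of the operation's definition, kept deliberately naive and
# separate from the package implementation it checks.

oracleSizeFactors <- function(cts) {
    geo <- apply(cts, 1, function(r) exp(mean(log(r))))
    use <- is.finite(geo) & geo > 0
    apply(cts, 2, function(col) median((col / geo)[use]))
}

# all-pairs >=1 bp overlap between 0-based half-open intervals
oracleOverlaps <- function(chromA, startA, endA, chromB, startB, endB) {
    vapply(seq_along(chromA), function(i)
        any(chromB == chromA[i] & startB < endA[i] & endB > startA[i]),
        logical(1))
}

grToDf <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               stringsAsFactors = FALSE)
}

# exhaustive active-set NNLS: try every support set, keep the feasible
# least-squares solution with the smallest residual
oracleNNLS <- function(A, b) {
    k <- ncol(A)
    best <- rep(0, k)
    bestR <- sum(b^2)
    for (S in seq_len(2^k) - 1L) {
        idx <- which(bitwAnd(S, 2^(seq_len(k) - 1)) > 0)
        if (!length(idx)) next
        sol <- tryCatch(qr.coef(qr(A[, idx, drop = FALSE]), b),
                        error = function(e) NULL)
        if (is.null(sol) || anyNA(sol) || any(sol < -1e-9)) next
        x <- rep(0, k)
        x[idx] <- pmax(sol, 0)
        r <- sum((A %*% x - b)^2)
        if (r < bestR - 1e-12) { bestR <- r; best <- x }
    }
    best
}

oracleWelch <- function(x, y) {
    m1 <- mean(x); m2 <- mean(y)
    v1 <- var(x) / length(x); v2 <- var(y) / length(y)
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
    c(t = t, p = 2 * pt(-abs(t), df))
}

# per-base expansion mean of a piecewise track over a 0-based interval
oracleTrackMean <- function(chrom, start0, end0, track) {
    bases <- seq(start0, end0 - 1)           # 0-based base positions
    scores <- vapply(bases, function(p) {
        hit <- which(as.character(GenomicRanges::seqnames(track)) == chrom &
                     GenomicRanges::start(track) - 1 <= p &
                     GenomicRanges::end(track) > p)
        if (length(hit)) track$score[hit[1]] else 0
    }, numeric(1))
    mean(scores)
}

oracleNearestTssDist <- function(chrom, mid0, tss) {
    pos <- tss$position[tss$chrom == chrom]
    if (!length(pos)) return(Inf)
    min(abs(mid0 - pos))
}

randomPeaks <- function(n, chromSizes, maxWidth = 500) {
    chrom <- sample(names(chromSizes), n, replace = TRUE)
    width <- sample(50:maxWidth, n, replace = TRUE)
    start0 <- vapply(seq_len(n), function(i)
        sample.int(chromSizes[[chrom[i]]] - width[i], 1) - 1L, integer(1))
    GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start0 + 1, start0 + width),
        score = runif(n, 0, 1000),
        name = sprintf("p%04d", seq_len(n)))
}

randomCounts <- function(nGenes, nSamples, lambda = 50) {
    matrix(rpois(nGenes * nSamples, lambda), nrow = nGenes,
           dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                           sprintf("s%02d", seq_len(nSamples))))
}
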
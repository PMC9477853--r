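#' @import GenomicRanges
#' @import IRanges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlevels
NULL

# Peak sets are GRanges with a numeric `score` (significance) and optional
# `name` metadata column; coordinates follow the BED convention at the I/O
# boundary (0-based half-open) and GRanges 1-based closed internally.

.sortPeaks <- function(gr) {
    gr[order(as.character(seqnames(gr)), start(gr), end(gr))]
}

#' Top-scoring peaks
#'
#' Selects the `n` highest-score intervals; ties at the cutoff are broken
#' deterministically by (chrom, start). Output is coordinate-sorted. When
#' `n` exceeds the set size the whole set is returned with a warning.
#'
#' @param peaks GRanges with a `score` metadata column.
#' @param n number of peaks to keep.
#' @return coordinate-sorted GRanges.
#' @export
topPeaks <- function(peaks, n) {
    stopifnot(n >= 1)
    if (n >= length(peaks)) {
        if (n > length(peaks))
            warning("n exceeds the number of peaks; returning all")
        return(.sortPeaks(peaks))
    }
    ord <- order(-peaks$score, as.character(seqnames(peaks)), start(peaks))
    .sortPeaks(peaks[ord[seq_len(n)]])
}

#' Remove peaks overlapping blacklist regions
#'
#' Drops every peak with at least 1 bp of overlap to any interval of any
#' blacklist set (whole-feature removal).
#'
#' @param peaks GRanges.
#' @param blacklists a GRanges or list of GRanges.
#' @return coordinate-sorted GRanges of surviving peaks.
#' @export
excludeRegions <- function(peaks, blacklists) {
    if (is(blacklists, "GRanges")) blacklists <- list(blacklists)
    bl <- if (length(blacklists))
        suppressWarnings(do.call(c, lapply(blacklists, GenomicRanges::granges)))
    else GRanges()
    .sortPeaks(IRanges::subsetByOverlaps(peaks, bl, invert = TRUE,
                                         ignore.strand = TRUE))
}

#' Gained and lost peaks between consecutive timepoints
#'
#' Gained peaks are the top-`n` peaks of the later timepoint with no (>= 1
#' bp) overlap to any peak of the earlier set; lost peaks are the top-`n`
#' of the earlier set with no overlap to any later peak. Subtraction is
#' whole-feature. Percents are relative to the realized top-set sizes.
#'
#' @param earlier,later GRanges peak sets with `score`.
#' @param n top-peak rank cutoff (default 100000).
#' @return list: `gained`, `lost` (sorted GRanges), `percentGained`,
#'   `percentLost`.
#' @export
gainLoss <- function(earlier, later, n = 100000) {
    topLater <- suppressWarnings(topPeaks(later, n))
    topEarlier <- suppressWarnings(topPeaks(earlier, n))
    gained <- IRanges::subsetByOverlaps(topLater, earlier, invert = TRUE,
                                        ignore.strand = TRUE)
    lost <- IRanges::subsetByOverlaps(topEarlier, later, invert = TRUE,
                                      ignore.strand = TRUE)
    list(gained = .sortPeaks(gained), lost = .sortPeaks(lost),
         percentGained = if (length(topLater))
             100 * length(gained) / length(topLater) else NA_real_,
         percentLost = if (length(topEarlier))
             100 * length(lost) / length(topEarlier) else NA_real_)
}

# Peak midpoints as 0-based positions: floor((start0 + end0) / 2).
.midpoint0 <- function(gr) {
    start0 <- start(gr) - 1L
    end0 <- end(gr)
    floor((start0 + end0) / 2)
}

#' Classify peaks as TSS-proximal or distal
#'
#' Distance is from the peak midpoint to the nearest annotated TSS position
#' on the same chromosome; a peak is proximal when that distance is at most
#' `cutoff` bp (2 kb default, inclusive). Peaks on chromosomes with no TSS
#' are classified distal with a warning.
#'
#' @param peaks GRanges.
#' @param tss data.frame with columns `gene`, `chrom`, `position` (0-based
#'   TSS coordinate) and optionally `strand`.
#' @param cutoff proximity cutoff in bp (default 2000).
#' @return list: `class` (character vector "proximal"/"distal" per peak, in
#'   the order of `peaks`), `distance` (bp to nearest TSS, `Inf` when none),
#'   `percentProximal`, `percentDistal`.
#' @export
classifyTssProximity <- function(peaks, tss, cutoff = 2000) {
    stopifnot(all(c("gene", "chrom", "position") %in% colnames(tss)))
    if (!nrow(tss)) stop("invalid argument: empty TSS annotation")
    mids <- .midpoint0(peaks)
    chroms <- as.character(seqnames(peaks))
    dist <- rep(Inf, length(peaks))
    for (chr in unique(chroms)) {
        pos <- sort(tss$position[tss$chrom == chr])
        idx <- which(chroms == chr)
        if (!length(pos)) {
            warning("no TSS on chromosome ", chr, "; peaks classified distal")
            next
        }
        # nearest sorted position via findInterval
        j <- findInterval(mids[idx], pos)
        lo <- pmax(j, 1L); hi <- pmin(j + 1L, length(pos))
        dist[idx] <- pmin(abs(mids[idx] - pos[lo]), abs(mids[idx] - pos[hi]))
    }
    cls <- ifelse(dist <= cutoff, "proximal", "distal")
    list(class = cls, distance = dist,
         percentProximal = 100 * mean(cls == "proximal"),
         percentDistal = 100 * mean(cls == "distal"))
}

#' Count peaks near each gene's TSS
#'
#' Counts, per gene, the peaks whose midpoint lies within `window` bp of the
#' gene's TSS (inclusive on both ends).
#'
#' @param peaks GRanges.
#' @param genes character vector of gene IDs; all must be present in `tss`.
#' @param tss TSS annotation data.frame (see [classifyTssProximity()]).
#' @param window half-width of the window in bp (default 50000; always
#'   report the value used — the choice materially affects counts).
#' @return named integer vector of peak counts per gene.
#' @export
peaksNearGenes <- function(peaks, genes, tss, window = 50000) {
    missing <- setdiff(genes, tss$gene)
    if (length(missing))
        stop("genes missing from the TSS annotation: ",
             paste(missing, collapse = ", "))
    ann <- tss[match(genes, tss$gene), ]
    mids <- .midpoint0(peaks)
    chroms <- as.character(seqnames(peaks))
    counts <- vapply(seq_along(genes), function(i)
        sum(chroms == ann$chrom[i] &
                abs(mids - ann$position[i]) <= window), integer(1))
    stats::setNames(counts, genes)
}

#' Welch t-test between per-gene gained and lost peak counts
#'
#' @param gainedCounts,lostCounts numeric vectors over the same genes.
#' @return named numeric: `meanDifference` (gained - lost), `t`, `p`
#'   (two-sided Welch).
#' @export
comparePeakCounts <- function(gainedCounts, lostCounts) {
    stopifnot(length(gainedCounts) == length(lostCounts))
    if (length(gainedCounts) < 2)
        stop("invalid argument: need at least 2 genes")
    if (stats::sd(gainedCounts) == 0 && stats::sd(lostCounts) == 0) {
        d <- mean(gainedCounts) - mean(lostCounts)
        return(c(meanDifference = d, t = if (d == 0) 0 else Inf,
                 p = if (d == 0) 1 else 0))
    }
    tt <- stats::t.test(gainedCounts, lostCounts, var.equal = FALSE)
    c(meanDifference = mean(gainedCounts) - mean(lostCounts),
      t = unname(tt$statistic), p = tt$p.value)
}

# Length-weighted mean score of `regions` under a piecewise-constant track
# (GRanges with `score`); bases not covered by the track score 0.
.trackMeans <- function(regions, track) {
    hits <- GenomicRanges::findOverlaps(regions, track, ignore.strand = TRUE)
    ov <- IRanges::pintersect(regions[S4Vectors::queryHits(hits)],
                              track[S4Vectors::subjectHits(hits)])
    contrib <- width(ov) * track$score[S4Vectors::subjectHits(hits)]
    sums <- rep(0, length(regions))
    agg <- tapply(contrib, S4Vectors::queryHits(hits), sum)
    sums[as.integer(names(agg))] <- agg
    sums / width(regions)
}

#' Mean conservation of regions versus a random genomic background
#'
#' Averages a per-base score track (e.g. phastCons) over a set of regions
#' and over a seeded background of random fixed-length intervals sampled
#' uniformly from the genome (chromosome chosen proportional to its length).
#'
#' @param regions GRanges; must be non-empty.
#' @param track GRanges with a `score` column: a piecewise-constant per-base
#'   track. Uncovered bases score 0.
#' @param chromSizes named integer vector of chromosome lengths.
#' @param backgroundN number of background intervals (default 49896).
#' @param backgroundLength background interval length in bp (default 2000).
#' @param seed seed for the background sampling.
#' @return list: `foregroundMean`, `backgroundMean`, `regionMeans`
#'   (per-region mean score).
#' @export
regionConservation <- function(regions, track, chromSizes,
                               backgroundN = 49896, backgroundLength = 2000,
                               seed = 1) {
    if (!length(regions)) stop("invalid argument: empty region set")
    regionMeans <- .trackMeans(regions, track)
    bg <- .withSeed(seed, {
        usable <- chromSizes[chromSizes >= backgroundLength]
        if (!length(usable)) stop("no chromosome fits the background length")
        chr <- sample(names(usable), backgroundN, replace = TRUE,
                      prob = as.numeric(usable))
        startMax <- usable[chr] - backgroundLength
        start0 <- floor(stats::runif(backgroundN, 0, startMax + 1))
        GRanges(chr, IRanges(start0 + 1, width = backgroundLength))
    })
    list(foregroundMean = mean(regionMeans),
         backgroundMean = mean(.trackMeans(bg, track)),
         regionMeans = regionMeans)
}
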
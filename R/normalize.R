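#' Median-of-ratios size factors
#'
#' Computes per-sample size factors by the median-of-ratios method: for every
#' gene with a strictly positive geometric mean across samples, the ratio of
#' its count in a sample to that geometric mean is formed, and the sample's
#' factor is the median of those ratios. Genes with a zero count in any
#' sample are excluded from the reference (their geometric mean is zero).
#'
#' @param x a [TimecourseExperiment-class] or a non-negative count matrix
#'   (genes x samples).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' cts <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("a", "b")))
#' medianOfRatios(cts)  # b sequenced twice as deep as a
#' @export
medianOfRatios <- function(x) {
    cts <- .countsOf(x)
    logGeo <- rowMeans(log(cts))
    use <- is.finite(logGeo)          # zero count anywhere => -Inf
    if (!any(use))
        stop("degenerate input: no gene has nonzero counts in every sample ",
             "(no reference genes for median-of-ratios)")
    sf <- apply(cts[use, , drop = FALSE], 2, function(col)
        stats::median(exp(log(col) - logGeo[use])))
    if (any(!is.finite(sf) | sf <= 0))
        stop("degenerate input: non-positive size factor")
    sf
}

.countsOf <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        cts <- SummarizedExperiment::assay(x, "counts")
    } else {
        cts <- as.matrix(x)
    }
    if (any(cts < 0)) stop("counts must be non-negative")
    cts
}

#' Normalize counts by median-of-ratios size factors
#'
#' Divides each sample's counts by its size factor, so that
#' `normalized * size_factor == counts` holds exactly. For a
#' `TimecourseExperiment` the normalized values are added as a `normalized`
#' assay and the factors stored in `colData(x)$sizeFactor`.
#'
#' @inheritParams medianOfRatios
#' @param sizeFactors optional precomputed factors; defaults to
#'   [medianOfRatios()] of `x`.
#' @return object of the same class as `x`: a `TimecourseExperiment` with a
#'   `normalized` assay, or a plain matrix with a `sizeFactors` attribute.
#' @export
normalizeCounts <- function(x, sizeFactors = medianOfRatios(x)) {
    cts <- .countsOf(x)
    stopifnot(length(sizeFactors) == ncol(cts), all(sizeFactors > 0))
    norm <- sweep(cts, 2, sizeFactors, "/")
    if (is(x, "SummarizedExperiment")) {
        SummarizedExperiment::assays(x)$normalized <- norm
        colData(x)$sizeFactor <- unname(sizeFactors)
        x
    } else {
        attr(norm, "sizeFactors") <- sizeFactors
        norm
    }
}

#' Extract the normalized assay, computing it if absent
#' @keywords internal
.normalizedOf <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        if (!"normalized" %in% SummarizedExperiment::assayNames(x))
            x <- normalizeCounts(x)
        SummarizedExperiment::assay(x, "normalized")
    } else if (!is.null(attr(x, "sizeFactors"))) {
        x
    } else {
        normalizeCounts(x)
    }
}

#' Counts per million
#'
#' @param x count matrix or `TimecourseExperiment`.
#' @return matrix of CPM values: `counts * 1e6 / colSums(counts)`.
#' @export
cpm <- function(x) {
    cts <- .countsOf(x)
    tot <- colSums(cts)
    if (any(tot <= 0)) stop("degenerate input: sample with zero total counts")
    sweep(cts, 2, tot, "/") * 1e6
}

#' Expressed-gene filter: CPM at least a threshold in all replicates of a
#' condition
#'
#' A gene is called expressed when there is at least one condition group in
#' `scope` in which every replicate has CPM greater than or equal to
#' `cpmThreshold` (the threshold is inclusive). Condition groups default to
#' the timepoint-by-condition combinations of the sample metadata, matching
#' the usual "CPM >= 5 in all replicates at any age" filter.
#'
#' @param x a [TimecourseExperiment-class].
#' @param cpmThreshold inclusive CPM cutoff (default 5).
#' @param scope character vector of condition-group labels to consider;
#'   defaults to all groups present. Labels are
#'   `paste(timepoint, condition, sep = ".")` unless `groups` is given.
#' @param groups optional explicit per-sample grouping vector overriding the
#'   timepoint x condition default.
#' @return character vector of expressed gene IDs (in matrix row order).
#' @export
expressedGenes <- function(x, cpmThreshold = 5, scope = NULL, groups = NULL) {
    cpmMat <- cpm(x)
    if (is.null(groups)) {
        if (!is(x, "SummarizedExperiment"))
            stop("groups must be given for a plain matrix")
        groups <- paste(colData(x)$timepoint, colData(x)$condition, sep = ".")
    }
    groups <- as.character(groups)
    if (is.null(scope)) scope <- unique(groups)
    if (!length(scope)) stop("invalid argument: empty condition scope")
    if (!all(scope %in% groups))
        stop("scope contains unknown condition groups: ",
             paste(setdiff(scope, groups), collapse = ", "))
    ok <- vapply(scope, function(g) {
        cols <- which(groups == g)
        apply(cpmMat[, cols, drop = FALSE] >= cpmThreshold, 1, all)
    }, logical(nrow(cpmMat)))
    rownames(cpmMat)[rowSums(as.matrix(ok)) > 0]
}
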
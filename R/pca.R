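#' Sample PCA on normalized expression
#'
#' Genes are filtered to those with more than `minReads` normalized reads in
#' at least one sample, log-transformed (`log2(x + 1)`), per-gene
#' mean-centered and scaled to unit variance, and the samples projected onto
#' principal components.
#'
#' @param x a [TimecourseExperiment-class] (normalized assay computed on
#'   demand) or a normalized matrix.
#' @param minReads gene filter: keep genes with normalized value strictly
#'   greater than this in at least one sample (default 10).
#' @param nComponents number of components to return (default
#'   `min(n_samples, n_genes)` after filtering, capped at `nSamples`).
#' @return list with `scores` (sample x component matrix), `varianceExplained`
#'   (percent per component, non-increasing) and `genesUsed`.
#' @export
pcaSamples <- function(x, minReads = 10, nComponents = NULL) {
    norm <- .normalizedOf(x)
    if (ncol(norm) < 2) stop("invalid argument: need at least 2 samples")
    keep <- apply(norm > minReads, 1, any)
    mat <- log2(norm[keep, , drop = FALSE] + 1)
    sds <- apply(mat, 1, stats::sd)
    mat <- mat[sds > 0, , drop = FALSE]      # constant genes carry no signal
    if (!nrow(mat)) stop("degenerate input: no variable genes after filtering")
    X <- scale(t(mat))                        # samples x genes, unit variance
    maxK <- min(dim(X))
    if (is.null(nComponents)) nComponents <- maxK
    if (nComponents > ncol(norm))
        stop("invalid argument: more components than samples")
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    k <- min(nComponents, ncol(pc$x))
    ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         varianceExplained = ve[seq_len(k)],
         genesUsed = rownames(mat))
}
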
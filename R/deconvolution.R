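#' @importFrom pracma lsqnonneg
NULL

# Evaluate expr under set.seed(seed), restoring the caller's RNG state, so
# every generator is a pure function of its arguments.
.withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (had) old <- get(".Random.seed", envir = globalenv())
        on.exit({
            if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv())
        })
        set.seed(as.integer(seed))
    }
    force(expr)
}

#' Balance cluster sizes by seeded downsampling
#'
#' Reduces every cluster of a labeled single-cell count matrix to the size
#' of the smallest cluster, sampling cells without replacement, to avoid
#' biasing the reference against small clusters.
#'
#' @param counts gene x cell non-negative matrix (column names are cell IDs).
#' @param clusters character/factor cluster label per cell (same order as
#'   columns).
#' @param seed integer seed for the sampling (required, logged choice).
#' @return list with balanced `counts` and `clusters`. Cell order within a
#'   cluster follows the original column order.
#' @export
downsampleClusters <- function(counts, clusters, seed) {
    counts <- as.matrix(counts)
    clusters <- as.character(clusters)
    stopifnot(length(clusters) == ncol(counts))
    if (!length(clusters)) stop("invalid input: no cells")
    sizes <- table(clusters)
    if (any(sizes == 0)) stop("invalid input: empty cluster")
    target <- min(sizes)
    keep <- .withSeed(seed, {
        unlist(lapply(unique(clusters), function(cl) {
            idx <- which(clusters == cl)
            if (length(idx) > target) sort(sample(idx, target)) else idx
        }))
    })
    keep <- sort(keep)
    list(counts = counts[, keep, drop = FALSE], clusters = clusters[keep])
}

#' Per-cluster mean log expression profiles
#'
#' Cells are depth-normalized to the median total count, log-transformed with
#' `log1p`, and averaged within clusters.
#'
#' @inheritParams downsampleClusters
#' @return cluster x gene matrix of mean log expression.
#' @export
clusterProfiles <- function(counts, clusters) {
    counts <- as.matrix(counts)
    clusters <- as.character(clusters)
    stopifnot(length(clusters) == ncol(counts))
    depth <- colSums(counts)
    if (any(depth <= 0)) stop("invalid input: cell with zero total counts")
    scaled <- sweep(counts, 2, depth / stats::median(depth), "/")
    logm <- log1p(scaled)
    prof <- t(vapply(unique(clusters), function(cl)
        rowMeans(logm[, clusters == cl, drop = FALSE]),
        numeric(nrow(counts))))
    rownames(prof) <- unique(clusters)
    colnames(prof) <- rownames(counts)
    prof
}

#' Merge correlated clusters into transcriptional classes
#'
#' Restricts the cluster profiles to the `nTopVar` highest-variance genes
#' (variance across cluster profiles), computes the Pearson correlation
#' between every pair of clusters, and groups clusters by average-linkage
#' hierarchical clustering on correlation distance (1 - r), cutting the tree
#' at height `1 - corrThreshold` so merged classes have average within-class
#' correlation at least `corrThreshold`. Class profiles are the mean of
#' their member cluster profiles over all genes.
#'
#' @param profiles cluster x gene matrix from [clusterProfiles()].
#' @param nTopVar number of top-variance genes for the correlations
#'   (default 1000, capped at the number of genes).
#' @param corrThreshold within-class correlation cutoff in (-1, 1\]
#'   (default 0.8).
#' @return a [ClassModel-class].
#' @export
mergeClusters <- function(profiles, nTopVar = 1000, corrThreshold = 0.8) {
    stopifnot(is.matrix(profiles), !is.null(rownames(profiles)))
    if (corrThreshold <= -1 || corrThreshold > 1)
        stop("invalid argument: corrThreshold must be in (-1, 1]")
    nTopVar <- min(nTopVar, ncol(profiles))
    if (nrow(profiles) == 1) {
        assignment <- stats::setNames("class1", rownames(profiles))
        prof <- profiles
        rownames(prof) <- "class1"
        return(new("ClassModel", assignment = assignment, profiles = prof,
                   clusterProfiles = profiles,
                   genesUsed = colnames(profiles)[seq_len(nTopVar)],
                   corrThreshold = corrThreshold))
    }
    vars <- apply(profiles, 2, stats::var)
    topGenes <- colnames(profiles)[order(vars, decreasing = TRUE)[seq_len(nTopVar)]]
    sub <- profiles[, topGenes, drop = FALSE]
    ok <- apply(sub, 1, stats::sd) > 0
    if (!all(ok)) stop("invalid input: constant cluster profile on top genes")
    r <- stats::cor(t(sub))
    hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
    grp <- stats::cutree(hc, h = 1 - corrThreshold + 1e-12)
    # stable class names in order of first appearance
    lev <- unique(grp[hc$labels])
    classNames <- paste0("class", seq_along(lev))
    assignment <- stats::setNames(classNames[match(grp, lev)], names(grp))
    prof <- t(vapply(classNames, function(cl)
        colMeans(profiles[names(assignment)[assignment == cl], , drop = FALSE]),
        numeric(ncol(profiles))))
    rownames(prof) <- classNames
    new("ClassModel", assignment = assignment, profiles = prof,
        clusterProfiles = profiles, genesUsed = topGenes,
        corrThreshold = corrThreshold)
}

#' Non-negative least squares fit of a bulk profile to class profiles
#'
#' Expresses a bulk expression vector as a non-negative linear combination
#' of the class mean profiles: `w = argmin || b - t(P) w ||_2, w >= 0`,
#' solved by the Lawson-Hanson active-set method. The fit is done on the
#' intersection of bulk and reference genes. Proportions are the weights
#' normalized to percent; an all-zero weight vector is flagged degenerate.
#'
#' @param bulk named numeric expression vector.
#' @param model a [ClassModel-class] (or a class x gene matrix).
#' @param stage tag recorded in the result (default "all_classes").
#' @param genes optional restriction of the fit to a gene subset (e.g. the
#'   model's merge genes).
#' @return a [DeconvolutionResult-class].
#' @export
nnlsFit <- function(bulk, model, stage = "all_classes", genes = NULL) {
    P <- if (is(model, "ClassModel")) classProfiles(model) else as.matrix(model)
    shared <- intersect(names(bulk), colnames(P))
    if (!is.null(genes)) shared <- intersect(shared, genes)
    if (!length(shared)) stop("invalid input: no shared genes")
    A <- t(P[, shared, drop = FALSE])            # gene x class design
    b <- as.numeric(bulk[shared])
    if (all(b == 0)) {
        w <- stats::setNames(numeric(nrow(P)), rownames(P))
        return(new("DeconvolutionResult", weights = w, proportions = w,
                   residual = 0, stage = stage, degenerate = TRUE))
    }
    fit <- pracma::lsqnonneg(A, b)
    w <- stats::setNames(pmax(fit$x, 0), rownames(P))
    tot <- sum(w)
    degenerate <- tot <= 0
    props <- if (degenerate) w * 0 else 100 * w / tot
    new("DeconvolutionResult", weights = w, proportions = props,
        residual = sqrt(sum((A %*% w - b)^2)), stage = stage,
        degenerate = degenerate)
}

#' Two-stage NNLS deconvolution against a labeled single-cell reference
#'
#' Stage 1 runs the full reference pipeline on all clusters — balanced
#' downsampling to the smallest cluster, per-cluster mean log profiles,
#' correlation-based merging into classes, NNLS fit of the bulk profile.
#' Stage 2 repeats the identical pipeline restricted to cholinergic-flagged
#' clusters, resolving the bulk signal into classes of cholinergic cell
#' types. Top-variance genes for merging are recomputed within each stage.
#'
#' @param bulk named numeric bulk expression vector (normalized scale; it is
#'   log-transformed with `log1p` to match the reference profiles unless
#'   `bulkIsLog = TRUE`).
#' @param counts gene x cell reference count matrix.
#' @param clusters cluster label per cell.
#' @param cholinergic named logical per cluster (names = cluster labels).
#' @param seed seed for the downsampling.
#' @param nTopVar,corrThreshold passed to [mergeClusters()].
#' @param bulkIsLog set TRUE when `bulk` is already on the log scale.
#' @return list with elements `stage1` and `stage2`
#'   ([DeconvolutionResult-class]) and the two [ClassModel-class] objects
#'   (`model1`, `model2`). When no cluster is flagged cholinergic, `stage2`
#'   and `model2` are `NULL` and a warning is raised; stage 1 is still
#'   returned.
#' @export
twoStageDeconvolve <- function(bulk, counts, clusters, cholinergic, seed,
                               nTopVar = 1000, corrThreshold = 0.8,
                               bulkIsLog = FALSE) {
    clusters <- as.character(clusters)
    missing <- setdiff(unique(clusters), names(cholinergic))
    if (length(missing))
        stop("clusters without a cholinergic flag: ",
             paste(missing, collapse = ", "))
    logBulk <- if (bulkIsLog) bulk else stats::setNames(log1p(bulk), names(bulk))
    runStage <- function(cts, cls, tag) {
        bal <- downsampleClusters(cts, cls, seed = seed)
        prof <- clusterProfiles(bal$counts, bal$clusters)
        model <- mergeClusters(prof, nTopVar = nTopVar,
                               corrThreshold = corrThreshold)
        list(fit = nnlsFit(logBulk, model, stage = tag), model = model)
    }
    s1 <- runStage(counts, clusters, "all_classes")
    cholClusters <- names(cholinergic)[cholinergic]
    s2 <- NULL
    if (!any(clusters %in% cholClusters)) {
        warning("no cholinergic clusters: stage 2 skipped")
    } else {
        keep <- clusters %in% cholClusters
        s2 <- runStage(counts[, keep, drop = FALSE], clusters[keep],
                       "cholinergic_only")
    }
    list(stage1 = s1$fit, model1 = s1$model,
         stage2 = if (is.null(s2)) NULL else s2$fit,
         model2 = if (is.null(s2)) NULL else s2$model)
}
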
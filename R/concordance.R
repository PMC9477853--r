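#' Pair two DE contrasts into a concordance table
#'
#' Joins two [DEResult-class] objects on their shared gene universe (inner
#' join; exclusions counted) and assigns each gene one of eight categories
#' from its (log fold change, significance) pair in each contrast:
#' `shared_up` / `shared_down` (significant in both, same sign),
#' `opposite` (significant in both, opposite signs), `x_specific_up` /
#' `x_specific_down` / `y_specific_up` / `y_specific_down` (significant in
#' one only), `stable` (significant in neither). Significance reuses the DE
#' call (fold and p thresholds) by default; `mode = "lfc-only"` instead
#' thresholds on `|lfc| > lfcCut` alone, the quadrant-count variant used for
#' activity-blockade comparisons.
#'
#' @param deX,deY [DEResult-class] objects for contrasts X and Y.
#' @param mode `"call"` (default; significance = DE call not stable) or
#'   `"lfc-only"`.
#' @param lfcCut log2 fold-change cutoff for `mode = "lfc-only"` (default 0).
#' @return a [ConcordanceTable-class].
#' @export
buildConcordance <- function(deX, deY, mode = c("call", "lfc-only"),
                             lfcCut = 0) {
    mode <- match.arg(mode)
    tx <- deTable(deX); ty <- deTable(deY)
    shared <- intersect(tx$gene, ty$gene)
    if (!length(shared)) stop("invalid input: no shared genes")
    excluded <- (nrow(tx) - length(shared)) + (nrow(ty) - length(shared))
    tx <- tx[match(shared, tx$gene), ]
    ty <- ty[match(shared, ty$gene), ]
    if (mode == "call") {
        sigX <- tx$call != "stable"
        sigY <- ty$call != "stable"
    } else {
        sigX <- abs(tx$log2FC) > lfcCut
        sigY <- abs(ty$log2FC) > lfcCut
    }
    upX <- tx$log2FC > 0; upY <- ty$log2FC > 0
    category <- rep("stable", length(shared))
    both <- sigX & sigY
    category[both & upX & upY] <- "shared_up"
    category[both & !upX & !upY] <- "shared_down"
    category[both & (upX != upY)] <- "opposite"
    category[sigX & !sigY & upX] <- "x_specific_up"
    category[sigX & !sigY & !upX] <- "x_specific_down"
    category[!sigX & sigY & upY] <- "y_specific_up"
    category[!sigX & sigY & !upY] <- "y_specific_down"
    tab <- data.frame(gene = shared, lfcX = tx$log2FC, lfcY = ty$log2FC,
                      sigX = sigX, sigY = sigY, category = category,
                      stringsAsFactors = FALSE, row.names = NULL)
    new("ConcordanceTable", table = tab, excluded = as.integer(excluded))
}

#' Summarize a concordance table
#'
#' Category counts, the core-program size (genes significant and
#' same-direction in both contrasts), and the recapitulation percents: of
#' the genes dynamic in contrast Y, the percent whose dynamics are
#' recapitulated (same direction, significant) in contrast X. The up
#' denominator is `shared_up + opposite-with-Y-up + y_specific_up`; a
#' variant excluding the opposite-regulated genes from the denominator is
#' also reported.
#'
#' @param x a [ConcordanceTable-class].
#' @return list with `counts` (named integer per category),
#'   `coreProgramSize`, `percentUpRecapitulated`,
#'   `percentDownRecapitulated`, and the `...NoOpposite` denominator
#'   variants. Percents are `NA` when no gene is Y-dynamic in that
#'   direction.
#' @export
summarizeConcordance <- function(x) {
    stopifnot(is(x, "ConcordanceTable"))
    tab <- concordanceTable(x)
    if (!nrow(tab)) stop("degenerate input: empty concordance table")
    counts <- vapply(.concordanceCategories,
                     function(cc) sum(tab$category == cc), integer(1))
    oppYUp <- sum(tab$category == "opposite" & tab$lfcY > 0)
    oppYDown <- sum(tab$category == "opposite" & tab$lfcY <= 0)
    pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    upDen <- counts["shared_up"] + oppYUp + counts["y_specific_up"]
    downDen <- counts["shared_down"] + oppYDown + counts["y_specific_down"]
    list(counts = counts,
         coreProgramSize = unname(counts["shared_up"] + counts["shared_down"]),
         percentUpRecapitulated = unname(pct(counts["shared_up"], upDen)),
         percentDownRecapitulated = unname(pct(counts["shared_down"], downDen)),
         percentUpRecapitulatedNoOpposite =
             unname(pct(counts["shared_up"], upDen - oppYUp)),
         percentDownRecapitulatedNoOpposite =
             unname(pct(counts["shared_down"], downDen - oppYDown)))
}

#' Pearson correlation of paired log fold changes
#'
#' @param x a [ConcordanceTable-class].
#' @param subset optional logical vector or gene character vector selecting
#'   rows; default all genes.
#' @return named numeric `c(r, p)`: Pearson r and the two-sided p-value from
#'   the linear-model t statistic.
#' @export
lfcCorrelation <- function(x, subset = NULL) {
    tab <- concordanceTable(x)
    if (!is.null(subset)) {
        if (is.character(subset)) subset <- tab$gene %in% subset
        tab <- tab[subset, , drop = FALSE]
    }
    if (nrow(tab) < 3) stop("invalid argument: need at least 3 genes")
    if (stats::sd(tab$lfcX) == 0 || stats::sd(tab$lfcY) == 0)
        stop("undefined correlation: zero variance in one axis")
    ct <- stats::cor.test(tab$lfcX, tab$lfcY, method = "pearson")
    c(r = unname(ct$estimate), p = ct$p.value)
}

#' Genes regulated in the same direction across independent datasets
#'
#' Given a focal up- and down-regulated gene set and one or more other
#' datasets' (up, down) sets, counts the focal genes regulated in the same
#' direction in every other dataset and reports the shared percent.
#'
#' @param focalUp,focalDown character vectors of focal gene sets.
#' @param others list of lists, each with elements `up` and `down`.
#' @return data.frame with rows `up` and `down`: `nFocal`, `nShared`,
#'   `percentShared` (`NA` for an empty focal set).
#' @examples
#' sharedAcrossDatasets(c("a", "b"), c("c"),
#'     list(list(up = c("a", "b"), down = c("c", "d"))))
#' @export
sharedAcrossDatasets <- function(focalUp, focalDown, others) {
    if (!length(others)) stop("invalid argument: need at least one other dataset")
    inter <- function(focal, key) {
        shared <- focal
        for (o in others) shared <- intersect(shared, o[[key]])
        shared
    }
    row <- function(focal, key) {
        shared <- inter(focal, key)
        data.frame(direction = key, nFocal = length(focal),
                   nShared = length(shared),
                   percentShared = if (length(focal))
                       100 * length(shared) / length(focal) else NA_real_)
    }
    rbind(row(focalUp, "up"), row(focalDown, "down"))
}
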
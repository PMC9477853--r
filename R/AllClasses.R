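#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   colData<- rowData
NULL

#' TimecourseExperiment: gene x sample counts with ordered timepoints
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' non-negative integer `counts` assay, per-sample `timepoint`, `replicate`
#' and `condition` columns, and the declared timepoint order in
#' `metadata(x)$timepointOrder`. All expression-level operations in the
#' package (`medianOfRatios()`, `normalizeCounts()`, `expressedGenes()`,
#' `deTest()`, `pcaSamples()`) consume this class.
#'
#' @slot .Data inherited SummarizedExperiment representation.
#' @seealso [TimecourseExperiment()] for the user-facing constructor.
#' @exportClass TimecourseExperiment
setClass("TimecourseExperiment", contains = "SummarizedExperiment")

setValidity("TimecourseExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    cd <- colData(object)
    for (f in c("timepoint", "replicate", "condition"))
        if (!f %in% colnames(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", f))
    tpo <- metadata(object)$timepointOrder
    if (is.null(tpo)) {
        msg <- c(msg, "metadata(x)$timepointOrder is required")
    } else if ("timepoint" %in% colnames(cd) &&
               !all(cd$timepoint %in% tpo)) {
        msg <- c(msg, "every sample timepoint must be in timepointOrder")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene IDs")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate sample IDs")
    if (length(msg)) msg else TRUE
})

#' Construct a TimecourseExperiment
#'
#' @param counts non-negative integer matrix, genes as rows, samples as
#'   columns; dimnames required.
#' @param timepoint character/factor of length `ncol(counts)`; values must be
#'   drawn from `timepointOrder`.
#' @param replicate integer replicate index per sample.
#' @param condition condition tag per sample (e.g. `"in_vivo"`,
#'   `"in_vitro"`); recycled if length 1.
#' @param timepointOrder character vector giving the developmental order of
#'   the timepoint labels. Defaults to the order of first appearance.
#'
#' @return A [TimecourseExperiment-class] object.
#' @examples
#' cts <- matrix(rpois(40, 50), nrow = 10,
#'               dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' tc <- TimecourseExperiment(cts, timepoint = rep(c("E10.5", "P21"), each = 2),
#'                            replicate = rep(1:2, 2))
#' tc
#' @export
TimecourseExperiment <- function(counts, timepoint,
                                 replicate = seq_len(ncol(counts)),
                                 condition = "in_vivo",
                                 timepointOrder = unique(as.character(timepoint))) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
    storage.mode(counts) <- "double"
    cd <- DataFrame(timepoint = as.character(timepoint),
                    replicate = as.integer(replicate),
                    condition = rep_len(as.character(condition), ncol(counts)),
                    row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    metadata(se)$timepointOrder <- as.character(timepointOrder)
    new("TimecourseExperiment", se)
}

#' @describeIn TimecourseExperiment ordered timepoint labels of the experiment.
#' @param x a `TimecourseExperiment`.
#' @export
timepointOrder <- function(x) metadata(x)$timepointOrder

#' @describeIn TimecourseExperiment per-sample timepoint labels.
#' @export
timepoints <- function(x) colData(x)$timepoint

#' DEResult: one two-group differential expression contrast
#'
#' Result container for [deTest()]: per-gene log2 fold change (group B over
#' group A), exact-test p-value, group means on the normalized scale, and the
#' up/down/stable call at the configured thresholds.
#'
#' @slot table data.frame with columns `gene`, `log2FC`, `pValue`, `meanA`,
#'   `meanB`, `call`.
#' @slot groupA,groupB character vectors of sample IDs.
#' @slot foldThreshold,pThreshold numeric calling thresholds (fold change is
#'   inclusive, p strict).
#' @slot dispersion the common NB dispersion used by the exact test.
#' @exportClass DEResult
setClass("DEResult",
    representation(table = "data.frame", groupA = "character",
                   groupB = "character", foldThreshold = "numeric",
                   pThreshold = "numeric", dispersion = "numeric"))

setValidity("DEResult", function(object) {
    tab <- object@table
    need <- c("gene", "log2FC", "pValue", "meanA", "meanB", "call")
    if (!all(need %in% colnames(tab)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tab)) {
        if (any(tab$pValue < 0 | tab$pValue > 1)) return("p-values outside [0,1]")
        if (!all(tab$call %in% c("up", "down", "stable")))
            return("call must be up/down/stable")
        lfcCut <- log2(object@foldThreshold)
        bad <- (tab$call == "up" &
                    !(tab$log2FC >= lfcCut & tab$pValue < object@pThreshold)) |
               (tab$call == "down" &
                    !(tab$log2FC <= -lfcCut & tab$pValue < object@pThreshold))
        if (any(bad)) return("calls inconsistent with thresholds")
    }
    TRUE
})

#' @describeIn DEResult the per-gene result table.
#' @param x a `DEResult`.
#' @export
deTable <- function(x) x@table

#' @describeIn DEResult named vector of up/down/stable calls.
#' @export
deCalls <- function(x) stats::setNames(x@table$call, x@table$gene)

#' ClassModel: merged single-cell reference for deconvolution
#'
#' Produced by [mergeClusters()]: the cluster-to-class assignment obtained by
#' average-linkage grouping on correlation distance over the top-variance
#' genes, and the class mean-log profiles used as the NNLS design.
#'
#' @slot assignment named character: cluster -> class.
#' @slot profiles class x gene matrix of mean log expression.
#' @slot clusterProfiles cluster x gene matrix the classes were merged from.
#' @slot genesUsed genes used to compute the merging correlations.
#' @slot corrThreshold the within-class correlation cutoff used.
#' @exportClass ClassModel
setClass("ClassModel",
    representation(assignment = "character", profiles = "matrix",
                   clusterProfiles = "matrix", genesUsed = "character",
                   corrThreshold = "numeric"))

setValidity("ClassModel", function(object) {
    if (!length(object@assignment)) return("at least one cluster required")
    if (is.null(names(object@assignment))) return("assignment must be named")
    if (!all(object@assignment %in% rownames(object@profiles)))
        return("every assigned class needs a profile row")
    if (anyDuplicated(names(object@assignment)))
        return("each cluster must be in exactly one class")
    TRUE
})

#' @describeIn ClassModel cluster-to-class assignment.
#' @param x a `ClassModel`.
#' @export
classAssignment <- function(x) x@assignment

#' @describeIn ClassModel class x gene profile matrix.
#' @export
classProfiles <- function(x) x@profiles

#' DeconvolutionResult: NNLS weights and proportions for one stage
#'
#' @slot weights named non-negative NNLS weights per class.
#' @slot proportions weights normalized to percent (all zero, with
#'   `degenerate = TRUE`, when every weight is zero).
#' @slot residual residual L2 norm of the fit.
#' @slot stage `"all_classes"` or `"cholinergic_only"` (or a custom tag).
#' @slot degenerate TRUE when the weight vector was all-zero.
#' @exportClass DeconvolutionResult
setClass("DeconvolutionResult",
    representation(weights = "numeric", proportions = "numeric",
                   residual = "numeric", stage = "character",
                   degenerate = "logical"))

setValidity("DeconvolutionResult", function(object) {
    if (any(object@weights < -1e-10)) return("weights must be non-negative")
    if (length(object@weights) != length(object@proportions))
        return("weights and proportions lengths differ")
    if (!object@degenerate &&
        abs(sum(object@proportions) - 100) > 1e-6)
        return("proportions must sum to 100%")
    if (object@residual < 0) return("residual must be non-negative")
    TRUE
})

#' @describeIn DeconvolutionResult raw NNLS weights.
#' @param x a `DeconvolutionResult`.
#' @export
deconvWeights <- function(x) x@weights

#' @describeIn DeconvolutionResult class proportions in percent.
#' @export
deconvProportions <- function(x) x@proportions

#' ConcordanceTable: paired-contrast fold-change classification
#'
#' Per-gene pairing of two differential expression contrasts (X, e.g. the in
#' vitro DIV0 to DIV28 series; Y, e.g. the in vivo E10.5 to P21 series) with
#' an exclusive category label.
#'
#' @slot table data.frame with columns `gene`, `lfcX`, `lfcY`, `sigX`,
#'   `sigY`, `category`.
#' @slot excluded number of genes dropped because they were tested in only
#'   one contrast.
#' @exportClass ConcordanceTable
setClass("ConcordanceTable",
    representation(table = "data.frame", excluded = "integer"))

.concordanceCategories <- c("shared_up", "shared_down", "opposite",
                            "x_specific_up", "x_specific_down",
                            "y_specific_up", "y_specific_down", "stable")

setValidity("ConcordanceTable", function(object) {
    tab <- object@table
    need <- c("gene", "lfcX", "lfcY", "sigX", "sigY", "category")
    if (!all(need %in% colnames(tab)))
        return(paste("table must have columns:", paste(need, collapse = ", ")))
    if (nrow(tab) && !all(tab$category %in% .concordanceCategories))
        return("unknown category label")
    if (anyDuplicated(tab$gene)) return("duplicate genes")
    TRUE
})

#' @describeIn ConcordanceTable the per-gene table.
#' @param x a `ConcordanceTable`.
#' @export
concordanceTable <- function(x) x@table

setMethod("show", "TimecourseExperiment", function(object) {
    callNextMethod()
    cat("timepoint order:", paste(timepointOrder(object), collapse = " < "),
        "\n")
})

setMethod("show", "DEResult", function(object) {
    tab <- object@table
    cat(sprintf("DEResult: %d genes, %d vs %d samples\n", nrow(tab),
                length(object@groupA), length(object@groupB)))
    cat(sprintf("  thresholds: fold >= %g (inclusive), p < %g\n",
                object@foldThreshold, object@pThreshold))
    cat(sprintf("  common dispersion: %.4g\n", object@dispersion))
    print(table(factor(tab$call, levels = c("up", "down", "stable"))))
})

setMethod("show", "ClassModel", function(object) {
    cat(sprintf("ClassModel: %d clusters -> %d classes (corr threshold %.2f)\n",
                length(object@assignment), nrow(object@profiles),
                object@corrThreshold))
    for (cl in rownames(object@profiles))
        cat(sprintf("  %s: %s\n", cl,
                    paste(names(object@assignment)[object@assignment == cl],
                          collapse = ", ")))
})

setMethod("show", "DeconvolutionResult", function(object) {
    cat(sprintf("DeconvolutionResult [%s]%s\n", object@stage,
                if (object@degenerate) " (degenerate: all weights zero)" else ""))
    df <- data.frame(weight = signif(object@weights, 4),
                     percent = round(object@proportions, 2))
    print(df)
    cat(sprintf("  residual: %.4g\n", object@residual))
})

setMethod("show", "ConcordanceTable", function(object) {
    cat(sprintf("ConcordanceTable: %d genes (%d excluded by inner join)\n",
                nrow(object@table), object@excluded))
    print(table(factor(object@table$category,
                       levels = .concordanceCategories)))
})
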
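#' @importFrom yaml read_yaml
NULL

.defaultThresholds <- function() {
    list(cpm = 5, fold = 2, p = 0.001, pcaMinReads = 10, tssCutoff = 2000,
         topN = 100000, corrThreshold = 0.8, windowBp = 50000)
}

#' Run the full maturation analysis pipeline from a config
#'
#' Orchestrates the stages in analysis order: normalization, expressed-gene
#' filtering, differential testing per consecutive timepoint transition,
#' temporal dynamics summary, sample PCA, then optionally paired-series
#' concordance, two-stage deconvolution, and peak-set dynamics. Each stage
#' writes provenanced TSVs into `outputDir` and its headline numbers land in
#' `summary.json`. Missing input files are enumerated before any computation
#' starts; a stage failure stops the run with earlier artifacts intact.
#'
#' @param config a named list or a YAML file path. Recognized fields:
#'   `counts`, `metadata` (required paths); `paired` (list with `counts`,
#'   `metadata`); `cells` (list with `counts`, `metadata` — cell metadata
#'   TSV needs columns `cell`, `cluster`, `cholinergic` — and `bulkSample`,
#'   a sample ID of the main experiment, or `bulk`, a TSV path with columns
#'   `gene`, `value`); `peaks` (list with `beds`: named list of BED paths in
#'   timepoint order, `tss` path, optional `chromSizes`); `thresholds`
#'   (overrides of cpm/fold/p/pcaMinReads/tssCutoff/topN/corrThreshold/
#'   windowBp); `seed`; `outputDir`.
#' @param outputDir overrides `config$outputDir`.
#' @return invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
runPipeline <- function(config, outputDir = NULL) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    thr <- utils::modifyList(.defaultThresholds(),
                             config$thresholds %||% list())
    seed <- config$seed %||% 1
    outDir <- outputDir %||% config$outputDir %||% stop("outputDir required")

    paths <- c(config$counts, config$metadata,
               config$paired$counts, config$paired$metadata,
               config$cells$counts, config$cells$metadata, config$cells$bulk,
               unlist(config$peaks$beds), config$peaks$tss,
               config$peaks$chromSizes)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
        stop("missing input files: ", paste(missing, collapse = ", "))
    if (!is.null(config$cells) && is.null(config$cells$bulk) &&
        is.null(config$cells$bulkSample))
        stop("deconvolution enabled but neither cells$bulk nor ",
             "cells$bulkSample is set")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(seed = seed, thresholds = thr)

    # expression core
    tc <- readCounts(config$counts, config$metadata)
    tc <- normalizeCounts(tc)
    writeProvenancedTable(
        data.frame(sample = colnames(tc), sizeFactor = colData(tc)$sizeFactor),
        file.path(outDir, "size_factors.tsv"), seed = seed)
    expressed <- expressedGenes(tc, cpmThreshold = thr$cpm)
    writeLines(expressed, file.path(outDir, "expressed_genes.txt"))
    summary$nExpressed <- length(expressed)

    tps <- timepointOrder(tc)
    deList <- list()
    for (i in seq_len(length(tps) - 1)) {
        ga <- colnames(tc)[timepoints(tc) == tps[i]]
        gb <- colnames(tc)[timepoints(tc) == tps[i + 1]]
        de <- deTest(tc, ga, gb, genes = expressed,
                     foldThreshold = thr$fold, pThreshold = thr$p)
        lab <- paste(tps[i], tps[i + 1], sep = "->")
        deList[[lab]] <- de
        writeDEResult(de, file.path(outDir,
            sprintf("de_%s_vs_%s.tsv", tps[i], tps[i + 1])))
    }
    dyn <- percentDynamic(deList, expressed)
    writeProvenancedTable(dyn, file.path(outDir, "transition_summary.tsv"),
                          seed = seed)
    summary$percentDynamic <- stats::setNames(
        as.list(dyn$percentDynamic), dyn$transition)

    pca <- pcaSamples(tc, minReads = thr$pcaMinReads)
    writeProvenancedTable(
        data.frame(sample = rownames(pca$scores), pca$scores,
                   check.names = FALSE),
        file.path(outDir, "pca_scores.tsv"), seed = seed)
    summary$pc1VarianceExplained <- pca$varianceExplained[1]

    # paired-series concordance
    if (!is.null(config$paired)) {
        pairTc <- readCounts(config$paired$counts, config$paired$metadata)
        ptps <- timepointOrder(pairTc)
        pexp <- expressedGenes(pairTc, cpmThreshold = thr$cpm)
        deY <- deTest(tc, colnames(tc)[timepoints(tc) == tps[1]],
                      colnames(tc)[timepoints(tc) == tps[length(tps)]],
                      genes = expressed,
                      foldThreshold = thr$fold, pThreshold = thr$p)
        deX <- deTest(pairTc,
                      colnames(pairTc)[timepoints(pairTc) == ptps[1]],
                      colnames(pairTc)[timepoints(pairTc) == ptps[length(ptps)]],
                      genes = pexp,
                      foldThreshold = thr$fold, pThreshold = thr$p)
        conc <- buildConcordance(deX, deY)
        writeProvenancedTable(concordanceTable(conc),
                              file.path(outDir, "concordance.tsv"),
                              seed = seed)
        cs <- summarizeConcordance(conc)
        summary$concordance <- cs[c("coreProgramSize",
                                    "percentUpRecapitulated",
                                    "percentDownRecapitulated")]
        summary$concordance$counts <- as.list(cs$counts)
        corr <- lfcCorrelation(conc)
        summary$concordance$r <- unname(corr["r"])
        summary$concordance$p <- unname(corr["p"])
    }

    # deconvolution
    if (!is.null(config$cells)) {
        cellMeta <- read.delim(config$cells$metadata, comment.char = "#",
                               stringsAsFactors = FALSE)
        cellCounts <- if (grepl("\\.mtx$", config$cells$counts)) {
            m <- as.matrix(Matrix::readMM(config$cells$counts))
            rownames(m) <- readLines(paste0(config$cells$counts, ".genes"))
            colnames(m) <- readLines(paste0(config$cells$counts, ".samples"))
            m
        } else {
            tab <- read.delim(config$cells$counts, comment.char = "#",
                              check.names = FALSE)
            m <- as.matrix(tab[, -1, drop = FALSE]); rownames(m) <- tab[[1]]
            m
        }
        cellMeta <- cellMeta[match(colnames(cellCounts), cellMeta$cell), ]
        chol <- tapply(as.logical(cellMeta$cholinergic), cellMeta$cluster,
                       any)
        bulk <- if (!is.null(config$cells$bulk)) {
            tab <- readProvenancedTable(config$cells$bulk)
            stats::setNames(tab$value, tab$gene)
        } else {
            norm <- SummarizedExperiment::assay(tc, "normalized")
            stats::setNames(norm[, config$cells$bulkSample],
                            rownames(norm))
        }
        dec <- twoStageDeconvolve(bulk, cellCounts, cellMeta$cluster,
                                  cholinergic = chol[unique(cellMeta$cluster)],
                                  seed = seed,
                                  corrThreshold = thr$corrThreshold)
        for (st in c("stage1", "stage2")) {
            if (is.null(dec[[st]])) next
            fit <- dec[[st]]
            writeProvenancedTable(
                data.frame(class = names(deconvWeights(fit)),
                           weight = deconvWeights(fit),
                           percent = deconvProportions(fit)),
                file.path(outDir, paste0("deconvolution_", st, ".tsv")),
                seed = seed,
                extra = list(stage = fit@stage,
                             corrThreshold = thr$corrThreshold))
        }
        summary$deconvolution <- list(
            stage1 = as.list(deconvProportions(dec$stage1)),
            stage2 = if (!is.null(dec$stage2))
                as.list(deconvProportions(dec$stage2)) else NULL)
    }

    # peak dynamics
    if (!is.null(config$peaks)) {
        beds <- lapply(config$peaks$beds, readBed)
        tss <- readTss(config$peaks$tss)
        labs <- names(beds) %||% paste0("tp", seq_along(beds))
        peakSummary <- list()
        for (i in seq_len(length(beds) - 1)) {
            gl <- gainLoss(beds[[i]], beds[[i + 1]], n = thr$topN)
            lab <- paste(labs[i], labs[i + 1], sep = "->")
            writeBed(gl$gained, file.path(outDir,
                sprintf("gained_%s_to_%s.bed", labs[i], labs[i + 1])))
            writeBed(gl$lost, file.path(outDir,
                sprintf("lost_%s_to_%s.bed", labs[i], labs[i + 1])))
            peakSummary[[lab]] <- list(percentGained = gl$percentGained,
                                       percentLost = gl$percentLost)
        }
        prox <- lapply(beds, classifyTssProximity, tss = tss,
                       cutoff = thr$tssCutoff)
        peakSummary$percentProximal <-
            stats::setNames(lapply(prox, `[[`, "percentProximal"), labs)
        summary$peaks <- peakSummary
    }

    summaryPath <- file.path(outDir, "summary.json")
    jsonlite::write_json(summary, summaryPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
    invisible(summary)
}

#' Write a self-contained demo input tree for [runPipeline()]
#'
#' Generates a small paired in vivo / in vitro time course (single
#' E10.5 -> P21 style transition), a labeled single-cell reference, and a
#' two-timepoint peak universe with TSS annotation, writes them in the
#' standard formats under `dir`, and returns a ready-to-run pipeline config
#' together with the generator truth. The defaults encode the study
#' conditions the package's synthetic checks assume: 40% of in vivo
#' dynamics recapitulated upward in vitro, 30% downward, and 20% of peaks
#' gained and lost per transition.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving every generator.
#' @param nGenes genes in the expression fixtures.
#' @param nPeaks peaks per timepoint.
#' @return list with `config` (pass to [runPipeline()]) and `truth`
#'   (per-stage generator ground truth).
#' @export
writeDemoFixtures <- function(dir, seed = 1, nGenes = 1200, nPeaks = 400) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    cfg <- timecourseConfig(nGenes = nGenes, timepoints = c("E10.5", "P21"),
                            replicates = 3, dynamicFraction = 0.4,
                            baseMeanLogRange = c(5, 9), dispersion = 0.05,
                            seed = seed)
    vivo <- simulateTimecourse(cfg)
    vitro <- simulatePairedSeries(vivo$truth, sharedUpFrac = 0.4,
                                  sharedDownFrac = 0.3, oppositeFrac = 0.05,
                                  seed = seed + 1,
                                  timepoints = c("DIV0", "DIV28"))
    writeCounts(vivo$experiment, file.path(dir, "vivo_counts.tsv"),
                file.path(dir, "vivo_meta.tsv"), seed = seed)
    writeCounts(vitro$experiment, file.path(dir, "vitro_counts.tsv"),
                file.path(dir, "vitro_meta.tsv"), seed = seed)

    chromSizes <- c(chr1 = 2e6, chr2 = 1e6)
    set.seed(seed + 2)
    tss <- data.frame(gene = sprintf("gene%04d", seq_len(60)),
                      chrom = sample(names(chromSizes), 60, replace = TRUE),
                      position = floor(stats::runif(60, 1e4, 9e5)),
                      strand = "+")
    write.table(tss, file.path(dir, "tss.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    pu <- simulatePeakUniverse(chromSizes, c("E10.5", "P21"),
                               nPeaks = nPeaks, gainFrac = 0.2,
                               lossFrac = 0.2, proximalFrac = 0.3,
                               tss = tss, seed = seed + 3)
    bedPaths <- list()
    for (tp in names(pu$peakSets)) {
        p <- file.path(dir, paste0("peaks_", tp, ".bed"))
        writeBed(pu$peakSets[[tp]], p)
        bedPaths[[tp]] <- p
    }
    config <- list(
        counts = file.path(dir, "vivo_counts.tsv"),
        metadata = file.path(dir, "vivo_meta.tsv"),
        paired = list(counts = file.path(dir, "vitro_counts.tsv"),
                      metadata = file.path(dir, "vitro_meta.tsv")),
        peaks = list(beds = bedPaths, tss = file.path(dir, "tss.tsv")),
        seed = seed,
        outputDir = file.path(dir, "results"))
    list(config = config,
         truth = list(vivo = vivo$truth, vitro = vitro$truth, peaks = pu$truth))
}
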
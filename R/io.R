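#' @importFrom utils read.delim write.table count.fields head tail
#' @importFrom Matrix readMM writeMM
#' @importFrom jsonlite write_json read_json
NULL

# ---- provenance -----------------------------------------------------------

.provenanceLines <- function(seed = NULL, extra = list()) {
    fields <- c(list(tool = paste0("maturekit ",
                                   as.character(utils::packageVersion("maturekit"))),
                     written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
                if (!is.null(seed)) list(seed = seed), extra)
    vapply(names(fields), function(k)
        sprintf("# %s: %s", k, paste(fields[[k]], collapse = " ")),
        character(1))
}

#' Write a data.frame as TSV with a provenance comment block
#'
#' The file starts with `#`-prefixed provenance lines (tool version,
#' timestamp, seed, any extra key/values); stripping them yields clean TSV.
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed seed to record, or NULL.
#' @param extra named list of extra provenance fields.
#' @export
writeProvenancedTable <- function(df, path, seed = NULL, extra = list()) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(.provenanceLines(seed, extra), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV written by [writeProvenancedTable()]
#' @param path file path.
#' @return data.frame (provenance comments skipped).
#' @export
readProvenancedTable <- function(path) {
    read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
               check.names = FALSE)
}

.readProvenance <- function(path) {
    lines <- readLines(path)
    lines <- lines[startsWith(lines, "#")]
    kv <- regmatches(lines, regexec("^# ([^:]+): (.*)$", lines))
    out <- list()
    for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
    out
}

# ---- counts ---------------------------------------------------------------

.checkRectangular <- function(path) {
    nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
    nf <- nf[!is.na(nf)]
    if (length(unique(nf)) > 1) {
        bad <- which(nf != nf[1])[1]
        stop("parse error in ", path, ": ragged row at data line ", bad,
             " (", nf[bad], " fields, expected ", nf[1], ")")
    }
}

#' Read a count matrix and sample metadata into a TimecourseExperiment
#'
#' The counts file is either TSV (genes as rows, first column gene IDs,
#' header = sample IDs) or MatrixMarket (`.mtx`, with gene and sample name
#' sidecar files). The metadata TSV must have columns `sample`, `timepoint`,
#' `replicate`, `condition`; its row order defines the timepoint order
#' unless a `timepointOrder` provenance field or argument is given.
#'
#' @param countsPath counts TSV or MTX path.
#' @param metadataPath sample metadata TSV path.
#' @param genesPath,samplesPath sidecar name files for MTX input (defaults:
#'   `<countsPath>.genes` / `<countsPath>.samples`, one name per line).
#' @param timepointOrder optional explicit timepoint order.
#' @return a [TimecourseExperiment-class].
#' @export
readCounts <- function(countsPath, metadataPath,
                       genesPath = paste0(countsPath, ".genes"),
                       samplesPath = paste0(countsPath, ".samples"),
                       timepointOrder = NULL) {
    if (grepl("\\.mtx$", countsPath)) {
        m <- as.matrix(Matrix::readMM(countsPath))
        rownames(m) <- readLines(genesPath)
        colnames(m) <- readLines(samplesPath)
    } else {
        .checkRectangular(countsPath)
        tab <- read.delim(countsPath, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
        if (anyDuplicated(tab[[1]]))
            stop("parse error: duplicate gene IDs: ",
                 paste(head(tab[[1]][duplicated(tab[[1]])], 3), collapse = ", "))
        m <- as.matrix(tab[, -1, drop = FALSE])
        rownames(m) <- tab[[1]]
    }
    if (!is.numeric(m)) stop("parse error: non-numeric counts")
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop("parse error: negative count at gene '", rownames(m)[neg[1, 1]],
             "', sample '", colnames(m)[neg[1, 2]], "'")
    meta <- read.delim(metadataPath, comment.char = "#",
                       stringsAsFactors = FALSE)
    need <- c("sample", "timepoint", "replicate", "condition")
    if (!all(need %in% colnames(meta)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    missing <- setdiff(colnames(m), meta$sample)
    if (length(missing))
        stop("samples missing from metadata: ", paste(missing, collapse = ", "))
    meta <- meta[match(colnames(m), meta$sample), ]
    if (is.null(timepointOrder)) timepointOrder <- unique(meta$timepoint)
    TimecourseExperiment(m, timepoint = meta$timepoint,
                         replicate = meta$replicate,
                         condition = meta$condition,
                         timepointOrder = timepointOrder)
}

#' Write a TimecourseExperiment to disk
#'
#' @param x a [TimecourseExperiment-class].
#' @param countsPath output counts path; `.mtx` selects MatrixMarket with
#'   `.genes`/`.samples` sidecars, anything else TSV.
#' @param metadataPath output metadata TSV path.
#' @param seed optional seed recorded in the provenance block.
#' @export
writeCounts <- function(x, countsPath, metadataPath, seed = NULL) {
    cts <- SummarizedExperiment::assay(x, "counts")
    if (grepl("\\.mtx$", countsPath)) {
        Matrix::writeMM(Matrix::Matrix(cts, sparse = TRUE), countsPath)
        writeLines(rownames(cts), paste0(countsPath, ".genes"))
        writeLines(colnames(cts), paste0(countsPath, ".samples"))
    } else {
        df <- data.frame(gene = rownames(cts), cts, check.names = FALSE)
        writeProvenancedTable(df, countsPath, seed = seed)
    }
    meta <- data.frame(sample = colnames(x),
                       timepoint = colData(x)$timepoint,
                       replicate = colData(x)$replicate,
                       condition = colData(x)$condition)
    writeProvenancedTable(meta, metadataPath, seed = seed,
                          extra = list(timepointOrder =
                                           paste(timepointOrder(x),
                                                 collapse = ",")))
    invisible(countsPath)
}

# ---- BED / bedGraph / annotation ------------------------------------------

#' Read a BED3+ file into a GRanges peak set
#'
#' Coordinates are BED-convention 0-based half-open on disk and converted to
#' the 1-based closed GRanges representation; an interval `chr1 0 100` has
#' width 100. Column 4 becomes `name`, column 5 `score` (0 when absent).
#' Malformed lines (start >= end, negative coordinates) are rejected with
#' their line numbers.
#'
#' @param path BED file path.
#' @return GRanges with `name` and `score` metadata columns.
#' @export
readBed <- function(path) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    if (!any(keep)) return(GRanges())
    fields <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineNo <- which(keep)
    n <- lengths(fields)
    if (any(n < 3))
        stop("parse error: fewer than 3 BED fields at line ",
             lineNo[which(n < 3)[1]])
    chrom <- vapply(fields, `[`, "", 1)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3)))
    bad <- which(is.na(start0) | is.na(end0) | start0 < 0 | start0 >= end0)
    if (length(bad))
        stop("parse error: invalid interval (need 0 <= start < end) at line ",
             lineNo[bad[1]])
    name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else "", "")
    score <- vapply(fields, function(f)
        if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
        numeric(1))
    score[is.na(score)] <- 0
    GRanges(chrom, IRanges(start0 + 1, end0), name = name, score = score)
}

#' Write a peak set as BED6
#'
#' @param peaks GRanges (optionally with `name`/`score`).
#' @param path output path.
#' @export
writeBed <- function(peaks, path) {
    name <- if (!is.null(peaks$name)) peaks$name
            else sprintf("peak%05d", seq_along(peaks))
    score <- if (!is.null(peaks$score)) pmin(round(peaks$score), 1000) else 0
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     name = name, score = score, strand = ".")
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    invisible(path)
}

#' Read a bedGraph score track
#' @param path bedGraph path.
#' @return GRanges with a `score` column.
#' @export
readBedGraph <- function(path) {
    rtracklayer::import(path, format = "bedGraph")
}

#' Write a score track as bedGraph
#' @param track GRanges with `score`.
#' @param path output path.
#' @export
writeBedGraph <- function(track, path) {
    rtracklayer::export(track, path, format = "bedGraph")
    invisible(path)
}

#' Read a TSS annotation TSV
#'
#' Four columns: `gene`, `chrom`, `position` (0-based TSS coordinate),
#' `strand`.
#'
#' @param path TSV path (header required).
#' @return data.frame with one primary TSS per gene.
#' @export
readTss <- function(path) {
    tss <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("gene", "chrom", "position")
    if (!all(need %in% colnames(tss)))
        stop("TSS annotation must have columns: ",
             paste(need, collapse = ", "))
    if (anyDuplicated(tss$gene))
        stop("parse error: multiple TSS rows for gene ",
             tss$gene[duplicated(tss$gene)][1])
    if (any(tss$position < 0)) stop("parse error: negative TSS position")
    tss
}

#' Read a two-column chrom-sizes file
#' @param path TSV with chromosome name and length.
#' @return named integer vector.
#' @export
readChromSizes <- function(path) {
    tab <- read.delim(path, header = FALSE, comment.char = "#",
                      stringsAsFactors = FALSE)
    sizes <- as.integer(tab[[2]])
    if (any(is.na(sizes) | sizes < 1)) stop("parse error: invalid chrom size")
    stats::setNames(sizes, tab[[1]])
}

# ---- DE results -----------------------------------------------------------

#' Write a DEResult as a provenanced TSV
#' @param de a [DEResult-class].
#' @param path output path.
#' @export
writeDEResult <- function(de, path) {
    writeProvenancedTable(deTable(de), path,
        extra = list(groupA = paste(de@groupA, collapse = ","),
                     groupB = paste(de@groupB, collapse = ","),
                     foldThreshold = de@foldThreshold,
                     pThreshold = de@pThreshold,
                     dispersion = de@dispersion))
}

#' Read a DEResult TSV written by [writeDEResult()]
#' @param path file path.
#' @return a [DEResult-class].
#' @export
readDEResult <- function(path) {
    tab <- readProvenancedTable(path)
    prov <- .readProvenance(path)
    new("DEResult", table = tab,
        groupA = strsplit(prov$groupA %||% "", ",")[[1]],
        groupB = strsplit(prov$groupB %||% "", ",")[[1]],
        foldThreshold = as.numeric(prov$foldThreshold %||% 2),
        pThreshold = as.numeric(prov$pThreshold %||% 0.001),
        dispersion = as.numeric(prov$dispersion %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
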
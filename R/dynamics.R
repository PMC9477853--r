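#' Percent of expressed genes dynamic at each consecutive transition
#'
#' Summarizes a list of [DEResult-class] objects, one per consecutive
#' timepoint pair, into up/down counts and percents of the expressed-gene
#' universe. No re-testing happens here: counts are tallied straight from
#' the stored calls, restricted to `expressed`.
#'
#' @param deResults named list of `DEResult`, in transition order; names are
#'   used as transition labels (default `"A->B"` style is up to the caller).
#' @param expressed character vector: the expressed-gene universe.
#' @return data.frame with one row per transition: `transition`, `nUp`,
#'   `nDown`, `percentUp`, `percentDown`, `percentDynamic`.
#' @export
percentDynamic <- function(deResults, expressed) {
    if (!length(expressed)) stop("degenerate input: empty expressed set")
    if (!length(deResults)) stop("invalid argument: no DE results")
    rows <- lapply(seq_along(deResults), function(i) {
        de <- deResults[[i]]
        stopifnot(is(de, "DEResult"))
        tab <- deTable(de)
        tab <- tab[tab$gene %in% expressed, , drop = FALSE]
        nUp <- sum(tab$call == "up"); nDown <- sum(tab$call == "down")
        data.frame(transition = if (!is.null(names(deResults)))
                       names(deResults)[i] else paste0("transition", i),
                   nUp = nUp, nDown = nDown,
                   percentUp = 100 * nUp / length(expressed),
                   percentDown = 100 * nDown / length(expressed),
                   percentDynamic = 100 * (nUp + nDown) / length(expressed),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Keyword-based effector categorization from gene descriptions
#'
#' Assigns each gene to a functional effector category from its symbol and
#' free-text description, using case-insensitive substring rules:
#' channels contain "channel"; receptors contain "receptor" but not
#' "nuclear"; collagens have a symbol beginning "Col" (case-sensitive,
#' canonical mouse capitalization); transcription factors contain
#' "transcription", or contain both "receptor" and "nuclear" (nuclear
#' receptors); chromatin regulators contain "histone" or "chromatin";
#' kinases contain "kinase". Unmatched genes get `"none"`.
#'
#' When `multiLabel = FALSE` colliding rules are resolved by the precedence
#' transcription_factor > chromatin_regulator > channel > receptor >
#' kinase > collagen.
#'
#' @param catalog data.frame with columns `symbol` and `description`
#'   (unique symbols).
#' @param multiLabel if TRUE, return a logical membership matrix (gene x
#'   category) instead of a single label per gene.
#' @return named character vector of categories (or a logical matrix when
#'   `multiLabel = TRUE`).
#' @examples
#' cat <- data.frame(symbol = c("Kcnq2", "Nr3c1", "Col5a3"),
#'     description = c("voltage-gated potassium channel subunit",
#'                     "nuclear receptor subfamily 3 group C member 1", ""))
#' categorizeEffectors(cat)
#' @export
categorizeEffectors <- function(catalog, multiLabel = FALSE) {
    stopifnot(all(c("symbol", "description") %in% colnames(catalog)))
    if (!nrow(catalog)) stop("invalid argument: empty catalog")
    if (anyDuplicated(catalog$symbol)) stop("duplicate symbols in catalog")
    desc <- tolower(ifelse(is.na(catalog$description), "",
                           catalog$description))
    has <- function(word) grepl(word, desc, fixed = TRUE)
    m <- cbind(
        transcription_factor = has("transcription") |
            (has("receptor") & has("nuclear")),
        chromatin_regulator = has("histone") | has("chromatin"),
        channel = has("channel"),
        receptor = has("receptor") & !has("nuclear"),
        kinase = has("kinase"),
        collagen = startsWith(catalog$symbol, "Col"))
    rownames(m) <- catalog$symbol
    if (multiLabel) return(m)
    lab <- apply(m, 1, function(row)
        if (any(row)) colnames(m)[which(row)[1]] else "none")
    stats::setNames(lab, catalog$symbol)
}

#' Fraction of each effector category induced over a contrast
#'
#' For each category, the percent of its expressed members that start below
#' an expression ceiling at the first timepoint (mean normalized expression
#' `< exprCeiling`) and are called up in the supplied first-to-last
#' contrast. Categories with no expressed members are reported `NA`.
#'
#' @param assignments named character vector from [categorizeEffectors()].
#' @param norm normalized expression matrix or `TimecourseExperiment`.
#' @param de a [DEResult-class] for the first-to-last transition; its
#'   `meanA` column is the first-timepoint mean used against the ceiling.
#' @param expressed character vector of expressed genes.
#' @param exprCeiling first-timepoint mean expression ceiling (default 100).
#' @return data.frame: `category`, `nExpressed`, `nInduced`,
#'   `percentInduced`.
#' @export
inducedFractionByCategory <- function(assignments, norm, de, expressed,
                                      exprCeiling = 100) {
    stopifnot(is(de, "DEResult"))
    tab <- deTable(de)
    cats <- setdiff(unique(assignments), "none")
    rows <- lapply(cats, function(cc) {
        members <- intersect(names(assignments)[assignments == cc], expressed)
        members <- intersect(members, tab$gene)
        if (!length(members))
            return(data.frame(category = cc, nExpressed = 0L, nInduced = NA,
                              percentInduced = NA))
        sub <- tab[match(members, tab$gene), ]
        induced <- sub$meanA < exprCeiling & sub$call == "up"
        data.frame(category = cc, nExpressed = length(members),
                   nInduced = sum(induced),
                   percentInduced = 100 * mean(induced))
    })
    do.call(rbind, rows)
}

#' Timing of marker-gene induction across two contrasts
#'
#' Fractions of a marker list called up in an early contrast (e.g. E10.5 to
#' E13.5) and a late contrast (e.g. P4 to P21), summarizing whether an
#' identity program is established embryonically or postnatally.
#'
#' @param markers character vector of marker genes; must all be tested in
#'   both contrasts.
#' @param earlyDE,lateDE [DEResult-class] objects.
#' @return named numeric: `fracEarlyUp`, `fracLateUp`.
#' @export
markerTiming <- function(markers, earlyDE, lateDE) {
    if (!length(markers)) stop("invalid argument: empty marker list")
    for (de in list(earlyDE, lateDE)) {
        missing <- setdiff(markers, deTable(de)$gene)
        if (length(missing))
            stop("markers not tested: ", paste(missing, collapse = ", "))
    }
    frac <- function(de) {
        calls <- deCalls(de)[markers]
        mean(calls == "up")
    }
    c(fracEarlyUp = frac(earlyDE), fracLateUp = frac(lateDE))
}
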
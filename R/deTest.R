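#' Negative-binomial exact test between two sample groups
#'
#' Two-group differential expression for one timepoint transition, following
#' the classic exact-test contract for overdispersed counts: counts are put
#' on a common scale by median-of-ratios normalization (equalized effective
#' library sizes), a single common NB dispersion is estimated across genes by
#' method of moments, and each gene's group sums are compared with a
#' two-sided conditional exact test under the negative binomial. The log2
#' fold change is computed on normalized group means with a pseudocount; the
#' p-value comes from the exact test, not the pseudocounted ratio.
#'
#' Calls are `up` when `log2FC >= log2(foldThreshold)` (inclusive) and
#' `pValue < pThreshold` (strict), symmetrically `down`, else `stable`.
#' Genes with zero counts in both groups are `stable` with p = 1.
#'
#' @param x a [TimecourseExperiment-class] or count matrix.
#' @param groupA,groupB character vectors of sample IDs (or column indices);
#'   the fold change is B over A (later over earlier).
#' @param genes optional gene subset to test (e.g. from [expressedGenes()]).
#' @param foldThreshold inclusive fold-change cutoff for calling (default 2).
#' @param pThreshold strict p-value cutoff for calling (default 0.001).
#' @param pseudocount added to both normalized means for the reported log2
#'   fold change (default 0.5 normalized units).
#' @param dispersion optional fixed common dispersion phi
#'   (variance = mu + phi * mu^2); estimated from the data when `NULL`.
#' @return a [DEResult-class].
#' @examples
#' sim <- simulateTimecourse(timecourseConfig(
#'     nGenes = 200, timepoints = c("t0", "t1"), replicates = 3, seed = 1))
#' tc <- sim$experiment
#' res <- deTest(tc, groupA = colnames(tc)[timepoints(tc) == "t0"],
#'               groupB = colnames(tc)[timepoints(tc) == "t1"])
#' res
#' @export
deTest <- function(x, groupA, groupB, genes = NULL, foldThreshold = 2,
                   pThreshold = 0.001, pseudocount = 0.5, dispersion = NULL) {
    cts <- .countsOf(x)
    groupA <- .resolveSamples(cts, groupA, "groupA")
    groupB <- .resolveSamples(cts, groupB, "groupB")
    if (!length(groupA) || !length(groupB))
        stop("invalid argument: empty sample group")
    if (length(intersect(groupA, groupB)))
        stop("invalid argument: groups overlap")
    sub <- cts[, c(groupA, groupB), drop = FALSE]
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(sub))
        if (length(missing))
            stop("genes not in matrix: ", paste(utils::head(missing, 5),
                                                collapse = ", "))
        sub <- sub[genes, , drop = FALSE]
    }
    if (all(colSums(sub[, groupA, drop = FALSE]) == 0) ||
        all(colSums(sub[, groupB, drop = FALSE]) == 0))
        stop("degenerate input: a group has zero total counts for all genes")

    sf <- tryCatch(medianOfRatios(sub),
                   error = function(e) {
                       tot <- colSums(sub)
                       tot / exp(mean(log(tot)))   # library-size fallback
                   })
    norm <- sweep(sub, 2, sf, "/")
    pseudo <- round(norm)     # equalized effective library sizes
    idxA <- match(groupA, colnames(sub))
    idxB <- match(groupB, colnames(sub))

    if (is.null(dispersion))
        dispersion <- .commonDispersion(pseudo, idxA, idxB)

    sA <- rowSums(pseudo[, idxA, drop = FALSE])
    sB <- rowSums(pseudo[, idxB, drop = FALSE])
    pvals <- nbExactPValue(sA, sB, length(idxA), length(idxB), dispersion)

    mA <- rowMeans(norm[, idxA, drop = FALSE])
    mB <- rowMeans(norm[, idxB, drop = FALSE])
    lfc <- log2((mB + pseudocount) / (mA + pseudocount))
    lfc[mA == 0 & mB == 0] <- 0

    lfcCut <- log2(foldThreshold)
    call <- rep("stable", nrow(sub))
    call[lfc >= lfcCut & pvals < pThreshold] <- "up"
    call[lfc <= -lfcCut & pvals < pThreshold] <- "down"

    tab <- data.frame(gene = rownames(sub), log2FC = unname(lfc),
                      pValue = unname(pvals), meanA = unname(mA),
                      meanB = unname(mB), call = call,
                      stringsAsFactors = FALSE, row.names = NULL)
    new("DEResult", table = tab, groupA = groupA, groupB = groupB,
        foldThreshold = foldThreshold, pThreshold = pThreshold,
        dispersion = dispersion)
}

.resolveSamples <- function(cts, g, what) {
    if (is.numeric(g)) g <- colnames(cts)[g]
    bad <- setdiff(g, colnames(cts))
    if (length(bad))
        stop("unknown samples in ", what, ": ", paste(bad, collapse = ", "))
    as.character(g)
}

# Method-of-moments common dispersion on the equalized counts. Per gene the
# within-group moments give an unbiased estimate of phi * mu^2 via
# (variance - mean); pooling numerators and denominators across genes and
# groups stabilizes the ratio without per-gene clipping bias.
.commonDispersion <- function(pseudo, idxA, idxB) {
    num <- 0; den <- 0
    for (idx in list(idxA, idxB)) {
        n <- length(idx)
        if (n < 2) next
        m <- rowMeans(pseudo[, idx, drop = FALSE])
        v <- apply(pseudo[, idx, drop = FALSE], 1, stats::var)
        keep <- m > 0
        num <- num + sum((v - m)[keep]) * (n - 1)
        den <- den + sum((m^2)[keep]) * (n - 1)
    }
    if (den <= 0) return(0)
    max(num / den, 0)
}

#' Conditional NB exact-test p-values for group sums
#'
#' For each gene, conditions on the total `sA + sB` and computes the
#' two-sided "double tail" p-value: the probability, under equal per-sample
#' means, of any split of the total at most as likely as the observed one.
#' Group sums of `n` iid NB(mu, phi) counts are NB with mean `n * mu` and
#' size `n / phi`; `phi = 0` reduces to Poisson, whose conditional law is
#' binomial.
#'
#' @param sA,sB integer group sums (vectors, one entry per gene).
#' @param nA,nB group sizes.
#' @param dispersion common NB dispersion phi.
#' @return numeric vector of p-values in \[0, 1\].
#' @export
nbExactPValue <- function(sA, sB, nA, nB, dispersion) {
    stopifnot(length(sA) == length(sB))
    vapply(seq_along(sA), function(i)
        .nbExactOne(sA[i], sB[i], nA, nB, dispersion), numeric(1))
}

.nbExactOne <- function(sA, sB, nA, nB, phi, bigTotal = 5e5) {
    tot <- sA + sB
    if (tot == 0) return(1)
    mu <- tot / (nA + nB)          # per-sample mean under the null
    if (tot > bigTotal)            # normal approximation to the conditional law
        return(.nbExactNormalApprox(sA, tot, nA, nB, mu, phi))
    s <- 0:tot
    if (phi <= 0) {
        la <- stats::dpois(s, nA * mu, log = TRUE)
        lb <- stats::dpois(tot - s, nB * mu, log = TRUE)
    } else {
        la <- stats::dnbinom(s, size = nA / phi, mu = nA * mu, log = TRUE)
        lb <- stats::dnbinom(tot - s, size = nB / phi, mu = nB * mu, log = TRUE)
    }
    lp <- la + lb
    obs <- lp[sA + 1]
    keep <- lp <= obs + 1e-8       # tolerance for ties in log space
    m <- max(lp)
    min(1, sum(exp(lp[keep] - m)) / sum(exp(lp - m)))
}

.nbExactNormalApprox <- function(sA, tot, nA, nB, mu, phi) {
    vA <- nA * mu * (1 + phi * mu)
    vB <- nB * mu * (1 + phi * mu)
    condMean <- tot * nA / (nA + nB)
    condVar <- vA * vB / (vA + vB)
    min(1, 2 * stats::pnorm(-abs(sA - condMean) / sqrt(condVar)))
}
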
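#' Configuration for the synthetic time-course generator
#'
#' Bundles and validates the parameters of [simulateTimecourse()]. Defaults
#' emulate a developmental nuclear RNA-seq design: seven ordered ages, three
#' replicates, strong early dynamics that taper with age, NB counts with a
#' single global dispersion and log-normal library-size variation.
#'
#' @param nGenes positive integer number of genes.
#' @param timepoints ordered character vector of timepoint labels
#'   (length >= 2).
#' @param replicates positive integer replicates per timepoint.
#' @param dynamicFraction fraction of genes dynamic at each transition;
#'   scalar or one value per transition, each in \[0, 1\].
#' @param lfcMagnitude absolute log2 effect of a dynamic gene (default 2,
#'   i.e. 4-fold).
#' @param baseMeanLogRange range (log2 units) of the per-gene baseline mean.
#' @param dispersion NB dispersion phi, variance = mu + phi mu^2.
#' @param librarySizeCV coefficient of variation of the log-normal
#'   per-sample library factors.
#' @param seed integer seed; the generator is a pure function of config +
#'   seed.
#' @return validated list of class `timecourseConfig`.
#' @export
timecourseConfig <- function(nGenes = 2000,
                             timepoints = c("E10.5", "E13.5", "P4", "P13",
                                            "P21", "P56", "P2yr"),
                             replicates = 3,
                             dynamicFraction = 0.2,
                             lfcMagnitude = 2,
                             baseMeanLogRange = c(3, 9),
                             dispersion = 0.1,
                             librarySizeCV = 0.1,
                             seed = 1) {
    if (length(nGenes) != 1 || nGenes < 1 || nGenes != round(nGenes))
        stop("invalid config: nGenes must be a positive integer")
    if (length(timepoints) < 2) stop("invalid config: need >= 2 timepoints")
    if (replicates < 1 || replicates != round(replicates))
        stop("invalid config: replicates must be a positive integer")
    nTrans <- length(timepoints) - 1
    dynamicFraction <- rep_len(dynamicFraction, nTrans)
    if (any(dynamicFraction < 0 | dynamicFraction > 1))
        stop("invalid config: dynamic fractions must be in [0, 1]")
    if (lfcMagnitude <= 0) stop("invalid config: lfcMagnitude must be > 0")
    if (dispersion < 0) stop("invalid config: dispersion must be >= 0")
    if (librarySizeCV < 0) stop("invalid config: librarySizeCV must be >= 0")
    structure(list(nGenes = as.integer(nGenes),
                   timepoints = as.character(timepoints),
                   replicates = as.integer(replicates),
                   dynamicFraction = dynamicFraction,
                   lfcMagnitude = lfcMagnitude,
                   baseMeanLogRange = baseMeanLogRange,
                   dispersion = dispersion,
                   librarySizeCV = librarySizeCV,
                   seed = as.integer(seed)),
              class = "timecourseConfig")
}

.cumsumRows <- function(m) {
    # row-wise cumulative sum that keeps matrix shape for a single column
    out <- m
    for (j in seq_len(ncol(m))[-1]) out[, j] <- out[, j - 1] + m[, j]
    out
}

.libFactors <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.rcounts <- function(n, mu, dispersion) {
    if (dispersion <= 0) stats::rpois(n, mu)
    else stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate an ordered time course with known per-gene trajectories
#'
#' Draws NB counts for an ordered multi-timepoint design. At each
#' transition, exactly `floor(dynamicFraction * nGenes)` genes (a seeded
#' sample, split evenly up/down) carry a log2 effect of
#' `+/- lfcMagnitude`; gene means follow
#' `baseMean * 2^(cumulative effect) * libraryFactor`.
#'
#' @param config a [timecourseConfig()].
#' @return list with `experiment` (a [TimecourseExperiment-class]) and
#'   `truth`, itself a list: `class` (gene x transition matrix of
#'   up/down/stable), `effect` (matching log2 effects, 0 iff stable),
#'   `libraryFactors` (per sample), `baseMean`, and the `config`.
#' @export
simulateTimecourse <- function(config) {
    stopifnot(inherits(config, "timecourseConfig"))
    .withSeed(config$seed, {
        G <- config$nGenes
        tps <- config$timepoints
        nT <- length(tps); nTrans <- nT - 1; R <- config$replicates
        genes <- sprintf("gene%04d", seq_len(G))
        baseMean <- 2^stats::runif(G, config$baseMeanLogRange[1],
                                   config$baseMeanLogRange[2])
        effect <- matrix(0, G, nTrans,
                         dimnames = list(genes,
                             paste(tps[-nT], tps[-1], sep = "->")))
        cls <- matrix("stable", G, nTrans, dimnames = dimnames(effect))
        for (t in seq_len(nTrans)) {
            nDyn <- floor(config$dynamicFraction[t] * G)
            if (nDyn == 0) next
            idx <- sample(G, nDyn)
            nUp <- ceiling(nDyn / 2)
            up <- idx[seq_len(nUp)]
            down <- idx[-seq_len(nUp)]
            effect[up, t] <- config$lfcMagnitude
            effect[down, t] <- -config$lfcMagnitude
            cls[up, t] <- "up"
            cls[down, t] <- "down"
        }
        cumLfc <- cbind(0, .cumsumRows(effect))
        mu <- baseMean * 2^cumLfc              # gene x timepoint means
        lib <- .libFactors(nT * R, config$librarySizeCV)
        sampleTp <- rep(tps, each = R)
        sampleRep <- rep(seq_len(R), nT)
        samples <- paste(sampleTp, sampleRep, sep = "_")
        counts <- matrix(0, G, nT * R, dimnames = list(genes, samples))
        for (s in seq_len(nT * R)) {
            tpIdx <- match(sampleTp[s], tps)
            counts[, s] <- .rcounts(G, mu[, tpIdx] * lib[s],
                                    config$dispersion)
        }
        experiment <- TimecourseExperiment(counts, timepoint = sampleTp,
                                           replicate = sampleRep,
                                           condition = "in_vivo",
                                           timepointOrder = tps)
        list(experiment = experiment,
             truth = list(class = cls, effect = effect,
                          libraryFactors = stats::setNames(lib, samples),
                          baseMean = stats::setNames(baseMean, genes),
                          config = config))
    })
}

#' Simulate a paired series recapitulating a fraction of the dynamics
#'
#' Generates a second (e.g. in vitro) count series over the genes of an
#' existing truth table. Per transition, exact counts of the first series'
#' dynamic genes are assigned: `floor(sharedUpFrac * nUp)` of the up genes
#' carry the same-direction effect, `floor(oppositeFrac * nUp)` the opposite
#' effect, the rest are flat (likewise for down genes with
#' `sharedDownFrac`). Assignment is by exact counts of a seeded shuffle, not
#' per-gene coin flips, so truth counts are deterministic.
#'
#' @param truth the `truth` element returned by [simulateTimecourse()].
#' @param sharedUpFrac,sharedDownFrac,oppositeFrac fractions in \[0, 1\];
#'   `sharedUpFrac + oppositeFrac <= 1` and
#'   `sharedDownFrac + oppositeFrac <= 1`.
#' @param seed integer seed.
#' @param timepoints labels for the paired series (default `DIV0 ...`, one
#'   per timepoint of the original design).
#' @param condition condition tag for the generated samples.
#' @return list with `experiment` and `truth`; the paired truth adds an
#'   `assignment` matrix with labels `shared_up`, `shared_down`, `opposite`,
#'   `flat`, `not_dynamic_in_first`.
#' @export
simulatePairedSeries <- function(truth, sharedUpFrac, sharedDownFrac,
                                 oppositeFrac, seed,
                                 timepoints = NULL, condition = "in_vitro") {
    cfg <- truth$config
    if (any(c(sharedUpFrac, sharedDownFrac, oppositeFrac) < 0))
        stop("invalid config: fractions must be >= 0")
    if (sharedUpFrac + oppositeFrac > 1 || sharedDownFrac + oppositeFrac > 1)
        stop("invalid config: fraction sums exceed 1")
    nTrans <- ncol(truth$class)
    if (is.null(timepoints))
        timepoints <- paste0("DIV", round(seq(0, 28,
                                              length.out = nTrans + 1)))
    stopifnot(length(timepoints) == nTrans + 1)
    .withSeed(seed, {
        G <- nrow(truth$class)
        genes <- rownames(truth$class)
        effect <- matrix(0, G, nTrans,
                         dimnames = list(genes,
                             paste(timepoints[-(nTrans + 1)],
                                   timepoints[-1], sep = "->")))
        assignment <- matrix("not_dynamic_in_first", G, nTrans,
                             dimnames = dimnames(effect))
        for (t in seq_len(nTrans)) {
            for (dir in c("up", "down")) {
                idx <- which(truth$class[, t] == dir)
                if (!length(idx)) next
                idx <- sample(idx)            # seeded shuffle, exact splits
                sharedFrac <- if (dir == "up") sharedUpFrac else sharedDownFrac
                nShared <- floor(sharedFrac * length(idx))
                nOpp <- floor(oppositeFrac * length(idx))
                shared <- idx[seq_len(nShared)]
                opp <- if (nOpp) idx[nShared + seq_len(nOpp)] else integer()
                flat <- idx[-seq_len(nShared + nOpp)]
                if (nShared + nOpp == 0) flat <- idx
                effect[shared, t] <- truth$effect[shared, t]
                effect[opp, t] <- -truth$effect[opp, t]
                assignment[shared, t] <- paste0("shared_", dir)
                assignment[opp, t] <- "opposite"
                assignment[flat, t] <- "flat"
            }
        }
        cls <- matrix("stable", G, nTrans, dimnames = dimnames(effect))
        cls[effect > 0] <- "up"
        cls[effect < 0] <- "down"
        cumLfc <- cbind(0, .cumsumRows(effect))
        mu <- truth$baseMean * 2^cumLfc
        nT <- nTrans + 1; R <- cfg$replicates
        lib <- .libFactors(nT * R, cfg$librarySizeCV)
        sampleTp <- rep(timepoints, each = R)
        sampleRep <- rep(seq_len(R), nT)
        samples <- paste(sampleTp, sampleRep, sep = "_")
        counts <- matrix(0, G, nT * R, dimnames = list(genes, samples))
        for (s in seq_len(nT * R)) {
            tpIdx <- match(sampleTp[s], timepoints)
            counts[, s] <- .rcounts(G, mu[, tpIdx] * lib[s], cfg$dispersion)
        }
        experiment <- TimecourseExperiment(counts, timepoint = sampleTp,
                                           replicate = sampleRep,
                                           condition = condition,
                                           timepointOrder = timepoints)
        list(experiment = experiment,
             truth = list(class = cls, effect = effect,
                          assignment = assignment,
                          libraryFactors = stats::setNames(lib, samples),
                          baseMean = truth$baseMean, config = cfg))
    })
}

#' Simulate a clustered single-cell reference with latent classes
#'
#' Builds cluster archetypes organized into transcriptional classes: within
#' a class, cluster log-mean profiles share a latent class component so
#' their pairwise correlation is `withinClassCorr` in expectation; between
#' classes the correlation is near zero. Cell counts are NB-sampled around
#' the cluster archetypes with log-normal per-cell depth variation.
#'
#' @param nClasses number of latent classes (>= 1).
#' @param clustersPerClass clusters per class.
#' @param cellsPerCluster integer vector of length
#'   `nClasses * clustersPerClass`.
#' @param nGenes number of genes.
#' @param withinClassCorr expected correlation of archetypes within a class.
#' @param seed integer seed.
#' @param dispersion NB dispersion of the cell counts (default 0.3).
#' @param depthCV coefficient of variation of per-cell depth (default 0.3).
#' @return list: `counts` (gene x cell), `clusters` (per cell),
#'   `clusterArchetypes` (cluster x gene log-mean), `classArchetypes`,
#'   `classTruth` (named cluster -> class).
#' @export
simulateCellReference <- function(nClasses, clustersPerClass, cellsPerCluster,
                                  nGenes, withinClassCorr = 0.9, seed = 1,
                                  dispersion = 0.3, depthCV = 0.3) {
    if (nClasses < 1) stop("invalid config: nClasses must be >= 1")
    nClusters <- nClasses * clustersPerClass
    if (length(cellsPerCluster) != nClusters)
        stop("invalid config: cellsPerCluster must have length ",
             "nClasses * clustersPerClass")
    if (withinClassCorr < 0 || withinClassCorr > 1)
        stop("invalid config: withinClassCorr must be in [0, 1]")
    .withSeed(seed, {
        genes <- sprintf("gene%04d", seq_len(nGenes))
        baseLog <- log(5)
        sigma <- 1.5
        rho <- withinClassCorr
        zClass <- matrix(stats::rnorm(nGenes * nClasses), nGenes, nClasses)
        clusterNames <- character(nClusters)
        archetype <- matrix(0, nClusters, nGenes,
                            dimnames = list(NULL, genes))
        classTruth <- character(nClusters)
        k <- 0
        for (cc in seq_len(nClasses)) for (j in seq_len(clustersPerClass)) {
            k <- k + 1
            zk <- stats::rnorm(nGenes)
            x <- sqrt(rho) * zClass[, cc] + sqrt(1 - rho) * zk
            archetype[k, ] <- baseLog + sigma * x
            clusterNames[k] <- sprintf("cluster%02d", k)
            classTruth[k] <- sprintf("class%d", cc)
        }
        rownames(archetype) <- clusterNames
        names(classTruth) <- clusterNames
        classArch <- t(vapply(unique(classTruth), function(cc)
            colMeans(archetype[classTruth == cc, , drop = FALSE]),
            numeric(nGenes)))
        totalCells <- sum(cellsPerCluster)
        counts <- matrix(0, nGenes, totalCells, dimnames = list(genes, NULL))
        clusters <- character(totalCells)
        depth <- .libFactors(totalCells, depthCV)
        cell <- 0
        for (k in seq_len(nClusters)) {
            mu <- exp(archetype[k, ])
            for (i in seq_len(cellsPerCluster[k])) {
                cell <- cell + 1
                counts[, cell] <- .rcounts(nGenes, mu * depth[cell],
                                           dispersion)
                clusters[cell] <- clusterNames[k]
            }
        }
        colnames(counts) <- sprintf("cell%05d", seq_len(totalCells))
        list(counts = counts, clusters = clusters,
             clusterArchetypes = archetype, classArchetypes = classArch,
             classTruth = classTruth)
    })
}

#' Simulate a bulk mixture of class profiles with known weights
#'
#' `bulk = sum_i w_i * profile_i + N(0, noiseSd)`, clipped at zero.
#'
#' @param profiles class x gene matrix (e.g. [classProfiles()] of a
#'   [ClassModel-class], or generated class archetypes).
#' @param weights non-negative weights, one per class.
#' @param noiseSd Gaussian noise standard deviation (default 0).
#' @param seed integer seed (only used when `noiseSd > 0`).
#' @return named numeric bulk expression vector over the profile genes.
#' @export
simulateBulkMixture <- function(profiles, weights, noiseSd = 0, seed = 1) {
    profiles <- as.matrix(profiles)
    if (length(weights) != nrow(profiles))
        stop("invalid config: weights length must equal number of classes")
    if (any(weights < 0)) stop("invalid config: negative weight")
    if (noiseSd < 0) stop("invalid config: negative noiseSd")
    bulk <- as.numeric(t(profiles) %*% weights)
    if (noiseSd > 0)
        bulk <- .withSeed(seed,
                          bulk + stats::rnorm(ncol(profiles), 0, noiseSd))
    stats::setNames(pmax(bulk, 0), colnames(profiles))
}

.seqinfoFor <- function(chromSizes) {
    GenomeInfoDb::Seqinfo(names(chromSizes), unname(as.integer(chromSizes)))
}

.placePeak <- function(chromSizes, tss, proximal, width, occ,
                       maxTries = 2000) {
    # occ: per-chromosome matrices of occupied (start0, end0) intervals
    for (i in seq_len(maxTries)) {
        if (proximal && nrow(tss)) {
            row <- tss[sample(nrow(tss), 1), ]
            mid <- row$position + round(stats::runif(1, -2000, 2000))
            chr <- row$chrom
        } else {
            chr <- sample(names(chromSizes), 1,
                          prob = as.numeric(chromSizes))
            mid <- floor(stats::runif(1, 0, chromSizes[[chr]]))
        }
        start0 <- mid - floor(width / 2)
        end0 <- start0 + width
        if (start0 < 0 || end0 > chromSizes[[chr]]) next
        if (!proximal && nrow(tss)) {
            d <- suppressWarnings(min(abs(mid - tss$position[tss$chrom == chr])))
            if (is.finite(d) && d <= 2000) next   # keep distal truly distal
        }
        taken <- occ[[chr]]
        if (!is.null(taken) &&
            any(taken[, 1] < end0 & taken[, 2] > start0)) next
        return(list(chrom = chr, start0 = start0, end0 = end0))
    }
    stop("generation error: could not place a non-overlapping peak (",
         maxTries, " tries)")
}

.occAdd <- function(occ, chrom, start0, end0) {
    occ[[chrom]] <- rbind(occ[[chrom]], c(start0, end0))
    occ
}

.occFromGRanges <- function(gr) {
    occ <- list()
    for (chr in unique(as.character(seqnames(gr)))) {
        sel <- as.character(seqnames(gr)) == chr
        occ[[chr]] <- cbind(start(gr)[sel] - 1L, end(gr)[sel])
    }
    occ
}

#' Simulate per-timepoint peak sets with known gain/loss truth
#'
#' Builds a first-timepoint peak set of `nPeaks` non-overlapping scored
#' intervals — a configured fraction placed with midpoint within 2 kb of a
#' TSS, the rest strictly farther — then, for each subsequent timepoint,
#' removes exactly `floor(lossFrac * nPeaks)` peaks and adds exactly
#' `floor(gainFrac * nPeaks)` new non-overlapping peaks (avoiding the
#' previous set, so gains and losses are exact under whole-feature
#' subtraction).
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param timepoints character vector of timepoint labels.
#' @param nPeaks peaks in the initial set.
#' @param gainFrac,lossFrac per-transition gain/loss fractions in \[0, 1\].
#' @param proximalFrac fraction of placed peaks proximal to a TSS.
#' @param tss TSS annotation data.frame (`gene`, `chrom`, `position`).
#' @param seed integer seed.
#' @param peakWidth interval width in bp (default 200).
#' @return list: `peakSets` (named list of sorted GRanges with `score` and
#'   `name`), `truth` with per-transition `gained`/`lost` peak names and
#'   expected percents, and per-peak `proximal` logicals.
#' @export
simulatePeakUniverse <- function(chromSizes, timepoints, nPeaks, gainFrac,
                                 lossFrac, proximalFrac, tss, seed,
                                 peakWidth = 200) {
    stopifnot(length(timepoints) >= 1, nPeaks >= 1)
    if (any(c(gainFrac, lossFrac, proximalFrac) < 0) ||
        any(c(gainFrac, lossFrac, proximalFrac) > 1))
        stop("invalid config: fractions must be in [0, 1]")
    .withSeed(seed, {
        si <- .seqinfoFor(chromSizes)
        empty <- GRanges(seqinfo = si)
        newPeaks <- function(nNew, avoid, tag) {
            # avoid: GRanges whose footprint must stay peak-free
            if (nNew == 0) return(empty)
            nProx <- floor(proximalFrac * nNew)
            occ <- .occFromGRanges(avoid)
            chrom <- character(nNew)
            start0 <- integer(nNew); end0 <- integer(nNew)
            for (i in seq_len(nNew)) {
                p <- .placePeak(chromSizes, tss, proximal = i <= nProx,
                                width = peakWidth, occ = occ)
                chrom[i] <- p$chrom; start0[i] <- p$start0; end0[i] <- p$end0
                occ <- .occAdd(occ, p$chrom, p$start0, p$end0)
            }
            out <- GRanges(chrom, IRanges(start0 + 1, end0), seqinfo = si)
            out$name <- sprintf("%s_peak%05d", tag, seq_len(nNew))
            out$score <- round(stats::runif(nNew, 20, 1000))
            out$proximal <- seq_len(nNew) <= nProx
            out
        }
        sets <- list()
        current <- newPeaks(nPeaks, empty, timepoints[1])
        sets[[timepoints[1]]] <- .sortPeaks(current)
        truth <- list()
        if (length(timepoints) > 1) for (t in 2:length(timepoints)) {
            nLose <- floor(lossFrac * nPeaks)
            nGain <- floor(gainFrac * nPeaks)
            loseIdx <- if (nLose) sample(length(current), nLose) else integer()
            kept <- if (nLose) current[-loseIdx] else current
            gained <- newPeaks(nGain, avoid = current, tag = timepoints[t])
            lost <- if (nLose) current[loseIdx] else empty
            nxt <- c(kept, gained)
            truth[[paste(timepoints[t - 1], timepoints[t], sep = "->")]] <-
                list(gained = gained$name, lost = lost$name,
                     percentGained = 100 * nGain / length(nxt),
                     percentLost = 100 * nLose / length(current))
            current <- nxt
            sets[[timepoints[t]]] <- .sortPeaks(current)
        }
        list(peakSets = sets, truth = truth)
    })
}

#' Simulate a piecewise-constant per-base score track
#'
#' Covers every chromosome with contiguous segments of geometric-ish random
#' length carrying uniform scores in \[0, 1\] (a conservation-track stand-in),
#' or a single constant score when `constant` is given.
#'
#' @param chromSizes named integer vector of chromosome lengths.
#' @param seed integer seed.
#' @param meanSegment mean segment length in bp (default 500).
#' @param constant when non-NULL, every base scores this value.
#' @return GRanges with a `score` column, covering the genome.
#' @export
simulateScoreTrack <- function(chromSizes, seed = 1, meanSegment = 500,
                               constant = NULL) {
    if (any(chromSizes < 1)) stop("invalid chrom sizes")
    .withSeed(seed, {
        segs <- lapply(names(chromSizes), function(chr) {
            L <- chromSizes[[chr]]
            if (!is.null(constant))
                return(GRanges(chr, IRanges(1, L), score = constant,
                               seqinfo = .seqinfoFor(chromSizes)))
            starts <- integer()
            pos <- 1
            while (pos <= L) {
                starts <- c(starts, pos)
                pos <- pos + max(1, stats::rgeom(1, 1 / meanSegment))
            }
            ends <- c(starts[-1] - 1, L)
            GRanges(chr, IRanges(starts, ends),
                    score = stats::runif(length(starts)),
                    seqinfo = .seqinfoFor(chromSizes))
        })
        do.call(c, segs)
    })
}
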
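#' Construct QC thresholds
#'
#' @param exonicLo,exonicHi retained nuclei satisfy
#'   `exonicLo <= pct_exonic <= exonicHi` (default 0.25--0.75).
#' @param mitoMax retained nuclei satisfy `pct_mito <= mitoMax` (default
#'   0.14).
#' @param geneMinCount,geneMinCells gene retained when its row total exceeds
#'   `geneMinCount` (default 10) and it is detected in at least
#'   `geneMinCells` nuclei (default 31).
#' @param doubletCut nuclei with doublet score at or above this are flagged
#'   (default 1.5).
#' @param identityMin minimum best identity score in percent (default 20);
#'   applied after classification, see [filterLowQuality()].
#' @return a \linkS4class{QCThresholds}.
#' @export
qcThresholds <- function(exonicLo = 0.25, exonicHi = 0.75, mitoMax = 0.14,
                         geneMinCount = 10, geneMinCells = 31,
                         doubletCut = 1.5, identityMin = 20) {
    new("QCThresholds", exonicLo = exonicLo, exonicHi = exonicHi,
        mitoMax = mitoMax, geneMinCount = geneMinCount,
        geneMinCells = geneMinCells, doubletCut = doubletCut,
        identityMin = identityMin)
}

emptyExclusionLog <- function() {
    S4Vectors::DataFrame(id = character(), stage = character(),
                         reason = character())
}

exclusionLog <- function(id, stage, reason) {
    id <- as.character(id)
    S4Vectors::DataFrame(id = id, stage = rep_len(stage, length(id)),
                         reason = rep_len(reason, length(id)))
}

#' Nucleus-level QC on exonic and mitochondrial fractions
#'
#' Retains nuclei with `exonicLo <= pct_exonic <= exonicHi` and
#' `pct_mito <= mitoMax`.  Each excluded nucleus appears exactly once in the
#' log with the first rule it failed.
#'
#' @param sce a `SingleCellExperiment` whose `colData` has `pct_exonic` and
#'   `pct_mito` columns (fractions in [0, 1]).
#' @param thr a \linkS4class{QCThresholds}.
#' @return list with elements `sce` (filtered) and `log` (a `DataFrame` of
#'   exclusions: id, stage, reason).
#' @export
filterNucleiQC <- function(sce, thr = qcThresholds()) {
    stopifnot(is(thr, "QCThresholds"))
    missing <- setdiff(c("pct_exonic", "pct_mito"), colnames(colData(sce)))
    if (length(missing))
        stop("configuration error: colData lacks column(s) ",
             paste(missing, collapse = ", "))
    ex <- colData(sce)$pct_exonic
    mt <- colData(sce)$pct_mito
    badExonic <- ex < thr@exonicLo | ex > thr@exonicHi
    badMito <- mt > thr@mitoMax
    keep <- !badExonic & !badMito
    reason <- ifelse(badExonic, "exonic", "mito")
    log <- exclusionLog(colnames(sce)[!keep], "nucleus_qc", reason[!keep])
    list(sce = sce[, keep], log = log)
}

#' Gene-level filter on total counts and detection breadth
#'
#' Default interpretation: a gene is kept when its row total is strictly
#' greater than `geneMinCount` and it is detected (count > 0) in at least
#' `geneMinCells` nuclei.  With `strict = TRUE` the literal reading is
#' applied instead: count strictly greater than `geneMinCount` in each of at
#' least `geneMinCells` nuclei (this removes nearly all genes at realistic
#' sequencing depth and exists for comparison only).
#'
#' @inheritParams filterNucleiQC
#' @param strict use the literal per-cell reading of the rule.
#' @return list with elements `sce` and `log` as in [filterNucleiQC()].
#' @export
filterGenes <- function(sce, thr = qcThresholds(), strict = FALSE) {
    stopifnot(is(thr, "QCThresholds"))
    m <- assay(sce, "counts")
    if (strict) {
        keep <- Matrix::rowSums(m > thr@geneMinCount) >= thr@geneMinCells
        reason <- rep("strict", sum(!keep))
    } else {
        totalOK <- Matrix::rowSums(m) > thr@geneMinCount
        detectOK <- Matrix::rowSums(m > 0) >= thr@geneMinCells
        keep <- totalOK & detectOK
        reason <- ifelse(!totalOK[!keep], "total", "detection")
    }
    log <- exclusionLog(rownames(sce)[!keep], "gene_filter", reason)
    list(sce = sce[keep, ], log = log)
}

#' Density-ratio doublet scores
#'
#' Simulated doublets are sums of randomly paired observed nuclei.  Nuclei
#' and simulated doublets are embedded in a reduced space with two kinds of
#' axes: standardized principal components of the depth-normalized
#' log2 expression (capturing profile mixing) and a standardized
#' log2-library-size axis (capturing the roughly doubled depth of a
#' doublet).  Each nucleus is scored by the ratio of the local density of
#' simulated doublets to the local density of observed nuclei, with
#' Gaussian-kernel estimates whose bandwidth is the median k-th
#' nearest-neighbour distance.  Scores are non-negative; in a homogeneous
#' singlet population they sit near zero, while true doublets score high on
#' both the depth and profile axes.  Nuclei scoring at or above the doublet
#' cut are candidate doublets.  This is a density-ratio scorer in the
#' spirit of the simulation-based doublet tools used for droplet data;
#' exact parity with any of them is not claimed.
#'
#' @inheritParams filterNucleiQC
#' @param nSim number of simulated doublets (default `2 * ncol(sce)`).
#' @param k neighbourhood size for the kernel bandwidth.
#' @param d number of profile principal components.
#' @param seed integer seed for pairing reproducibility.
#' @return named numeric vector of scores (one per nucleus).
#' @export
doubletScores <- function(sce, nSim = 2L * ncol(sce), k = 10L, d = 5L,
                          seed = 1L) {
    if (nSim < 1) stop("nSim must be at least 1")
    n <- ncol(sce)
    if (n < 20L) stop("need at least 20 nuclei to score doublets")
    set.seed(seed)
    counts <- as.matrix(assay(sce, "counts"))
    lib <- colSums(counts)
    if (any(lib == 0)) stop("all-zero nuclei present; filter first")
    med <- stats::median(lib)
    normLog <- function(m) t(log2(sweep(m, 2L, colSums(m), "/") * med + 1))

    d <- min(d, n - 1L, nrow(counts))
    pc <- stats::prcomp(normLog(counts), rank. = d, center = TRUE)
    sdd <- pmax(apply(pc$x, 2L, stats::sd), 1e-12)
    libMu <- mean(log2(lib))
    libSd <- max(stats::sd(log2(lib)), 1e-12)
    embed <- function(proj, l)
        cbind(sweep(proj, 2L, sdd, "/"), (log2(l) - libMu) / libSd)
    obs <- embed(pc$x, lib)

    i1 <- sample.int(n, nSim, replace = TRUE)
    shift <- sample.int(n - 1L, nSim, replace = TRUE)
    i2 <- 1L + (i1 - 1L + shift) %% n      # uniform partner != i1
    sm <- counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]
    sim <- embed(sweep(normLog(sm), 2L, pc$center) %*% pc$rotation,
                 colSums(sm))

    sqdist <- function(a, b) {
        out <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
        pmax(out, 0)
    }
    dObs <- sqdist(obs, obs)
    diag(dObs) <- Inf
    h2 <- stats::median(apply(dObs, 1L, function(z) sort(z, partial = k)[k]))
    dObs[!is.finite(dObs)] <- 0           # self term dropped below
    obsDens <- (rowSums(exp(-dObs / h2)) - 1) / (n - 1L)
    simDens <- rowSums(exp(-sqdist(obs, sim) / h2)) / nSim
    score <- simDens / obsDens
    names(score) <- colnames(sce)
    score
}
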
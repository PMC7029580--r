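#' Keep the most highly expressed genes by mean
#'
#' Retains genes whose mean expression lies strictly above the
#' `centralPct` quantile of all gene means (default: the top 5\%).  When
#' ties make the strict rule degenerate (e.g. all means equal), the top
#' `ceiling((1 - centralPct) * n)` genes by stable order are kept instead
#' and the fallback is flagged in the `"tie_fallback"` attribute.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or gene x nucleus
#'   matrix.
#' @param centralPct quantile defining the cut (default 0.95).
#' @return character vector of retained gene names.
#' @export
filterTopMean <- function(x, centralPct = 0.95) {
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    if (!nrow(m) || !ncol(m)) stop("empty expression matrix")
    mu <- Matrix::rowMeans(m)
    thr <- stats::quantile(mu, centralPct, names = FALSE)
    keep <- mu > thr
    fallback <- FALSE
    if (!any(keep)) {
        fallback <- TRUE
        nKeep <- ceiling((1 - centralPct) * length(mu) - 1e-9)
        keep <- seq_along(mu) %in% order(-mu)[seq_len(nKeep)]
    }
    out <- rownames(m)[keep]
    attr(out, "tie_fallback") <- fallback
    out
}

#' Differential gene--gene correlation between two conditions
#'
#' For every gene pair, computes Pearson correlations within each
#' condition, a z statistic for their difference (Fisher transforms scaled
#' by `sqrt(1/(nA-3) + 1/(nB-3))`) and an empirical p-value against a
#' permutation null: condition labels are permuted `nPerm` times and the
#' null |z| values of `nPairs` sampled pairs are pooled across pairs and
#' permutations (pooling is what makes p-values below `1/nPerm` reachable
#' with only 100 permutations; per-pair nulls are available via
#' `poolNull = FALSE`).  Pairs are also classed by their per-condition
#' sign/significance pattern (`+`, `-` or `0` at the 0.05 level of the
#' two-sided t test on r), e.g. `+/0` or `+/-`.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or gene x nucleus
#'   matrix (typically already restricted with [filterTopMean()]).
#' @param condition two-level factor (or coercible), one label per nucleus;
#'   each condition needs at least 4 nuclei.
#' @param nPerm number of label permutations (default 100).
#' @param nPairs number of pairs sampled per permutation for the pooled
#'   null (default 1000).
#' @param seed integer seed.
#' @param poolNull pool null |z| across pairs (default) or keep per-pair
#'   nulls.
#' @return data.frame with one row per pair: gene1, gene2, r per condition,
#'   n per condition, z_diff, p_empirical, p_adjusted (BH), class.  Genes
#'   with zero variance in either condition are skipped and recorded in the
#'   `"skipped_genes"` attribute.
#' @export
differentialCorrelation <- function(x, condition, nPerm = 100L,
                                    nPairs = 1000L, seed = 1L,
                                    poolNull = TRUE) {
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    m <- as.matrix(m)
    condition <- factor(condition)
    if (nlevels(condition) != 2L)
        stop("need exactly two conditions, got ", nlevels(condition))
    nA <- sum(condition == levels(condition)[1])
    nB <- sum(condition == levels(condition)[2])
    if (min(nA, nB) < 4L) stop("each condition needs at least 4 nuclei")
    set.seed(seed)

    vA <- matrixStats::rowVars(m[, condition == levels(condition)[1], drop = FALSE])
    vB <- matrixStats::rowVars(m[, condition == levels(condition)[2], drop = FALSE])
    skipped <- rownames(m)[vA == 0 | vB == 0]
    use <- vA > 0 & vB > 0
    m <- m[use, , drop = FALSE]
    p <- nrow(m)
    if (p < 2L) stop("fewer than 2 usable genes")

    scale <- sqrt(1 / (nA - 3) + 1 / (nB - 3))
    clamp <- function(r) pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
    zmat <- function(lab) {
        rA <- stats::cor(t(m[, lab == levels(condition)[1], drop = FALSE]))
        rB <- stats::cor(t(m[, lab == levels(condition)[2], drop = FALSE]))
        (atanh(clamp(rA)) - atanh(clamp(rB))) / scale
    }
    ut <- upper.tri(matrix(0, p, p))
    rA <- stats::cor(t(m[, condition == levels(condition)[1], drop = FALSE]))
    rB <- stats::cor(t(m[, condition == levels(condition)[2], drop = FALSE]))
    z <- ((atanh(clamp(rA)) - atanh(clamp(rB))) / scale)[ut]

    totalPairs <- sum(ut)
    sampleIdx <- if (totalPairs > nPairs)
        sort(sample.int(totalPairs, nPairs)) else seq_len(totalPairs)
    nullAbs <- matrix(NA_real_, length(sampleIdx), nPerm)
    for (b in seq_len(nPerm)) {
        lab <- condition[sample.int(length(condition))]
        nullAbs[, b] <- abs(zmat(lab)[ut][sampleIdx])
    }
    if (poolNull) {
        pooled <- sort(as.numeric(nullAbs))
        ge <- length(pooled) - findInterval(abs(z) - 1e-12, pooled)
        pEmp <- (1 + ge) / (1 + length(pooled))
    } else {
        # per-pair null only defined for the sampled pairs; others pooled
        pEmp <- rep(NA_real_, length(z))
        for (i in seq_along(sampleIdx))
            pEmp[sampleIdx[i]] <-
                (1 + sum(nullAbs[i, ] >= abs(z[sampleIdx[i]]) - 1e-12)) /
                (1 + nPerm)
        pooled <- sort(as.numeric(nullAbs))
        miss <- is.na(pEmp)
        ge <- length(pooled) - findInterval(abs(z[miss]) - 1e-12, pooled)
        pEmp[miss] <- (1 + ge) / (1 + length(pooled))
    }

    corClass <- function(r, n) {
        t <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
        sig <- 2 * stats::pt(-abs(t), n - 2) < 0.05
        ifelse(sig & r > 0, "+", ifelse(sig & r < 0, "-", "0"))
    }
    idx <- which(ut, arr.ind = TRUE)
    out <- data.frame(
        gene1 = rownames(m)[idx[, 1]], gene2 = rownames(m)[idx[, 2]],
        r_A = rA[ut], r_B = rB[ut], n_A = nA, n_B = nB,
        z_diff = z, p_empirical = pEmp,
        p_adjusted = stats::p.adjust(pEmp, "BH"),
        class = paste(corClass(rA[ut], nA), corClass(rB[ut], nB), sep = "/"),
        stringsAsFactors = FALSE)
    names(out)[names(out) == "r_A"] <- paste0("r_", levels(condition)[1])
    names(out)[names(out) == "r_B"] <- paste0("r_", levels(condition)[2])
    names(out)[names(out) == "n_A"] <- paste0("n_", levels(condition)[1])
    names(out)[names(out) == "n_B"] <- paste0("n_", levels(condition)[2])
    attr(out, "skipped_genes") <- skipped
    out
}
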
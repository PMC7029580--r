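#' Rank-based gene-set scores of cluster-average expression
#'
#' A contract-level implementation of the rank/random-walk gene-set scoring
#' used for cluster annotation: per gene, a Gaussian-kernel CDF estimate of
#' its expression across clusters (bandwidth `sd * m^(-1/5)` for `m`
#' clusters); per cluster, genes are ordered by these values and a weighted
#' Kolmogorov--Smirnov random walk is computed for each set, where set genes
#' step up proportionally to a symmetric rank weight and other genes step
#' down uniformly.  The score is the maximum deviation of the walk (the
#' `mx.diff = FALSE` convention).  Scores only depend on within-gene
#' orderings and kernel CDF values, so adding a constant to (or positively
#' rescaling) a gene's row leaves them unchanged.  Bit parity with any
#' released implementation is a non-goal; scores are used comparatively.
#'
#' @param clusterMeans gene x cluster matrix (>= 3 clusters) of average
#'   normalized expression, see [clusterMeans()].
#' @param genesets a \linkS4class{GeneSetList}; sets with fewer than 2 genes
#'   in the matrix are skipped with a warning.
#' @param tau exponent on the rank weight (1 = the usual choice).
#' @return set x cluster matrix of enrichment scores.
#' @export
gsvaScores <- function(clusterMeans, genesets, tau = 1) {
    X <- as.matrix(clusterMeans)
    p <- nrow(X); m <- ncol(X)
    if (m < 3L) stop("need at least 3 clusters (columns), got ", m)
    sets <- intersectSets(genesets, rownames(X), minSize = 2L, onEmpty = "skip")
    if (!length(sets)) stop("no usable gene sets")

    # Gaussian-kernel CDF estimate per gene across clusters
    Z <- matrix(0, p, m, dimnames = dimnames(X))
    h <- matrixStats::rowSds(X) * m^(-1 / 5)
    h[h == 0 | !is.finite(h)] <- 1e-8
    for (i in seq_len(p))
        Z[i, ] <- colMeans(stats::pnorm(outer(-X[i, ], X[i, ], "+") / h[i]))

    w <- abs(p / 2 - seq_len(p) + 0.5)^tau   # symmetric rank weight
    es <- matrix(NA_real_, length(sets), m,
                 dimnames = list(names(sets), colnames(X)))
    setIdx <- lapply(sets, function(g) rownames(X) %in% g)
    for (j in seq_len(m)) {
        ord <- order(Z[, j], decreasing = TRUE)
        for (s in seq_along(sets)) {
            inSet <- setIdx[[s]][ord]
            msize <- sum(inSet)
            up <- cumsum(w * inSet) / sum(w[inSet])
            down <- if (p > msize) cumsum(!inSet) / (p - msize) else rep(0, p)
            v <- up - down
            es[s, j] <- v[which.max(abs(v))]
        }
    }
    es
}

#' Row z-scaling for display
#'
#' @param x numeric matrix; constant rows are left at zero.
#' @export
zScaleRows <- function(x) {
    mu <- rowMeans(x)
    sd <- matrixStats::rowSds(x)
    sd[sd == 0] <- 1
    (x - mu) / sd
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric p-value for the overlap of a query gene list
#' with each set, BH-adjusted across sets.  A generic replacement for
#' web-service GO enrichment: bring your own annotation sets.
#'
#' @param query character vector of genes; must be a subset of `universe`.
#' @param genesets a \linkS4class{GeneSetList}.
#' @param universe character vector of all testable genes.
#' @return data.frame with columns set, overlap, set_size, query_size,
#'   universe_size, p_value, fdr.
#' @export
hypergeomEnrich <- function(query, genesets, universe) {
    if (!length(universe)) stop("empty universe")
    universe <- unique(universe)
    query <- unique(query)
    if (!all(query %in% universe))
        stop("query contains genes outside the universe: ",
             paste(head(setdiff(query, universe), 5L), collapse = ", "))
    sets <- lapply(geneSets(genesets), intersect, universe)
    res <- lapply(names(sets), function(nm) {
        K <- length(sets[[nm]])
        k <- length(intersect(query, sets[[nm]]))
        p <- stats::phyper(k - 1, K, length(universe) - K, length(query),
                           lower.tail = FALSE)
        data.frame(set = nm, overlap = k, set_size = K,
                   query_size = length(query),
                   universe_size = length(universe), p_value = p)
    })
    res <- do.call(rbind, res)
    res$fdr <- stats::p.adjust(res$p_value, "BH")
    res
}
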
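#' Coarse pre-grouping of nuclei for pooled normalization
#'
#' Groups nuclei by rank-correlation-distance (Spearman) hierarchical
#' clustering, the coarse stratification used for pooled size-factor
#' estimation.  Among tree cuts whose groups all reach `minSize`, the cut
#' with the highest average silhouette is used; when no cut shows real
#' separation a single group is returned, so homogeneous data are not
#' split.  With fewer than `2 * minSize` nuclei a single group is returned
#' with a warning.
#'
#' @param sce a `SingleCellExperiment` (or bare count matrix).
#' @param minSize minimum group size.
#' @return factor of group labels, one per nucleus.
#' @export
quickClusterNuclei <- function(sce, minSize = 50L) {
    m <- if (is(sce, "SummarizedExperiment")) assay(sce, "counts") else sce
    n <- ncol(m)
    if (n < 2L * minSize) {
        warning("too few nuclei (", n, ") for min group size ", minSize,
                "; returning a single group")
        return(factor(rep(1L, n)))
    }
    ranks <- apply(as.matrix(m), 2L, rank)
    D <- 1 - stats::cor(ranks)
    hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
    # among cuts whose groups all reach minSize, take the one with the best
    # silhouette; below a minimal separation keep a single group
    best <- rep(1L, n)
    bestSil <- 0.1
    for (k in 2:max(2L, n %/% minSize)) {
        labs <- stats::cutree(hc, k)
        if (min(table(labs)) < minSize) next
        sil <- mean(cluster::silhouette(labs, dmatrix = D)[, "sil_width"])
        if (sil > bestSil) {
            best <- labs
            bestSil <- sil
        }
    }
    factor(best)
}

#' Pooled (deconvolution) size factors
#'
#' Estimates per-nucleus size factors by pooling counts within coarse groups
#' and deconvolving the pooled estimates, then rescales so the global
#' geometric mean of the factors is exactly one.  Nuclei whose deconvolved
#' factor is non-positive fall back to a library-size factor (matched to the
#' scale of the valid deconvolved factors); their barcodes are recorded in
#' the `"fallback"` attribute.
#'
#' @param sce a `SingleCellExperiment` or count matrix with no all-zero
#'   nuclei.
#' @param clusters optional grouping factor from [quickClusterNuclei()].
#' @return named numeric vector of positive size factors with geometric mean
#'   1; attribute `"fallback"` lists nuclei that required the library-size
#'   fallback.
#' @export
computeSizeFactors <- function(sce, clusters = NULL) {
    m <- if (is(sce, "SummarizedExperiment")) assay(sce, "counts") else sce
    lib <- Matrix::colSums(m)
    if (any(lib == 0)) stop("all-zero nuclei present; filter first")
    if (is.null(clusters)) clusters <- factor(rep(1L, ncol(m)))
    minCl <- min(table(clusters))
    sizes <- unique(pmin(c(21L, 41L, 61L), minCl))
    f <- suppressWarnings(scran::calculateSumFactors(
        m, clusters = clusters, sizes = sizes, positive = FALSE,
        min.mean = 0.05))
    bad <- !is.finite(f) | f <= 0
    if (any(bad)) {
        ratio <- stats::median(f[!bad] / lib[!bad])
        f[bad] <- lib[bad] * ratio
    }
    f <- f / exp(mean(log(f)))
    names(f) <- colnames(m)
    attr(f, "fallback") <- colnames(m)[bad]
    f
}

#' Log-normalize counts with size factors
#'
#' Computes `log2(count / factor + 1)` and stores it as the `logcounts`
#' assay; the factors are stored as the object's size factors.  Zeros map to
#' zero, so sparsity is preserved.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param factors positive size factors from [computeSizeFactors()]; default
#'   recomputes them with a single group.
#' @return `sce` with a `logcounts` assay added.
#' @export
logNormalize <- function(sce, factors = computeSizeFactors(sce)) {
    stopifnot(all(factors > 0), length(factors) == ncol(sce))
    m <- assay(sce, "counts")
    if (is(m, "CsparseMatrix")) {
        norm <- m
        norm@x <- norm@x / rep.int(as.numeric(factors), diff(norm@p))
        norm@x <- log2(norm@x + 1)
    } else {
        norm <- log2(sweep(as.matrix(m), 2L, as.numeric(factors), "/") + 1)
    }
    SingleCellExperiment::logcounts(sce) <- norm
    SingleCellExperiment::sizeFactors(sce) <- as.numeric(factors)
    sce
}

#' Per-cluster mean expression
#'
#' @param logexpr gene x nucleus matrix (usually `logcounts`).
#' @param labels cluster label per nucleus.
#' @return gene x cluster matrix of means.
#' @export
clusterMeans <- function(logexpr, labels) {
    labels <- factor(labels)
    out <- vapply(levels(labels), function(l) {
        Matrix::rowMeans(logexpr[, labels == l, drop = FALSE])
    }, numeric(nrow(logexpr)))
    rownames(out) <- rownames(logexpr)
    out
}
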
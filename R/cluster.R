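#' Low-dimensional embedding of nuclei
#'
#' Either an exact PCA (top components of the log-expression matrix) or a
#' t-SNE embedding (run on the top 50 principal components, deterministic
#' under a fixed seed).  t-SNE is the embedding the pre-clustering step of
#' the emulated study used; PCA is offered as the linear alternative.
#'
#' @param x a `SingleCellExperiment` with `logcounts`, or a gene x nucleus
#'   matrix.
#' @param method `"tsne"` or `"pca"`.
#' @param nDim number of output dimensions (2 or 3).
#' @param perplexity t-SNE perplexity; must be below `(n - 1) / 3`.
#' @param seed integer seed.
#' @return nuclei x `nDim` coordinate matrix.
#' @export
embedNuclei <- function(x, method = c("tsne", "pca"), nDim = 2L,
                        perplexity = 30, seed = 1L) {
    method <- match.arg(method)
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    X <- t(as.matrix(m))
    n <- nrow(X)
    set.seed(seed)
    if (method == "pca") {
        coord <- stats::prcomp(X, rank. = nDim, center = TRUE)$x
    } else {
        maxPerp <- (n - 1) / 3
        if (perplexity >= maxPerp)
            stop("perplexity too large for ", n, " nuclei; must be below ",
                 format(maxPerp, digits = 4))
        coord <- Rtsne::Rtsne(X, dims = nDim, perplexity = perplexity,
                              pca = TRUE, initial_dims = min(50L, ncol(X), n - 1L),
                              check_duplicates = FALSE)$Y
        rownames(coord) <- rownames(X)
    }
    colnames(coord) <- paste0(method, seq_len(ncol(coord)))
    coord
}

#' Shared-nearest-neighbour pre-clustering
#'
#' Builds an SNN graph on embedding coordinates --- edges connect mutual
#' k-nearest neighbours, weighted by the number of neighbours shared between
#' their two k-NN lists (zero-weight edges are dropped) --- and partitions
#' it by walktrap community detection.  Small `kSnn` deliberately
#' over-partitions into many homogeneous pre-clusters, which the identity
#' classifier then audits and agglomerates.
#'
#' @param coords nuclei x dims coordinate matrix from [embedNuclei()].
#' @param kSnn number of nearest neighbours (>= 2, < number of nuclei).
#' @param seed integer seed (community detection is deterministic given the
#'   graph; the seed guards any internal tie-breaking).
#' @return factor of pre-cluster labels.
#' @export
snnPrecluster <- function(coords, kSnn = 6L, seed = 1L) {
    n <- nrow(coords)
    if (kSnn < 2L) stop("kSnn must be at least 2")
    if (kSnn >= n) stop("kSnn must be smaller than the number of nuclei (", n, ")")
    set.seed(seed)
    nn <- BiocNeighbors::findKNN(coords, k = kSnn, warn.ties = FALSE)
    inc <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kSnn),
                                j = as.integer(t(nn$index)), x = 1,
                                dims = c(n, n))
    shared <- Matrix::tcrossprod(inc)     # [i, j] = |kNN(i) /\ kNN(j)|
    mutual <- inc * Matrix::t(inc)        # edges only between mutual kNN
    w <- shared * mutual
    # exact duplicates are the same point: always connect them (arbitrary
    # k-NN tie-breaking must not fragment ties)
    dup <- as.vector(t(nn$distance == 0))
    if (any(dup)) {
        zadj <- Matrix::sparseMatrix(i = rep(seq_len(n), each = kSnn)[dup],
                                     j = as.integer(t(nn$index))[dup],
                                     x = 1, dims = c(n, n))
        zadj <- (zadj + Matrix::t(zadj)) > 0
        w <- w + zadj * (shared + 1)
    }
    Matrix::diag(w) <- 0
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    comm <- igraph::cluster_walktrap(g)
    labs <- factor(igraph::membership(comm))
    if (!is.null(rownames(coords))) names(labs) <- rownames(coords)
    labs
}

# SC3-style symmetric normalized graph Laplacian of a distance matrix
normLaplacian <- function(D) {
    A <- exp(-D / max(D))
    dd <- 1 / sqrt(rowSums(A))
    diag(nrow(A)) - (A * dd) * rep(dd, each = nrow(A))
}


#' Consensus k-means sub-clustering
#'
#' For every combination of distance measure (Euclidean, Pearson, Spearman),
#' spectral transform (PCA of the distance matrix, or eigenvectors of its
#' normalized graph Laplacian) and dimensionality `d` in `dRange`, runs
#' k-means on the first `d` components.  The consensus matrix is the mean of
#' the binary co-clustering matrices over all runs; final labels are a
#' hierarchical (complete-linkage) cut of the consensus at `k`, and each
#' cluster's average silhouette width is computed on consensus distances.
#' k-means uses ten random restarts per run; under a fixed seed the whole
#' procedure is reproducible, and with genuine cluster structure the result
#' is equivariant under reordering of nuclei (every restart converges to
#' the same partition).
#'
#' @param x `SingleCellExperiment` with `logcounts`, or gene x nucleus
#'   matrix (already restricted to one master class; the contract is that
#'   sub-clustering never sees other classes' nuclei).
#' @param k number of clusters (>= 2; requires at least `5 * k` nuclei).
#' @param dRange integer vector of component counts; default 4--7\% of the
#'   number of nuclei (at most 15 values), the usual consensus-clustering
#'   convention.
#' @param distances,transforms subsets of the defaults, mainly for testing.
#' @param seed integer seed for the k-means restarts.
#' @return a \linkS4class{ConsensusResult}.
#' @export
consensusSubcluster <- function(x, k,
                                dRange = NULL,
                                distances = c("euclidean", "pearson", "spearman"),
                                transforms = c("pca", "laplacian"),
                                seed = 1L) {
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    X <- t(as.matrix(m))
    n <- nrow(X)
    k <- as.integer(k)
    if (k < 2L) stop("k must be at least 2")
    if (k > n / 2) stop("k = ", k, " too large for ", n, " nuclei")
    if (n < 5L * k) stop("need at least 5 * k = ", 5L * k, " nuclei, got ", n)
    distances <- match.arg(distances, several.ok = TRUE)
    transforms <- match.arg(transforms, several.ok = TRUE)
    if (is.null(dRange)) {
        dRange <- floor(0.04 * n):ceiling(0.07 * n)
        dRange <- dRange[dRange >= 2L & dRange <= n - 1L]
        if (!length(dRange)) dRange <- min(4L, n - 1L)
        if (length(dRange) > 15L)
            dRange <- unique(round(seq(min(dRange), max(dRange),
                                       length.out = 15L)))
    }
    stopifnot(all(dRange >= 1L), all(dRange <= n))
    set.seed(seed)

    distMat <- function(type) switch(type,
        euclidean = as.matrix(stats::dist(X)),
        pearson = 1 - stats::cor(t(X)),
        spearman = 1 - stats::cor(apply(X, 1L, rank)))
    consensus <- matrix(0, n, n)
    runs <- 0L
    for (dt in distances) {
        D <- distMat(dt)
        for (tr in transforms) {
            comp <- if (tr == "pca") {
                stats::prcomp(D, center = TRUE, scale. = TRUE)$x
            } else {
                ev <- eigen(normLaplacian(D), symmetric = TRUE)
                ev$vectors[, order(ev$values), drop = FALSE]
            }
            for (d in dRange) {
                cl <- stats::kmeans(comp[, seq_len(min(d, ncol(comp))),
                                         drop = FALSE], centers = k,
                                    nstart = 10L, iter.max = 100L)$cluster
                consensus <- consensus + outer(cl, cl, "==")
                runs <- runs + 1L
            }
        }
    }
    consensus <- consensus / runs
    dimnames(consensus) <- list(rownames(X), rownames(X))
    hc <- stats::hclust(stats::as.dist(1 - consensus), method = "complete")
    labels <- factor(stats::cutree(hc, k))
    sil <- cluster::silhouette(as.integer(labels), dmatrix = 1 - consensus)
    perCluster <- tapply(sil[, "sil_width"], labels, mean)
    new("ConsensusResult", consensus = consensus, labels = labels,
        silhouette = stats::setNames(as.numeric(perCluster), levels(labels)),
        k = k,
        params = list(distances = distances, transforms = transforms,
                      dRange = dRange, seed = seed))
}
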
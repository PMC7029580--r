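#' AUROC + rank-test cluster markers
#'
#' For every gene and cluster, computes the area under the ROC curve of the
#' gene's expression separating that cluster from all other nuclei
#' (equivalently the rank-sum statistic scaled to [0, 1], with half credit
#' for ties) and a two-sided Wilcoxon rank test p-value, adjusted with the
#' Holm method within each cluster.  Records are retained when
#' `auroc > aurocMin` and adjusted p below `pMax`; the p threshold is a
#' knob because both 0.05 and 0.01 are conventional.
#'
#' @param x `SingleCellExperiment` with `logcounts`, or gene x nucleus
#'   matrix.
#' @param labels cluster label per nucleus; at least two clusters.
#' @param aurocMin minimum AUROC (default 0.65).
#' @param pMax maximum Holm-adjusted p (default 0.05).
#' @param filter return only passing records (default) or all.
#' @return data.frame with columns gene, cluster, auroc, p_value,
#'   p_adjusted, sorted by cluster then decreasing AUROC.
#' @export
aurocMarkers <- function(x, labels, aurocMin = 0.65, pMax = 0.05,
                         filter = TRUE) {
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    m <- as.matrix(m)
    lab <- factor(labels)
    if (nlevels(lab) < 2L) stop("need at least two clusters")
    stopifnot(ncol(m) == length(lab))
    r <- matrixStats::rowRanks(m, ties.method = "average")
    out <- lapply(levels(lab), function(cl) {
        inC <- lab == cl
        n1 <- sum(inC); n2 <- sum(!inC)
        R1 <- rowSums(r[, inC, drop = FALSE])
        auroc <- (R1 - n1 * (n1 + 1) / 2) / (n1 * n2)
        p <- apply(m, 1L, function(v)
            stats::wilcox.test(v[inC], v[!inC], exact = FALSE)$p.value)
        p[is.na(p)] <- 1   # constant genes
        data.frame(gene = rownames(m), cluster = cl, auroc = auroc,
                   p_value = p, p_adjusted = stats::p.adjust(p, "holm"),
                   row.names = NULL)
    })
    out <- do.call(rbind, out)
    if (filter) out <- out[out$auroc > aurocMin & out$p_adjusted < pMax, ]
    out <- out[order(out$cluster, -out$auroc, out$gene), ]
    rownames(out) <- NULL
    out
}

#' Pairwise Welch-t cluster markers against a log-fold-change threshold
#'
#' For each cluster and each other cluster, tests every gene's mean
#' log2-expression difference against the threshold `lfcThreshold` (a
#' shifted-null Welch t-test, so significance requires the fold change to
#' exceed the threshold, not merely zero).  With `direction = "any"` the
#' test is two-sided.  Per gene, p-values are combined across the
#' comparisons by Simes' rule and converted to a BH FDR within each
#' cluster.  Genes with zero variance in some cluster are handled by a
#' small variance floor and recorded in the `"floored_genes"` attribute.
#'
#' @inheritParams aurocMarkers
#' @param lfcThreshold log2 fold-change threshold (default 0.5).
#' @param direction `"any"` (two-sided), `"up"` or `"down"`.
#' @return named list with one data.frame per cluster: columns `gene`, one
#'   `lfc.<other>` per comparison, `lfc_sum`, `p_combined`, `fdr`.
#' @export
pairwiseTMarkers <- function(x, labels, lfcThreshold = 0.5,
                             direction = c("any", "up", "down")) {
    direction <- match.arg(direction)
    m <- if (is(x, "SummarizedExperiment")) logcounts(x) else x
    m <- as.matrix(m)
    lab <- factor(labels)
    if (nlevels(lab) < 2L) stop("need at least two clusters")
    sizes <- table(lab)
    if (any(sizes < 3L))
        stop("every cluster needs at least 3 nuclei; too small: ",
             paste(names(sizes)[sizes < 3L], collapse = ", "))
    mu <- vapply(levels(lab), function(l)
        rowMeans(m[, lab == l, drop = FALSE]), numeric(nrow(m)))
    vr <- vapply(levels(lab), function(l)
        matrixStats::rowVars(m[, lab == l, drop = FALSE]), numeric(nrow(m)))
    floored <- rownames(m)[rowSums(vr == 0) > 0]
    vr <- pmax(vr, 1e-8)
    n <- as.numeric(sizes)
    names(n) <- levels(lab)

    tables <- lapply(levels(lab), function(cl) {
        others <- setdiff(levels(lab), cl)
        lfc <- matrix(NA_real_, nrow(m), length(others),
                      dimnames = list(rownames(m), paste0("lfc.", others)))
        pmat <- matrix(NA_real_, nrow(m), length(others))
        for (j in seq_along(others)) {
            o <- others[j]
            d <- mu[, cl] - mu[, o]
            se <- sqrt(vr[, cl] / n[cl] + vr[, o] / n[o])
            df <- se^4 / ((vr[, cl] / n[cl])^2 / (n[cl] - 1) +
                          (vr[, o] / n[o])^2 / (n[o] - 1))
            pmat[, j] <- switch(direction,
                any = stats::pt((abs(d) - lfcThreshold) / se, df,
                                lower.tail = FALSE) +
                      stats::pt((abs(d) + lfcThreshold) / se, df,
                                lower.tail = FALSE),
                up = stats::pt((d - lfcThreshold) / se, df,
                               lower.tail = FALSE),
                down = stats::pt((-d - lfcThreshold) / se, df,
                                 lower.tail = FALSE))
            lfc[, j] <- d
        }
        # Simes combination across the comparisons for this cluster
        pComb <- apply(pmat, 1L, function(p) {
            p <- sort(p)
            min(pmin(length(p) * p / seq_along(p), 1))
        })
        df <- data.frame(gene = rownames(m), lfc, check.names = FALSE,
                         row.names = NULL)
        df$lfc_sum <- rowSums(lfc)
        df$p_combined <- pComb
        df$fdr <- stats::p.adjust(pComb, "BH")
        df
    })
    names(tables) <- levels(lab)
    attr(tables, "floored_genes") <- floored
    tables
}

#' Ranked, specificity-filtered marker lists
#'
#' Builds the per-cluster marker lists: genes are ranked by the descending
#' sum of their log-fold changes against all other clusters, and any gene
#' with one or more negative per-comparison fold changes, or an FDR above
#' the cut, is excluded even if its sum is large --- negative fold changes
#' mean the gene is higher somewhere else, so keeping it would sacrifice
#' specificity.
#'
#' @param tables output of [pairwiseTMarkers()].
#' @param fdrMax FDR cut (default 0.05).
#' @return named list of character vectors (ordered gene lists per cluster);
#'   ties in `lfc_sum` are broken alphabetically for stability.
#' @export
rankedMarkerList <- function(tables, fdrMax = 0.05) {
    lapply(tables, function(tab) {
        lfcCols <- grep("^lfc\\.", colnames(tab))
        anyNeg <- rowSums(tab[, lfcCols, drop = FALSE] < 0) > 0
        keep <- tab[!anyNeg & tab$fdr <= fdrMax, , drop = FALSE]
        keep$gene[order(-keep$lfc_sum, keep$gene)]
    })
}

#' Top-marker export table
#'
#' One column per cluster, padded with empty strings; the shape used for
#' publication-style marker tables.
#' @param rankedLists output of [rankedMarkerList()].
#' @param n number of genes per cluster.
#' @export
topMarkerTable <- function(rankedLists, n = 10L) {
    cols <- lapply(rankedLists, function(g) c(head(g, n), rep("", max(0L, n - length(g)))))
    as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
}
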
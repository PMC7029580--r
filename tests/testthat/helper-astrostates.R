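library(SingleCellExperiment)
library(Matrix)

# adjusted Rand index between two labelings
ari <- function(a, b) {
    t <- table(a, b)
    n <- sum(t)
    si <- sum(choose(t, 2))
    sa <- sum(choose(rowSums(t), 2))
    sb <- sum(choose(colSums(t), 2))
    e <- sa * sb / choose(n, 2)
    (si - e) / ((sa + sb) / 2 - e)
}

# minimal SingleCellExperiment around a count matrix
toySCE <- function(counts, condition = NULL, pct_exonic = NULL,
                   pct_mito = NULL) {
    counts <- as(as.matrix(counts), "CsparseMatrix")
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("C%03d", seq_len(ncol(counts)))
    cd <- DataFrame(row.names = colnames(counts))
    if (!is.null(condition)) cd$condition <- condition
    if (!is.null(pct_exonic)) cd$pct_exonic <- pct_exonic
    if (!is.null(pct_mito)) cd$pct_mito <- pct_mito
    SingleCellExperiment(assays = list(counts = counts), colData = cd)
}

# small simulated cohort shared by several tests
smallCohort <- function(seed = 42L, nPerClass = 30L, nGenes = 600L, ...) {
    simulateCohort(simConfig(nPerClass = nPerClass, nGenes = nGenes,
                             seed = seed, ...))
}
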
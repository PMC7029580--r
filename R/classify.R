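MASTER_CLASS_ORDER <- c("Neuron", "Astrocyte", "Oligodendrocyte", "OPC",
                        "Microglia", "Endothelial")

#' Per-nucleus identity scores
#'
#' The identity score of a nucleus for a cell class is the percentage of
#' that class's marker genes detected (raw count > 0) in the nucleus, out of
#' the marker genes present in the matrix's gene universe.  Scores are
#' invariant to any monotone transform of the counts that preserves zero
#' versus non-zero, so counts and log-normalized expression give identical
#' results.
#'
#' @param x a `SingleCellExperiment` (counts assay used) or a gene x nucleus
#'   matrix.
#' @param genesets a \linkS4class{GeneSetList} of class marker lists; an
#'   error names any class whose list has no genes in the universe.
#' @return numeric matrix, nuclei x classes, of scores in [0, 100].
#' @export
identityScores <- function(x, genesets = cellClassMarkers()) {
    m <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    detected <- m > 0
    sets <- intersectSets(genesets, rownames(m), onEmpty = "error")
    scores <- vapply(sets, function(g) {
        100 * Matrix::colSums(detected[g, , drop = FALSE]) / length(g)
    }, numeric(ncol(m)))
    if (ncol(m) == 1L) scores <- matrix(scores, nrow = 1L,
                                        dimnames = list(colnames(m), names(sets)))
    rownames(scores) <- colnames(m)
    scores
}

#' Assign classes from identity scores with ambiguity flagging
#'
#' Each nucleus is assigned the class with its highest score (argmax), with
#' ties broken by a fixed class order for determinism.  The ambiguity rule
#' compares the flatness of the score curve: with top-three scores
#' `s1 >= s2 >= s3`, the nucleus is ambiguous when `s2 + s3 > rho * s1`.
#' The default `rho = 1` operationalizes the published "flattened curve"
#' idea; `rho = 2` preserves the rule exactly as printed, but that
#' inequality can never hold for strictly ordered scores (since
#' `s2 + s3 <= 2 * s1`), so the literal mode never flags anything ---
#' both modes are provided and neither intent is guessed.
#' Nuclei with all-zero scores are assigned "Unknown" and flagged ambiguous.
#'
#' @param scores matrix from [identityScores()].
#' @param rho ambiguity ratio threshold (> 0); 1 by default, 2 for the
#'   literal printed rule.
#' @param identityMin quality floor in percent: nuclei whose best score is
#'   below it fail `qualityPass`.
#' @param tieOrder class order used to break argmax ties.
#' @return an \linkS4class{IdentityProfile}.
#' @export
assignClasses <- function(scores, rho = 1, identityMin = 20,
                          tieOrder = MASTER_CLASS_ORDER) {
    stopifnot(rho > 0, is.matrix(scores))
    order_ <- c(intersect(tieOrder, colnames(scores)),
                setdiff(colnames(scores), tieOrder))
    s <- scores[, order_, drop = FALSE]
    n <- nrow(s)
    assigned <- character(n)
    ambiguous <- logical(n)
    for (i in seq_len(n)) {
        v <- s[i, ]
        if (all(v == 0)) {
            assigned[i] <- "Unknown"
            ambiguous[i] <- TRUE
            next
        }
        assigned[i] <- order_[which.max(v)]   # first max in tie order
        top <- sort(v, decreasing = TRUE)
        top <- c(top, 0, 0)                   # pad for < 3 classes
        ambiguous[i] <- (top[2] + top[3]) > rho * top[1]
    }
    new("IdentityProfile", scores = scores, assignedClass = assigned,
        ambiguous = ambiguous,
        qualityPass = matrixStats::rowMaxs(scores) >= identityMin,
        params = list(rho = rho, identityMin = identityMin,
                      tieOrder = order_))
}

#' Drop low-quality nuclei by identity score
#'
#' Removes nuclei whose best identity score falls below the quality floor
#' (the score threshold lives in \linkS4class{QCThresholds} for
#' configuration unity but is applied here, once scores exist).
#'
#' @param sce a `SingleCellExperiment` aligned with `profile`.
#' @param profile an \linkS4class{IdentityProfile} for the same nuclei.
#' @return list with elements `sce`, `profile` (both filtered) and `log`.
#' @export
filterLowQuality <- function(sce, profile) {
    stopifnot(ncol(sce) == length(assignedClass(profile)))
    keep <- qualityPass(profile)
    log <- exclusionLog(colnames(sce)[!keep], "identity_qc", "identity")
    prof <- new("IdentityProfile",
        scores = profile@scores[keep, , drop = FALSE],
        assignedClass = profile@assignedClass[keep],
        ambiguous = profile@ambiguous[keep],
        qualityPass = profile@qualityPass[keep], params = profile@params)
    list(sce = sce[, keep], profile = prof, log = log)
}

#' Flag pre-clusters with mixed class enrichment
#'
#' A pre-cluster is called mixed when at least two classes have enrichment
#' scores within `delta` (a fraction of the global score range) of the
#' cluster's maximum --- i.e. no single class dominates.  This
#' operationalizes the manual inspection of enrichment heatmaps used to
#' spot lineage-discordant pre-clusters.
#'
#' @param enrichment matrix of enrichment scores, clusters x classes (e.g.
#'   the transpose of [gsvaScores()] output on pre-cluster mean expression).
#' @param delta closeness margin as a fraction of the score range.
#' @return named logical vector, one flag per cluster (row).
#' @export
flagMixed <- function(enrichment, delta = 0.1) {
    stopifnot(is.matrix(enrichment), ncol(enrichment) >= 2L)
    margin <- delta * diff(range(enrichment))
    out <- apply(enrichment, 1L, function(v) sum(v >= max(v) - margin) >= 2L)
    names(out) <- rownames(enrichment)
    out
}

#' Resolve mixed pre-clusters by per-nucleus argmax class
#'
#' Nuclei belonging to mixed pre-clusters are split into new clusters named
#' `<Class>_r<original>` according to each nucleus's argmax identity class;
#' clean pre-clusters pass through untouched.  Provenance (original label,
#' whether reassigned) is retained.
#'
#' @param preclusters pre-cluster label per nucleus.
#' @param mixed named logical per pre-cluster, from [flagMixed()].
#' @param profile an \linkS4class{IdentityProfile} aligned with
#'   `preclusters`.
#' @return a `DataFrame` with columns `precluster`, `resolved`,
#'   `reassigned`, `argmax_class`.
#' @export
resolveMixedPreclusters <- function(preclusters, mixed, profile) {
    pc <- as.character(preclusters)
    stopifnot(length(pc) == length(assignedClass(profile)),
              all(pc %in% names(mixed)))
    cls <- assignedClass(profile)
    isMixed <- mixed[pc]
    resolved <- ifelse(isMixed, paste0(cls, "_r", pc), pc)
    S4Vectors::DataFrame(precluster = pc, resolved = resolved,
                         reassigned = unname(isMixed), argmax_class = cls)
}

#' Master class per nucleus
#'
#' Agglomerates resolved pre-clusters into the six master classes: nuclei
#' from resolved (formerly mixed) pre-clusters carry their argmax class;
#' clean pre-clusters adopt the class with their highest enrichment score.
#'
#' @param resolution a `DataFrame` from [resolveMixedPreclusters()].
#' @param enrichment clusters x classes enrichment matrix (same as passed to
#'   [flagMixed()]).
#' @return character vector of master classes, one per nucleus.
#' @export
masterClasses <- function(resolution, enrichment) {
    clusterClass <- colnames(enrichment)[max.col(enrichment,
                                                 ties.method = "first")]
    names(clusterClass) <- rownames(enrichment)
    ifelse(resolution$reassigned, resolution$argmax_class,
           clusterClass[resolution$precluster])
}
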
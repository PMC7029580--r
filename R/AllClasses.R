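#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment assay assays colData rowData colData<-
#' @importFrom SingleCellExperiment SingleCellExperiment logcounts logcounts<- sizeFactors sizeFactors<-
NULL

#' Named collection of gene sets over a declared universe
#'
#' Holds the cell-class marker lists (or any other named gene sets) used for
#' identity scoring and enrichment. The universe is the set of gene names the
#' sets may legitimately be intersected with; an empty universe means "take
#' the universe from the expression matrix at time of use".
#'
#' @slot sets named list of character vectors of gene identifiers.
#' @slot universe character vector of gene identifiers (possibly empty).
#' @export
setClass("GeneSetList", representation(sets = "list", universe = "character"))

setValidity("GeneSetList", function(object) {
    s <- object@sets
    if (length(s) == 0L) return("at least one gene set is required")
    if (is.null(names(s)) || any(!nzchar(names(s))) || anyDuplicated(names(s)))
        return("gene sets must have unique, non-empty names")
    if (!all(vapply(s, is.character, logical(1))))
        return("every gene set must be a character vector")
    if (any(vapply(s, length, integer(1)) == 0L))
        return("empty gene set")
    TRUE
})

#' Quality-control thresholds
#'
#' Defaults follow the study design this package implements: nuclei kept with
#' 25--75\% exonic reads and at most 14\% mitochondrial reads; genes kept with
#' more than 10 total counts and detection in at least 31 nuclei; nuclei with
#' a doublet score of at least 1.5 excluded; nuclei whose best identity score
#' is below 20\% treated as low quality.
#'
#' @slot exonicLo,exonicHi inclusive bounds on the per-nucleus exonic read
#'   fraction.
#' @slot mitoMax maximum mitochondrial read fraction.
#' @slot geneMinCount minimum total count per gene (strictly greater than).
#' @slot geneMinCells minimum number of nuclei a gene must be detected in.
#' @slot doubletCut doublet-score threshold at or above which a nucleus is
#'   flagged.
#' @slot identityMin minimum best identity score, in percent.
#' @export
setClass("QCThresholds", representation(
    exonicLo = "numeric", exonicHi = "numeric", mitoMax = "numeric",
    geneMinCount = "numeric", geneMinCells = "numeric",
    doubletCut = "numeric", identityMin = "numeric"))

setValidity("QCThresholds", function(object) {
    if (!(object@exonicLo >= 0 && object@exonicLo < object@exonicHi &&
          object@exonicHi <= 1))
        return("need 0 <= exonicLo < exonicHi <= 1")
    if (!(object@mitoMax > 0 && object@mitoMax <= 1))
        return("mitoMax must lie in (0, 1]")
    if (object@geneMinCount < 0 || object@geneMinCells < 0)
        return("count thresholds must be non-negative")
    if (object@geneMinCount != round(object@geneMinCount) ||
        object@geneMinCells != round(object@geneMinCells))
        return("count thresholds must be integers")
    TRUE
})

#' Rule set for supervised astrocyte state classification
#'
#' Each rule is a conjunction of three threshold comparisons on log-expression
#' of the sentinel genes SLC1A2, MT2A and GFAP.  A side of \code{"ge"} means
#' the gene must be at or above its threshold, \code{"lt"} strictly below.
#' Validity requires the comparison patterns to be pairwise distinct, which
#' (for shared thresholds) makes the rules mutually exclusive, so the
#' Ambiguous outcome is unreachable under the default rules.
#'
#' @slot thresholds named numeric: thresholds for SLC1A2, MT2A, GFAP on the
#'   log2(normalized count + 1) scale.
#' @slot rules data.frame with columns \code{state}, \code{SLC1A2},
#'   \code{MT2A}, \code{GFAP}; the last three take values "ge" or "lt".
#' @export
setClass("StateRuleSet",
    representation(thresholds = "numeric", rules = "data.frame"))

setValidity("StateRuleSet", function(object) {
    need <- c("SLC1A2", "MT2A", "GFAP")
    if (!all(need %in% names(object@thresholds)))
        return("thresholds must be named SLC1A2, MT2A, GFAP")
    r <- object@rules
    if (!all(c("state", need) %in% colnames(r)))
        return("rules need columns state, SLC1A2, MT2A, GFAP")
    if (!all(unlist(r[need]) %in% c("ge", "lt")))
        return("rule sides must be 'ge' or 'lt'")
    if (anyDuplicated(r$state)) return("duplicate state names")
    pat <- apply(r[need], 1L, paste, collapse = "")
    if (anyDuplicated(pat))
        return("rules are not mutually exclusive (duplicate comparison pattern)")
    TRUE
})

#' Per-nucleus identity profile
#'
#' The output of identity scoring plus class assignment: one row per nucleus,
#' one identity score per cell class (percent of that class's marker list
#' detected in the nucleus), the argmax class, the ambiguity flag from the
#' flatness rule, and the quality flag (best score at or above the minimum).
#'
#' @slot scores numeric matrix, nuclei x classes, values in [0, 100].
#' @slot assignedClass character vector, the argmax class per nucleus
#'   ("Unknown" when every score is zero).
#' @slot ambiguous logical vector from the score-flatness rule.
#' @slot qualityPass logical vector; best score >= identityMin.
#' @slot params list recording rho, identityMin and the tie-break order.
#' @export
setClass("IdentityProfile", representation(
    scores = "matrix", assignedClass = "character", ambiguous = "logical",
    qualityPass = "logical", params = "list"))

setValidity("IdentityProfile", function(object) {
    n <- nrow(object@scores)
    if (length(object@assignedClass) != n || length(object@ambiguous) != n ||
        length(object@qualityPass) != n)
        return("per-nucleus vectors must match the score matrix rows")
    if (any(object@scores < 0 | object@scores > 100))
        return("identity scores must lie in [0, 100]")
    TRUE
})

#' Result of consensus k-means sub-clustering
#'
#' @slot consensus symmetric nucleus x nucleus matrix of co-clustering
#'   frequencies in [0, 1] with unit diagonal.
#' @slot labels factor of final cluster labels (hierarchical cut of the
#'   consensus matrix at k).
#' @slot silhouette named numeric, average silhouette width per cluster
#'   computed on consensus distances.
#' @slot k integer, the number of clusters requested.
#' @slot params list (distances, transforms, d range, seed).
#' @export
setClass("ConsensusResult", representation(
    consensus = "matrix", labels = "factor", silhouette = "numeric",
    k = "integer", params = "list"))

setValidity("ConsensusResult", function(object) {
    cm <- object@consensus
    if (nrow(cm) != ncol(cm)) return("consensus matrix must be square")
    if (length(object@labels) != nrow(cm))
        return("labels must match consensus dimension")
    if (any(cm < -1e-8 | cm > 1 + 1e-8))
        return("consensus entries must lie in [0, 1]")
    if (max(abs(cm - t(cm))) > 1e-8) return("consensus must be symmetric")
    if (nrow(cm) > 0 && max(abs(diag(cm) - 1)) > 1e-8)
        return("consensus diagonal must be 1")
    sil <- object@silhouette
    if (length(sil) && any(sil < -1 - 1e-8 | sil > 1 + 1e-8))
        return("silhouette widths must lie in [-1, 1]")
    TRUE
})
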
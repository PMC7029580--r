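#' @rdname GeneSetList-class
#' @param object,x a \linkS4class{GeneSetList}, \linkS4class{IdentityProfile}
#'   or \linkS4class{ConsensusResult}.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetList-class
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))

#' @rdname IdentityProfile-class
#' @export
setGeneric("identityScoreMatrix", function(x) standardGeneric("identityScoreMatrix"))

#' @rdname IdentityProfile-class
#' @export
setGeneric("assignedClass", function(x) standardGeneric("assignedClass"))

#' @rdname IdentityProfile-class
#' @export
setGeneric("isAmbiguous", function(x) standardGeneric("isAmbiguous"))

#' @rdname IdentityProfile-class
#' @export
setGeneric("qualityPass", function(x) standardGeneric("qualityPass"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ConsensusResult-class
#' @export
setGeneric("silhouetteWidths", function(x) standardGeneric("silhouetteWidths"))

#' @rdname GeneSetList-class
#' @export
setMethod("geneSets", "GeneSetList", function(x) x@sets)

#' @rdname GeneSetList-class
#' @export
setMethod("geneUniverse", "GeneSetList", function(x) x@universe)

#' @rdname IdentityProfile-class
#' @export
setMethod("identityScoreMatrix", "IdentityProfile", function(x) x@scores)

#' @rdname IdentityProfile-class
#' @export
setMethod("assignedClass", "IdentityProfile", function(x) x@assignedClass)

#' @rdname IdentityProfile-class
#' @export
setMethod("isAmbiguous", "IdentityProfile", function(x) x@ambiguous)

#' @rdname IdentityProfile-class
#' @export
setMethod("qualityPass", "IdentityProfile", function(x) x@qualityPass)

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)

#' @rdname ConsensusResult-class
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x) x@labels)

#' @rdname ConsensusResult-class
#' @export
setMethod("silhouetteWidths", "ConsensusResult", function(x) x@silhouette)

#' @rdname GeneSetList-class
#' @export
setMethod("show", "GeneSetList", function(object) {
    cat("GeneSetList with", length(object@sets), "sets:",
        paste(head(names(object@sets), 6L), collapse = ", "),
        if (length(object@sets) > 6L) "..." else "", "\n")
    cat("  universe:", length(object@universe), "genes\n")
})

#' @rdname QCThresholds-class
#' @param object a \linkS4class{QCThresholds}.
#' @export
setMethod("show", "QCThresholds", function(object) {
    cat(sprintf(paste0(
        "QCThresholds: exonic [%.2f, %.2f], mito <= %.2f,\n",
        "  gene total > %d in >= %d nuclei, doublet cut %.2f, identity >= %.0f%%\n"),
        object@exonicLo, object@exonicHi, object@mitoMax,
        as.integer(object@geneMinCount), as.integer(object@geneMinCells),
        object@doubletCut, object@identityMin))
})

#' @rdname StateRuleSet-class
#' @param object a \linkS4class{StateRuleSet}.
#' @export
setMethod("show", "StateRuleSet", function(object) {
    thr <- object@thresholds
    cat(sprintf("StateRuleSet (SLC1A2 @ %.3g, MT2A @ %.3g, GFAP @ %.3g):\n",
        thr["SLC1A2"], thr["MT2A"], thr["GFAP"]))
    r <- object@rules
    for (i in seq_len(nrow(r))) {
        sym <- function(s) if (s == "ge") ">=" else "<"
        cat(sprintf("  %-10s SLC1A2 %s %.3g & MT2A %s %.3g & GFAP %s %.3g\n",
            r$state[i], sym(r$SLC1A2[i]), thr["SLC1A2"],
            sym(r$MT2A[i]), thr["MT2A"], sym(r$GFAP[i]), thr["GFAP"]))
    }
})

#' @rdname IdentityProfile-class
#' @export
setMethod("show", "IdentityProfile", function(object) {
    cat("IdentityProfile for", nrow(object@scores), "nuclei over",
        ncol(object@scores), "classes\n")
    tab <- table(object@assignedClass)
    cat("  assigned:", paste(names(tab), as.integer(tab), sep = "=",
        collapse = ", "), "\n")
    cat(sprintf("  ambiguous: %d, below quality floor: %d\n",
        sum(object@ambiguous), sum(!object@qualityPass)))
})

#' @rdname ConsensusResult-class
#' @export
setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult: k =", object@k, "over", nrow(object@consensus),
        "nuclei\n")
    cat("  cluster sizes:", paste(as.integer(table(object@labels)),
        collapse = ", "), "\n")
    cat("  avg silhouette per cluster:",
        paste(sprintf("%.2f", object@silhouette), collapse = ", "), "\n")
})
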
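#' Default astrocyte state rules
#'
#' The supervised classifier assigns astrocytes to four states from
#' log2-expression of three sentinel genes, with thresholds SLC1A2 at 2,
#' MT2A at 4 and GFAP at 3:
#' \itemize{
#'   \item Quiescent: SLC1A2 >= 2, MT2A < 4, GFAP < 3 (protoplasmic profile)
#'   \item State1Q: SLC1A2 >= 2, MT2A >= 4, GFAP < 3 (quiescent with early
#'     reactive, metallothionein-high features)
#'   \item State2R: SLC1A2 < 2, MT2A >= 4, GFAP >= 3 (reactive, MT-high)
#'   \item State3R: SLC1A2 < 2, MT2A < 4, GFAP >= 3 (reactive, MT-low)
#' }
#' Triplets matching no rule are Unknown; matching more than one, Ambiguous.
#' Because the four comparison patterns are distinct, Ambiguous is
#' unreachable with shared thresholds: it is retained for generality with
#' user-supplied rule tables.
#'
#' @param slc1a2,mt2a,gfap thresholds on the log2(normalized count + 1)
#'   scale.
#' @return a \linkS4class{StateRuleSet}.
#' @examples
#' classifyState(cbind(SLC1A2 = 3, MT2A = 1, GFAP = 0.5), defaultStateRules())
#' @export
defaultStateRules <- function(slc1a2 = 2, mt2a = 4, gfap = 3) {
    new("StateRuleSet",
        thresholds = c(SLC1A2 = slc1a2, MT2A = mt2a, GFAP = gfap),
        rules = data.frame(
            state = c("Quiescent", "State1Q", "State2R", "State3R"),
            SLC1A2 = c("ge", "ge", "lt", "lt"),
            MT2A = c("lt", "ge", "ge", "lt"),
            GFAP = c("lt", "lt", "ge", "ge"),
            stringsAsFactors = FALSE))
}

#' All state labels the classifier can emit
#' @export
stateLevels <- function()
    c("Quiescent", "State1Q", "State2R", "State3R", "Unknown", "Ambiguous")

#' Classify astrocytes into reactivity states
#'
#' Applies the threshold rules to a matrix of sentinel log-expression values.
#'
#' @param triplets numeric matrix (or coercible) with columns SLC1A2, MT2A,
#'   GFAP on the log2(normalized count + 1) scale; one row per astrocyte.
#' @param rules a \linkS4class{StateRuleSet}.
#' @return factor of state calls with levels [stateLevels()].
#' @export
classifyState <- function(triplets, rules = defaultStateRules()) {
    stopifnot(is(rules, "StateRuleSet"))
    triplets <- as.matrix(triplets)
    if (is.null(colnames(triplets)) && ncol(triplets) == 3L)
        colnames(triplets) <- c("SLC1A2", "MT2A", "GFAP")
    stopifnot(all(c("SLC1A2", "MT2A", "GFAP") %in% colnames(triplets)))
    x <- triplets[, c("SLC1A2", "MT2A", "GFAP"), drop = FALSE]
    if (any(!is.finite(x)))
        stop("non-finite sentinel expression value(s)")
    thr <- rules@thresholds[c("SLC1A2", "MT2A", "GFAP")]
    nmatch <- integer(nrow(x))
    call <- rep("Unknown", nrow(x))
    for (i in seq_len(nrow(rules@rules))) {
        r <- rules@rules[i, ]
        ok <- rep(TRUE, nrow(x))
        for (g in c("SLC1A2", "MT2A", "GFAP")) {
            ok <- ok & if (r[[g]] == "ge") x[, g] >= thr[[g]] else x[, g] < thr[[g]]
        }
        call[ok & nmatch == 0L] <- r$state
        nmatch <- nmatch + ok
    }
    call[nmatch > 1L] <- "Ambiguous"
    out <- factor(call, levels = stateLevels())
    names(out) <- rownames(x)
    out
}

#' Per-condition composition of astrocyte states
#'
#' @param calls factor of state calls (from [classifyState()]).
#' @param condition condition label per call.
#' @return matrix condition x state of proportions; each row sums to one
#'   (rows for empty conditions are dropped with a warning).
#' @export
stateComposition <- function(calls, condition) {
    stopifnot(length(calls) == length(condition))
    calls <- factor(calls, levels = stateLevels())
    tab <- table(condition = condition, state = calls)
    empty <- rowSums(tab) == 0
    if (any(empty)) {
        warning("condition(s) with no astrocytes dropped: ",
                paste(rownames(tab)[empty], collapse = ", "))
        tab <- tab[!empty, , drop = FALSE]
    }
    prop <- sweep(unclass(tab), 1L, rowSums(tab), "/")
    prop
}

#' Cross-tabulate state calls against sub-cluster labels
#'
#' @param calls factor of state calls.
#' @param clusters sub-cluster label per call (aligned with `calls`).
#' @return contingency table cluster x state; row sums equal cluster sizes.
#' @export
clusterStateCrosstab <- function(calls, clusters) {
    stopifnot(length(calls) == length(clusters))
    table(cluster = clusters, state = factor(calls, levels = stateLevels()))
}

#' Sentinel triplet extraction from log-normalized expression
#'
#' Convenience helper pulling the SLC1A2/MT2A/GFAP rows for a set of nuclei.
#' @param logexpr gene x nucleus matrix of log2(normalized count + 1).
#' @param cells optional column subset (e.g. astrocyte barcodes).
#' @return nuclei x 3 matrix ready for [classifyState()].
#' @export
sentinelTriplets <- function(logexpr, cells = NULL) {
    missing <- setdiff(SENTINELS, rownames(logexpr))
    if (length(missing))
        stop("sentinel gene(s) absent from matrix: ",
             paste(missing, collapse = ", "))
    m <- logexpr[SENTINELS, , drop = FALSE]
    if (!is.null(cells)) m <- m[, cells, drop = FALSE]
    t(as.matrix(m))
}
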
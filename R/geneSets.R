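#' Construct a GeneSetList
#'
#' @param sets named list of character vectors (gene identifiers).
#' @param universe optional character vector declaring the gene universe.
#' @return a \linkS4class{GeneSetList}.
#' @examples
#' gs <- GeneSetList(list(A = c("G1", "G2"), B = "G3"))
#' geneSets(gs)
#' @export
GeneSetList <- function(sets, universe = character()) {
    sets <- lapply(sets, function(g) unique(as.character(g)))
    new("GeneSetList", sets = sets, universe = as.character(universe))
}

#' Read and write GMT gene-set files
#'
#' One set per line: name, description, then gene identifiers, tab-separated.
#' The bundled file \code{cell_class_markers.gmt} carries literature-derived
#' marker lists for the six cortical cell classes (neurons, astrocytes,
#' oligodendrocytes, OPCs, microglia, endothelial cells) used for identity
#' scoring; the astrocyte state sentinels (SLC1A2, MT2A, GFAP) are kept out
#' of the class lists so state and class signals stay separable.
#'
#' @param path file path.
#' @param universe optional universe passed to [GeneSetList()].
#' @return `readGMT` returns a \linkS4class{GeneSetList}; `writeGMT` is called
#'   for its side effect and returns `path` invisibly.
#' @examples
#' gmt <- system.file("extdata", "cell_class_markers.gmt",
#'                    package = "astrostates")
#' readGMT(gmt)
#' @export
readGMT <- function(path, universe = character()) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("malformed GMT line ", i, ": expected name, description, ",
                 "and at least one gene")
        sets[[f[[1]]]] <- f[-(1:2)]
    }
    GeneSetList(sets, universe)
}

#' @rdname readGMT
#' @param x a \linkS4class{GeneSetList} to write.
#' @export
writeGMT <- function(x, path) {
    stopifnot(is(x, "GeneSetList"))
    lines <- vapply(names(geneSets(x)), function(nm) {
        paste(c(nm, nm, geneSets(x)[[nm]]), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Default cell-class marker sets
#'
#' Convenience loader for the bundled six-class marker GMT.
#' @return a \linkS4class{GeneSetList} with sets Neuron, Astrocyte,
#'   Oligodendrocyte, OPC, Microglia, Endothelial.
#' @export
cellClassMarkers <- function() {
    readGMT(system.file("extdata", "cell_class_markers.gmt",
                        package = "astrostates", mustWork = TRUE))
}

# Intersect sets with a universe, erroring (or warning) on empty results.
intersectSets <- function(gs, universe, minSize = 1L, onEmpty = c("error", "skip")) {
    onEmpty <- match.arg(onEmpty)
    out <- lapply(geneSets(gs), intersect, universe)
    bad <- vapply(out, length, integer(1)) < minSize
    if (any(bad)) {
        msg <- paste0("gene set(s) with fewer than ", minSize,
                      " genes in the universe: ",
                      paste(names(out)[bad], collapse = ", "))
        if (onEmpty == "error") stop(msg)
        warning(msg, "; skipped")
        out <- out[!bad]
    }
    out
}
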
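#' Write and read 10x-style sparse count directories
#'
#' `write10x` writes `matrix.mtx` (MatrixMarket triplets), `features.tsv`,
#' `barcodes.tsv` and a `metadata.tsv` sidecar holding every `colData`
#' column (at minimum condition, pct_exonic, pct_mito for real cohorts;
#' simulated cohorts also round-trip their truth columns). `read10x`
#' reconstructs the `SingleCellExperiment`; the round trip is exact.
#'
#' @param sce a `SingleCellExperiment` with a `counts` assay.
#' @param path directory to create/read.
#' @return `write10x` returns `path` invisibly; `read10x` returns a
#'   `SingleCellExperiment`.
#' @examples
#' cfg <- simConfig(nPerClass = 5L, nGenes = 400L, seed = 3L)
#' sce <- simulateCohort(cfg)
#' d <- tempfile()
#' write10x(sce, d)
#' sce2 <- read10x(d)
#' @export
write10x <- function(sce, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(assay(sce, "counts"), sparse = TRUE)
    Matrix::writeMM(as(m, "generalMatrix"), file.path(path, "matrix.mtx"))
    writeLines(as.character(rownames(sce)), file.path(path, "features.tsv"))
    writeLines(as.character(colnames(sce)), file.path(path, "barcodes.tsv"))
    meta <- as.data.frame(colData(sce))
    meta <- cbind(barcode = colnames(sce), meta)
    utils::write.table(meta, file.path(path, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

# locate the first malformed line of a MatrixMarket triplet file so parse
# failures can be reported with a line number
checkMMFile <- function(file) {
    lines <- readLines(file)
    body <- which(!startsWith(lines, "%"))
    if (!length(lines) || !startsWith(lines[1], "%%MatrixMarket"))
        stop("malformed triplet file ", file, " at line 1: missing ",
             "MatrixMarket header")
    for (i in body) {
        f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
        ok <- length(f) == 3L && !anyNA(suppressWarnings(as.numeric(f)))
        if (!ok)
            stop("malformed triplet file ", file, " at line ", i,
                 ": expected three numeric fields, got '", lines[i], "'")
    }
    invisible(TRUE)
}

#' @rdname write10x
#' @export
read10x <- function(path) {
    mtx <- file.path(path, "matrix.mtx")
    for (f in c(mtx, file.path(path, c("features.tsv", "barcodes.tsv"))))
        if (!file.exists(f)) stop("missing file: ", f)
    m <- tryCatch(Matrix::readMM(mtx), error = function(e) {
        checkMMFile(mtx)   # stops with a line number if it finds the fault
        stop("malformed triplet file ", mtx, ": ", conditionMessage(e))
    })
    # symmetric/triplet variants all normalise to general column-sparse
    m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
    feats <- readLines(file.path(path, "features.tsv"))
    bcs <- readLines(file.path(path, "barcodes.tsv"))
    if (nrow(m) != length(feats) || ncol(m) != length(bcs))
        stop("matrix dimensions (", nrow(m), " x ", ncol(m),
             ") do not match features/barcodes (", length(feats), " x ",
             length(bcs), ")")
    dimnames(m) <- list(feats, bcs)
    metaFile <- file.path(path, "metadata.tsv")
    hasMeta <- file.exists(metaFile) &&
        any(nzchar(readLines(metaFile, n = 1L)))
    if (hasMeta) {
        meta <- utils::read.table(metaFile, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE, check.names = FALSE)
        rownames(meta) <- meta$barcode
        meta <- meta[bcs, setdiff(colnames(meta), "barcode"), drop = FALSE]
        meta <- S4Vectors::DataFrame(meta)
    } else {
        meta <- S4Vectors::DataFrame(row.names = bcs)
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = methods::as(m, "CsparseMatrix")),
        colData = meta)
}
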
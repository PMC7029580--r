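#' Configuration for the synthetic snRNA-seq cohort generator
#'
#' The generator emulates the structure of a droplet single-nucleus RNA-seq
#' study of two-condition human cortex: six cell classes with overlapping
#' marker programs, negative-binomial counts with per-nucleus depth variation,
#' astrocyte reactivity states planted through the three sentinel genes
#' (SLC1A2, MT2A, GFAP), condition-specific astrocyte sub-programs, a
#' configurable doublet fraction, and per-nucleus exonic/mitochondrial read
#' fractions drawn from Beta distributions.
#'
#' @slot nPerClass integer vector (scalar, or named by class): nuclei per
#'   class per condition.
#' @slot nGenes total number of genes, including marker, sentinel and filler
#'   genes.
#' @slot classMarkerSets a \linkS4class{GeneSetList} of class marker lists.
#' @slot markerEffect fold-elevation of a class's marker means over baseline
#'   (> 0; 1 = null configuration).
#' @slot baselineMean mean count per non-marker gene before depth scaling.
#' @slot dispersion negative-binomial size parameter; `Inf` gives the Poisson
#'   limit.
#' @slot conditions character vector of condition labels.
#' @slot stateMix matrix (condition x state) of astrocyte state probabilities;
#'   rows sum to one.
#' @slot stateMeans matrix (state x sentinel) of target log2-expression for
#'   SLC1A2, MT2A, GFAP; each row must fall inside its own state's rule
#'   region.
#' @slot nSubprograms,subprogramGenes,subprogramEffect per-condition astrocyte
#'   sub-programs: how many, how many dedicated genes each, and their
#'   fold-elevation.  These plant the sub-cluster structure that consensus
#'   clustering is expected to recover.
#' @slot doubletRate fraction of final barcodes that are synthetic doublets.
#' @slot exonicBeta,mitoBeta shape parameters of the Beta distributions for
#'   per-nucleus exonic and mitochondrial fractions.
#' @slot depthSdLog standard deviation of per-nucleus log depth factors.
#' @slot sentinelDispersion NB size for the sentinel genes (large = tight,
#'   so planted triplets stay inside their rule region after normalization).
#' @slot seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @export
setClass("SimConfig", representation(
    nPerClass = "integer", nGenes = "integer", classMarkerSets = "GeneSetList",
    markerEffect = "numeric", baselineMean = "numeric", dispersion = "numeric",
    conditions = "character", stateMix = "matrix", stateMeans = "matrix",
    nSubprograms = "integer", subprogramGenes = "integer",
    subprogramEffect = "numeric", doubletRate = "numeric",
    exonicBeta = "numeric", mitoBeta = "numeric", depthSdLog = "numeric",
    sentinelDispersion = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
    if (any(object@nPerClass < 0L)) return("nPerClass must be non-negative")
    if (object@doubletRate < 0 || object@doubletRate > 1)
        return("doubletRate must lie in [0, 1]")
    if (object@baselineMean <= 0 || object@markerEffect <= 0 ||
        object@subprogramEffect <= 0)
        return("all means and effects must be positive")
    if (object@dispersion <= 0) return("dispersion must be positive")
    if (!setequal(rownames(object@stateMix), object@conditions))
        return("stateMix rows must be named by condition")
    if (any(abs(rowSums(object@stateMix) - 1) > 1e-9))
        return("stateMix rows must sum to 1")
    if (!setequal(rownames(object@stateMeans), colnames(object@stateMix)))
        return("stateMeans rows must match stateMix states")
    if (!identical(colnames(object@stateMeans), c("SLC1A2", "MT2A", "GFAP")))
        return("stateMeans columns must be SLC1A2, MT2A, GFAP")
    TRUE
})

# Astrocyte state proportions observed in the study per condition,
# renormalized over the four defined states (the residual unknown/ambiguous
# calls arise from rule geometry and cannot be planted directly).
defaultStateMix <- function(conditions = c("Control", "HD")) {
    raw <- rbind(Control = c(Quiescent = 49.3, State1Q = 21.0,
                             State2R = 1.4, State3R = 2.5),
                 HD = c(Quiescent = 1.6, State1Q = 37.4,
                        State2R = 14.0, State3R = 7.9))
    raw <- raw[conditions, , drop = FALSE]
    sweep(raw, 1L, rowSums(raw), "/")
}

# Target sentinel log2-expression per state, placed >= 1.5 log2 units inside
# each rule boundary (thresholds 2/4/3) so NB noise rarely crosses a boundary.
defaultStateMeans <- function() {
    m <- rbind(Quiescent = c(3.5, 1.5, 1.0),
               State1Q   = c(3.5, 5.5, 1.0),
               State2R   = c(0.5, 5.5, 4.5),
               State3R   = c(0.5, 1.5, 4.5))
    colnames(m) <- c("SLC1A2", "MT2A", "GFAP")
    m
}

#' Create a simulator configuration
#'
#' Defaults describe the emulated study: six classes, two conditions
#' (Control/HD), 100 nuclei per class per condition (1,200 barcodes before
#' doublets), 1,500 genes, and astrocyte state mixtures matching the
#' condition-specific state proportions reported for human cingulate cortex.
#' The configuration is rejected if any planted state's sentinel triplet
#' fails to classify to its own state under `rules` (an inconsistent config).
#'
#' @param nPerClass,nGenes,classMarkerSets,markerEffect,baselineMean,dispersion
#'   see \linkS4class{SimConfig}.
#' @param conditions,stateMix,stateMeans,nSubprograms,subprogramGenes
#'   see \linkS4class{SimConfig}.
#' @param subprogramEffect,doubletRate,exonicBeta,mitoBeta,depthSdLog see
#'   \linkS4class{SimConfig}.
#' @param sentinelDispersion,seed see \linkS4class{SimConfig}.
#' @param rules the \linkS4class{StateRuleSet} used to check that planted
#'   state targets are self-consistent.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nPerClass = 20L, nGenes = 400L, seed = 7L)
#' sce <- simulateCohort(cfg)
#' @export
simConfig <- function(nPerClass = 100L, nGenes = 1500L,
                      classMarkerSets = cellClassMarkers(),
                      markerEffect = 8, baselineMean = 0.2, dispersion = 2,
                      conditions = c("Control", "HD"),
                      stateMix = defaultStateMix(conditions),
                      stateMeans = defaultStateMeans(),
                      nSubprograms = 3L, subprogramGenes = 30L,
                      subprogramEffect = 10, doubletRate = 0.05,
                      exonicBeta = c(6, 6), mitoBeta = c(1.5, 20),
                      depthSdLog = 0.2, sentinelDispersion = 100,
                      seed = 1L, rules = defaultStateRules()) {
    cfg <- new("SimConfig", nPerClass = as.integer(nPerClass),
        nGenes = as.integer(nGenes), classMarkerSets = classMarkerSets,
        markerEffect = markerEffect, baselineMean = baselineMean,
        dispersion = dispersion, conditions = conditions,
        stateMix = stateMix, stateMeans = stateMeans,
        nSubprograms = as.integer(nSubprograms),
        subprogramGenes = as.integer(subprogramGenes),
        subprogramEffect = subprogramEffect, doubletRate = doubletRate,
        exonicBeta = exonicBeta, mitoBeta = mitoBeta, depthSdLog = depthSdLog,
        sentinelDispersion = sentinelDispersion, seed = as.integer(seed))
    planted <- classifyState(cfg@stateMeans, rules)
    bad <- planted != rownames(cfg@stateMeans)
    if (any(bad))
        stop("inconsistent config: state target(s) ",
             paste(rownames(cfg@stateMeans)[bad], collapse = ", "),
             " fall outside their own rule region (classified as ",
             paste(planted[bad], collapse = ", "), ")")
    cfg
}

SENTINELS <- c("SLC1A2", "MT2A", "GFAP")

# draw NB counts with the Poisson limit at size = Inf
rcounts <- function(n, mu, size) {
    if (is.infinite(size)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = size)
}

#' Simulate a droplet snRNA-seq cohort with known ground truth
#'
#' Generates a sparse gene x nucleus count matrix as a
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment] whose
#' `colData` carries both the observable metadata (condition, exonic and
#' mitochondrial fractions) and the planted truth (class, astrocyte state,
#' sub-program, doublet flag).  Marker genes of a nucleus's class have mean
#' `baselineMean * markerEffect`; astrocyte sentinel genes are drawn around
#' their planted state's target triplet; doublets are sums of two randomly
#' paired singlet nuclei and inherit the first member's metadata.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a `SingleCellExperiment` with assay `counts` and truth columns
#'   `true_class`, `true_state`, `true_subprogram`, `is_doublet` in
#'   `colData`, plus `condition`, `pct_exonic`, `pct_mito`.
#' @seealso [simTruth()] to extract only the ground-truth columns.
#' @export
simulateCohort <- function(config) {
    stopifnot(is(config, "SimConfig"))
    set.seed(config@seed)
    classes <- names(geneSets(config@classMarkerSets))
    nPer <- config@nPerClass
    if (length(nPer) == 1L) {
        nPer <- rep(nPer, length(classes))
    } else if (!is.null(names(nPer))) {
        stopifnot(setequal(names(nPer), classes))
        nPer <- nPer[classes]
    } else stopifnot(length(nPer) == length(classes))

    markerGenes <- unique(unlist(geneSets(config@classMarkerSets)))
    markerGenes <- setdiff(markerGenes, SENTINELS)
    states <- colnames(config@stateMix)
    nProgBlocks <- config@nSubprograms * length(config@conditions)
    nFiller <- config@nGenes - length(markerGenes) - length(SENTINELS)
    if (nFiller < nProgBlocks * config@subprogramGenes)
        stop("nGenes too small for the requested marker sets and sub-programs")
    filler <- sprintf("GENE%05d", seq_len(nFiller))
    genes <- c(markerGenes, SENTINELS, filler)
    # dedicated filler block per (condition, sub-program)
    progGenes <- split(filler[seq_len(nProgBlocks * config@subprogramGenes)],
                       rep(seq_len(nProgBlocks), each = config@subprogramGenes))
    progKey <- expand.grid(program = seq_len(config@nSubprograms),
                           condition = config@conditions,
                           stringsAsFactors = FALSE)

    # baseline mean per gene per class
    muClass <- matrix(config@baselineMean, length(genes), length(classes),
                      dimnames = list(genes, classes))
    for (cl in classes) {
        mk <- setdiff(intersect(geneSets(config@classMarkerSets)[[cl]], genes),
                      SENTINELS)
        muClass[mk, cl] <- config@baselineMean * config@markerEffect
    }

    design <- expand.grid(class = classes, condition = config@conditions,
                          stringsAsFactors = FALSE)
    design <- design[rep(seq_len(nrow(design)),
                         times = rep(nPer, length(config@conditions))), ]
    n <- nrow(design)
    depth <- exp(stats::rnorm(n, 0, config@depthSdLog))

    isAstro <- design$class == "Astrocyte"
    state <- rep(NA_character_, n)
    program <- rep(NA_integer_, n)
    for (cond in config@conditions) {
        idx <- which(isAstro & design$condition == cond)
        if (!length(idx)) next
        state[idx] <- sample(states, length(idx), replace = TRUE,
                             prob = config@stateMix[cond, ])
        program[idx] <- sample.int(config@nSubprograms, length(idx),
                                   replace = TRUE)
    }

    counts <- matrix(0L, length(genes), n, dimnames = list(genes, NULL))
    for (j in seq_len(n)) {
        mu <- muClass[, design$class[j]] * depth[j]
        counts[, j] <- rcounts(length(genes), mu, config@dispersion)
        if (isAstro[j]) {
            blk <- which(progKey$program == program[j] &
                         progKey$condition == design$condition[j])
            pg <- progGenes[[blk]]
            counts[pg, j] <- rcounts(length(pg),
                config@baselineMean * config@subprogramEffect * depth[j],
                config@dispersion)
            target <- config@stateMeans[state[j], ]
            counts[SENTINELS, j] <- rcounts(3L, (2^target - 1) * depth[j],
                                            config@sentinelDispersion)
        }
    }

    meta <- S4Vectors::DataFrame(
        condition = design$condition,
        true_class = design$class,
        true_state = state,
        true_subprogram = ifelse(isAstro,
            paste0(design$condition, "_P", program), NA_character_),
        is_doublet = logical(n),
        pct_exonic = stats::rbeta(n, config@exonicBeta[1], config@exonicBeta[2]),
        pct_mito = stats::rbeta(n, config@mitoBeta[1], config@mitoBeta[2]))

    # doublets: sums of random singlet pairs, metadata from the first member
    nDoub <- round(config@doubletRate * n / (1 - config@doubletRate))
    if (nDoub > 0) {
        i1 <- sample.int(n, nDoub, replace = TRUE)
        i2 <- vapply(i1, function(i) sample(setdiff(seq_len(n), i), 1L),
                     integer(1))
        dcounts <- counts[, i1, drop = FALSE] + counts[, i2, drop = FALSE]
        dmeta <- meta[i1, ]
        dmeta$is_doublet <- TRUE
        counts <- cbind(counts, dcounts)
        meta <- rbind(meta, dmeta)
    }
    rownames(meta) <- colnames(counts) <- sprintf("BC%05d", seq_len(ncol(counts)))

    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
        colData = meta)
    S4Vectors::metadata(sce)$simConfig <- config
    sce
}

#' Extract the planted ground truth of a simulated cohort
#'
#' @param sce a `SingleCellExperiment` from [simulateCohort()].
#' @return a `DataFrame` with columns `true_class`, `true_state`,
#'   `true_subprogram`, `is_doublet`, `condition`.
#' @export
simTruth <- function(sce) {
    cols <- c("true_class", "true_state", "true_subprogram", "is_doublet",
              "condition")
    missing <- setdiff(cols, colnames(colData(sce)))
    if (length(missing))
        stop("not a simulated cohort: missing ", paste(missing, collapse = ", "))
    colData(sce)[, cols]
}
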
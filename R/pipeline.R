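#' Pipeline configuration
#'
#' Bundles every stage's settings.  Exactly one of `input` (a 10x-style
#' directory for [read10x()]) or `sim` (a \linkS4class{SimConfig}) must be
#' given.  The resolved configuration is written beside the outputs of
#' every run.
#'
#' @param input path to a 10x-style directory, or `NULL`.
#' @param sim a \linkS4class{SimConfig}, or `NULL`.
#' @param genesets class marker \linkS4class{GeneSetList}.
#' @param qc a \linkS4class{QCThresholds}.
#' @param rho ambiguity ratio for [assignClasses()].
#' @param embedMethod,embedDim,perplexity embedding settings.
#' @param kSnn SNN neighbourhood size.
#' @param subclusterClass master class to sub-cluster (default Astrocyte).
#' @param kSub number of consensus sub-clusters.
#' @param mixedDelta closeness margin for [flagMixed()].
#' @param stateRules a \linkS4class{StateRuleSet}.
#' @param centralPct,nPerm,nPairs differential-correlation settings.
#' @param lfcThreshold pairwise marker fold-change threshold.
#' @param seed master seed; all stage seeds derive from it.
#' @return a validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(input = NULL, sim = NULL,
                           genesets = cellClassMarkers(),
                           qc = qcThresholds(), rho = 1,
                           embedMethod = c("tsne", "pca"), embedDim = 2L,
                           perplexity = 30, kSnn = 6L,
                           subclusterClass = "Astrocyte", kSub = 6L,
                           mixedDelta = 0.1,
                           stateRules = defaultStateRules(),
                           centralPct = 0.95, nPerm = 100L, nPairs = 1000L,
                           lfcThreshold = 0.5, seed = 1L) {
    if (is.null(input) == is.null(sim))
        stop("give exactly one of 'input' (a directory) or 'sim' (a SimConfig)")
    if (!is.null(input) && !dir.exists(input))
        stop("input directory does not exist: ", input)
    if (!is.null(sim)) stopifnot(is(sim, "SimConfig"))
    stopifnot(is(genesets, "GeneSetList"), is(qc, "QCThresholds"),
              is(stateRules, "StateRuleSet"), rho > 0, kSnn >= 2, kSub >= 2)
    cfg <- list(input = input, sim = sim, genesets = genesets, qc = qc,
                rho = rho, embedMethod = match.arg(embedMethod),
                embedDim = as.integer(embedDim), perplexity = perplexity,
                kSnn = as.integer(kSnn), subclusterClass = subclusterClass,
                kSub = as.integer(kSub), mixedDelta = mixedDelta,
                stateRules = stateRules, centralPct = centralPct,
                nPerm = as.integer(nPerm), nPairs = as.integer(nPairs),
                lfcThreshold = lfcThreshold, seed = as.integer(seed))
    class(cfg) <- "PipelineConfig"
    cfg
}

# flatten the config into plain lists for the resolved-config YAML
configAsList <- function(cfg) {
    simList <- if (is.null(cfg$sim)) NULL else {
        s <- cfg$sim
        list(nPerClass = as.integer(s@nPerClass), nGenes = s@nGenes,
             markerEffect = s@markerEffect, baselineMean = s@baselineMean,
             dispersion = s@dispersion, conditions = s@conditions,
             stateMix = apply(s@stateMix, 1L, as.list, simplify = FALSE),
             doubletRate = s@doubletRate, seed = s@seed)
    }
    qc <- cfg$qc
    list(input = cfg$input, sim = simList,
         genesets = names(geneSets(cfg$genesets)),
         qc = list(exonic = c(qc@exonicLo, qc@exonicHi), mitoMax = qc@mitoMax,
                   geneMinCount = qc@geneMinCount,
                   geneMinCells = qc@geneMinCells, doubletCut = qc@doubletCut,
                   identityMin = qc@identityMin),
         rho = cfg$rho, embedMethod = cfg$embedMethod,
         embedDim = cfg$embedDim, perplexity = cfg$perplexity,
         kSnn = cfg$kSnn, subclusterClass = cfg$subclusterClass,
         kSub = cfg$kSub, mixedDelta = cfg$mixedDelta,
         stateThresholds = as.list(cfg$stateRules@thresholds),
         centralPct = cfg$centralPct, nPerm = cfg$nPerm, nPairs = cfg$nPairs,
         lfcThreshold = cfg$lfcThreshold, seed = cfg$seed)
}

#' Drop genes and re-normalize
#'
#' Removes the given genes from the counts, recomputes size factors and
#' log-normalized expression.  Used e.g. to strip dominant off-lineage
#' genes (such as GFAP/AQP4 before neuronal sub-clustering) so they cannot
#' drive the clustering.
#'
#' @param sce `SingleCellExperiment` with counts.
#' @param genes character vector of genes to exclude.
#' @param clusters optional grouping for [computeSizeFactors()].
#' @return re-normalized `SingleCellExperiment` without the genes.
#' @export
excludeGenesRenormalize <- function(sce, genes, clusters = NULL) {
    sce <- sce[setdiff(rownames(sce), genes), ]
    logNormalize(sce, computeSizeFactors(sce, clusters))
}

writeTSV <- function(x, path) {
    utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
}

#' Run the full annotation pipeline
#'
#' Orchestrates simulate-or-read, nucleus QC, gene filtering, doublet
#' exclusion, pooled normalization, identity scoring and classification,
#' identity-based quality filtering, embedding, SNN pre-clustering,
#' enrichment-based resolution of mixed pre-clusters into master classes,
#' consensus sub-clustering of the chosen class, marker discovery,
#' state classification and differential correlation.  Every stage's
#' nucleus/gene tallies are logged; all outputs are flat TSV/JSON files
#' plus the resolved configuration, and identical config + seed give
#' byte-identical outputs.
#'
#' @param config a [pipelineConfig()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with all intermediate objects (`sce`,
#'   `profile`, `resolution`, `master`, `subclusters`, `markers`,
#'   `states`, `composition`, `diffcorr`, `tallies`, `outdir`).
#' @export
runPipeline <- function(config, outdir) {
    stopifnot(inherits(config, "PipelineConfig"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- config$seed
    tallies <- list()
    note <- function(stage, sce, extra = "")
        tallies[[length(tallies) + 1L]] <<- data.frame(
            stage = stage, n_nuclei = ncol(sce), n_genes = nrow(sce),
            note = extra)
    exclusions <- emptyExclusionLog()

    sce <- if (!is.null(config$sim)) simulateCohort(config$sim)
           else read10x(config$input)
    note("input", sce)

    nqc <- filterNucleiQC(sce, config$qc)
    sce <- nqc$sce
    exclusions <- rbind(exclusions, nqc$log)
    note("nucleus_qc", sce)

    gqc <- filterGenes(sce, config$qc)
    sce <- gqc$sce
    exclusions <- rbind(exclusions, gqc$log)
    note("gene_filter", sce)

    dbl <- doubletScores(sce, seed = seed + 101L)
    isDbl <- dbl >= config$qc@doubletCut
    exclusions <- rbind(exclusions,
                        exclusionLog(names(dbl)[isDbl], "doublet", "doublet"))
    sce <- sce[, !isDbl]
    note("doublet_filter", sce)

    groups <- quickClusterNuclei(sce, minSize = min(50L, ncol(sce) %/% 4L))
    sf <- computeSizeFactors(sce, groups)
    sce <- logNormalize(sce, sf)
    note("normalize", sce,
         paste0("fallback_factors=", length(attr(sf, "fallback"))))

    scores <- identityScores(sce, config$genesets)
    profile <- assignClasses(scores, rho = config$rho,
                             identityMin = config$qc@identityMin)
    lq <- filterLowQuality(sce, profile)
    sce <- lq$sce
    profile <- lq$profile
    exclusions <- rbind(exclusions, lq$log)
    note("identity_qc", sce)

    coords <- embedNuclei(sce, method = config$embedMethod,
                          nDim = config$embedDim,
                          perplexity = min(config$perplexity,
                                           (ncol(sce) - 1) / 3 - 1),
                          seed = seed + 202L)
    pre <- snnPrecluster(coords, kSnn = config$kSnn, seed = seed + 303L)
    note("precluster", sce, paste0("n_preclusters=", nlevels(pre)))

    # enrichment of class signatures per pre-cluster; with too few
    # pre-clusters for the rank scoring, mean identity scores stand in
    enrichment <- if (nlevels(pre) >= 3L) {
        t(gsvaScores(clusterMeans(logcounts(sce), pre), config$genesets))
    } else {
        t(clusterMeans(t(identityScoreMatrix(profile)), pre))
    }
    mixed <- flagMixed(enrichment, delta = config$mixedDelta)
    resolution <- resolveMixedPreclusters(pre, mixed, profile)
    master <- masterClasses(resolution, enrichment)
    note("master_class", sce, paste0("n_mixed=", sum(mixed)))

    target <- config$subclusterClass
    astro <- colnames(sce)[master == target]
    subclusters <- NULL
    markers <- NULL
    ranked <- NULL
    if (length(astro) >= 5L * config$kSub) {
        subclusters <- consensusSubcluster(logcounts(sce)[, astro],
                                           k = config$kSub,
                                           seed = seed + 404L)
        tabs <- pairwiseTMarkers(logcounts(sce)[, astro],
                                 clusterLabels(subclusters),
                                 lfcThreshold = config$lfcThreshold)
        ranked <- rankedMarkerList(tabs)
        markers <- aurocMarkers(logcounts(sce)[, astro],
                                clusterLabels(subclusters))
        note("subcluster", sce[, astro],
             paste0("k=", config$kSub, "; silhouettes=",
                    paste(sprintf("%.2f", silhouetteWidths(subclusters)),
                          collapse = ",")))
    }

    states <- composition <- crosstab <- NULL
    if (length(astro) >= 2L) {
        trip <- sentinelTriplets(logcounts(sce), astro)
        states <- classifyState(trip, config$stateRules)
        composition <- stateComposition(states,
                                        colData(sce)[astro, "condition"])
        if (!is.null(subclusters))
            crosstab <- clusterStateCrosstab(states,
                                             clusterLabels(subclusters))
        note("states", sce[, astro])
    }

    dcor <- NULL
    if (length(astro) >= 8L) {
        top <- filterTopMean(logcounts(sce)[, astro], config$centralPct)
        dcor <- differentialCorrelation(
            logcounts(sce)[top, astro],
            colData(sce)[astro, "condition"],
            nPerm = config$nPerm, nPairs = config$nPairs,
            seed = seed + 505L)
        note("diffcorr", sce[top, astro])
    }

    ## ---- outputs ----
    yaml::write_yaml(configAsList(config), file.path(outdir, "resolved_config.yaml"))
    tallies <- do.call(rbind, tallies)
    writeTSV(tallies, file.path(outdir, "stage_log.tsv"))
    writeTSV(exclusions, file.path(outdir, "exclusions.tsv"))
    prof <- data.frame(barcode = colnames(sce),
                       identityScoreMatrix(profile),
                       assigned = assignedClass(profile),
                       ambiguous = isAmbiguous(profile), check.names = FALSE)
    writeTSV(prof, file.path(outdir, "identity_profiles.tsv"))
    writeTSV(data.frame(barcode = colnames(sce), precluster = as.character(pre),
                        resolved = resolution$resolved, master_class = master),
             file.path(outdir, "master_classes.tsv"))
    writeTSV(data.frame(cluster = rownames(enrichment), enrichment,
                        mixed = mixed, check.names = FALSE),
             file.path(outdir, "precluster_enrichment.tsv"))
    if (!is.null(subclusters))
        writeTSV(data.frame(barcode = astro,
                            subcluster = as.character(clusterLabels(subclusters))),
                 file.path(outdir, "subclusters.tsv"))
    if (!is.null(ranked))
        writeTSV(topMarkerTable(ranked, 25L), file.path(outdir, "markers_ranked.tsv"))
    if (!is.null(markers))
        writeTSV(markers, file.path(outdir, "markers_auroc.tsv"))
    if (!is.null(states)) {
        writeTSV(data.frame(barcode = astro, state = as.character(states)),
                 file.path(outdir, "state_calls.tsv"))
        writeTSV(data.frame(condition = rownames(composition), composition,
                            check.names = FALSE),
                 file.path(outdir, "state_composition.tsv"))
        jsonlite::write_json(
            lapply(seq_len(nrow(composition)), function(i)
                as.list(composition[i, ])) |>
                stats::setNames(rownames(composition)),
            file.path(outdir, "state_composition.json"), auto_unbox = TRUE,
            digits = NA)
    }
    if (!is.null(crosstab))
        writeTSV(as.data.frame.matrix(crosstab) |>
                     (\(d) cbind(cluster = rownames(d), d))(),
                 file.path(outdir, "state_cluster_crosstab.tsv"))
    if (!is.null(dcor))
        writeTSV(dcor, file.path(outdir, "diffcorr.tsv"))

    invisible(list(sce = sce, profile = profile, preclusters = pre,
                   enrichment = enrichment, resolution = resolution,
                   master = master, subclusters = subclusters,
                   markers = markers, ranked = ranked, states = states,
                   composition = composition, crosstab = crosstab,
                   diffcorr = dcor, tallies = tallies,
                   exclusions = exclusions, outdir = outdir))
}
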
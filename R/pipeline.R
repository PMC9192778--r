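## End-to-end orchestration: simulate/read -> QC -> preprocess -> DE/panel
## -> principal-curve pseudotime -> enrichment scan + ssGSEA -> hazard
## tree, with every intermediate written as TSV and a bookkeeping summary.

#' Pipeline configuration
#'
#' Collects every tunable of the full analysis. Input is either a
#' simulation block (a [cohortConfig()]) or paths to a counts TSV and a
#' sample-metadata TSV (columns `patient`, `lesion`, `section`, `tissue`,
#' `status`, `subtype`, `rawReads`, `pctUniqueMap`, `pctReadsInGenes`).
#'
#' @param simulate a [cohortConfig()], or `NULL` when reading from files.
#' @param countsPath,metaPath input files when `simulate` is `NULL`.
#' @param qc a [qcThresholds()].
#' @param receptors a [receptorThresholds()].
#' @param scan a [scanConfig()].
#' @param boundaries a [segmentBoundaries()].
#' @param panelAlpha adjusted-p cutoff for the pseudotime gene panel.
#' @param nBoot bootstrap replicates for the trend fit.
#' @param seed integer seed governing every random stage.
#' @return named list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(simulate = cohortConfig(), countsPath = NULL,
                           metaPath = NULL, qc = qcThresholds(),
                           receptors = receptorThresholds(),
                           scan = scanConfig(),
                           boundaries = segmentBoundaries(),
                           panelAlpha = 1e-5, nBoot = 10000L, seed = 1L) {
    if (is.null(simulate) &&
        (is.null(countsPath) || is.null(metaPath)))
        stop("either a simulate block or counts/meta paths are required")
    if (is.null(simulate))
        for (p in c(countsPath, metaPath))
            if (!file.exists(p)) stop("no such file: ", p)
    structure(list(simulate = simulate, countsPath = countsPath,
                   metaPath = metaPath, qc = qc, receptors = receptors,
                   scan = scan, boundaries = boundaries,
                   panelAlpha = panelAlpha, nBoot = as.integer(nBoot),
                   seed = as.integer(seed)),
              class = "pipelineConfig")
}

#' @rdname pipelineConfig
#' @param path YAML file whose top-level keys override the defaults
#'   (nested keys for `simulate`, `scan`, `boundaries`).
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    if (!is.null(y$simulate))
        args$simulate <- do.call(cohortConfig, y$simulate)
    if (identical(y$simulate, FALSE)) args["simulate"] <- list(NULL)
    for (k in c("countsPath", "metaPath", "panelAlpha", "nBoot", "seed"))
        if (!is.null(y[[k]])) args[[k]] <- y[[k]]
    if (!is.null(y$scan)) args$scan <- do.call(scanConfig, y$scan)
    if (!is.null(y$boundaries))
        args$boundaries <- do.call(segmentBoundaries, y$boundaries)
    do.call(pipelineConfig, args)
}

.tsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Run the full progression-continuum analysis
#'
#' Executes, in order: cohort simulation (or reading), the four-stage
#' quality filter, gene filtering + TMM + log2-CPM, the in-situ-vs-
#' invasive differential expression restricted to patients carrying both
#' tissues (with patient blocking) and panel selection, panel PCA +
#' principal-curve fitting + PCP ordering and segmentation, the
#' sliding-window enrichment scan and ssGSEA scoring over the planted
#' program gene sets, a bootstrap trend of the basal-program score, the
#' Welch comparison of PCP positions by patient outcome, receptor calls
#' and the marker decision tree with its enrichment folds. Every stage
#' writes its table under `outDir` before the next stage runs, and a
#' machine-readable summary collects all bookkeeping counts. A fixed seed
#' makes the whole bundle reproducible.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return (invisibly) a list with the per-stage objects and the
#'   `summary` list written to `summary.yaml`.
#' @export
runFullPipeline <- function(config = pipelineConfig(), outDir = tempdir()) {
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    stage <- function(name, expr) tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
    summary <- list(seed = config$seed)

    ## ---- input -----------------------------------------------------------
    se <- stage("input", {
        if (!is.null(config$simulate)) {
            cfg <- config$simulate
            cfg$seed <- config$seed
            simulateCohort(cfg)
        } else {
            counts <- readCounts(config$countsPath)
            meta <- read.delim(config$metaPath, row.names = 1, quote = "")
            SummarizedExperiment::SummarizedExperiment(
                assays = list(counts = counts),
                colData = S4Vectors::DataFrame(meta[colnames(counts), ,
                                                    drop = FALSE]))
        }
    })
    writeCounts(se, file.path(outDir, "counts.tsv"))
    meta <- as.data.frame(SummarizedExperiment::colData(se))
    .tsv(data.frame(sample_id = rownames(meta), meta),
         file.path(outDir, "meta.tsv"))
    summary$input <- c(genes = nrow(se), samples = ncol(se))

    ## ---- quality filter --------------------------------------------------
    qc <- stage("qc", runQC(se, thresholds = config$qc))
    writeQCReport(qc, file.path(outDir, "qc_report.tsv"))
    summary$qc <- as.list(qcCounts(qc))
    se <- se[, qcRetained(qc)]
    meta <- meta[qcRetained(qc), , drop = FALSE]

    ## ---- normalisation ---------------------------------------------------
    se <- stage("preprocess", filterGenes(se))
    nf <- tmmFactors(se)
    expr <- logCPM(se, nf)
    summary$filteredGenes <- nrow(se)

    ## ---- DE and panel ----------------------------------------------------
    de.res <- stage("diffexp", {
        by.pat <- table(meta$patient, meta$tissue)
        both <- rownames(by.pat)[by.pat[, "DCIS"] > 0 & by.pat[, "IDC"] > 0]
        if (length(both) < 2)
            stop("no patients with both in-situ and invasive tissue")
        s <- rownames(meta)[meta$patient %in% both &
                            meta$tissue %in% c("DCIS", "IDC")]
        groups <- factor(meta[s, "tissue"], levels = c("DCIS", "IDC"))
        de <- fitDE(se[, s], groups, patient = meta[s, "patient"])
        list(de = de, fitSamples = s, nPatients = length(both))
    })
    .tsv(data.frame(gene_id = rownames(de.res$de), de.res$de),
         file.path(outDir, "de.tsv"))
    panel <- stage("panel", selectPanel(de.res$de, config$panelAlpha))
    writeLines(panel, file.path(outDir, "panel.txt"))
    summary$de <- list(contrastSamples = length(de.res$fitSamples),
                       contrastPatients = de.res$nPatients,
                       degAdj05 = sum(de.res$de$adjP < 0.05),
                       panelSize = length(panel))

    ## ---- pseudotime ------------------------------------------------------
    traj <- stage("pseudotime", {
        emb <- pcaEmbedPanel(expr, panel, de.res$fitSamples)
        curve <- fitPrincipalCurve(emb$coords[, 1:2])
        ord <- orderSamples(curve, setNames(meta$tissue, rownames(meta)))
        seg <- segmentPositions(ord, config$boundaries)
        list(emb = emb, curve = curve, order = ord, segment = seg)
    })
    pt <- data.frame(sample_id = traj$order$sample_id,
                     pc1 = traj$emb$coords[traj$order$sample_id, 1],
                     pc2 = traj$emb$coords[traj$order$sample_id, 2],
                     pcp_position = traj$order$position,
                     pcp_rank = traj$order$rank,
                     segment = as.character(traj$segment))
    .tsv(pt, file.path(outDir, "pseudotime.tsv"))
    summary$pseudotime <- list(
        pc1VarFrac = round(traj$emb$model$varExplained[1], 4),
        curveConverged = traj$curve@converged)
    if (!is.null(meta$latentTime)) {
        pos <- setNames(traj$order$position, traj$order$sample_id)
        summary$pseudotime$truthSpearmanAbs <- abs(cor(
            pos, meta[names(pos), "latentTime"], method = "spearman"))
    }
    if (!is.null(meta$status)) {
        dcis <- traj$order$sample_id[
            meta[traj$order$sample_id, "tissue"] == "DCIS"]
        cmp <- compareGroupPositions(
            setNames(traj$order$position, traj$order$sample_id)[dcis],
            factor(meta[dcis, "status"], levels = c("Pure", "NotPure")))
        summary$positionByOutcome <- list(meanDiff = cmp$meanDiff,
                                          p = cmp$p)
    }

    ## ---- gene-set stages -------------------------------------------------
    sets <- stage("genesets", {
        blocks <- SummarizedExperiment::rowData(se)$block
        if (is.null(blocks)) NULL else
            split(rownames(se), blocks)[c("basal", "emt", "prolif")]
    })
    scan <- ssg <- trend <- NULL
    if (!is.null(sets) && all(lengths(sets) >= 2)) {
        writeGMT(sets, file.path(outDir, "programs.gmt"))
        ssg <- stage("ssgsea",
                     ssgseaScores(expr, sets, config$scan$ssgseaAlpha))
        .tsv(data.frame(set = rownames(ssg), ssg, check.names = FALSE),
             file.path(outDir, "ssgsea.tsv"))
        if (nrow(traj$order) >= config$scan$window) {
            scan <- stage("scan", windowEnrichmentScan(
                traj$order, se, sets, config$scan))
            .tsv(scan, file.path(outDir, "scan.tsv"))
            summary$scan <- list(
                windows = length(unique(scan$windowStart)),
                significantPairs = sum(scan$significant))
        }
        trend <- stage("trend", bootstrapTrend(
            ssg["basal", traj$order$sample_id], traj$order$rank,
            nBoot = config$nBoot, seed = config$seed))
        summary$basalTrend <- list(slope = trend$slope, r2 = trend$r2,
                                   slopeCI = trend$slopeCI)
    }

    ## ---- biomarkers ------------------------------------------------------
    receptors <- stage("receptors", {
        if (all(names(config$receptors) %in% rownames(expr)))
            receptorStatusCall(expr, config$receptors) else NULL
    })
    if (!is.null(receptors))
        .tsv(receptors, file.path(outDir, "receptor_status.tsv"))
    hazard <- stage("hazard", {
        if (all(markerPanel()$gene[markerPanel()$role != "annotation"]
                %in% rownames(expr)))
            assignHazardGroups(expr, meta) else NULL
    })
    if (!is.null(hazard)) {
        .tsv(hazard, file.path(outDir, "hazard.tsv"))
        if (!is.null(meta$status)) {
            outcome <- setNames(meta$status, meta$patient)
            outcome <- outcome[!duplicated(names(outcome))]
            lower <- hazardEnrichment(hazard, outcome, "LowerHazard",
                                      "Pure", "NotPure")
            higher <- hazardEnrichment(hazard, outcome, "HigherHazard",
                                       "NotPure", "Pure")
            summary$hazard <- list(
                groups = as.list(table(hazard$group)),
                lowerHazardFold = lower$fold,
                lowerHazardProps = c(lower$propA, lower$propB),
                higherHazardFold = higher$fold,
                higherHazardProps = c(higher$propA, higher$propB))
        }
    }

    yaml::write_yaml(summary, file.path(outDir, "summary.yaml"))
    invisible(list(se = se, qc = qc, expr = expr, de = de.res$de,
                   panel = panel, curve = traj$curve, order = traj$order,
                   segment = traj$segment, ssgsea = ssg, scan = scan,
                   trend = trend, receptors = receptors, hazard = hazard,
                   summary = summary))
}
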
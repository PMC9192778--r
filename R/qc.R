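## Four-stage sample quality filter:
##   0. library metrics (raw reads, unique mapping %, reads-in-genes %)
##   1. iterative correlation to the cohort (tissue-class) mean profile
##   2. samples closer to the cohort mean than to their patient's mean
##   3. iterative correlation to the patient mean profile
## Stages 1-3 run independently within each tissue class; samples of basal
## molecular subtype use the more lenient thresholds of the next class up.

#' Quality-filter correlation thresholds per sample class
#'
#' Pearson-correlation thresholds for the iterative cohort filter
#' (`cohort`) and the iterative patient filter (`patient`), by sample
#' class: most samples use 0.70/0.80, invasive (IDC) samples 0.65/0.75
#' (their heterogeneity is higher), basal-subtype DCIS samples the IDC
#' thresholds, and basal-subtype IDC samples 0.60/0.70.
#'
#' @param cohort,patient named numeric vectors over classes `default`,
#'   `idc`, `basalDcis`, `basalIdc`; all values in (0, 1).
#' @return list of class `qcThresholds`.
#' @export
qcThresholds <- function(cohort = c(default = 0.70, idc = 0.65,
                                    basalDcis = 0.65, basalIdc = 0.60),
                         patient = c(default = 0.80, idc = 0.75,
                                     basalDcis = 0.75, basalIdc = 0.70)) {
    keys <- c("default", "idc", "basalDcis", "basalIdc")
    stopifnot(all(keys %in% names(cohort)), all(keys %in% names(patient)),
              all(cohort > 0 & cohort < 1), all(patient > 0 & patient < 1))
    structure(list(cohort = cohort[keys], patient = patient[keys]),
              class = "qcThresholds")
}

.qcClass <- function(tissue, subtype) {
    basal <- !is.na(subtype) & subtype == "Basal"
    ifelse(tissue == "IDC" & basal, "basalIdc",
    ifelse(tissue == "DCIS" & basal, "basalDcis",
    ifelse(tissue == "IDC", "idc", "default")))
}

#' Library-metrics filter
#'
#' A sample fails if any of: fewer than 1 million raw reads, under 15%
#' uniquely mapping reads, or under 5% of raw reads mapping to genes.
#' Boundary values pass (the criteria are strict "fail if below").
#'
#' @param stats data.frame with rownames = sample IDs and columns
#'   `rawReads`, `pctUniqueMap`, `pctReadsInGenes`.
#' @return list with character vectors `pass` and `fail`.
#' @export
initialMetricsFilter <- function(stats) {
    need <- c("rawReads", "pctUniqueMap", "pctReadsInGenes")
    if (!all(need %in% colnames(stats)))
        stop("stats must provide columns ", paste(need, collapse = ", "))
    bad.na <- !complete.cases(as.data.frame(stats)[, need])
    if (any(bad.na))
        stop("missing library metrics for sample(s): ",
             paste(rownames(stats)[bad.na], collapse = ", "))
    fail <- stats$rawReads < 1e6 | stats$pctUniqueMap < 15 |
        stats$pctReadsInGenes < 5
    list(pass = rownames(stats)[!fail], fail = rownames(stats)[fail])
}

## Pearson correlation between matching columns of X and Y.
.pairedCor <- function(X, Y) {
    cx <- sweep(X, 2, colMeans(X))
    cy <- sweep(Y, 2, colMeans(Y))
    den <- sqrt(colSums(cx^2) * colSums(cy^2))
    r <- colSums(cx * cy) / den
    r[den == 0] <- NA_real_
    r
}

## Correlation of each sample to the mean profile of the *other* samples
## in the matrix (self excluded from the mean to avoid inflation).
.corToLooMean <- function(expr) {
    m <- ncol(expr)
    loo <- (rowSums(expr) - expr) / (m - 1)
    setNames(.pairedCor(expr, loo), colnames(expr))
}

.worstSample <- function(deficit) {
    # most-negative margin; ties broken by lexicographically smallest ID
    ids <- names(deficit)[deficit == min(deficit)]
    sort(ids)[1]
}

#' Iterative correlation filter against a (leave-one-out) mean profile
#'
#' Repeatedly computes each remaining sample's Pearson correlation to the
#' mean log2-CPM profile of the other remaining samples, removes the worst
#' sample whenever any correlation falls below its threshold, and
#' recomputes the mean, until every remaining sample meets its threshold.
#' A sample with zero variance (correlation undefined) is treated as
#' failing. Groups with fewer than 3 samples are skipped with a warning;
#' removal stops if only 2 samples remain.
#'
#' `iterativeCohortFilter()` applies this within one tissue class;
#' `iterativePatientFilter()` applies it within each patient's samples.
#'
#' @param expr log2-CPM matrix (genes x samples) for one class.
#' @param threshold scalar, or per-sample named numeric (e.g. basal-subtype
#'   samples carrying a more lenient threshold within their class).
#' @return character vector of removed sample IDs, in removal order.
#' @export
iterativeCohortFilter <- function(expr, threshold = 0.70) {
    ids <- colnames(expr)
    thr <- if (length(threshold) == 1) setNames(rep(threshold, length(ids)),
                                                ids) else threshold[ids]
    if (length(ids) < 3) {
        warning("fewer than 3 samples; cohort filter skipped")
        return(character())
    }
    # the correlation of sample j to the leave-one-out mean depends only
    # on running sums: with T = rowSums over the kept set, the mean
    # profile excluding j is (T - x_j)/(m-1) and correlation is invariant
    # to that scaling, so per-column statistics plus the cross-products
    # C_j = <x_j, T> give every correlation in O(m); removing a sample
    # updates T and C with a single matrix-vector product
    ng <- nrow(expr)
    s1 <- colSums(expr)
    s2 <- colSums(expr^2)
    T <- rowSums(expr)
    C <- as.vector(crossprod(expr, T))
    names(C) <- ids
    sumT <- sum(T); sumT2 <- sum(T^2)
    keep <- ids
    removed <- character()
    repeat {
        sy <- sumT - s1[keep]
        sy2 <- sumT2 - 2 * C[keep] + s2[keep]
        sxy <- C[keep] - s2[keep]
        num <- ng * sxy - s1[keep] * sy
        den2 <- (ng * s2[keep] - s1[keep]^2) * (ng * sy2 - sy^2)
        r <- ifelse(den2 <= 0, NA_real_, num / sqrt(pmax(den2, 0)))
        deficit <- ifelse(is.na(r), -Inf, r) - thr[keep]
        if (all(deficit >= 0)) break
        worst <- .worstSample(deficit)
        removed <- c(removed, worst)
        keep <- setdiff(keep, worst)
        x <- expr[, worst]
        sumT2 <- sumT2 - 2 * C[worst] + s2[worst]
        sumT <- sumT - s1[worst]
        C <- C - as.vector(crossprod(expr, x))
        T <- T - x
        if (length(keep) <= 2) {
            warning("iterative filter stopped with only 2 samples left")
            break
        }
    }
    removed
}

#' @rdname iterativeCohortFilter
#' @param patient factor/character of patient IDs aligned to samples.
#' @export
iterativePatientFilter <- function(expr, patient, threshold = 0.80) {
    patient <- setNames(as.character(patient), colnames(expr))
    removed <- character()
    for (p in unique(patient)) {
        s <- names(patient)[patient == p]
        if (length(s) < 3) next   # nothing to iterate over
        removed <- c(removed,
                     suppressWarnings(iterativeCohortFilter(
                         expr[, s, drop = FALSE], threshold)))
    }
    removed
}

#' Patient-vs-cohort correlation filter
#'
#' Removes a sample when it is more correlated to the cohort mean profile
#' (all other samples in the class) than to its own patient's mean profile
#' (the patient's other samples) -- such samples look generic rather than
#' patient-specific and are treated as likely contamination or swaps.
#' Patients contributing a single sample are exempt.
#'
#' @param expr log2-CPM matrix (genes x samples) for one class.
#' @param patient patient IDs aligned to `colnames(expr)`.
#' @return character vector of removed sample IDs.
#' @export
patientMeanFilter <- function(expr, patient) {
    patient <- setNames(as.character(patient), colnames(expr))
    m <- ncol(expr)
    if (m < 3) return(character())
    r.cohort <- .corToLooMean(expr)
    tot <- rowSums(expr)
    removed <- character()
    for (p in unique(patient)) {
        s <- names(patient)[patient == p]
        if (length(s) < 2) next
        sub <- expr[, s, drop = FALSE]
        loo.pat <- (rowSums(sub) - sub) / (length(s) - 1)
        r.pat <- .pairedCor(sub, loo.pat)
        worse <- !is.na(r.pat) & !is.na(r.cohort[s]) & r.cohort[s] > r.pat
        removed <- c(removed, s[worse])
    }
    removed
}

#' Run the full four-stage quality filter
#'
#' Applies, in order and each on the survivors of the previous stage:
#' the library-metrics filter, then -- independently within each tissue
#' class (normal, benign, atypia, DCIS, IDC) on log2-CPM over
#' prevalence-filtered genes -- the iterative cohort-correlation filter,
#' the patient-vs-cohort filter, and the iterative patient-correlation
#' filter. Basal-subtype samples use the lenient thresholds of
#' [qcThresholds()].
#'
#' @param object counts matrix or `SummarizedExperiment`.
#' @param meta data.frame-like with rownames = sample IDs and columns
#'   `tissue`, `patient` and optionally `subtype`; taken from `colData`
#'   when `object` is a `SummarizedExperiment`.
#' @param stats library metrics (see [initialMetricsFilter()]); also taken
#'   from `meta` columns when present.
#' @param thresholds a [qcThresholds()].
#' @param minFrac gene-prevalence fraction used before computing log2-CPM.
#' @return a [QCReport-class] object.
#' @export
runQC <- function(object, meta = NULL, stats = NULL,
                  thresholds = qcThresholds(), minFrac = 0.05) {
    counts <- .asCounts(object)
    if (is.null(meta)) {
        if (!methods::is(object, "SummarizedExperiment"))
            stop("meta required for plain matrices")
        meta <- as.data.frame(SummarizedExperiment::colData(object))
    } else meta <- as.data.frame(meta)
    if (is.null(stats)) stats <- meta
    stopifnot(identical(sort(rownames(meta)), sort(colnames(counts))))
    meta <- meta[colnames(counts), , drop = FALSE]
    if (is.null(meta$subtype)) meta$subtype <- NA_character_

    input <- colnames(counts)
    stage0 <- initialMetricsFilter(stats[input, , drop = FALSE])
    alive <- stage0$pass

    removed <- list(metrics = stage0$fail, cohort = character(),
                    patientVsCohort = character(), patient = character())
    cls <- setNames(.qcClass(meta$tissue, meta$subtype), input)
    thr.cohort <- setNames(thresholds$cohort[cls], input)
    thr.patient <- setNames(thresholds$patient[cls], input)

    for (tt in unique(meta[alive, "tissue"])) {
        s <- alive[meta[alive, "tissue"] == tt]
        if (length(s) < 3) {
            warning("tissue class '", tt, "' has <3 samples; filters skipped")
            next
        }
        sub <- filterGenes(counts[, s, drop = FALSE], minFrac)
        expr <- logCPM(sub)
        r1 <- iterativeCohortFilter(expr, thr.cohort[s])
        removed$cohort <- c(removed$cohort, r1)
        s <- setdiff(s, r1)

        r2 <- patientMeanFilter(expr[, s, drop = FALSE],
                                meta[s, "patient"])
        removed$patientVsCohort <- c(removed$patientVsCohort, r2)
        s <- setdiff(s, r2)

        r3 <- iterativePatientFilter(expr[, s, drop = FALSE],
                                     meta[s, "patient"], thr.patient[s])
        removed$patient <- c(removed$patient, r3)
    }
    retained <- setdiff(input, unlist(removed, use.names = FALSE))
    methods::new("QCReport", input = input, removed = removed,
                 retained = retained)
}

#' @rdname runQC
#' @param report a [QCReport-class].
#' @param path output TSV path (columns `sample_id`, `disposition`).
#' @export
writeQCReport <- function(report, path) {
    disp <- setNames(rep("retained", length(report@input)), report@input)
    for (st in names(report@removed))
        disp[report@removed[[st]]] <- paste0("removed_", st)
    write.table(data.frame(sample_id = report@input,
                           disposition = disp[report@input]),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
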
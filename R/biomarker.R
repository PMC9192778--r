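## Receptor-status calls, per-patient marker calls, the progressor tally,
## the hazard decision tree, enrichment folds and cumulative-frequency
## comparisons.

#' Receptor-call log2-CPM thresholds
#'
#' @param esr1,pgr,erbb2 log2-CPM thresholds above which a sample is
#'   called positive for ER, PR and Her2 respectively (boundary values
#'   count as positive).
#' @return named numeric vector.
#' @export
receptorThresholds <- function(esr1 = 6, pgr = 6, erbb2 = 10.5) {
    stopifnot(is.finite(esr1), is.finite(pgr), is.finite(erbb2))
    c(ESR1 = esr1, PGR = pgr, ERBB2 = erbb2)
}

#' Per-sample ER/PR/Her2 receptor status from expression
#'
#' A sample is receptor-positive when its log2-CPM for the receptor gene
#' is at or above the threshold; samples negative for all three are
#' flagged triple negative.
#'
#' @param expr log2-CPM matrix containing rows `ESR1`, `PGR`, `ERBB2`.
#' @param thresholds a [receptorThresholds()] vector.
#' @return data.frame (`sample_id`, `er`, `pr`, `her2`,
#'   `tripleNegative`).
#' @export
receptorStatusCall <- function(expr, thresholds = receptorThresholds()) {
    missing <- setdiff(names(thresholds), rownames(expr))
    if (length(missing))
        stop("receptor gene(s) missing from expression: ",
             paste(missing, collapse = ", "))
    er <- expr["ESR1", ] >= thresholds[["ESR1"]]
    pr <- expr["PGR", ] >= thresholds[["PGR"]]
    her2 <- expr["ERBB2", ] >= thresholds[["ERBB2"]]
    data.frame(sample_id = colnames(expr), er = er, pr = pr, her2 = her2,
               tripleNegative = !er & !pr & !her2, row.names = NULL)
}

#' The marker decision-tree panel
#'
#' The built-in panel: anchor `CAMK2N1` (low expression associated with
#' invasive disease), the four Progressor genes `MNX1`, `HOXC11`,
#' `ANKRD22`, `ADCY5` (low = IDC-associated), refiner `SCGB2A1` (high =
#' IDC-associated) and rescuer `THRSP` (low = IDC-associated). `HOXC10`
#' and `HOTAIR` are carried as annotations only and take no part in the
#' tree. Per-gene high/low cuts default to the pooled per-gene median of
#' the supplied expression when not given.
#'
#' @param cuts optional named numeric of log2-CPM cut points per gene.
#' @return data.frame (`gene`, `role`, `idcAssociated`, `cut`).
#' @export
markerPanel <- function(cuts = NULL) {
    panel <- .MARKER.GENES[.MARKER.GENES$role %in%
                           c("anchor", "progressor", "refiner", "rescuer",
                             "annotation"), ]
    panel$cut <- if (is.null(cuts)) NA_real_ else unname(cuts[panel$gene])
    panel
}

## IDC-associated side of the cut: "low" genes are on the IDC side at or
## below the cut, "high" genes strictly above it.
.onIdcSide <- function(values, cut, direction) {
    if (direction == "low") values <= cut else values > cut
}

#' Per-patient marker call from in-situ samples
#'
#' A patient is called IDC-associated for a gene when at least
#' `minSamples` of their in-situ (DCIS) samples fall on the IDC-associated
#' side of the expression cut. Patients with fewer than `minSamples`
#' usable samples are Unassigned (`NA`).
#'
#' @param expr log2-CPM matrix.
#' @param meta data.frame-like with rownames = sample IDs and columns
#'   `patient` and `tissue`; only `tissue == "DCIS"` samples are used.
#' @param gene marker gene ID (must be present in `expr`).
#' @param cut log2-CPM cut point; defaults to the pooled median over the
#'   used samples.
#' @param direction which side of the cut is IDC-associated (`"low"` or
#'   `"high"`).
#' @param minSamples samples required both for eligibility and for an
#'   IDC-associated call (default 2).
#' @return named logical per patient; `NA` = Unassigned.
#' @export
patientMarkerStatus <- function(expr, meta, gene, cut = NULL,
                                direction = c("low", "high"),
                                minSamples = 2L) {
    direction <- match.arg(direction)
    if (!gene %in% rownames(expr)) stop("gene absent from expression: ", gene)
    meta <- as.data.frame(meta)
    use <- rownames(meta)[meta$tissue == "DCIS"]
    use <- intersect(use, colnames(expr))
    vals <- expr[gene, use]
    if (is.null(cut) || is.na(cut)) cut <- median(vals)
    patient <- meta[use, "patient"]
    vapply(split(vals, patient), function(v) {
        if (length(v) < minSamples) return(NA)
        sum(.onIdcSide(v, cut, direction)) >= minSamples
    }, logical(1))
}

#' Progressor-gene tally
#'
#' Number of the four Progressor genes (MNX1, HOXC11, ANKRD22, ADCY5)
#' called down-regulated (IDC-associated) for each patient; `NA` in any
#' call propagates to an `NA` tally (Unassigned).
#'
#' @param calls logical matrix or data.frame, patients x 4 progressor
#'   calls.
#' @return named integer vector, 0-4 or `NA`.
#' @export
progressorTally <- function(calls) {
    calls <- as.matrix(calls)
    if (ncol(calls) != 4) stop("expected calls for the 4 progressor genes")
    tally <- rowSums(calls)
    as.integer(round(tally))
}

#' The hazard decision tree
#'
#' Deterministic, total rule set over the per-patient calls:
#' \itemize{
#'   \item anchor (CAMK2N1) IDC-associated (low) -> `HigherHazard`;
#'   \item otherwise tally 3-4 -> `HigherHazard` (within this branch, when
#'     the refiner is not IDC-associated, a rescuer (THRSP) that is *not*
#'     IDC-associated, i.e. still high, is recorded as a mitigating
#'     sub-label);
#'   \item otherwise tally 2 -> `Indeterminate` (the printed rules cover
#'     0-1 and 3-4 only);
#'   \item otherwise (tally 0-1): refiner (SCGB2A1) not IDC-associated
#'     (low) -> `LowerHazard`; refiner IDC-associated (high) ->
#'     `HigherHazard`.
#' }
#' Any `NA` call needed by the applicable rule gives `Unassigned`.
#'
#' @param anchorCall,refinerCall,rescuerCall logical IDC-associated calls
#'   (see [patientMarkerStatus()]).
#' @param tally integer 0-4 from [progressorTally()].
#' @return data.frame (`group` factor with levels `LowerHazard`,
#'   `HigherHazard`, `Indeterminate`, `Unassigned`; `rescuerMitigated`
#'   logical sub-label).
#' @export
assignHazard <- function(anchorCall, tally, refinerCall,
                         rescuerCall = NA) {
    n <- max(length(anchorCall), length(tally))
    anchorCall <- rep_len(anchorCall, n); tally <- rep_len(tally, n)
    refinerCall <- rep_len(refinerCall, n)
    rescuerCall <- rep_len(rescuerCall, n)
    group <- character(n); mitig <- rep(FALSE, n)
    for (i in seq_len(n)) {
        a <- anchorCall[i]; k <- tally[i]; rf <- refinerCall[i]
        rs <- rescuerCall[i]
        group[i] <- if (is.na(a) || is.na(k)) "Unassigned"
            else if (a) "HigherHazard"
            else if (k >= 3) {
                if (!is.na(rf) && !rf && !is.na(rs) && !rs)
                    mitig[i] <- TRUE
                "HigherHazard"
            }
            else if (k == 2) "Indeterminate"
            else if (is.na(rf)) "Unassigned"
            else if (rf) "HigherHazard" else "LowerHazard"
    }
    data.frame(group = factor(group,
                              levels = c("LowerHazard", "HigherHazard",
                                         "Indeterminate", "Unassigned")),
               rescuerMitigated = mitig)
}

#' Assign every patient a hazard group from expression
#'
#' Computes the per-patient marker calls for the anchor, the four
#' Progressor genes, the refiner and the rescuer from in-situ samples,
#' tallies the Progressors and runs the decision tree.
#'
#' @inheritParams patientMarkerStatus
#' @param cuts optional named numeric log2-CPM cuts per panel gene;
#'   pooled per-gene medians when missing.
#' @return data.frame, one row per patient: the individual calls, `tally`,
#'   `group` and `rescuerMitigated`.
#' @export
assignHazardGroups <- function(expr, meta, cuts = NULL, minSamples = 2L) {
    panel <- markerPanel(cuts)
    panel <- panel[panel$role != "annotation", ]
    call1 <- function(g) {
        row <- panel[panel$gene == g, ]
        patientMarkerStatus(expr, meta, g, cut = row$cut,
                            direction = row$idcAssociated,
                            minSamples = minSamples)
    }
    anchor <- call1("CAMK2N1")
    prog <- vapply(c("MNX1", "HOXC11", "ANKRD22", "ADCY5"), call1,
                   logical(length(anchor)))
    refiner <- call1("SCGB2A1")
    rescuer <- call1("THRSP")
    tally <- progressorTally(prog)
    hz <- assignHazard(anchor, tally, refiner, rescuer)
    data.frame(patient = names(anchor), anchorCall = anchor,
               tally = tally, refinerCall = refiner,
               rescuerCall = rescuer, hz, row.names = NULL)
}

#' Enrichment fold between two outcome proportions
#'
#' The fold by which a decision-tree group is enriched for one outcome
#' over another: the proportion of outcome-A patients falling in the group
#' divided by the proportion of outcome-B patients falling in it,
#' reported to one decimal.
#'
#' @param propA,propB the two group-membership proportions (in `[0, 1]`);
#'   `propB = 0` gives an infinite fold.
#' @return list with `fold` (one-decimal report), `ratio` (unrounded),
#'   `propA`, `propB`.
#' @examples
#' enrichmentFold(0.36, 0.10)$fold  # 3.6
#' @export
enrichmentFold <- function(propA, propB) {
    stopifnot(propA >= 0, propA <= 1, propB >= 0, propB <= 1)
    ratio <- if (propB == 0) Inf else propA / propB
    list(fold = round(ratio, 1), ratio = ratio, propA = propA,
         propB = propB)
}

#' @rdname enrichmentFold
#' @param assignments data.frame from [assignHazardGroups()].
#' @param outcome named vector of patient outcomes (e.g. `Pure` /
#'   `NotPure`) covering `assignments$patient`.
#' @param group hazard group whose enrichment is measured.
#' @param outcomeA,outcomeB outcome labels for the numerator and
#'   denominator proportions.
#' @return `hazardEnrichment()`: the [enrichmentFold()] list plus the
#'   patient counts behind each proportion.
#' @export
hazardEnrichment <- function(assignments, outcome, group = "LowerHazard",
                             outcomeA = "Pure", outcomeB = "NotPure") {
    out <- outcome[assignments$patient]
    assigned <- assignments$group != "Unassigned"
    inA <- assigned & out == outcomeA
    inB <- assigned & out == outcomeB
    if (!any(inA) || !any(inB)) stop("both outcome classes must be present")
    pA <- mean(assignments$group[inA] == group)
    pB <- mean(assignments$group[inB] == group)
    c(enrichmentFold(pA, pB),
      list(nA = sum(inA), nB = sum(inB), group = group))
}

#' Cumulative-frequency comparison with a two-sided Fisher test
#'
#' Dichotomises two expression samples at a common point (the pooled
#' median by default) and applies the two-sided Fisher exact test to the
#' resulting 2x2 table; the empirical CDFs are returned for plotting.
#' A degenerate table (an empty margin) gives p = 1 with a warning.
#'
#' @param a,b numeric expression values for the two groups (nonempty).
#' @param at dichotomisation point.
#' @return list with `table`, `oddsRatio`, `p`, `at`, `ecdfA`, `ecdfB`.
#' @export
ecdfFisherCompare <- function(a, b, at = NULL) {
    if (!length(a) || !length(b)) stop("both groups must be nonempty")
    if (is.null(at)) at <- median(c(a, b))
    tab <- rbind(A = c(below = sum(a <= at), above = sum(a > at)),
                 B = c(below = sum(b <= at), above = sum(b > at)))
    if (any(colSums(tab) == 0)) {
        warning("degenerate table (empty margin); p = 1")
        return(list(table = tab, oddsRatio = NA_real_, p = 1, at = at,
                    ecdfA = stats::ecdf(a), ecdfB = stats::ecdf(b)))
    }
    ft <- fisher.test(tab)
    list(table = tab, oddsRatio = unname(ft$estimate), p = ft$p.value,
         at = at, ecdfA = stats::ecdf(a), ecdfB = stats::ecdf(b))
}
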
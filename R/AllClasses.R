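#' @import methods
#' @importFrom stats approx cor cor.test fisher.test lm lm.fit lowess median
#'   p.adjust phyper pt quantile rbinom rnbinom rnorm runif sd setNames
#'   t.test var coef complete.cases ecdf
#' @importFrom utils read.delim write.table head
NULL

#' Fitted principal curve with arc-length sample projections
#'
#' Container for a one-dimensional principal curve fitted in principal
#' component space by the Hastie-Stuetzle alternating smoothing/projection
#' algorithm. Each sample is projected orthogonally onto the curve and
#' carries an arc-length coordinate (its position on the progression
#' continuum, the "principal curve projection" or PCP position) and a
#' perpendicular projection distance.
#'
#' @slot vertices numeric matrix, ordered polyline vertices in PC space.
#' @slot arcLength numeric, cumulative arc length at each vertex.
#' @slot positions named numeric, arc-length position per sample.
#' @slot distances named numeric, squared orthogonal projection distance.
#' @slot msdTrace numeric, mean squared projection distance per iteration.
#' @slot converged logical flag; `FALSE` means the iteration limit was hit
#'   and the best iterate is returned.
#'
#' @seealso [fitPrincipalCurve()], [orderSamples()]
#' @export
setClass("PrincipalCurveModel",
    representation(
        vertices = "matrix",
        arcLength = "numeric",
        positions = "numeric",
        distances = "numeric",
        msdTrace = "numeric",
        converged = "logical"
    )
)

setValidity("PrincipalCurveModel", function(object) {
    msg <- character()
    if (nrow(object@vertices) != length(object@arcLength))
        msg <- c(msg, "one arc length per vertex required")
    if (is.unsorted(object@arcLength, strictly = FALSE))
        msg <- c(msg, "arc lengths must be non-decreasing")
    if (length(object@positions) != length(object@distances))
        msg <- c(msg, "positions and distances must align")
    if (is.null(names(object@positions)))
        msg <- c(msg, "positions must be named by sample")
    if (length(msg)) msg else TRUE
})

#' @describeIn PrincipalCurveModel compact summary
#' @param object a `PrincipalCurveModel`
#' @export
setMethod("show", "PrincipalCurveModel", function(object) {
    cat("PrincipalCurveModel\n")
    cat("  samples:   ", length(object@positions), "\n", sep = "")
    cat("  vertices:  ", nrow(object@vertices), " (", ncol(object@vertices),
        "-D)\n", sep = "")
    cat("  curve len: ", format(max(object@arcLength), digits = 5), "\n",
        sep = "")
    cat("  final MSD: ",
        format(object@msdTrace[length(object@msdTrace)], digits = 5), " after ",
        length(object@msdTrace), " iterations (converged: ",
        object@converged, ")\n", sep = "")
})

#' @rdname PrincipalCurveModel
#' @param curve a `PrincipalCurveModel`
#' @return `curvePositions()`: named numeric vector of arc-length positions.
#' @export
curvePositions <- function(curve) curve@positions

#' @rdname PrincipalCurveModel
#' @return `curveVertices()`: matrix of polyline vertices.
#' @export
curveVertices <- function(curve) curve@vertices

#' @rdname PrincipalCurveModel
#' @return `curveDistances()`: named numeric vector of squared projection
#'   distances.
#' @export
curveDistances <- function(curve) curve@distances

#' Bookkeeping for the four-stage sample quality filter
#'
#' Records which samples were removed at each stage of [runQC()] (library
#' metrics, iterative cohort correlation, patient-vs-cohort correlation,
#' iterative patient correlation) and which were retained. The partition is
#' exact: every input sample appears in exactly one list.
#'
#' @slot input character, all sample IDs presented to the filter.
#' @slot removed list of character vectors, one per stage, named
#'   `metrics`, `cohort`, `patientVsCohort`, `patient`.
#' @slot retained character, samples surviving all stages.
#'
#' @seealso [runQC()], [qcRetained()], [qcRemoved()]
#' @export
setClass("QCReport",
    representation(
        input = "character",
        removed = "list",
        retained = "character"
    )
)

setValidity("QCReport", function(object) {
    msg <- character()
    all.removed <- unlist(object@removed, use.names = FALSE)
    parts <- c(all.removed, object@retained)
    if (anyDuplicated(parts))
        msg <- c(msg, "removed/retained lists must be disjoint")
    if (!setequal(parts, object@input) || length(parts) != length(object@input))
        msg <- c(msg, "removed and retained must partition the input samples")
    if (!identical(names(object@removed),
                   c("metrics", "cohort", "patientVsCohort", "patient")))
        msg <- c(msg, "removed must have the four stage names in order")
    if (length(msg)) msg else TRUE
})

#' @describeIn QCReport per-stage counts
#' @param object a `QCReport`
#' @export
setMethod("show", "QCReport", function(object) {
    cat("QCReport: ", length(object@input), " samples in\n", sep = "")
    n <- vapply(object@removed, length, integer(1))
    stage.label <- c("library metrics", "cohort correlation",
                     "patient-vs-cohort", "patient correlation")
    for (i in seq_along(n))
        cat(sprintf("  removed by %-20s %d\n", paste0(stage.label[i], ":"),
                    n[i]))
    cat("  retained:                       ", length(object@retained), "\n",
        sep = "")
})

#' @rdname QCReport
#' @param report a `QCReport`
#' @return `qcRetained()`: character vector of retained sample IDs.
#' @export
qcRetained <- function(report) report@retained

#' @rdname QCReport
#' @param stage optional stage name (`"metrics"`, `"cohort"`,
#'   `"patientVsCohort"`, `"patient"`); default all stages.
#' @return `qcRemoved()`: character vector (one stage) or named list (all
#'   stages) of removed sample IDs.
#' @export
qcRemoved <- function(report, stage = NULL) {
    if (is.null(stage)) return(report@removed)
    stage <- match.arg(stage, names(report@removed))
    report@removed[[stage]]
}

#' @rdname QCReport
#' @return `qcCounts()`: named integer vector with the input size, the four
#'   per-stage removal counts and the retained count. The counts always
#'   satisfy input = retained + sum(removed).
#' @export
qcCounts <- function(report) {
    n <- vapply(report@removed, length, integer(1))
    c(input = length(report@input), n, retained = length(report@retained))
}

#' Retained-sample count from stage-wise removal bookkeeping
#'
#' The conservation arithmetic of the quality filter: starting from
#' `nInput` samples, each stage removes a disjoint set, so the final
#' retained count is the input count minus the per-stage removals. Used to
#' check a [QCReport()] against externally reported stage counts.
#'
#' @param nInput number of samples entering the filter.
#' @param removedPerStage integer vector of per-stage removal counts.
#' @return integer retained count.
#' @examples
#' retainedAfter(2724, c(414, 43, 45))
#' @export
retainedAfter <- function(nInput, removedPerStage) {
    stopifnot(nInput >= 0, all(removedPerStage >= 0),
              sum(removedPerStage) <= nInput)
    as.integer(nInput - sum(removedPerStage))
}
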
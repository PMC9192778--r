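## Gene filtering, TMM normalisation factors and log2-CPM transformation.

.asCounts <- function(object) {
    if (methods::is(object, "SummarizedExperiment"))
        SummarizedExperiment::assay(object, "counts")
    else as.matrix(object)
}

#' Filter genes by expression prevalence
#'
#' Retains genes with a nonzero count in at least `ceiling(minFrac * n)`
#' of the `n` samples (default: expressed in at least 5% of samples).
#' Gene order is preserved.
#'
#' @param object counts matrix or `SummarizedExperiment`.
#' @param minFrac required expressed fraction, in (0, 1].
#' @return the input object restricted to the retained genes.
#' @export
filterGenes <- function(object, minFrac = 0.05) {
    stopifnot(minFrac > 0, minFrac <= 1)
    counts <- .asCounts(object)
    need <- ceiling(minFrac * ncol(counts))
    keep <- rowSums(counts > 0) >= need
    if (!any(keep)) warning("no genes pass the expression filter")
    object[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalisation factors
#'
#' Computes per-sample TMM scaling factors (trimmed, weighted mean of
#' log-ratios against a reference sample, with 30% trimming on M values,
#' 5% on A values and inverse-asymptotic-variance weights; the reference is
#' the sample whose upper quartile is closest to the mean upper quartile).
#' The computation is delegated to `edgeR::calcNormFactors()`, whose TMM
#' method is the published definition; factors are rescaled to geometric
#' mean 1.
#'
#' @param object counts matrix or `SummarizedExperiment`; at least two
#'   samples, none with zero total count.
#' @return list with numeric vectors `tmm` (normalisation factor per
#'   sample, geometric mean 1) and `libSize` (column sums).
#' @export
tmmFactors <- function(object) {
    counts <- .asCounts(object)
    if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
    lib <- colSums(counts)
    if (any(lib == 0))
        stop("sample(s) with zero total count: ",
             paste(colnames(counts)[lib == 0], collapse = ", "))
    f <- edgeR::calcNormFactors(counts, method = "TMM")
    f <- f / exp(mean(log(f)))
    list(tmm = setNames(f, colnames(counts)),
         libSize = setNames(lib, colnames(counts)))
}

#' Log2 counts-per-million on TMM-effective library sizes
#'
#' `value = log2((count + 0.5) / (libSize * tmm + 1) * 1e6)`, the
#' voom-style prior-count convention (half a count added to the numerator,
#' one to the effective library size), strictly monotone in the count.
#'
#' @param object counts matrix or `SummarizedExperiment`.
#' @param factors optional result of [tmmFactors()] aligned to the samples;
#'   computed from `object` when missing.
#' @return numeric matrix of log2-CPM values with the input dimnames.
#' @export
logCPM <- function(object, factors = NULL) {
    counts <- .asCounts(object)
    if (is.null(factors)) factors <- tmmFactors(counts)
    if (!setequal(names(factors$tmm), colnames(counts)) ||
        length(factors$tmm) != ncol(counts))
        stop("normalisation factors do not match the sample set")
    eff <- factors$libSize[colnames(counts)] * factors$tmm[colnames(counts)]
    log2(sweep(counts + 0.5, 2, eff + 1, "/") * 1e6)
}
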
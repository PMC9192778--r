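## Panel-based PCA, Hastie-Stuetzle principal curve, arc-length ordering
## (the principal curve projection, PCP), segmentation and position
## statistics.

#' Panel-gene PCA with out-of-sample embedding
#'
#' PCA (SVD of the column-centred panel-gene matrix) fitted on a subset of
#' samples; all samples are then projected using the fitting-set centring
#' vector and loadings. Fitting on the contrast samples only and embedding
#' the rest avoids the embedded tissues influencing the axes.
#'
#' @param expr log2-CPM matrix (genes x samples).
#' @param panel character vector of panel gene IDs (all must be present).
#' @param fitSamples sample IDs the PCA is fitted on.
#' @param allSamples sample IDs to project (default: all columns);
#'   must contain `fitSamples`.
#' @return list with `coords` (samples x PCs score matrix) and `model`
#'   (list: `center`, `rotation` with orthonormal columns, `varExplained`
#'   non-increasing fractions).
#' @export
pcaEmbedPanel <- function(expr, panel, fitSamples,
                          allSamples = colnames(expr)) {
    missing <- setdiff(panel, rownames(expr))
    if (length(missing))
        stop("panel gene(s) absent from expression matrix: ",
             paste(head(missing, 5), collapse = ", "))
    if (!all(fitSamples %in% allSamples))
        stop("fitSamples must be a subset of allSamples")
    X <- t(expr[panel, fitSamples, drop = FALSE])
    center <- colMeans(X)
    sv <- svd(sweep(X, 2, center))
    rotation <- sv$v
    rownames(rotation) <- panel
    colnames(rotation) <- paste0("PC", seq_len(ncol(rotation)))
    coords <- sweep(t(expr[panel, allSamples, drop = FALSE]), 2,
                    center) %*% rotation
    list(coords = coords,
         model = list(center = center, rotation = rotation,
                      varExplained = sv$d^2 / sum(sv$d^2)))
}

## Project points (n x d) onto a polyline (m x d vertices); returns the
## arc-length position of the closest point on the polyline and the
## squared orthogonal distance, minimised over segments.
.projectToPolyline <- function(points, vertices) {
    n <- nrow(points); m <- nrow(vertices)
    seg <- diff(vertices)                       # (m-1) x d
    len2 <- rowSums(seg^2)
    cum <- c(0, cumsum(sqrt(len2)))
    best.d2 <- rep(Inf, n)
    best.pos <- rep(0, n)
    for (i in seq_len(m - 1)) {
        if (len2[i] == 0) next
        rel <- sweep(points, 2, vertices[i, ])
        tt <- pmin(pmax(as.vector(rel %*% seg[i, ]) / len2[i], 0), 1)
        d2 <- rowSums((rel - outer(tt, seg[i, ]))^2)
        upd <- d2 < best.d2
        best.d2[upd] <- d2[upd]
        best.pos[upd] <- cum[i] + tt[upd] * sqrt(len2[i])
    }
    list(position = setNames(best.pos, rownames(points)),
         dist2 = setNames(best.d2, rownames(points)),
         arcLength = cum)
}

#' Fit a principal curve by the Hastie-Stuetzle algorithm
#'
#' Alternating smoothing and projection: sample positions are initialised
#' by PC1 rank; each coordinate is then smoothed against arc-length
#' position with a local-linear scatterplot smoother (`lowess`, span
#' `span`), the smooth is discretised into an ordered polyline, every
#' sample is projected orthogonally onto the polyline, and positions are
#' re-parameterised by cumulative arc length. Iteration stops when the
#' mean squared projection distance changes by less than `tol`
#' (relatively) or after `maxIter` iterations, in which case the best
#' iterate is returned with a warning and `converged = FALSE`.
#'
#' @param points numeric matrix (samples x dimensions, typically the first
#'   two PC scores); at least 10 finite points.
#' @param maxIter maximum number of smoothing/projection rounds.
#' @param tol relative tolerance on the mean squared projection distance.
#' @param span lowess smoother span.
#' @param nVertices number of polyline vertices the smooth is discretised
#'   into (capped at the number of samples).
#' @return a [PrincipalCurveModel-class].
#' @export
fitPrincipalCurve <- function(points, maxIter = 50, tol = 1e-4, span = 0.6,
                              nVertices = 250) {
    points <- as.matrix(points)
    if (nrow(points) < 10) stop("need at least 10 points")
    if (!all(is.finite(points))) stop("points must be finite")
    ids <- rownames(points)
    if (is.null(ids)) ids <- rownames(points) <- sprintf(
        "p%05d", seq_len(nrow(points)))
    d <- ncol(points)
    lambda <- rank(points[, 1], ties.method = "first")
    nV <- min(nVertices, nrow(points))

    best <- NULL
    msd <- numeric()
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        grid <- seq(min(lambda), max(lambda), length.out = nV)
        V <- vapply(seq_len(d), function(k) {
            lw <- lowess(lambda, points[, k], f = span)
            approx(lw$x, lw$y, xout = grid, rule = 2, ties = mean)$y
        }, numeric(nV))
        V <- V[!duplicated(V), , drop = FALSE]
        pr <- .projectToPolyline(points, V)
        msd <- c(msd, mean(pr$dist2))
        if (is.null(best) || msd[it] <= best$msd)
            best <- list(V = V, pr = pr, msd = msd[it])
        if (it > 1 && abs(msd[it] - msd[it - 1]) <
                tol * max(msd[it - 1], .Machine$double.eps)) {
            converged <- TRUE
            break
        }
        lambda <- pr$position
    }
    if (!converged)
        warning("principal curve did not converge in ", maxIter,
                " iterations; returning best iterate")
    methods::new("PrincipalCurveModel",
                 vertices = best$V,
                 arcLength = best$pr$arcLength,
                 positions = best$pr$position,
                 distances = best$pr$dist2,
                 msdTrace = msd,
                 converged = converged)
}

#' Order samples along the curve (the PCP ordering)
#'
#' Samples sorted by their arc-length position. When tissue labels are
#' supplied the orientation is fixed so that the mean position of normal
#' and benign epithelium is smaller than that of invasive (IDC) samples --
#' i.e. the continuum runs from normal towards invasive disease. Ties are
#' broken by sample ID for determinism.
#'
#' @param curve a [PrincipalCurveModel-class].
#' @param tissue optional named (or curve-aligned) tissue labels used for
#'   orientation.
#' @param lowTissues,highTissues tissue labels anchoring the start and end
#'   of the continuum.
#' @return data.frame (`sample_id`, `position`, `rank`) sorted by rank,
#'   with attribute `flipped` recording whether orientation was reversed.
#' @export
orderSamples <- function(curve, tissue = NULL,
                         lowTissues = c("normal", "benign"),
                         highTissues = "IDC") {
    pos <- curvePositions(curve)
    flipped <- FALSE
    if (!is.null(tissue)) {
        if (is.null(names(tissue))) names(tissue) <- names(pos)
        lo <- pos[names(tissue)[tissue %in% lowTissues]]
        hi <- pos[names(tissue)[tissue %in% highTissues]]
        if (length(lo) && length(hi) && mean(lo) > mean(hi)) {
            pos <- max(curve@arcLength) - pos
            flipped <- TRUE
        }
    }
    ord <- order(pos, names(pos))
    out <- data.frame(sample_id = names(pos)[ord], position = pos[ord],
                      rank = seq_along(pos), row.names = NULL)
    attr(out, "flipped") <- flipped
    out
}

#' Early/late segment boundaries on the ordering
#'
#' @param E1,E2,L1,L2 boundaries with `E1 < E2 <= L1 < L2`; interpreted as
#'   rank quantiles by [segmentPositions()] when `quantiles = TRUE`
#'   (the default placement), otherwise as arc-length positions.
#' @return named numeric vector.
#' @export
segmentBoundaries <- function(E1 = 0.15, E2 = 0.45, L1 = 0.55, L2 = 0.85) {
    if (!(E1 < E2 && E2 <= L1 && L1 < L2))
        stop("boundaries must satisfy E1 < E2 <= L1 < L2")
    c(E1 = E1, E2 = E2, L1 = L1, L2 = L2)
}

#' Assign ordered samples to continuum segments
#'
#' Labels every sample with one of `preE1`, `E1E2` (the early stage),
#' `mid`, `L1L2` (the late stage) or `postL2`. Intervals are left-closed:
#' a sample exactly at a boundary belongs to the segment the boundary
#' opens.
#'
#' @param order data.frame from [orderSamples()].
#' @param boundaries a [segmentBoundaries()] vector.
#' @param quantiles `TRUE` (default) treats boundaries as rank quantiles;
#'   `FALSE` as arc-length positions.
#' @return factor of segment labels aligned to `order$sample_id`.
#' @export
segmentPositions <- function(order, boundaries = segmentBoundaries(),
                             quantiles = TRUE) {
    b <- segmentBoundaries(boundaries[["E1"]], boundaries[["E2"]],
                           boundaries[["L1"]], boundaries[["L2"]])
    if (quantiles) {
        # rank <= q*n stays below the boundary; the first rank strictly
        # above q*n opens the next segment (left-closed convention)
        x <- order$rank
        cut.at <- b * nrow(order) + 1e-9
        below <- function(v, c) v <= c
    } else {
        x <- order$position
        cut.at <- b
        below <- function(v, c) v < c
    }
    lab <- ifelse(below(x, cut.at[1]), "preE1",
           ifelse(below(x, cut.at[2]), "E1E2",
           ifelse(below(x, cut.at[3]), "mid",
           ifelse(below(x, cut.at[4]), "L1L2", "postL2"))))
    factor(setNames(lab, order$sample_id),
           levels = c("preE1", "E1E2", "mid", "L1L2", "postL2"))
}

#' Welch comparison of PCP positions between two patient groups
#'
#' Two-sided Welch unequal-variance two-sample t-test of arc-length
#' positions, e.g. lesions from patients with pure in-situ disease versus
#' patients with an invasive diagnosis.
#'
#' @param positions numeric vector of positions.
#' @param group two-level factor aligned to `positions`; both groups must
#'   have at least 2 values.
#' @return list with `meanDiff` (first level minus second), `t`, `df`,
#'   `p`.
#' @export
compareGroupPositions <- function(positions, group) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) != 2) stop("exactly two groups required")
    a <- positions[group == levels(group)[1]]
    b <- positions[group == levels(group)[2]]
    if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
    ht <- t.test(a, b, var.equal = FALSE)
    list(meanDiff = mean(a) - mean(b), t = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
}

#' Spearman trend of one gene's expression over ordered tissue groups
#'
#' Spearman rank correlation between expression and the ordinal tissue
#' code (normal < benign < atypia < DCIS < IDC), with a two-sided,
#' uncorrected p-value.
#'
#' @param expr numeric expression values for one gene.
#' @param tissue tissue labels aligned to `expr`; at least two distinct
#'   levels must be present.
#' @param levels the tissue order.
#' @return list with `rho` and `p`; constant expression gives `rho = NA`
#'   with a `note`.
#' @export
spearmanTissueTrend <- function(expr, tissue,
                                levels = c("normal", "benign", "atypia",
                                           "DCIS", "IDC")) {
    code <- as.integer(factor(tissue, levels = levels))
    if (anyNA(code)) stop("unknown tissue label(s)")
    if (length(unique(code)) < 2)
        stop("at least two distinct tissue levels required")
    if (sd(expr) == 0)
        return(list(rho = NA_real_, p = NA_real_,
                    note = "constant expression; rho undefined"))
    ct <- suppressWarnings(cor.test(expr, code, method = "spearman",
                                    exact = FALSE))
    list(rho = unname(ct$estimate), p = ct$p.value)
}
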
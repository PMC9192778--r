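## Moderated two-group differential expression on log2-CPM with voom
## precision weights, a consensus intra-patient correlation and
## empirical-Bayes variance shrinkage; Benjamini-Hochberg correction and
## panel selection for the pseudotime.

#' Two-group moderated differential expression with patient blocking
#'
#' Fits a per-gene linear model of the group effect on voom-transformed
#' counts. With `patient` supplied, voom precision weights are estimated,
#' a single consensus intra-patient correlation is estimated (see
#' [consensusCorrelation()]), and the fit runs exact generalized least
#' squares under the compound-symmetry patient block at that correlation
#' (numerically identical to limma's generic blocked fit, but in closed
#' form). Moderated t-statistics come from empirical-Bayes shrinkage of
#' the residual variances toward a pooled prior (`limma::squeezeVar`),
#' matching `limma::eBayes`. The sign convention is `log2FC > 0` means
#' higher expression in the *second* level of `groups`.
#'
#' Setting `moderated = FALSE`, `weights = FALSE` and `patient = NULL`
#' reduces the result to the ordinary two-sample regression t-test, which
#' is how the machinery is validated.
#'
#' @param object counts matrix or `SummarizedExperiment`.
#' @param groups two-level factor aligned to samples.
#' @param patient optional patient IDs for blocking; a group lying entirely
#'   within one patient is an error (the effect is confounded).
#' @param moderated apply empirical-Bayes moderation (default `TRUE`).
#' @param weights apply voom precision weights (default `TRUE`).
#' @param corFrac fraction of most-expressed genes the consensus
#'   intra-patient correlation is estimated on (default 0.1); the
#'   correlation of a random pair of measurements is a single cohort-level
#'   number, so estimating it on the best-measured tenth of the
#'   transcriptome is both stabler and far cheaper than using every gene.
#' @return data.frame with rownames = gene IDs and columns `log2FC`, `t`,
#'   `p`, `adjP` (BH-adjusted).
#' @export
fitDE <- function(object, groups, patient = NULL, moderated = TRUE,
                  weights = TRUE, corFrac = 0.1) {
    counts <- .asCounts(object)
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) != 2)
        stop("groups must have exactly two nonempty levels")
    if (length(groups) != ncol(counts))
        stop("groups must align to the samples")
    if (!is.null(patient)) {
        patient <- as.character(patient)
        if (length(patient) != ncol(counts))
            stop("patient labels must cover all samples")
        for (lev in levels(groups))
            if (length(unique(patient[groups == lev])) == 1 &&
                length(unique(patient)) > 1)
                stop("group '", lev, "' lies entirely within one patient; ",
                     "the group effect is confounded with the block")
    }
    design <- stats::model.matrix(~groups)
    nf <- tmmFactors(counts)
    eff <- nf$libSize * nf$tmm

    if (!is.null(patient)) {
        if (weights) {
            v <- limma::voom(counts, design, lib.size = eff)
            rho <- consensusCorrelation(v$E, groups, patient, corFrac)
            fit <- .glsBlockFit(v$E, v$weights, design, patient, rho)
        } else {
            expr <- logCPM(counts, nf)
            rho <- consensusCorrelation(expr, groups, patient, corFrac)
            fit <- .glsBlockFit(expr, NULL, design, patient, rho)
        }
    } else {
        fit <- if (weights)
            limma::lmFit(limma::voom(counts, design, lib.size = eff),
                         design)
        else limma::lmFit(logCPM(counts, nf), design)
    }

    if (moderated) {
        sv <- limma::squeezeVar(fit$sigma^2, fit$df.residual)
        tt <- fit$coefficients[, 2] /
            (fit$stdev.unscaled[, 2] * sqrt(sv$var.post))
        df.total <- pmin(fit$df.residual + sv$df.prior,
                         sum(fit$df.residual))
        p <- 2 * pt(-abs(tt), df = df.total)
    } else {
        tt <- fit$coefficients[, 2] / (fit$stdev.unscaled[, 2] * fit$sigma)
        p <- 2 * pt(-abs(tt), df = fit$df.residual)
    }
    data.frame(log2FC = fit$coefficients[, 2], t = tt, p = p,
               adjP = bhAdjust(p), row.names = rownames(counts))
}

## Exact generalized least squares for a compound-symmetry block
## correlation (equal correlation rho within each patient), vectorised
## across genes. The within-block correlation matrix (1-rho)I + rho*J has
## the closed-form symmetric inverse square root
##   a (I - J/m) + c (J/m),  a = 1/sqrt(1-rho), c = 1/sqrt(1+(m-1)rho),
## so whitening a row vector is "shrink the block mean, scale the rest" --
## O(n) per gene instead of the O(n^2) rotation of a generic GLS. With
## per-observation weights, rows of the response and design are scaled by
## sqrt(w) per gene before whitening (the same convention limma uses).
## Returns the pieces empirical-Bayes moderation needs.
.glsBlockFit <- function(E, W, design, patient, rho) {
    n <- ncol(E); p <- ncol(design)
    stopifnot(p == 2)   # intercept + group effect
    patient <- as.character(patient)
    blocks <- split(seq_len(n), patient)
    a <- 1 / sqrt(1 - rho)
    whiten <- function(M) {
        for (j in blocks) {
            c.b <- 1 / sqrt(1 + (length(j) - 1) * rho)
            mu <- rowMeans(M[, j, drop = FALSE])
            M[, j] <- (M[, j, drop = FALSE] - mu) * a + mu * c.b
        }
        M
    }
    S <- if (is.null(W)) matrix(1, nrow(E), n) else sqrt(W)
    Z <- whiten(E * S)
    X1 <- whiten(S)                              # intercept column
    X2 <- whiten(sweep(S, 2, design[, 2], "*"))  # group column
    x11 <- rowSums(X1 * X1); x12 <- rowSums(X1 * X2)
    x22 <- rowSums(X2 * X2)
    y1 <- rowSums(X1 * Z); y2 <- rowSums(X2 * Z)
    det <- x11 * x22 - x12^2
    b1 <- (x22 * y1 - x12 * y2) / det
    b2 <- (x11 * y2 - x12 * y1) / det
    rss <- rowSums(Z * Z) - (b1 * y1 + b2 * y2)
    df <- n - p
    coefficients <- cbind(b1, b2)
    colnames(coefficients) <- colnames(design)
    rownames(coefficients) <- rownames(E)
    su <- cbind(sqrt(x22 / det), sqrt(x11 / det))
    list(coefficients = coefficients, stdev.unscaled = su,
         sigma = sqrt(pmax(rss, 0) / df),
         df.residual = rep(df, nrow(E)))
}

#' Consensus intra-patient correlation
#'
#' A single cohort-level estimate of the correlation between repeated
#' measurements from one patient: per-gene intraclass correlations of the
#' group-effect residuals (one-way random-effects ANOVA over patients,
#' with the standard unbalanced-design group-size correction) are averaged
#' on the hyperbolic-arctangent scale over the `corFrac` most-expressed
#' genes and transformed back. The best-measured genes estimate this one
#' number with the least noise; it feeds the generalized-least-squares
#' step of [fitDE()] as the block correlation.
#'
#' @param expr expression matrix (genes x samples), typically voom's
#'   log2-CPM.
#' @param groups factor whose effect is removed before the ANOVA.
#' @param patient patient IDs (the blocks).
#' @param corFrac fraction of most-expressed genes used.
#' @return a single correlation in (-1, 1).
#' @export
consensusCorrelation <- function(expr, groups, patient, corFrac = 0.1) {
    n.top <- max(50L, min(nrow(expr), ceiling(corFrac * nrow(expr))))
    E <- expr[order(rowMeans(expr), decreasing = TRUE)[seq_len(n.top)], ,
              drop = FALSE]
    groups <- as.factor(groups)
    # residuals after the group effect, per gene
    for (lev in levels(groups)) {
        j <- groups == lev
        E[, j] <- E[, j] - rowMeans(E[, j, drop = FALSE])
    }
    patient <- droplevels(as.factor(patient))
    n <- ncol(E)
    np <- as.numeric(table(patient))
    P <- length(np)
    if (P < 2 || P == n) return(0)
    gs <- t(rowsum(t(E), patient))              # genes x patients sums
    gm <- sweep(gs, 2, np, "/")                 # patient means
    grand <- rowMeans(E)
    ssb <- rowSums(sweep(sweep(gm, 1, grand)^2, 2, np, "*"))
    sst <- rowSums(sweep(E, 1, grand)^2)
    msb <- ssb / (P - 1)
    msw <- (sst - ssb) / (n - P)
    k0 <- (n - sum(np^2) / n) / (P - 1)
    icc <- (msb - msw) / (msb + (k0 - 1) * msw)
    icc <- pmin(pmax(icc, -0.95), 0.95)
    tanh(mean(atanh(icc)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sorted p-values are multiplied by `n/rank`, a
#' cumulative minimum is taken from the largest rank down, values are
#' capped at 1 and returned in input order. Delegates to
#' `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NaN`/`NA` is an error.
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p))) stop("NaN/NA p-values are not allowed")
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    p.adjust(p, method = "BH")
}

#' Select the pseudotime gene panel from a DE table
#'
#' Genes significant below `alpha` (by default on the BH-adjusted
#' p-value, matching the convention of selecting the most significant
#' genes for the ordering), ordered by increasing significance.
#'
#' @param de data.frame from [fitDE()].
#' @param alpha significance cutoff (default `1e-5`).
#' @param useAdjusted select on `adjP` (default) or on raw `p`.
#' @return character vector of gene IDs ordered by adjusted p-value.
#' @export
selectPanel <- function(de, alpha = 1e-5, useAdjusted = TRUE) {
    col <- if (useAdjusted) "adjP" else "p"
    keep <- de[[col]] < alpha
    if (!any(keep))
        stop("no genes pass alpha = ", alpha, "; relax alpha")
    rownames(de)[keep][order(de$adjP[keep])]
}
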
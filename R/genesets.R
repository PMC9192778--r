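## Per-sample ssGSEA scoring, sliding-window over-representation along the
## PCP ordering, and residual-resampling bootstrap trend fits.

#' Sliding-window scan configuration
#'
#' @param window window size in samples (default 100).
#' @param step window step in samples (default 50); `0 < step <= window`.
#' @param fdrAlpha BH-adjusted cutoff flagging a window/set pair as
#'   enriched (default `1e-5`).
#' @param deAlpha within-window DE cutoff (adjusted p) defining the
#'   up-regulated hit list fed to the over-representation test.
#' @param ssgseaAlpha rank-weighting exponent for [ssgseaScores()].
#' @return named list of class `scanConfig`.
#' @export
scanConfig <- function(window = 100L, step = 50L, fdrAlpha = 1e-5,
                       deAlpha = 0.05, ssgseaAlpha = 0.25) {
    stopifnot(step > 0, step <= window, fdrAlpha > 0, fdrAlpha <= 1,
              deAlpha > 0, deAlpha <= 1, ssgseaAlpha > 0)
    structure(list(window = as.integer(window), step = as.integer(step),
                   fdrAlpha = fdrAlpha, deAlpha = deAlpha,
                   ssgseaAlpha = ssgseaAlpha), class = "scanConfig")
}

#' Single-sample gene-set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression; the score of a set is
#' the sum over the ranked list of the difference between the
#' rank-weighted (`rank^alpha`) empirical CDF of in-set genes and the
#' unweighted empirical CDF of out-of-set genes. Scores are rank-based and
#' therefore invariant to monotone transformations of the expression
#' values. With `normalize = TRUE` the whole score matrix is divided by
#' its range (max minus min), the standard ssGSEA normalisation.
#'
#' @param expr expression matrix (genes x samples), any monotone scale.
#' @param sets named list of gene-ID vectors; sets with fewer than 2
#'   expressed genes are skipped with a warning.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize min-max normalise the score matrix (default `TRUE`).
#' @return numeric matrix, sets x samples.
#' @export
ssgseaScores <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
    genes <- rownames(expr)
    sets <- lapply(sets, intersect, genes)
    ok <- lengths(sets) >= 2
    if (!all(ok)) {
        warning("skipping set(s) with <2 expressed genes: ",
                paste(names(sets)[!ok], collapse = ", "))
        sets <- sets[ok]
    }
    if (!length(sets)) stop("no usable gene sets")
    N <- nrow(expr)
    member <- vapply(sets, function(s) genes %in% s, logical(N))
    scores <- apply(expr, 2, function(x) {
        R <- rank(x, ties.method = "average")
        ord <- order(R, decreasing = TRUE)        # highest expression first
        w <- R[ord]^alpha
        m <- member[ord, , drop = FALSE]
        vapply(seq_len(ncol(m)), function(k) {
            inset <- m[, k]
            stepIn <- cumsum(w * inset) / sum(w[inset])
            stepOut <- cumsum(!inset) / (N - sum(inset))
            sum(stepIn - stepOut)
        }, numeric(1))
    })
    scores <- matrix(scores, nrow = length(sets),
                     dimnames = list(names(sets), colnames(expr)))
    if (normalize) {
        rng <- diff(range(scores))
        if (rng > 0) scores <- scores / rng
    }
    scores
}

#' Sliding-window over-representation scan along the ordering
#'
#' Slides a window of `config$window` samples along the PCP ordering in
#' steps of `config$step` (a final partial window is dropped). In each
#' window, genes up-regulated in the window versus all remaining samples
#' (via [fitDE()] at `adjP < config$deAlpha`, `log2FC > 0`) are tested per
#' gene set with a one-sided hypergeometric over-representation test
#' against the full gene background, with BH adjustment across sets within
#' the window.
#'
#' @param order data.frame from [orderSamples()].
#' @param object counts matrix or `SummarizedExperiment` containing all
#'   ordered samples.
#' @param sets named list of gene-ID vectors.
#' @param config a [scanConfig()].
#' @param deFun DE engine: `function(counts, groups)` returning a
#'   data.frame with rownames = genes and columns `log2FC`, `adjP`;
#'   defaults to [fitDE()] without blocking.
#' @return data.frame with one row per (window, set): `windowStart`,
#'   `windowEnd` (ranks), `set`, `overlap`, `nHits`, `fold`, `p`, `adjP`,
#'   `significant`.
#' @export
windowEnrichmentScan <- function(order, object, sets,
                                 config = scanConfig(), deFun = NULL) {
    counts <- .asCounts(object)[, order$sample_id, drop = FALSE]
    N <- nrow(order)
    if (N < config$window)
        stop("fewer samples (", N, ") than the window (", config$window, ")")
    if (is.null(deFun))
        deFun <- function(counts, groups) fitDE(counts, groups)
    background <- rownames(counts)
    sets <- lapply(sets, intersect, background)
    starts <- seq(1L, N - config$window + 1L, by = config$step)
    res <- lapply(starts, function(s) {
        idx <- seq(s, s + config$window - 1L)
        groups <- factor(ifelse(seq_len(N) %in% idx, "window", "rest"),
                         levels = c("rest", "window"))
        de <- deFun(counts, groups)
        hits <- rownames(de)[de$adjP < config$deAlpha & de$log2FC > 0]
        enr <- hypergeomEnrichment(hits, sets, background)
        data.frame(windowStart = s, windowEnd = s + config$window - 1L, enr)
    })
    out <- do.call(rbind, res)
    out$significant <- out$adjP < config$fdrAlpha
    out
}

#' One-sided hypergeometric over-representation of gene sets in a hit list
#'
#' For each set, the upper-tail hypergeometric probability of observing at
#' least the realised overlap between the hit list and the set, drawn from
#' the background; fold enrichment is the in-hit-list set proportion over
#' the background set proportion (0 when there is no overlap, with p = 1).
#' BH adjustment across sets.
#'
#' @param hits character vector of hit genes (subset of background).
#' @param sets named list of gene-ID vectors.
#' @param background the gene universe.
#' @return data.frame (`set`, `setSize`, `nHits`, `overlap`, `fold`, `p`,
#'   `adjP`).
#' @export
hypergeomEnrichment <- function(hits, sets, background) {
    hits <- intersect(hits, background)
    k <- length(hits)
    bg <- length(background)
    rows <- lapply(names(sets), function(nm) {
        s <- intersect(sets[[nm]], background)
        m <- length(s)
        q <- length(intersect(hits, s))
        p <- if (q == 0) 1 else phyper(q - 1, m, bg - m, k,
                                       lower.tail = FALSE)
        fold <- if (q == 0 || k == 0) 0 else (q / k) / (m / bg)
        data.frame(set = nm, setSize = m, nHits = k, overlap = q,
                   fold = fold, p = p)
    })
    out <- do.call(rbind, rows)
    out$adjP <- bhAdjust(out$p)
    out
}

#' Bootstrap linear trend of a per-sample score along the ordering
#'
#' Ordinary least squares of `score` on `positions`, with percentile
#' confidence intervals for the slope, the r-squared and the fitted line
#' obtained by residual resampling: residuals are drawn with replacement,
#' added back to the fitted values, and the model is refitted `nBoot`
#' times.
#'
#' @param score per-sample numeric score (e.g. an ssGSEA score).
#' @param positions PCP positions/ranks aligned to `score`; at least 10
#'   samples, not constant.
#' @param nBoot bootstrap replicates (default 10000).
#' @param seed integer seed; identical seeds give identical intervals.
#' @param level confidence level (default 0.95).
#' @param gridSize number of positions at which the fitted-line band is
#'   evaluated.
#' @return list with `slope`, `r2`, `slopeCI`, `r2CI`, `band`
#'   (data.frame `position`, `fit`, `lower`, `upper`) and `nBoot`.
#' @export
bootstrapTrend <- function(score, positions, nBoot = 10000L, seed = 1L,
                           level = 0.95, gridSize = 100L) {
    if (length(score) < 10) stop("need at least 10 samples")
    if (sd(positions) == 0) stop("positions are constant")
    X <- cbind(1, positions)
    fit <- lm.fit(X, score)
    slope <- unname(fit$coefficients[2])
    f <- fit$fitted.values
    res <- fit$residuals
    r2 <- 1 - sum(res^2) / sum((score - mean(score))^2)

    set.seed(seed)
    n <- length(score)
    H <- solve(crossprod(X), t(X))              # 2 x n projector
    grid <- seq(min(positions), max(positions), length.out = gridSize)
    Xg <- cbind(1, grid)
    slopes <- numeric(nBoot); r2s <- numeric(nBoot)
    lines <- matrix(NA_real_, nBoot, gridSize)
    chunk <- 1000L
    done <- 0L
    while (done < nBoot) {
        b <- min(chunk, nBoot - done)
        E <- matrix(sample(res, n * b, replace = TRUE), n, b)
        Y <- f + E
        B <- H %*% Y                            # 2 x b coefficients
        idx <- done + seq_len(b)
        slopes[idx] <- B[2, ]
        rss <- colSums((Y - X %*% B)^2)
        tss <- colSums(sweep(Y, 2, colMeans(Y))^2)
        r2s[idx] <- 1 - rss / tss
        lines[idx, ] <- t(Xg %*% B)
        done <- done + b
    }
    a <- (1 - level) / 2
    qs <- c(a, 1 - a)
    band <- apply(lines, 2, quantile, probs = qs)
    list(slope = slope, r2 = r2,
         slopeCI = unname(quantile(slopes, qs)),
         r2CI = unname(quantile(r2s, qs)),
         band = data.frame(position = grid, fit = as.vector(Xg %*%
                               c(fit$coefficients)),
                           lower = band[1, ], upper = band[2, ]),
         nBoot = nBoot)
}
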
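# Independent brute-force oracles used to validate the package's
# implementations. Each is written directly from the published definition
# of the statistic it checks, without reference to the implementation.

# Trimmed mean of M-values, computed directly: reference = sample whose
# upper quartile of count/libsize is closest to the mean upper quartile;
# per sample, two-sided rank trimming of 30% on M and 5% on A over genes
# nonzero in both sample and reference; weights = inverse asymptotic
# (delta-method) variance of M; factors rescaled to geometric mean 1.
naiveTMM <- function(counts) {
    lib <- colSums(counts)
    uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(counts)), function(j) {
        o <- counts[, j]; r <- counts[, ref]
        nO <- lib[j]; nR <- lib[ref]
        M <- log2((o / nO) / (r / nR))
        A <- (log2(o / nO) + log2(r / nR)) / 2
        v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
        fin <- is.finite(M) & is.finite(A)
        M <- M[fin]; A <- A[fin]; v <- v[fin]
        if (max(abs(M)) < 1e-6) return(1)
        n <- length(M)
        loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
        loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
        keep <- rank(M) >= loM & rank(M) <= hiM &
            rank(A) >= loA & rank(A) <= hiA
        2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
    }, numeric(1))
    f / exp(mean(log(f)))
}

# Benjamini-Hochberg by the step-up definition: sorted p * n / rank,
# cumulative minimum from the largest rank, capped at 1, input order.
naiveBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
}

# Two-sided Fisher exact p by full enumeration of all 2x2 tables with the
# observed margins: sum the hypergeometric probabilities of every table
# no more probable than the observed one.
enumFisher <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    xs <- max(0, r1 + c1 - n):min(r1, c1)
    pr <- dhyper(xs, c1, n - c1, r1)
    p.obs <- dhyper(tab[1, 1], c1, n - c1, r1)
    sum(pr[pr <= p.obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric by enumeration: probability of an overlap at
# least as large as observed between a hit list of size k and a set of
# size m drawn from a background of size bg.
enumHyperTail <- function(q, m, bg, k) {
    xs <- q:min(m, k)
    sum(dhyper(xs, m, bg - m, k))
}

# Iterative worst-sample removal, written naively: full recomputation of
# every leave-one-out correlation at each step with plain cor() loops.
naiveIterativeFilter <- function(expr, threshold) {
    ids <- colnames(expr)
    thr <- if (length(threshold) == 1)
        setNames(rep(threshold, length(ids)), ids) else threshold[ids]
    removed <- character()
    keep <- ids
    while (length(keep) > 2) {
        r <- sapply(keep, function(s) {
            m <- rowMeans(expr[, setdiff(keep, s), drop = FALSE])
            suppressWarnings(cor(expr[, s], m))
        })
        r[is.na(r)] <- -Inf
        deficit <- r - thr[keep]
        if (all(deficit >= 0)) break
        worst <- sort(names(deficit)[deficit == min(deficit)])[1]
        removed <- c(removed, worst)
        keep <- setdiff(keep, worst)
    }
    removed
}

# Small cohort configurations used across tests. Sizes are chosen so a
# single simulation stays around a second while keeping all five tissue
# types and several multi-lesion patients.
smallConfig <- function(seed = 1L, ...) {
    defaults <- list(nPatients = 15L, lesionsPerPatient = c(2L, 10L),
                     nGenes = 600L,
                     programSizes = c(basal = 60L, emt = 60L, prolif = 40L,
                                      marker = 12L),
                     fracLowQuality = 0, seed = seed)
    args <- utils::modifyList(defaults, list(...))
    do.call(cohortConfig, args)
}

# Pure-noise cohort: no progression programs, no marker effects.
nullConfig <- function(seed = 1L, nGenes = 500L, nPatients = 12L, ...) {
    smallConfig(seed = seed, nGenes = nGenes, nPatients = nPatients,
                programSizes = c(basal = 0L, emt = 0L, prolif = 0L,
                                 marker = 12L),
                markerEffect = 0, ...)
}
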
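test_that("panel PCA embeds fitting samples at their own scores", {
    set.seed(3)
    expr <- matrix(rnorm(40 * 30, 6, 2), 40,
                   dimnames = list(paste0("g", 1:40), paste0("s", 1:30)))
    panel <- paste0("g", 1:20)
    fit <- paste0("s", 1:18)
    emb <- pcaEmbedPanel(expr, panel, fit)
    pr <- prcomp(t(expr[panel, fit]), center = TRUE, scale. = FALSE)
    # scores agree up to per-axis sign
    for (k in 1:3) {
        a <- emb$coords[fit, k]; b <- pr$x[, k]
        expect_equal(abs(cor(a, b)), 1, tolerance = 1e-10)
        expect_equal(sort(abs(a)), sort(abs(b)), tolerance = 1e-8)
    }
    expect_equal(emb$model$varExplained,
                 pr$sdev^2 / sum(pr$sdev^2), tolerance = 1e-8)
    # loadings orthonormal, variance fractions non-increasing
    expect_equal(crossprod(emb$model$rotation),
                 diag(ncol(emb$model$rotation)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(emb$model$varExplained) <= 1e-12))

    # duplicating a fitting sample embeds at identical coordinates
    expr2 <- cbind(expr, dup = expr[, "s1"])
    emb2 <- pcaEmbedPanel(expr2, panel, fit)
    expect_equal(emb2$coords["dup", ], emb2$coords["s1", ],
                 tolerance = 1e-12)
    expect_error(pcaEmbedPanel(expr, c(panel, "missing"), fit), "absent")
})

test_that("rank-1 expression collapses onto PC1", {
    direction <- rnorm(15)
    weight <- seq(-2, 2, length.out = 25)
    expr <- outer(direction, weight) + 5
    dimnames(expr) <- list(paste0("g", 1:15), paste0("s", 1:25))
    emb <- pcaEmbedPanel(expr, rownames(expr), colnames(expr))
    expect_equal(emb$model$varExplained[1], 1, tolerance = 1e-10)
    expect_equal(unname(emb$coords[, 2]), rep(0, 25), tolerance = 1e-8)
})

test_that("principal curve on collinear points is the line itself", {
    set.seed(5)
    x <- sort(runif(40, -3, 3))
    pts <- cbind(x, 0.5 * x)      # a straight line through the origin
    rownames(pts) <- sprintf("s%02d", 1:40)
    curve <- fitPrincipalCurve(pts)
    expect_s4_class(curve, "PrincipalCurveModel")
    # zero projection distance and ordering identical to PC1 ordering
    expect_lt(max(curveDistances(curve)), 1e-10)
    pos <- curvePositions(curve)
    expect_identical(order(pos), order(x))
    # positions are the orthogonal projections: arc length along the line
    # grows linearly in x
    expect_equal(cor(pos, x * sqrt(1 + 0.25)), 1, tolerance = 1e-10)
    expect_equal(max(pos) - min(pos),
                 (max(x) - min(x)) * sqrt(1.25), tolerance = 1e-6)
})

test_that("principal curve recovers the ordering of a noiseless parabola", {
    x <- seq(-1, 1, length.out = 60)
    pts <- cbind(x, x^2)
    rownames(pts) <- sprintf("s%02d", 1:60)
    curve <- fitPrincipalCurve(pts)
    expect_equal(abs(cor(curvePositions(curve), x, method = "spearman")), 1)
})

test_that("mean squared projection distance never increases across iterations", {
    set.seed(7)
    x <- runif(150)
    pts <- cbind(x + rnorm(150, 0, 0.05), sin(2 * x) + rnorm(150, 0, 0.05))
    curve <- fitPrincipalCurve(pts)
    msd <- curve@msdTrace
    # small oscillations around the fixed point are expected for
    # alternating smoothing/projection; require non-increase within 0.5%
    expect_true(all(diff(msd) <= 5e-3 * pmax(msd[-length(msd)], 1e-12)))
})

test_that("ordering is invariant to input order and plane rotation", {
    set.seed(9)
    x <- runif(80)
    pts <- cbind(x, x^2) + matrix(rnorm(160, 0, 0.02), 80)
    rownames(pts) <- sprintf("s%02d", 1:80)
    o1 <- orderSamples(fitPrincipalCurve(pts))
    o2 <- orderSamples(fitPrincipalCurve(pts[rev(seq_len(80)), ]))
    expect_identical(o1$sample_id, o2$sample_id)

    theta <- 0.7
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    # rotation changes PC1, so anchor the comparison with a common
    # orientation reference instead of the raw arc direction
    tissue <- setNames(rep(c("normal", "IDC"), each = 40),
                       rownames(pts)[order(x)])
    o3 <- orderSamples(fitPrincipalCurve(pts), tissue)
    o4 <- orderSamples(fitPrincipalCurve(pts %*% R), tissue)
    expect_gt(cor(match(o3$sample_id, o4$sample_id), seq_len(80),
                  method = "spearman"), 0.999)
})

test_that("orientation places normal tissue before invasive tissue", {
    set.seed(11)
    x <- sort(runif(50))
    pts <- cbind(-x, 0.3 * x)    # PC1 decreasing in x
    rownames(pts) <- sprintf("s%02d", 1:50)
    tissue <- setNames(ifelse(x < 0.3, "normal", ifelse(x > 0.7, "IDC",
                                                        "DCIS")),
                       rownames(pts))
    ord <- orderSamples(fitPrincipalCurve(pts), tissue)
    pos <- setNames(ord$position, ord$sample_id)
    expect_lt(mean(pos[tissue == "normal"]), mean(pos[tissue == "IDC"]))
    # identical coordinates tie-break by sample ID
    pts2 <- rbind(pts, s51 = pts["s01", ], s00 = pts["s01", ])
    ord2 <- orderSamples(fitPrincipalCurve(pts2))
    trio <- ord2$sample_id[ord2$sample_id %in% c("s00", "s01", "s51")]
    expect_identical(trio, sort(trio))
})

test_that("segments partition the ordering with left-closed boundaries", {
    ord <- data.frame(sample_id = sprintf("s%03d", 1:100),
                      position = seq(0, 990, by = 10), rank = 1:100)
    seg <- segmentPositions(ord, segmentBoundaries(0.1, 0.4, 0.6, 0.9))
    expect_identical(as.integer(table(seg)[c("preE1", "E1E2", "mid",
                                             "L1L2", "postL2")]),
                     c(10L, 30L, 20L, 30L, 10L))
    # every sample gets exactly one label
    expect_false(anyNA(seg))
    # position exactly at a boundary opens the next segment
    segp <- segmentPositions(ord, segmentBoundaries(100, 400, 600, 900),
                             quantiles = FALSE)
    expect_identical(as.character(segp[ord$position == 100]), "E1E2")
    expect_identical(as.character(segp[ord$position == 90]), "preE1")
    expect_error(segmentBoundaries(0.5, 0.4, 0.6, 0.9), "E1 < E2")
})

test_that("Welch comparison matches the textbook computation", {
    a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
    res <- compareGroupPositions(c(a, b),
                                 factor(rep(c("A", "B"), each = 5)))
    # closed-form Welch statistic
    sa <- var(a) / 5; sb <- var(b) / 5
    t.exp <- (mean(a) - mean(b)) / sqrt(sa + sb)
    df.exp <- (sa + sb)^2 / (sa^2 / 4 + sb^2 / 4)
    expect_equal(res$meanDiff, -1)
    expect_equal(res$t, t.exp, tolerance = 1e-12)
    expect_equal(res$df, df.exp, tolerance = 1e-12)
    expect_equal(res$p, 2 * pt(-abs(t.exp), df.exp), tolerance = 1e-12)

    same <- compareGroupPositions(c(a, a),
                                  factor(rep(c("A", "B"), each = 5)))
    expect_equal(same$meanDiff, 0)
    expect_equal(same$p, 1)
    expect_error(compareGroupPositions(c(1, 2, 3),
                                       factor(c("A", "B", "B"))), ">= 2")
})

test_that("group positions are calibrated under an outcome-independent cohort", {
    pvals <- vapply(1:60, function(s) {
        set.seed(s)
        pos <- runif(60, 0, 1000)
        grp <- factor(sample(rep(c("Pure", "NotPure"), 30)))
        compareGroupPositions(pos, grp)$p
    }, numeric(1))
    ks <- ks.test(pvals, "punif")
    expect_gt(ks$p.value, 0.01)
})

test_that("tissue trend statistic behaves at its boundaries", {
    tis <- c("normal", "benign", "atypia", "DCIS", "IDC")
    up <- spearmanTissueTrend(1:5, tis)
    expect_equal(up$rho, 1)
    const <- spearmanTissueTrend(rep(2, 5), tis)
    expect_true(is.na(const$rho))
    expect_match(const$note, "constant")
    expect_error(spearmanTissueTrend(1:3, rep("DCIS", 3)), "two distinct")
    expect_error(spearmanTissueTrend(1:3, c("DCIS", "IDC", "bogus")),
                 "unknown")
    set.seed(41)
    null <- replicate(50, spearmanTissueTrend(
        rnorm(40), sample(tis, 40, replace = TRUE))$p)
    expect_lt(abs(mean(null < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 50))
})

test_that("arc-length positions recover the parameter of a noisy curve", {
    # points scattered around a bending arc: the curve must follow the
    # bend (a straight PC1 ordering would fold the ends together)
    set.seed(31)
    u <- sort(runif(300))
    arc <- cbind(sin(2.2 * u), 1 - cos(2.2 * u))
    pts <- arc + matrix(rnorm(600, 0, 0.04), 300)
    rownames(pts) <- sprintf("s%03d", 1:300)
    curve <- fitPrincipalCurve(pts)
    rho <- cor(curvePositions(curve), u, method = "spearman")
    expect_gte(abs(rho), 0.97)
    # and the curve explains the points far better than the PC1 line
    pc1 <- prcomp(pts)$x[, 1]
    resid.line <- sum((pts - prcomp(pts)$x[, 1, drop = FALSE] %*%
                       t(prcomp(pts)$rotation[, 1, drop = FALSE]) -
                       rep(colMeans(pts), each = 300))^2)
    expect_lt(sum(curveDistances(curve)), resid.line)
})
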
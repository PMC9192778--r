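test_that("GMT collections round-trip", {
    sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
    f <- withr::local_tempfile(fileext = ".gmt")
    writeGMT(sets, f)
    expect_identical(readGMT(f), sets)
    writeLines(c("full\tdesc\tg1\tg2", "empty\tdesc"), f)
    expect_warning(back <- readGMT(f), "empty")
    expect_identical(names(back), "full")
})

test_that("ssGSEA matches a step-by-step running-sum computation", {
    # 5-gene toy, one sample; set = the two top-ranked genes
    expr <- matrix(c(10, 8, 5, 3, 1), 5,
                   dimnames = list(paste0("g", 1:5), "s1"))
    alpha <- 0.25
    score <- ssgseaScores(expr, list(top = c("g1", "g2")), alpha,
                          normalize = FALSE)["top", 1]
    # by hand: ranks are 5,4,3,2,1; descending order g1..g5
    w <- c(5, 4, 3, 2, 1)^alpha
    inset <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
    step.in <- cumsum(w * inset) / sum(w[inset])
    step.out <- cumsum(!inset) / 3
    expect_equal(score, sum(step.in - step.out), tolerance = 1e-12)
    expect_gt(score, 0)
    # a set at the bottom ranks scores negative
    bottom <- ssgseaScores(expr, list(bot = c("g4", "g5")), alpha,
                           normalize = FALSE)["bot", 1]
    expect_lt(bottom, 0)
})

test_that("ssGSEA is rank-based and respects set membership only", {
    set.seed(3)
    expr <- matrix(rnorm(60 * 8, 6, 2), 60,
                   dimnames = list(paste0("g", 1:60), paste0("s", 1:8)))
    sets <- list(a = paste0("g", 1:10), b = paste0("g", 31:45))
    s1 <- ssgseaScores(expr, sets)
    s2 <- ssgseaScores(2 * expr + 7, sets)
    expect_equal(s1, s2, tolerance = 1e-12)

    # relabeling genes while preserving membership and ranks
    perm <- sample(60)
    expr3 <- expr[perm, ]
    rownames(expr3) <- paste0("h", seq_len(60))
    sets3 <- lapply(sets, function(s)
        paste0("h", match(match(s, rownames(expr)), perm)))
    s3 <- ssgseaScores(expr3, sets3)
    expect_equal(unname(s3), unname(s1), tolerance = 1e-12)

    expect_warning(ssgseaScores(expr, list(tiny = "g1", a = sets$a)),
                   "tiny")
    expect_error(suppressWarnings(ssgseaScores(expr, list(tiny = "g1"))),
                 "no usable")
})

test_that("window grid follows floor((N - window)/step) + 1", {
    set.seed(5)
    counts <- matrix(rnbinom(50 * 300, mu = 200, size = 5), 50,
                     dimnames = list(paste0("g", 1:50),
                                     sprintf("s%03d", 1:300)))
    ord <- data.frame(sample_id = colnames(counts), position = 1:300,
                      rank = 1:300)
    sets <- list(a = paste0("g", 1:10))
    # stub DE engine: constant hit list, isolates the window mechanics
    stub <- function(counts, groups)
        data.frame(log2FC = rep(1, 50), adjP = rep(1e-6, 50),
                   row.names = paste0("g", 1:50))
    scan <- windowEnrichmentScan(ord, counts, sets,
                                 scanConfig(window = 100, step = 50),
                                 deFun = stub)
    expect_identical(unique(scan$windowStart), c(1L, 51L, 101L, 151L, 201L))
    expect_identical(unique(scan$windowEnd - scan$windowStart + 1L), 100L)
    # every rank is covered at least once when step <= window
    covered <- unique(unlist(Map(seq, scan$windowStart, scan$windowEnd)))
    expect_setequal(covered, 1:300)
    expect_error(windowEnrichmentScan(ord[1:50, ], counts[, 1:50], sets,
                                      scanConfig(window = 100)), "fewer")
})

test_that("hypergeometric over-representation matches enumeration", {
    bg <- paste0("g", 1:20)
    sets <- list(s5 = paste0("g", 1:5))
    hits <- c("g1", "g2", "g3", "g12")
    res <- hypergeomEnrichment(hits, sets, bg)
    expect_equal(res$p, enumHyperTail(3, 5, 20, 4), tolerance = 1e-12)
    expect_equal(res$fold, (3 / 4) / (5 / 20))
    # zero-overlap set: fold 0, p 1
    res0 <- hypergeomEnrichment(c("g19", "g20"), list(s = paste0("g", 1:5)),
                                bg)
    expect_equal(res0$fold, 0)
    expect_equal(res0$p, 1)
    # random cases against enumeration on small backgrounds
    set.seed(7)
    for (i in 1:25) {
        nbg <- sample(10:25, 1)
        bgi <- paste0("g", seq_len(nbg))
        m <- sample(2:(nbg - 2), 1)
        k <- sample(1:(nbg - 1), 1)
        seti <- list(s = sample(bgi, m))
        hitsi <- sample(bgi, k)
        q <- length(intersect(hitsi, seti$s))
        got <- hypergeomEnrichment(hitsi, seti, bgi)$p
        want <- if (q == 0) 1 else enumHyperTail(q, m, nbg, k)
        expect_equal(got, want, tolerance = 1e-12)
    }
})

test_that("enrichment scan finds the planted program in its window", {
    se <- simulateCohort(smallConfig(seed = 43, nPatients = 30,
                                     nGenes = 500,
                                     programSizes = c(basal = 60, emt = 50,
                                                      prolif = 40,
                                                      marker = 12)))
    expr <- logCPM(SummarizedExperiment::assay(se))
    t <- latentTime(se)
    ord <- data.frame(sample_id = names(sort(t)),
                      position = sort(t), rank = seq_along(t))
    sets <- split(rownames(se), geneBlocks(se))[c("basal", "emt", "prolif")]
    scan <- windowEnrichmentScan(ord, SummarizedExperiment::assay(se), sets,
                                 scanConfig(window = 100, step = 100))
    # the earliest window is enriched for the declining basal program
    first <- scan[scan$windowStart == 1, ]
    expect_lt(first$adjP[first$set == "basal"], 1e-5)
})

test_that("bootstrap trend is exact in the noiseless limit and seeded", {
    x <- seq(1, 20, length.out = 40)
    y <- 2 + 3 * x
    tr <- bootstrapTrend(y, x, nBoot = 200, seed = 5)
    expect_equal(tr$slope, 3, tolerance = 1e-10)
    expect_equal(tr$r2, 1, tolerance = 1e-10)
    expect_lt(diff(tr$slopeCI), 1e-8)

    set.seed(9)
    yn <- y + rnorm(40, 0, 1)
    t1 <- bootstrapTrend(yn, x, nBoot = 500, seed = 11)
    t2 <- bootstrapTrend(yn, x, nBoot = 500, seed = 11)
    expect_identical(t1$slopeCI, t2$slopeCI)
    expect_identical(t1$band, t2$band)
    t3 <- bootstrapTrend(yn, x, nBoot = 500, seed = 12)
    expect_false(identical(t1$slopeCI, t3$slopeCI))

    expect_error(bootstrapTrend(yn, rep(1, 40)), "constant")
    expect_error(bootstrapTrend(1:5, 1:5), "10 samples")
})

test_that("bootstrap intervals cover the true slope at nominal rate", {
    hits <- vapply(1:200, function(rep) {
        set.seed(rep)
        x <- runif(200, 0, 10)
        y <- 1 + 1.0 * x + rnorm(200, 0, 0.5)
        ci <- bootstrapTrend(y, x, nBoot = 2000, seed = rep + 1000)$slopeCI
        ci[1] <= 1 && 1 <= ci[2]
    }, logical(1))
    expect_gte(mean(hits), 0.93)
})
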
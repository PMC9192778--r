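test_that("receptor calls use at-or-above thresholds", {
    expr <- rbind(ESR1 = c(7.2, 5, 6, 5),
                  PGR = c(8, 5, 6, 5),
                  ERBB2 = c(9, 9, 10.5, 9))
    colnames(expr) <- paste0("s", 1:4)
    rc <- receptorStatusCall(expr)
    expect_true(rc$er[1])                      # 7.2 above 6
    expect_false(rc$er[2])
    expect_true(rc$er[3] && rc$pr[3])          # boundary counts positive
    expect_true(rc$her2[3])                    # 10.5 exactly
    expect_true(rc$tripleNegative[2])          # (5, 5, 9)
    expect_false(rc$tripleNegative[4] && rc$her2[4])
    expect_error(receptorStatusCall(expr[1:2, ]), "ERBB2")
})

test_that("patient marker calls need two IDC-side in-situ samples", {
    expr <- matrix(0, 1, 9, dimnames = list("MNX1", paste0("s", 1:9)))
    expr["MNX1", ] <- c(1, 1, 8,   8, 8, 8, 8, 1,   1)
    meta <- data.frame(
        patient = c("A", "A", "A", "B", "B", "B", "B", "B", "C"),
        tissue = rep("DCIS", 9), row.names = paste0("s", 1:9))
    calls <- patientMarkerStatus(expr, meta, "MNX1", cut = 4,
                                 direction = "low")
    expect_true(calls[["A"]])     # 2 of 3 samples below the cut
    expect_false(calls[["B"]])    # only 1 of 5 below
    expect_true(is.na(calls[["C"]]))  # single sample: unassigned
    expect_error(patientMarkerStatus(expr, meta, "BOGUS"), "BOGUS")
    # non-DCIS samples are ignored
    meta2 <- meta; meta2$tissue[1] <- "IDC"
    calls2 <- patientMarkerStatus(expr, meta2, "MNX1", cut = 4,
                                  direction = "low")
    expect_false(calls2[["A"]])   # only 1 usable low sample left
})

test_that("progressor tally counts down-regulated calls and propagates NA", {
    calls <- rbind(p1 = c(TRUE, TRUE, TRUE, TRUE),
                   p2 = c(FALSE, FALSE, FALSE, FALSE),
                   p3 = c(TRUE, TRUE, FALSE, FALSE),
                   p4 = c(TRUE, NA, FALSE, FALSE))
    expect_identical(progressorTally(calls), c(4L, 0L, 2L, NA))
    expect_error(progressorTally(calls[, 1:3]), "4 progressor")
})

test_that("decision tree reproduces the published worked examples", {
    # anchor high, 1 progressor down, refiner low -> lower hazard
    expect_identical(
        as.character(assignHazard(FALSE, 1, FALSE, FALSE)$group),
        "LowerHazard")
    # anchor low alone is enough for higher hazard
    expect_identical(
        as.character(assignHazard(TRUE, 0, NA, NA)$group),
        "HigherHazard")
    # the 0-1 branch with refiner on the IDC side leans higher
    expect_identical(
        as.character(assignHazard(FALSE, 0, TRUE, NA)$group),
        "HigherHazard")
    # tally of two is not covered by the printed rules
    expect_identical(
        as.character(assignHazard(FALSE, 2, TRUE, NA)$group),
        "Indeterminate")
    # 3-4 down: higher hazard; rescuer still high is the mitigating flag
    hz <- assignHazard(FALSE, 4, FALSE, FALSE)
    expect_identical(as.character(hz$group), "HigherHazard")
    expect_true(hz$rescuerMitigated)
    hz2 <- assignHazard(FALSE, 4, FALSE, TRUE)
    expect_false(hz2$rescuerMitigated)
    # missing anchor or tally -> unassigned
    expect_identical(as.character(assignHazard(NA, 1, TRUE, NA)$group),
                     "Unassigned")
})

test_that("decision tree is total and deterministic over the call grid", {
    grid <- expand.grid(anchor = c(TRUE, FALSE), tally = 0:4,
                        refiner = c(TRUE, FALSE),
                        rescuer = c(TRUE, FALSE))
    hz <- assignHazard(grid$anchor, grid$tally, grid$refiner, grid$rescuer)
    expect_identical(nrow(hz), nrow(grid))
    expect_false(anyNA(hz$group))
    expect_false(any(hz$group == "Unassigned"))
    hz2 <- assignHazard(grid$anchor, grid$tally, grid$refiner,
                        grid$rescuer)
    expect_identical(hz, hz2)
})

test_that("enrichment folds reproduce printed proportions exactly", {
    expect_equal(enrichmentFold(0.36, 0.10)$fold, 3.6)
    expect_equal(enrichmentFold(0.71, 0.42)$fold, 1.7)
    expect_equal(enrichmentFold(0.25, 0.25)$fold, 1.0)
    expect_identical(enrichmentFold(0.3, 0)$fold, Inf)
    # reciprocal property on the unrounded ratio
    f1 <- enrichmentFold(0.36, 0.10)$ratio
    f2 <- enrichmentFold(0.10, 0.36)$ratio
    expect_equal(f1 * f2, 1, tolerance = 1e-12)
})

test_that("Fisher comparison matches full-table enumeration", {
    a <- c(rep(0, 8), rep(10, 2))
    b <- c(rep(0, 2), rep(10, 8))
    res <- ecdfFisherCompare(a, b, at = 5)
    expect_identical(unname(res$table), rbind(c(8L, 2L), c(2L, 8L)))
    expect_equal(res$p, enumFisher(res$table), tolerance = 1e-12)
    expect_equal(res$p, fisher.test(res$table)$p.value, tolerance = 1e-12)

    same <- ecdfFisherCompare(a, a)
    expect_equal(same$p, 1)

    expect_warning(deg <- ecdfFisherCompare(a, b, at = -1), "degenerate")
    expect_equal(deg$p, 1)

    # random tables with margins <= 25 against enumeration
    set.seed(17)
    for (i in 1:30) {
        x <- rnorm(sample(5:12, 1))
        y <- rnorm(sample(5:12, 1), mean = runif(1, -1, 1))
        r <- ecdfFisherCompare(x, y)
        expect_equal(r$p, enumFisher(r$table), tolerance = 1e-10)
    }
    expect_error(ecdfFisherCompare(numeric(), 1:3), "nonempty")
})

test_that("planted marker effects stratify patients by outcome", {
    folds <- vapply(c(51, 52), function(s) {
        se <- simulateCohort(smallConfig(seed = s, nPatients = 40,
                                         lesionsPerPatient = c(3L, 12L)))
        expr <- logCPM(SummarizedExperiment::assay(se))
        meta <- as.data.frame(SummarizedExperiment::colData(se))
        hz <- assignHazardGroups(expr, meta)
        outcome <- setNames(se$status, se$patient)
        outcome <- outcome[!duplicated(names(outcome))]
        hazardEnrichment(hz, outcome)$ratio
    }, numeric(1))
    expect_true(all(folds > 1))
})

test_that("hazard assignment bookkeeping is exact", {
    se <- simulateCohort(smallConfig(seed = 53, nPatients = 30))
    expr <- logCPM(SummarizedExperiment::assay(se))
    meta <- as.data.frame(SummarizedExperiment::colData(se))
    hz <- assignHazardGroups(expr, meta)
    # every patient with DCIS samples gets exactly one row and one group
    expect_identical(sort(hz$patient),
                     sort(unique(meta$patient[meta$tissue == "DCIS"])))
    expect_false(anyNA(hz$group))
    # patients with one DCIS sample are unassigned
    n.dcis <- table(meta$patient[meta$tissue == "DCIS"])
    singles <- names(n.dcis)[n.dcis == 1]
    expect_true(all(hz$group[hz$patient %in% singles] == "Unassigned"))
})
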
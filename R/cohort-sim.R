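#' Configuration for the synthetic lesion cohort generator
#'
#' Returns the parameter list consumed by [simulateCohort()]. The defaults
#' emulate a large micro-dissection study: ~145 patients contributing 1-16
#' lesions each, every lesion cut into 1-3 adjacent replicate sections, five
#' tissue types (normal epithelium, benign, atypia, DCIS, IDC) spanning a
#' latent progression coordinate `t` in [0,1]. Gene programs planted on `t`:
#' a monotone-declining basal/epithelial program, a two-peak
#' epithelial-mesenchymal transition (EMT) program (peaks near t = 0.25 and
#' t = 0.9), and a proliferation program that switches on only after the
#' first EMT peak. A small block of named marker genes (the progression
#' markers CAMK2N1, MNX1, HOXC11, ANKRD22, ADCY5, SCGB2A1, THRSP, HOXC10,
#' HOTAIR plus the receptors ESR1, PGR, ERBB2) carries outcome-linked
#' bimodal expression; all remaining genes are null.
#'
#' @param nPatients number of patients.
#' @param lesionsPerPatient integer range `c(lo, hi)`; lesion count drawn
#'   uniformly per patient.
#' @param sectionsPerLesion integer range within 1-3; replicate sections per
#'   lesion share the lesion's latent `t`.
#' @param nGenes total gene count.
#' @param programSizes named counts for the `basal`, `emt`, `prolif` and
#'   `marker` blocks; remaining genes are null. The marker block is the
#'   fixed set of 12 named genes. Defaults scale with `nGenes` (5% basal,
#'   5% EMT, 3% proliferation), giving 250/250/150 at the default 5000
#'   genes.
#' @param nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param patientSd SD (log2 units) of the per-patient, per-gene random
#'   effect inducing intra-patient correlation.
#' @param libsizeRange range of expected library sizes (counts).
#' @param fracPureDcis proportion of patients labelled `Pure` (no invasive
#'   disease); the rest are `NotPure`.
#' @param fracLowQuality proportion of samples corrupted by
#'   [injectLowQuality()] (0 disables injection).
#' @param markerEffect log2 shift of a marker gene in its outcome-linked
#'   "low" (or, for SCGB2A1, "high") state.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return named list of class `cohortConfig`.
#' @examples
#' cfg <- cohortConfig(nPatients = 10, nGenes = 400)
#' @export
cohortConfig <- function(nPatients = 145L,
                         lesionsPerPatient = c(1L, 16L),
                         sectionsPerLesion = c(1L, 3L),
                         nGenes = 5000L,
                         programSizes = NULL,
                         nbDispersion = 0.15,
                         patientSd = 0.7,
                         libsizeRange = c(8e5, 3e6),
                         fracPureDcis = 0.37,
                         fracLowQuality = 0.1,
                         markerEffect = 3,
                         seed = 1L) {
    if (is.null(programSizes))
        programSizes <- c(basal = round(0.05 * nGenes),
                          emt = round(0.05 * nGenes),
                          prolif = round(0.03 * nGenes),
                          marker = nrow(.MARKER.GENES))
    programSizes <- unlist(programSizes)
    cfg <- list(nPatients = as.integer(nPatients),
                lesionsPerPatient = as.integer(lesionsPerPatient),
                sectionsPerLesion = as.integer(sectionsPerLesion),
                nGenes = as.integer(nGenes),
                programSizes = programSizes,
                nbDispersion = nbDispersion, patientSd = patientSd,
                libsizeRange = libsizeRange, fracPureDcis = fracPureDcis,
                fracLowQuality = fracLowQuality, markerEffect = markerEffect,
                seed = as.integer(seed))
    validateCohortConfig(cfg)
    class(cfg) <- "cohortConfig"
    cfg
}

.MARKER.GENES <- data.frame(
    gene = c("CAMK2N1", "MNX1", "HOXC11", "ANKRD22", "ADCY5",
             "SCGB2A1", "THRSP", "HOXC10", "HOTAIR",
             "ESR1", "PGR", "ERBB2"),
    role = c("anchor", "progressor", "progressor", "progressor", "progressor",
             "refiner", "rescuer", "annotation", "annotation",
             "receptor", "receptor", "receptor"),
    # direction of the expression state associated with invasive disease
    idcAssociated = c("low", "low", "low", "low", "low",
                      "high", "low", "low", "low", NA, NA, NA),
    stringsAsFactors = FALSE
)

.TISSUES <- c("normal", "benign", "atypia", "DCIS", "IDC")
# latent-progression bands per tissue type; DCIS deliberately spans most of
# the coordinate, IDC sits at the invasive end
.T.BANDS <- rbind(normal = c(0.00, 0.15), benign = c(0.08, 0.30),
                  atypia = c(0.25, 0.50), DCIS = c(0.30, 0.95),
                  IDC = c(0.80, 1.00))
.TISSUE.PROB <- c(normal = 0.08, benign = 0.09, atypia = 0.09,
                  DCIS = 0.60, IDC = 0.14)

validateCohortConfig <- function(cfg) {
    stopifnot(cfg$nPatients >= 1, cfg$nGenes >= 1)
    ps <- cfg$programSizes
    if (!all(c("basal", "emt", "prolif", "marker") %in% names(ps)))
        stop("programSizes must name basal, emt, prolif and marker blocks")
    if (ps[["marker"]] != nrow(.MARKER.GENES))
        stop("the marker block is the fixed set of ", nrow(.MARKER.GENES),
             " named genes")
    if (sum(ps) > cfg$nGenes)
        stop("program sizes (", sum(ps), ") exceed nGenes (", cfg$nGenes, ")")
    rng <- function(r, lo, hi) length(r) == 2 && r[1] <= r[2] &&
        r[1] >= lo && r[2] <= hi
    if (!rng(cfg$lesionsPerPatient, 1L, Inf))
        stop("lesionsPerPatient must be a nonempty integer range")
    if (!rng(cfg$sectionsPerLesion, 1L, 3L))
        stop("sectionsPerLesion must be a range within 1-3")
    if (!rng(cfg$libsizeRange, 1, Inf))
        stop("libsizeRange must be a nonempty positive range")
    for (p in c("fracPureDcis", "fracLowQuality"))
        if (cfg[[p]] < 0 || cfg[[p]] > 1)
            stop(p, " must lie in [0,1]")
    if (cfg$fracLowQuality >= 0.5)
        stop("fracLowQuality must be < 0.5")
    stopifnot(cfg$nbDispersion > 0, cfg$patientSd >= 0)
    invisible(cfg)
}

#' Simulate a micro-dissected lesion cohort
#'
#' Draws a full synthetic cohort under the structure described in
#' [cohortConfig()]: per-lesion latent progression `t` (shared by the
#' lesion's replicate sections) drawn uniformly within tissue-specific
#' bands; gene programs shifting log2 mean expression as smooth functions
#' of `t`; per-patient random effects; negative-binomial counts at the
#' sample's library size; outcome-linked bimodal marker genes; and
#' (optionally) injected low-quality samples. Ground truth (latent `t`,
#' gene block membership, planted marker effects, injection flags) travels
#' with the object.
#'
#' @param config a [cohortConfig()].
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`; `colData` columns `patient`, `lesion`, `section`, `tissue`,
#'   `status` (Pure/NotPure), `subtype`, planted receptor calls
#'   (`erPlanted`, `prPlanted`, `her2Planted`), library statistics
#'   (`rawReads`, `pctUniqueMap`, `pctReadsInGenes`) and ground truth
#'   (`latentTime`, `injectedBad`); `rowData` columns `block` and
#'   `markerEffect`.
#' @examples
#' se <- simulateCohort(cohortConfig(nPatients = 6, nGenes = 300, seed = 7))
#' table(se$tissue)
#' @export
simulateCohort <- function(config = cohortConfig()) {
    validateCohortConfig(config)
    set.seed(config$seed)
    ps <- config$programSizes

    ## -- patients ----------------------------------------------------------
    np <- config$nPatients
    patients <- sprintf("P%03d", seq_len(np))
    status <- ifelse(runif(np) < config$fracPureDcis, "Pure", "NotPure")
    subtype <- sample(c("LumA", "LumB", "Her2", "Basal", "NormalLike"),
                      np, replace = TRUE, prob = c(.5, .1, .1, .1, .2))
    names(status) <- names(subtype) <- patients

    ## -- lesions and sections ---------------------------------------------
    lp <- config$lesionsPerPatient
    nles <- sample(seq(lp[1], lp[2]), np, replace = TRUE)
    les.patient <- rep(patients, nles)
    nl <- sum(nles)
    if (nl == 0) stop("empty cohort: no lesions drawn")
    les.tissue <- sample(.TISSUES, nl, replace = TRUE, prob = .TISSUE.PROB)
    # Pure patients by definition have no invasive lesion in any biopsy
    les.tissue[status[les.patient] == "Pure" & les.tissue == "IDC"] <- "DCIS"
    band <- .T.BANDS[les.tissue, , drop = FALSE]
    les.t <- runif(nl, band[, 1], band[, 2])
    sp <- config$sectionsPerLesion
    nsec <- sample(seq(sp[1], sp[2]), nl, replace = TRUE)

    samp.lesion <- rep(seq_len(nl), nsec)
    ns <- length(samp.lesion)
    meta <- S4Vectors::DataFrame(
        patient = les.patient[samp.lesion],
        lesion = sprintf("L%04d", samp.lesion),
        section = unlist(lapply(nsec, seq_len), use.names = FALSE),
        tissue = les.tissue[samp.lesion],
        row.names = sprintf("S%04d", seq_len(ns)))
    meta$status <- status[meta$patient]
    meta$subtype <- subtype[meta$patient]
    t.samp <- les.t[samp.lesion]

    ## -- gene blocks and baselines ----------------------------------------
    n.null <- config$nGenes - sum(ps)
    block <- rep(c("basal", "emt", "prolif", "marker", "null"),
                 c(ps[["basal"]], ps[["emt"]], ps[["prolif"]],
                   ps[["marker"]], n.null))
    gene.id <- c(sprintf("BASAL%03d", seq_len(ps[["basal"]])),
                 sprintf("EMT%03d", seq_len(ps[["emt"]])),
                 sprintf("PROLIF%03d", seq_len(ps[["prolif"]])),
                 .MARKER.GENES$gene,
                 sprintf("NULLG%04d", seq_len(n.null)))
    baseline <- pmin(pmax(rnorm(config$nGenes, 5, 1.8), 1), 10)
    names(baseline) <- gene.id
    baseline[.MARKER.GENES$gene] <- 7
    # receptor baselines follow the molecular subtype (set per patient below)

    ## -- log2 mean expression ---------------------------------------------
    L <- matrix(baseline, nrow = config$nGenes, ncol = ns,
                dimnames = list(gene.id, rownames(meta)))
    i.basal <- which(block == "basal")
    i.emt <- which(block == "emt")
    i.prolif <- which(block == "prolif")
    amp.basal <- runif(length(i.basal), 2, 4)
    amp.emt <- runif(length(i.emt), 2, 3)
    amp.prolif <- runif(length(i.prolif), 1.5, 2.5)
    emtShape <- function(t) exp(-(t - 0.25)^2 / (2 * 0.07^2)) +
        exp(-(t - 0.90)^2 / (2 * 0.05^2))
    prolifShape <- function(t) pmax(0, t - 0.30) / 0.70
    L[i.basal, ] <- L[i.basal, ] - outer(amp.basal, t.samp)
    L[i.emt, ] <- L[i.emt, ] + outer(amp.emt, emtShape(t.samp))
    L[i.prolif, ] <- L[i.prolif, ] + outer(amp.prolif, prolifShape(t.samp))

    ## -- markers: patient-level bimodal states ----------------------------
    marker.effect <- setNames(rep(NA_real_, config$nGenes), gene.id)
    mk <- .MARKER.GENES[!is.na(.MARKER.GENES$idcAssociated), ]
    p.state <- ifelse(status == "NotPure", 0.65, 0.25)   # per patient
    for (k in seq_len(nrow(mk))) {
        in.state <- rbinom(np, 1, p.state) == 1
        names(in.state) <- patients
        shift <- if (mk$idcAssociated[k] == "low") -config$markerEffect else
            config$markerEffect
        L[mk$gene[k], ] <- L[mk$gene[k], ] +
            shift * in.state[meta$patient]
        marker.effect[mk$gene[k]] <- shift
    }
    ## -- receptors: subtype-driven levels ---------------------------------
    rc <- list(ESR1 = c(LumA = 8.5, LumB = 8.5, Her2 = 7.5, Basal = 4,
                        NormalLike = 8.5),
               PGR = c(LumA = 8, LumB = 8, Her2 = 5, Basal = 3.5,
                       NormalLike = 8),
               ERBB2 = c(LumA = 9, LumB = 9, Her2 = 12, Basal = 9,
                         NormalLike = 9))
    for (g in names(rc)) L[g, ] <- rc[[g]][meta$subtype]
    meta$erPlanted <- rc$ESR1[meta$subtype] >= 6
    meta$prPlanted <- rc$PGR[meta$subtype] >= 6
    meta$her2Planted <- rc$ERBB2[meta$subtype] >= 10.5

    ## -- patient random effect, counts ------------------------------------
    if (config$patientSd > 0) {
        pe <- matrix(rnorm(config$nGenes * np, 0, config$patientSd),
                     nrow = config$nGenes, dimnames = list(NULL, patients))
        L <- L + pe[, meta$patient]
    }
    lib <- runif(ns, config$libsizeRange[1], config$libsizeRange[2])
    W <- 2^L
    mu <- sweep(W, 2, lib / colSums(W), "*")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nbDispersion),
                     nrow = config$nGenes,
                     dimnames = dimnames(L))
    storage.mode(counts) <- "integer"

    ## -- library statistics -----------------------------------------------
    meta$rawReads <- round(lib * runif(ns, 1.3, 1.7))
    meta$pctUniqueMap <- runif(ns, 55, 95)
    meta$pctReadsInGenes <- runif(ns, 20, 60)
    meta$latentTime <- t.samp
    meta$injectedBad <- FALSE

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = meta,
        rowData = S4Vectors::DataFrame(block = block,
                                       markerEffect = marker.effect,
                                       row.names = gene.id))
    if (config$fracLowQuality > 0)
        se <- injectLowQuality(se, config$fracLowQuality,
                               seed = config$seed + 1L)
    se
}

#' Corrupt a fraction of samples into low-quality libraries
#'
#' Selected samples have their counts shuffled across genes and their depth
#' reduced 10-fold, which drives their Pearson correlation to the cohort
#' mean log2-CPM profile well below the quality-filter threshold of 0.70.
#' Flags are recorded so filters can be scored against ground truth.
#'
#' @param object a `SummarizedExperiment` with a `counts` assay (or a plain
#'   counts matrix).
#' @param frac proportion of samples to corrupt, in `[0, 0.5)`.
#' @param seed integer seed; the same seed selects the same samples.
#' @return the same class as `object`; for a `SummarizedExperiment` the
#'   `injectedBad` colData column marks corrupted samples, for a matrix a
#'   list with elements `counts` and `flags`.
#' @export
injectLowQuality <- function(object, frac, seed = 1L) {
    if (frac < 0 || frac >= 0.5) stop("frac must lie in [0, 0.5)")
    is.se <- methods::is(object, "SummarizedExperiment")
    counts <- if (is.se) SummarizedExperiment::assay(object, "counts")
              else object
    ns <- ncol(counts)
    flags <- setNames(rep(FALSE, ns), colnames(counts))
    if (frac > 0 && ns > 0) {
        set.seed(seed)
        bad <- sample(ns, max(1L, floor(frac * ns)))
        for (j in bad)
            counts[, j] <- as.integer(round(sample(counts[, j]) / 10))
        flags[bad] <- TRUE
    }
    if (is.se) {
        SummarizedExperiment::assay(object, "counts") <- counts
        object$injectedBad <- flags | (if (!is.null(object$injectedBad))
            object$injectedBad else FALSE)
        object
    } else list(counts = counts, flags = flags)
}

#' @rdname simulateCohort
#' @param se a cohort `SummarizedExperiment` from [simulateCohort()].
#' @return `latentTime()`: named numeric, ground-truth progression per
#'   sample; `geneBlocks()`: named character, program block per gene;
#'   `injectedBad()`: named logical corruption flags.
#' @export
latentTime <- function(se) setNames(se$latentTime, colnames(se))

#' @rdname simulateCohort
#' @export
geneBlocks <- function(se)
    setNames(SummarizedExperiment::rowData(se)$block, rownames(se))

#' @rdname simulateCohort
#' @export
injectedBad <- function(se) setNames(se$injectedBad, colnames(se))

#' @rdname simulateCohort
#' @return `markerGenes()`: data.frame of the built-in marker panel genes
#'   with their role in the decision tree and the expression direction
#'   associated with invasive disease.
#' @export
markerGenes <- function() .MARKER.GENES
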
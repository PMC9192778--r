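# DCIScurve

Ordering micro-dissected breast ductal lesions on a progression continuum,
and asking which transcriptional programs and biomarkers track it.

Ductal carcinoma in situ (DCIS) is a non-invasive precursor of invasive
ductal carcinoma (IDC); many DCIS patients never progress, yet most are
treated as if they would. Given bulk RNA-seq of individually
micro-dissected lesions — normal epithelium, benign lesions, atypia, DCIS
and IDC, with several lesions per patient and replicate sections per
lesion — `DCIScurve` reconstructs a pseudotime for the disease: samples
are projected onto a principal curve fitted in the space of the genes that
best separate in-situ from invasive tissue, giving each lesion an
arc-length coordinate (the *principal curve projection*, PCP) running from
normal epithelium to invasive carcinoma.

The package implements the full analysis path for this design:

* **Preprocessing** — TMM normalisation factors and log2-CPM
  (`tmmFactors()`, `logCPM()`), prevalence-based gene filtering, TSV/MTX
  and GMT I/O.
* **Quality control** — a four-stage sample filter with exact bookkeeping
  (`runQC()`): library metrics; iterative correlation to the tissue-class
  mean (threshold 0.70, relaxed to 0.65/0.60 for invasive and
  basal-subtype samples); removal of samples closer to the cohort mean
  than to their own patient's mean; iterative correlation to the patient
  mean (0.80, relaxed likewise).
* **Differential expression** — moderated two-group fits on voom
  precision weights with a consensus intra-patient correlation and
  patient blocking (`fitDE()`), BH adjustment (`bhAdjust()`), and panel
  selection at adjusted p < 1e-5 (`selectPanel()`).
* **Trajectory** — panel PCA with out-of-sample embedding
  (`pcaEmbedPanel()`), a Hastie–Stuetzle principal curve
  (`fitPrincipalCurve()`), biology-anchored ordering (`orderSamples()`),
  early/late segmentation (`segmentPositions()`), Welch position
  comparisons and Spearman tissue trends.
* **Gene sets** — ssGSEA per-sample scoring (`ssgseaScores()`), a
  sliding-window over-representation scan along the ordering
  (`windowEnrichmentScan()`), and residual-resampling bootstrap trend
  fits (`bootstrapTrend()`).
* **Biomarkers** — log2-CPM receptor calls (ESR1/PGR/ERBB2 at 6/6/10.5),
  per-patient marker calls requiring two concordant in-situ samples, the
  Progressor-gene tally (MNX1, HOXC11, ANKRD22, ADCY5), and the hazard
  decision tree anchored on CAMK2N1 with SCGB2A1/THRSP refinement
  (`assignHazardGroups()`, `enrichmentFold()`, `ecdfFisherCompare()`).
* **Synthetic cohorts** — a negative-binomial generator
  (`simulateCohort()`) with a latent progression coordinate driving a
  declining basal program, a two-peak EMT program and late-onset
  proliferation, patient random effects, outcome-linked bimodal markers,
  and injectable low-quality samples, with ground truth attached.
* **Orchestration** — `runFullPipeline()` runs everything from a single
  seeded config (`pipelineConfig()`, YAML-overridable) and writes every
  intermediate as TSV plus a machine-readable summary.

## Worked example

```r
library(DCIScurve)
cfg <- pipelineConfig(simulate = cohortConfig(nPatients = 40,
                                              nGenes = 2000),
                      seed = 8)
res <- runFullPipeline(cfg, "pipeline-out")
str(res$summary[c("qc", "pseudotime", "hazard")], give.attr = FALSE)
```

On this 40-patient synthetic cohort the run prints (abridged):

```
$ qc        : input 655, cohort 65, patientVsCohort 1, retained 589
$ pseudotime: truthSpearmanAbs 0.980
$ hazard    : lowerHazardFold 7.1, higherHazardFold 2.1
```

Reading: of 655 sections, the quality filter removed the 65 corrupted
libraries (every injected one) plus 1 borderline sample; the recovered
PCP ordering matches the generator's hidden progression coordinate at
|Spearman| 0.98; and the marker decision tree's Lower Hazard group is
7.1-fold enriched for patients whose disease never becomes invasive —
the planted marker effects are strong at this cohort size, so the fold is
larger than one would expect from patient data. Per-stage tables
(`qc_report.tsv`, `de.tsv`, `pseudotime.tsv`, `scan.tsv`, `hazard.tsv`,
`summary.yaml`) land in `pipeline-out/`.

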
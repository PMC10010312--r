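# immunocentroid

Immunogenomic profiling of immunotherapy response in bulk RNA-seq cohorts of
renal cancer. The package is aimed at translational researchers who want to
ask, from pretreatment tumor expression profiles, whether immune gene
programs separate responders from non-responders, whether a de novo
expression classifier can be trained at small cohort sizes, and how immune
classification relates to survival — and who need every step testable
without access to protected patient data.

## What it implements

- **Expression preprocessing.** Low-expression filtering (≥ 10 reads in
  ≥ 5 samples by default), optional restriction to an explicit
  (e.g. protein-coding) gene universe, and the canonical normalization
  `v = log2(1 + x)` → per-sample upper-quartile scaling (75th percentile of
  positive log values, rescaled to the cohort mean quartile) → per-gene
  median centering, so every gene has median 0 across samples.
- **Signature scoring.** A signature score is the unweighted mean of a gene
  set's normalized values per sample. Group comparisons report two-sided
  Wilcoxon rank-sum p (exact enumeration for small untied groups), a
  pooled-variance t statistic (positive = higher in responders), and mean
  differences; enrichment of a gene list against a collection uses the
  one-sided hypergeometric upper tail with Benjamini–Hochberg adjustment.
- **Nearest-centroid response classifier.** Candidate genes pass a
  label-free double filter (median ≥ its 25th percentile, variance ≥ its
  70th percentile). Leave-one-out cross-validation scans a grid of model
  sizes m; within each fold, per-gene t statistics (CR/PR vs SD/PD) are
  recomputed on the training samples and the top m/2 genes per sign are
  selected before fitting class centroids. Prediction minimizes the
  standardized distance `d_k = Σ_g ((x_g − c_kg)/(s_g + s0))²`. The same
  machinery fits a fixed-gene-list molecular subtype classifier (ccA/ccB
  style) with a stratified 2/3–1/3 split.
- **Clinical outcomes.** Response rates (ORR, disease control, clinical
  benefit), Kaplan–Meier curves with median survival, Cox proportional
  hazards (Efron ties), log-rank, Fisher exact, Kruskal–Wallis, and
  multivariable logistic regression with separation detection.
- **Synthetic cohorts.** A negative-binomial simulator plants immune
  expression programs with known log2 effects in responders, assigns
  CR/PR/SD/PD deterministically from responder labels, and draws
  right-censored OS/PFS from a proportional-hazards model tied to an
  immune-high flag — so classifier recovery, survival calibration and the
  therapy-dependent myeloid contrast are all checkable against planted
  truth.

## Worked example

```r
library(immunocentroid)

cohort <- simulateCohort(SimConfig(seed = 7))
cohort$expression
#> ExpressionMatrix: 2000 genes x 35 samples [layer: counts]
cohort$clinical
#> ClinicalTable: 35 samples (CR 1, PR 12, SD 6, PD 16, NA 0)

norm  <- normalizeExpression(filterMinExpression(cohort$expression)$expression)
model <- trainResponseClassifier(norm, responderFromResponse(cohort$clinical))
model
#> CentroidModel: 8 genes, classes CR/PR vs SD/PD [standardized distance, s0 = 0]
#>   CV: accuracy 1.000 at 8 genes

responseRates(cohort$clinical)$percent
#>              orr  disease_control clinical_benefit
#>               37               54               43

coxPH(cohort$clinical$os_months, cohort$clinical$os_event,
      data.frame(immune_high = as.numeric(cohort$clinical$immune_high)))
#>                hr ci_lower ci_upper wald_p
#> immune_high 1.678    0.786     3.58  0.181
```

The simulated cohort reproduces the target cohort shape (1 CR, 12 PR, 6 SD,
16 PD → ORR 37%, disease control 54%, clinical benefit 43%). The planted
40-gene immune program separates responders perfectly under leave-one-out
cross-validation at 8 genes, and the immune-high half of the cohort trends
toward worse survival (the planted hazard ratio is 2; at n = 35 the
confidence interval is wide).

`runPipeline()` chains all stages into one reproducible, manifest-logged
run; `inst/scripts/immunocentroid.R` wraps it for the shell.

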
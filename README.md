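# altsig

Malignant-cell annotation and CD83 tumor-signature analysis for glioma
expression cohorts.

## The problem

In glioma single-cell RNA-seq, tumor cells and non-malignant brain and
immune cells are interleaved in every sample, and a rare population of
tumor cells — CD83⁺CD45⁻ "antigen-presenting-like" tumor cells (ALT) — is
of particular biological and clinical interest. `altsig` implements the
full computational path from raw counts to survival stratification:

1. **Tumor-cell annotation.** Each cell is called malignant when it meets
   one or more of three criteria:
   - *Marker mixture model*: for each marker gene *g* ∈ {SOX2, EGFR,
     PDGFRA}, a two-component Gaussian mixture
     `f(x) = π₁ N(x; μ₁, σ₁²) + π₂ N(x; μ₂, σ₂²)` is fitted to the
     log-normalized expression by expectation–maximization; a cell is
     marker-positive when its posterior probability of the tumor class
     exceeds τ (default 0.5, strict).
   - *CNV evidence*: arm-level expression shifts, computed from
     reference-centered, positionally smoothed expression; a large-scale
     alteration of any arm is sufficient evidence of malignancy.
   - *SNV evidence*: COSMIC-documented variants with dbSNP frequency
     < 0.1% in the glioma driver genes (IDH1/IDH2 R132H/R132C, EGFR).

   Mouse cohorts instead use fixed 99%-quantile thresholds
   (Pdgfra > 2.64, Egfr > 2.04, Sox2 > 1.95) or GFP expression.
2. **Signature derivation.** CD83⁺CD45⁻ tumor cells from a Cd83
   gain-of-function (GOF) condition are compared with CD83⁻CD45⁻ tumor
   cells from wild-type controls by per-gene Wilcoxon rank-sum tests;
   the signature is the up-regulated genes with log₂FC > 1 and
   Bonferroni-adjusted p < 0.05, mapped from mouse to human symbols.
3. **Scoring and refinement.** Cells are scored with binned-control
   module scores; samples (pseudobulk or bulk) with single-sample GSEA
   (ssGSEA, the rank-based running-sum statistic). Iterative ssGSEA
   prunes signature genes whose expression correlates < 0.5 with the
   enrichment score, to a fixed point.
4. **Cohort statistics.** Pearson correlation panels against immune gene
   sets; upper/lower-quartile stratification of signature scores;
   Kaplan–Meier curves and the log-rank test for survival contrasts.

Because the original patient cohorts are not public, the package ships a
synthetic-cohort generator (`simulate_sc_cohort()`,
`simulate_bulk_cohort()`, `simulate_survival()`) that reproduces the
statistical structure of every input — marker elevation, arm-level CNV
shifts, rare driver SNVs, a planted Cd83 program, coupled immune sets,
score-dependent hazards — with ground truth attached, so every stage is
testable end to end.

## Worked example

```r
library(altsig)

sim  <- simulate_sc_cohort(sim_cohort_spec(seed = 7))   # 2,000 cells, truth known
norm <- lognormalize(sim$counts)

gmm <- fit_em_gmm(norm$values["SOX2", ], marker = "SOX2")
gmm
#> MarkerMixtureModel [SOX2]
#>   weights: 0.5825 0.4175
#>   means:   0 3.671
#>   vars:    1e-06 0.5436
#>   tumor component: 2  tau: 0.5  iterations: 3

models <- lapply(sim$markers, function(m) fit_em_gmm(norm$values[m, ], marker = m))
names(models) <- sim$markers
ind <- marker_indicator_matrix(models, norm)
cnv <- cnv_evidence(norm, sim$gene_arms,
                    reference_cells = sim$counts$obs_ids[sim$counts$values["PTPRC", ] > 0])
snv <- snv_evidence(sim$variants, cells = sim$counts$obs_ids)
call <- call_tumor_cells(ind, cnv$cnv_flag, snv)

tum <- sim$truth$type == "tumor"
sprintf("tumor calls: %d of %d cells | precision %.3f | recall %.3f",
        sum(call), length(call), sum(call & tum) / sum(call), sum(call & tum) / sum(tum))
#> "tumor calls: 1049 of 2000 cells | precision 0.953 | recall 1.000"
```

The mixture model has found the low (normal, mean ≈ 0) and high (tumor,
mean ≈ 3.7) expression classes of SOX2 and the integrated OR rule
recovers the simulated malignant population almost exactly.

`run_pipeline(default_pipeline_config())` chains all stages — simulate,
QC, annotate, signature, score, refine, correlate, survive — through
files in one output directory and writes a manifest; the same run can be
driven from a shell via `inst/scripts/altsig`.

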
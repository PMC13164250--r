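# inflamapper

Phenotyping pipeline for plate-based inflammatory proteomics (Olink-style
NPX data) in cohorts stratified by glycemic status. Individuals with
severe obesity and the same glycemic label — normoglycemia (noDM),
prediabetes (PreDM), type 2 diabetes (T2DM) — differ widely in circulating
inflammatory proteins; this package implements the full analysis chain
used to ask whether those profiles define patient subgroups beyond the
clinical labels:

1. **QC** — exclude proteins with > 20% missing NPX measurements (strict
   inequality; NPX is a log2-scale relative abundance unit);
2. **bridge normalization** — per-protein plate offsets estimated as
   medians of paired bridge-sample differences and subtracted, replicates
   collapsed to one row per individual;
3. **differential expression** — per-protein Welch t-tests between groups;
   since NPX is log2, the mean difference Δ is directly a log2 fold
   change; Benjamini–Hochberg FDR within each contrast;
4. **Mapper (topological data analysis)** — PCA lens (PC1/PC2), an
   overlapping `nb` × `nb` interval cover with overlap ratio `bo`,
   single-linkage clustering within bins in full protein space, and a
   graph with Jaccard-weighted edges `J(A,B) = |A∩B| / |A∪B|`; resolution
   selectable by a scale-free grid search;
5. **communities** — deterministic Girvan–Newman (unweighted edge
   betweenness, modularity-best cut), per-sample cluster assignment, and
   bootstrap stability γ via `clusterboot`-style resampling;
6. **phenotyping** — cluster-vs-remainder signatures (per-protein z-scaled
   log2FC across clusters), Kruskal–Wallis/Dunn and chi-squared cluster
   association tests, Table-1-style cohort summaries, and multivariable
   OLS (glycemic class or continuous fasting glucose, adjusted for age,
   sex, BMI, MASLD stage, antidiabetic therapy, medication burden) with
   VIF and residual-normality diagnostics.

A synthetic cohort generator with planted ground truth (cluster structure,
group shifts, covariate slopes, batch offsets) emulates the study design —
142 subjects (69/25/48), 92 assays with 18 high-missingness, two plates
with 35 bridges, seven inflammatory phenotypes — so every stage is tested
by *recovery of known effects*, not by plausibility of outputs.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
cohort (seed 42) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 42
Rscript analysis/02_qc_normalize.R
Rscript analysis/03_diffexp.R
Rscript analysis/04_mapper_communities.R 42
Rscript analysis/05_phenotyping.R
```

Key output, as printed:

```
<qc_report> 74/92 proteins retained at missingness threshold 0.20
max |estimated - planted| plate offset: 7.77e-16 NPX over 74 proteins

planted-shift proteins, T2DM vs noDM:
 protein log2FC        p        q           class
     IL8  0.780 2.64e-11 1.95e-09 fdr_significant
   CDCP1  0.496 3.34e-06 1.24e-04 fdr_significant
   FLT3L  0.445 6.31e-05 1.56e-03 fdr_significant

<cluster_partition> 7 communities (Q = 0.764); cluster sizes: 48, 24, 22, 19, 16, 7, 6
adjusted Rand index vs planted phenotypes: 1.000
  cluster gamma dissolved     (bootstrap, B = 100)
1       1 1.000     FALSE
...
7       7 0.951     FALSE
```

Reading this: the 18 planted low-detectability assays are removed exactly
at the study's 74/92 ratio; noiseless bridge replicates let the median
estimator recover plate offsets to machine precision; the three planted
group shifts (0.62/0.47/0.49 NPX) are estimated within sampling error
(SE ≈ 0.094 NPX per cohort) and survive FDR correction, while no protein
is FDR-significant in the prediabetes contrasts; Mapper + Girvan–Newman
recovers the seven planted phenotypes perfectly at this seed, all stable
under resampling (γ ≥ 0.95). The T2DM-enriched community (cl7: 66.7%
T2DM, 0% noDM) shows coordinated cytokine upregulation, with IL8/FLT3L/
CDCP1 elevated through cluster composition alone. The adjusted
regressions recover the planted age slope on FLT3L (0.037, planted 0.033
NPX/yr) and FPG slope on CDCP1 (0.0103, planted 0.010 NPX per mg/dL).

`run_pipeline(default_config(seed = 42))` runs the same chain in one call
and returns a result bundle with a reproducibility manifest.

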
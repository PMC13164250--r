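---
title: "Inflammatory proteomic phenotyping with Mapper: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inflammatory proteomic phenotyping with Mapper}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflamapper)
```

# The analysis this package implements

Chronic low-grade inflammation accompanies obesity-associated dysglycemia,
but individuals with the same glycemic label (normoglycemia, prediabetes,
type 2 diabetes) differ widely in their circulating inflammatory protein
profiles. `inflamapper` implements a complete phenotyping pipeline for
plate-based targeted proteomics of such cohorts:

1. **QC** — protein-level missingness filter on NPX measurements;
2. **bridge normalization** — removal of between-plate offsets using
   samples measured on both plates;
3. **differential expression** — per-protein Welch t-tests between glycemic
   groups with Benjamini–Hochberg control;
4. **Mapper topological data analysis** — a graph whose nodes are
   overlapping groups of samples with similar multivariate profiles;
5. **community detection** — Girvan–Newman with a modularity-best cut, plus
   bootstrap stability scoring;
6. **phenotyping** — cluster-vs-remainder inflammatory signatures,
   cluster-wise clinical association tests, and multivariable regressions
   with collinearity and residual-normality diagnostics.

Every stage is exercised against a synthetic cohort generator with planted
ground truth, so recovery of known effects — not plausibility of outputs —
is what the test suite measures.

NPX (Normalized Protein Expression) is a relative abundance unit on a log2
scale: a difference of one NPX unit corresponds to a doubling of protein
level, so a difference of group means is directly a log2 fold change.

# The synthetic cohort generator

`cohort_spec()` / `generate_cohort()` produce cohorts whose value for
sample $i$ and protein $j$ is

$$y_{ij} = \mu_j + s\,\mathbf{1}[j \in B_{c(i)}] + \delta^{g(i)}_j +
\textstyle\sum_k \beta_k \,(x_{ik} - \bar x_{g(i),k}) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$

measured on the sample's home plate; plate-2 measurements additionally
carry a per-protein batch offset. Here $\mu_j$ is a protein baseline,
$B_c$ the signature block of planted phenotype $c$ with shift $s$
(`cluster_shift`, default 3.0 NPX), $\delta^g_j$ the per-group mean shift
(defaults: IL8 +0.62, FLT3L +0.47, CDCP1 +0.49 NPX in T2DM vs noDM, with
smaller prediabetic shifts), and $\beta_k$ planted covariate slopes
(defaults: age 0.033 NPX/yr on FLT3L; fasting plasma glucose 0.008 and
0.010 NPX per mg/dL on IL8 and CDCP1).

Defaults emulate the study design end to end: 142 individuals
(69 noDM / 25 PreDM / 48 T2DM), a 92-assay inflammation panel of which 18
low-detectability assays carry 35–60% missingness (so exactly 74 survive
the 20% filter in practice), two plates with 35 bridge-replicated samples
(12/12/11 by group), and seven planted phenotypes whose membership
probabilities depend on glycemic class so that one phenotype is
T2DM-enriched and two are predominantly normoglycemic.

Design choices worth knowing about:

* **Covariate effects act on group-mean-centred covariates.** Age and FPG
  differ systematically between glycemic groups; if slopes acted on raw
  covariates, the realized T2DM-vs-noDM contrast would be the planted
  group shift *plus* slope-times-group-difference, and no planted quantity
  would be identifiable. Centring within group makes the group-shift table
  alone govern expected between-group contrasts, while within-group slopes
  equal the planted values — which is exactly what a covariate-adjusted
  regression estimates.
* **Signature blocks exclude IL8, FLT3L and CDCP1.** The T2DM-enriched
  phenotype's block contains the cytokine/regulatory axis (IL6, IL10,
  CSF1, FGF23, CD8A, IL10RA). Because membership in that phenotype is
  itself T2DM-enriched, IL8/FLT3L/CDCP1 become elevated in it *through
  composition* — the cluster inherits the group shifts of its members —
  mirroring the biological situation without double-planting effects on
  the same proteins (which would make both unrecoverable).
* **MCAR missingness.** Real panel missingness is mostly
  limit-of-detection censoring, which is informative; we deliberately use
  the simplest mechanism consistent with a flat exclusion rule. Passing
  tests therefore demonstrate correctness of the filter's bookkeeping, not
  robustness to LOD censoring.
* **Noiseless bridges by default** (`bridge_noise_sd = 0`): the two plate
  measurements of a bridge sample differ exactly by the planted offset, so
  bridge normalization must recover offsets to numerical precision — a
  sharp correctness check. Set `bridge_noise_sd > 0` for realism.
* **Clinical covariates** are drawn group-wise from published-scale
  means/SDs, truncated to plausible ranges; fasting glucose truncation
  respects the diagnostic bands (prediabetes 110–125 mg/dL). Only summary
  statistics of the real cohort are public, so joint correlations between
  covariates (beyond group structure) are not emulated.

What the generator does **not** emulate: LOD censoring, plate-position or
freeze–thaw artifacts, heavy-tailed measurement error, within-pathway
protein correlation beyond the planted blocks, and enrollment selection
effects. Recovery results on synthetic cohorts bound what the pipeline can
do under its own assumptions; they do not certify behavior on real data.

# QC and bridge normalization

The missingness filter removes proteins with **strictly more than** 20%
missing measurements — a protein at exactly the threshold is retained.
The filter is idempotent and reports both retained and excluded sets.

Bridge adjustments are per-protein **medians** of paired differences
(other plate minus reference plate) over pairwise-complete bridge pairs;
the median tolerates a single aberrant bridge sample. After subtraction,
replicate rows of a bridge sample are collapsed to their mean (NA-aware),
yielding one row per individual. The collapse rule is a package choice —
published analyses rarely state how technical replicates enter downstream
statistics; the mean uses all information and is unbiased under exchangeable
replicates. Applying estimate-then-apply twice is a no-op (the second
adjustment is identically zero), and within-plate contrasts between
non-bridge samples are invariant under the adjustment.

A hook (`bridge_normalize(..., adjuster = )`) accepts alternative
adjusters for two-step refinement schemes; only plain bridge
normalization is implemented here.

# Differential expression

Welch's unequal-variance t-test per protein, complete-case within protein.
Welch is the standard choice for targeted proteomics panels because group
variances routinely differ; the cost relative to Student's t under exact
homoscedasticity is negligible at these group sizes. A protein with fewer
than two observed values in a group is flagged untested rather than
producing an undefined statistic; a protein with zero variance in both
groups reports $t = 0, p = 1$ when the means agree.

Each of the three pairwise glycemic contrasts is run independently and
BH-adjusted within contrast across the retained proteins. `volcano_table()`
labels proteins `fdr_significant` (q < 0.05), `nominal_only`
(p < 0.05 only), or `ns`.

One precision fact matters when interpreting recovery experiments at the
design scale: with residual noise $\sigma = 0.5$ NPX and groups of 69 and
48, the difference-of-means estimator has standard error
$0.5\sqrt{1/69 + 1/48} \approx 0.094$ NPX. Any single cohort therefore
estimates a planted 0.62-NPX shift only to about $\pm 0.18$ at 95%
confidence; averaging across replicate cohorts (as the acceptance script
does) is what pins down the recovered value.

# The Mapper core

**Lens.** The first two principal components of the median-imputed,
mean-centred matrix. NPX values are already log2-scaled and cross-protein
comparable, so columns are *not* scaled to unit variance (configurable by
pre-scaling the input). Signs are fixed deterministically: per component,
the protein with the largest absolute loading gets a positive loading.
Median imputation is used *only* for geometry (lens and distances); every
inferential statistic uses observed values.

**Cover.** Per lens dimension the data range is split into `nb` base
intervals of width $w = \mathrm{range}/nb$; interval $i$ is
$[\min + iw - gw/2,\ \min + (i{+}1)w + gw/2]$ clipped to the range, with
$g$ the overlap ratio `bo`, so adjacent intervals overlap by $g\,w$. The
2D bins are products of the two interval lists. A degenerate (zero-range)
lens dimension falls back to a single interval with a warning.

**Within-bin clustering and the cut policy.** Samples in each bin are
clustered by single linkage on Euclidean distances in the full protein
space (nodes must group samples with similar *multivariate* profiles, not
merely nearby lens values). The dendrogram is cut by a gap rule on merge
heights, with two refinements over the textbook "first empty histogram
bar" heuristic, both adopted after the literal rule produced artifacts on
data with known structure:

1. *Guarded gap.* An empty bin of the 10-bin histogram over
   $[\min h, \max h]$ counts as a gap only if at least half the merge
   heights lie below it. A gap is supposed to separate the bulk of
   within-cluster merges from the few between-cluster merges; without the
   guard, a single unusually small first merge creates a spurious "gap"
   at the bottom of the histogram and the cut shatters a homogeneous bin
   into singletons.
2. *Dataset-level cut scale.* When the merge heights of the full dataset's
   single-linkage dendrogram show a (guarded) gap, every bin is cut at one
   shared height placed just below the smallest merge height above that
   gap. Bin-local histograms built from a handful of heights are noisy: a
   sparse right tail fakes a gap and shaves outliers off homogeneous bins,
   while bins with two samples (a single merge height) or with uniformly
   large pairwise distances carry no local evidence at all and would
   otherwise become hub nodes gluing unrelated communities. Cutting at the
   *top* of the global gap (rather than its lower edge) keeps loose
   outlier merges attached to their bulk. The bin-local guarded rule is
   the fallback when the dataset shows no global gap.

**Graph.** Nodes are the resulting sample sets; every intersecting pair of
nodes is joined by an edge weighted by the Jaccard index
$J(A,B) = |A \cap B| / |A \cup B|$. The graph is invariant to sample and
protein order.

**Resolution selection.** `grid_search()` scans `nb` in 4–10 and `bo` in
0.10–0.30, requiring admissible pairs to place at least 95% of samples in
the largest connected component and produce at least two nodes, then
maximizes the $R^2$ of a log–log least-squares fit of degree frequency
against degree (the scale-free criterion), breaking ties toward smaller
`nb`, then smaller `bo`. The admissibility thresholds are package-defined
operationalizations of "stable and interpretable". Note that on strongly
clustered cohorts — including this package's default synthetic design —
the Mapper graph is *intentionally* disconnected, so no pair is admissible
and the grid search reports a diagnostic instead of a selection; the
criterion targets connected real-data topologies, and the analysis scripts
then run at the study resolution `nb = 5`, `bo = 0.20`.

# Communities and stability

**Girvan–Newman.** Unweighted edge betweenness (Brandes accumulation),
removing the highest-betweenness edge iteratively; ties are broken
lexicographically by the sorted endpoint id pair, making the algorithm
fully deterministic. Every fragmentation is recorded, and the recorded
partition maximizing Newman modularity
$Q = \sum_c \left[ L_c/m - (d_c/2m)^2 \right]$ on the *original* graph is
returned; earliest (fewest communities) wins ties. Jaccard weights are
deliberately not used during removal — they matter only for
sample-assignment tie-breaks. Isolated nodes form singleton communities.
The implementation is verified against an independent brute-force oracle
(explicit shortest-path enumeration, definitional modularity) on every
connected graph with up to five nodes and on random larger graphs.

**Sample assignment.** A sample occupying several overlapping nodes joins
the community holding the most of its node memberships; ties go to the
community with the larger summed Jaccard weight to the sample's nodes,
then to the larger community. Cluster ids are relabelled by size
(descending), so cluster 1 is always the largest — published cluster
labels are matched by composition, not by id.

**Bootstrap stability.** Samples are resampled with replacement, the whole
Mapper + Girvan–Newman chain is rerun at fixed resolution, and each
baseline cluster is scored by its best Jaccard match among bootstrap
clusters, computed on sets of original sample ids with duplicates
collapsed and the baseline cluster restricted to samples actually drawn.
$\gamma_c$ is the mean over replicates; $\gamma_c < 0.5$ flags a dissolved
cluster. The resampler is injectable, so the bookkeeping is testable
exactly: an identity permutation must give $\gamma = 1$. Resampling is at
the sample level (before binning), matching standard cluster-stability
practice.

# Phenotyping

**Signatures.** $\Delta_{pc}$ = mean NPX of cluster $c$ minus mean of the
remainder (observed values), which is a log2FC on the NPX scale; the
scaled signature is the per-protein z-score of $\Delta_{pc}$ across
clusters. Published "scaled log2FC" heatmaps leave the scaling unstated;
z-across-clusters reproduces the published magnitude range (about ±2 over
seven clusters) and is the normative choice here, so exact reproduction of
published signature values is not promised. A cluster with no observed
value for a protein (possible for singleton clusters) gets `NA`, not a
fabricated zero. Merging all non-$c$ clusters leaves $\Delta_{pc}$
unchanged — the "remainder" is a single pooled group.

**Cluster-wise clinical tests.** Continuous variables: Kruskal–Wallis
across clusters, then Dunn's pairwise z-tests on pooled mean ranks with
the standard tie correction, BH-adjusted. Categorical variables:
chi-squared on the cluster-by-level table. Missing values are dropped per
variable and counted. Constant variables are reported untested. Dunn's
test is implemented in-package (no installed package provides it) and
validated against an independently computed oracle.

**Cohort summary.** Per variable, a D'Agostino–Pearson omnibus gate
(α = 0.05, pooled sample) routes continuous variables to mean ± SD with
ANOVA + Tukey HSD, or median [IQR] with Kruskal–Wallis + Dunn (BH);
categorical variables get counts (%) with overall and BH-adjusted pairwise
chi-squared tests. The omnibus test (D'Agostino skewness Z plus
Anscombe–Glynn kurtosis Z, $K^2 \sim \chi^2_2$) is implemented in-package —
note the kurtosis term requires a signed cube root, since its base is
negative for platykurtic samples.

**Regressions.** OLS of a protein's NPX on glycemic class
(treatment-coded; references: noDM, female, No MASL, medication burden 0)
adjusted for age, sex, BMI, MASLD stage, antidiabetic therapy, and
medication burden; the burden factor is additionally tested at the model
level with an F-test. Complete cases only, with dropped rows counted. A
rank-deficient design is an error naming the collinear columns, never a
silently aliased fit. VIFs use the auxiliary-$R^2$ definition per model
matrix column (cross-checked against `car::vif` in the tests); residual
normality is assessed by D'Agostino–Pearson, Shapiro–Wilk, and
Lilliefors-corrected Kolmogorov–Smirnov tests. `fpg_sensitivity()` swaps
categorical class for continuous fasting plasma glucose with identical
adjustment.

One estimand subtlety: in the FPG sensitivity model the coefficient mixes
within-group dose–response with between-group composition (class is not in
the model), so it does not estimate the generator's within-group planted
slope — omitting class inflates it toward the marginal association. The
*recovery* experiments in the acceptance machinery therefore estimate the
planted FPG slope from a model that adjusts for glycemic class, matching
the generating process; the sensitivity model remains available as the
descriptive analysis it is.

# Problem sizes and reproducibility

All randomness flows through explicit seeds (`with_seed` preserves the
caller's RNG state), and `run_pipeline()` emits a manifest (package
version, seed, config hash, per-stage dimensions) such that identical
configs reproduce results bit-for-bit.

The test-suite experiment sizes are package choices balancing statistical
resolution against turnaround: 200 replicate cohorts for shift recovery,
300 for confidence-interval coverage of planted slopes, 500 null panels
for false-positive control, 100 replicates for the null FPG rejection
rate, bootstrap B = 50–100, and exhaustive graph enumeration up to five
nodes. The full suite runs in well under a minute on one core.

# Known limitations

* Mapper output at fixed resolution can include singleton or tiny
  communities (isolated stray samples); these are faithful artifacts of
  the cover construction, are typically flagged as dissolved by the
  bootstrap, and are reported as-is rather than merged away.
* Node-level identity with other Mapper implementations is not expected —
  binning arithmetic and in-bin clustering conventions differ between
  implementations; community-level agreement is the meaningful target.
* The per-replicate precision of group-shift recovery is bounded by the
  design (see the standard-error note above); claims at tighter tolerances
  require averaging over replicate cohorts.
* The generator's MCAR missingness and independent residuals are idealized;
  see the generator section for the full list of non-emulated features.
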
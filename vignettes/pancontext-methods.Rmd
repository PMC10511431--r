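---
title: "Pan-cancer query-gene association profiling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pan-cancer query-gene association profiling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancontext)
```

# Scope

`pancontext` charts the association landscape of one *query gene* across a
multi-cancer expression cohort and a cell-line panel: co-expression
screening, pre-ranked geneset enrichment, TP53-stratified delta analyses,
survival screening, second-order correlation-vs-hazard analyses, consensus
clustering of cancer types, and drug-response correlation screens. This
vignette documents the statistical models, the tunable parameters and their
defaults, the synthetic-data generator used for validation, and the design
decisions taken where reasonable alternatives existed.

# The co-expression model

All correlation analyses are rank-based. Within a *context* (a cancer type,
optionally restricted to a TP53 stratum), the query gene is correlated with
every other gene by Spearman's ρ with mid-ranks for ties, computed on
pairwise-complete observations; a gene with fewer than 3 complete pairs or
zero variance in the context is recorded as missing and excluded from the
multiple-testing family. Two-sided p-values use the exact permutation
distribution of the rank statistic for n ≤ 10 and the t approximation
`t = ρ√((n−2)/(1−ρ²))` otherwise; Benjamini–Hochberg q-values are computed
within each context, matching the practice of correcting per cancer type.

The screen that defines "correlated genes" is a threshold on the effect
size, |ρ| ≥ 0.6, with q-values reported alongside. The threshold-only rule
is primary because, at cohort sample sizes (hundreds of tumors per type),
correlations of that magnitude are essentially always significant after
correction; a configuration flag (`requireQ`) can additionally demand
q < α. Genes passing in at least one cancer type form the union list whose
gene × cancer-type ρ matrix feeds the heatmap, the consensus clustering and
the second-order analyses.

Upstream of everything, genes are filtered per cancer type: a gene is kept
iff its mean log10(FPKM+1) expression exceeds 0.5 *and* its sample SD
exceeds 0.2 in at least one type (strict inequalities). The query gene is
force-retained with a warning if it fails, since the pipeline is undefined
without it.

# Pre-ranked GSEA

The enrichment engine is written from first principles. For a geneset S
inside a ranked list of N genes with scores r (here: ρ with the query
gene, sorted decreasing), the running sum increments by |r_i|^p normalised
by the sum over members at each member, and decrements by 1/(N−|S|) at each
non-member; the enrichment score ES is the signed maximum-magnitude
deviation. The weight exponent p defaults to 1 (the classic weighted
statistic); p = 0 gives the unweighted Kolmogorov–Smirnov form. When every
member weight is zero the member increments fall back to 1/|S|.

Because the input is a pre-ranked list, the null distribution is built by
*gene-label* permutation: `nPerm` (default 1000) random draws of |S| genes
from the ranked universe, sharing one null per distinct set size.
Normalisation and inference follow the standard recipe:

* NES = ES / mean(|permutation ES| of the same sign);
* nominal p = same-sign tail proportion with add-one smoothing (so p is
  never exactly 0);
* FDR q = ratio-of-tails estimate on NES, computed separately for positive
  and negative NES and capped at 1.

The default pan-cancer reporting rule keeps genesets with q < 0.001 and
|NES| > 2.3 in at least one context — strict thresholds retained as printed
defaults and fully configurable. A fast O(|S|) evaluation of ES from hit
positions only is used inside the permutation loop; it is verified against
full running-sum enumeration in the test suite, and the ES statistic is
additionally cross-checked against the independent `fgsea` implementation.
Exact magnitude ties between a positive and a negative excursion (a
measure-zero event under continuous scores) break by list position, and
magnitudes are rounded at 1e-10 before the argmax so both code paths
resolve ties identically.

# TP53 stratification

Samples are classified from variant-class and copy-number records:
any non-silent variant or homozygous deletion makes a sample MUT;
nonsense/frameshift/splice/homdel map to the Truncating/HomDel class,
missense/inframe to Inframe/Missense, with severity precedence
Truncating/HomDel > Inframe/Missense for mixed records. The exact
functional grouping used by any given upstream resource varies, so the
class map is an explicit, overridable argument. Samples of unknown status
are excluded from stratified analyses but retained in ALL-stratum analyses.

Stratified profiles are computed only in cancer types with more than 20
patients in *each* stratum (strict `>` by default; `inclusive = TRUE`
gives ≥, since sources differ on the boundary). Per gene,
Δρ = ρ_MUT − ρ_WT, significant when |Δρ| > 0.6; per geneset,
ΔNES = NES_MUT − NES_WT with two thresholds, 0.6 for significance and 2.3
for figure-level reporting. The MUT − WT orientation is fixed so that a
positive delta reads "more positively correlated with the query gene when
TP53 is mutant". Both deltas are antisymmetric under exchanging the strata,
which the tests assert exactly.

Expression differences by status use the two-sided Student's t-test with
pooled variance, per cancer type and per group pair; groups with fewer than
2 samples are skipped with a notice rather than an error.

# Survival screening

Overall survival in days is modelled by Cox proportional hazards via the
`survival` package (partial-likelihood maximisation; Efron tie correction
by default, Breslow available). The query gene is dichotomized at the
within-context median — ties go to the low group — and the reported HR is
the hazard of high vs low expression with Wald 95% CI and p-value.
Monotone likelihoods (complete separation) and non-convergence yield a
flagged row with missing HR rather than an exception; the flag triggers on
an unbounded coefficient (|β| > 20) or standard error (> 10³).

Gates: a univariate fit requires ≥ 10 events in the context; the
multivariate fit (ordinal tumor size, nodal and metastatic stage, plus
AURKA log-expression as a continuous proliferation covariate) additionally
requires ≥ 3 of the 4 covariates to be recorded for ≥ 20 patients.
Covariate-incomplete rows are dropped complete-case within the model.
Whether the proliferation covariate should itself be dichotomized is
unspecified in common practice; continuous entry is the default here as it
preserves information. Ineligible cells are absent from the output grid —
blanks, not zeros. Kaplan–Meier curves and the two-group log-rank test
(hypergeometric variance, χ² with 1 df) are provided for display and
cross-checking; the tests verify the log-rank statistic against a
hand-computed oracle and the Cox HR against the closed-form two-sample
exponential rate-ratio MLE at the ~5% level those two estimators admit at
n = 2000 (they are distinct estimators differing at O(n^{−1/2})).

# Second-order analyses and consensus clustering

For every gene (or geneset), the vector of its per-cancer ρ (or NES) values
is correlated with the per-cancer univariate HRs over pairwise-complete
contexts, requiring at least 3 contexts. Spearman correlation is the
default for consistency with the rest of the pipeline (Pearson available);
HRs enter as printed, with log-HR optional. Counts of genes with r > 0.5
and r < −0.5 summarise the histogram.

Cancer types are clustered on their correlation profiles by consensus
K-means: for each candidate k, `reps` (default 1000) subsamples of 80% of
the items are clustered (Euclidean K-means, k-means++ seeding, 10 restarts,
300-iteration cap) and co-clustering frequencies among co-sampled pairs
accumulate into a consensus matrix. Missing ρ entries (gene not profiled in
a context) enter as 0 — absence of association evidence. The consensus CDF
area per k uses the identity ∫₀¹F = 1 − mean of the consensus entries; the
delta-area sequence is the raw area at the smallest k followed by relative
successive increases.

**Choice of k.** The delta-area plot is conventionally read at its elbow.
We select, among the k whose delta-area exceeds `elbowThreshold` (default
0.025), the k with the largest *drop* to the next delta-area value. A
simpler rule — the largest k above the threshold — is available
(`kSelection = "threshold"`) but has a structural flaw under a K-means
inner loop: splitting a clean cluster breaks a fixed fraction of
co-clustered pairs and therefore raises the CDF area by far more than any
small threshold at *every* k, so that rule runs to the top of the k range
even on perfectly separated two-group data. The elbow rule recovers k = 2
and k = 3 on separated synthetic profile groups (asserted in the tests).
Final assignments cut an average-linkage hierarchical tree of
1 − consensus at the chosen k. Degenerate inputs (all items identical) are
flagged with no k chosen.

# Pharmacogenomic screen

Cell lines flagged Engineered or Fibroblast are removed, then cancer types
with fewer than two remaining lines. Per (compound, cancer type), lines
with an observed AUC count as tested; eligibility demands ≥ 10 tested
lines, ≥ 2 sensitive (AUC < 0.8) and ≥ 2 resistant (AUC > 0.8). Spearman ρ
between query expression and AUC is computed only when eligible, so a
reported ρ always rests on both response classes being represented.
Positive ρ means high expression accompanies resistance. Compounds eligible
in at least `minTypes` cancer types (default 11) are reported as a
compound × type matrix with missing cells for ineligible pairs. Multiple
response sources are kept separate via a `source` column — compounds are
never merged across assay technologies, and any [0,1]-scaled response
column is accepted where true dose-response AUCs are unavailable. The mRNA–
protein check sums the listed protein isoform channels per line and
correlates the sum with query expression (Pearson by default, as the
quantities are on comparable continuous scales; Spearman available).
CRISPR viability scores are consumed as provided for display only — their
normalisation is an upstream concern.

# The synthetic-data generator

The generator exists so that every pipeline stage has a ground truth. Its
defaults are the package's reference study conditions: 10 cancer types ×
300 samples, a 2000-gene universe, 40% mutation fraction, a positive and a
negative 50-gene module at ρ = ±0.7, a 50-gene stratum-switching module
(ρ = −0.4 in WT, +0.4 in MUT), per-type log hazard ratios spanning
−1.2…1.2 with 30% censoring, a three-compound drug panel (slopes −2, +2,
0), 30 cell lines per type, and an mRNA–protein correlation target of 0.62
(the strong-correlation regime reported for large proteogenomic cell-line
panels). These values were chosen once as representative of cohort-scale
data and are not tuned per analysis.

*Correlation structure.* Within a type, a latent standard normal drives
module genes through a one-factor Gaussian copula with latent Pearson
parameter `r = 2 sin(πρ/6)` — the exact inverse of the normal-copula
Spearman relation — followed by a strictly increasing softplus-style map
onto the log10(x+1) scale. Monotone maps preserve Spearman ρ, so each
module gene attains its target rank correlation exactly in expectation; at
n = 2000 the empirical ρ sits within ±0.05 of the target. For
stratum-specific modules the copula parameter switches with the sample's
mutation status.

*Survival.* Event times are exponential with hazard
`baseline_rate · exp(log_hr · [query > within-type median])`; censoring is
independent uniform on [0, T_max], with T_max solved numerically so the
expected censored fraction equals the requested rate — the simplest
mechanism satisfying the proportional-hazards assumptions with a
controlled censoring level.

*Drug response and protein.* AUC = inverse-logit(slope · standardized
query expression + Gaussian noise) keeps values in (0,1) with the slope
sign controlling the planted correlation direction. The protein signal is
planted on the observed expression scale (not the latent scale) so the
target *Pearson* correlation of the summed isoform channels with mRNA is
achieved without attenuation from the marginal transform; it is split into
three isoform channels plus small channel noise. Engineered/fibroblast
decoy lines exercise the panel filter.

*Reproducibility.* A single master seed feeds per-type, per-component
substreams (status, expression, survival, covariates, panel, protein) via
a deterministic tag hash, so enlarging the gene universe never perturbs
the survival draws and identical seeds give bit-identical outputs.

*What the generator does not emulate:* empirical library-size and batch
structure, gene–gene correlation beyond the one-factor modules,
non-proportional hazards, subtype mixtures within a cancer type, and
dose-response curve shapes (AUC is generated directly). Passing tests
therefore demonstrate the correctness and calibration of the estimators
under a controlled model, not robustness to every artefact of real cohort
data.

# Numerical choices and degenerate inputs

* Duplicate gene symbols in input files keep the row with highest mean
  expression (deterministic, common practice); duplicate sample ids are an
  error. Identifier matching is exact and case-sensitive — no alias
  resolution (a documented limitation).
* Masked (missing) expression cells never enter any statistic: all
  correlations are pairwise-complete, and a context is skipped per gene
  below 3 complete pairs.
* A gene with zero variance in a context has no defined ρ; it is reported
  missing and leaves the BH family rather than being coerced to 0.
* Median dichotomization sends ties to the low group and errors when a
  split is impossible (all values equal, or a group would be empty).
* Cox fits cap at 50 Newton iterations with a 1e-9 partial-log-likelihood
  tolerance; separation is flagged, not thrown.
* The consensus matrix is forced exactly symmetric and unit-diagonal;
  empty co-sampling cells (possible at extreme subsampling) default to 0.
* Test problem sizes (n = 300–2000 per check, 50-replicate power studies,
  150–1000 consensus repetitions) were chosen to make Monte-Carlo bands
  comfortably wider than estimator noise while keeping the default test
  run fast.

# Known limitations

* The 0.6 correlation screen, 0.001/2.3 GSEA rule and 0.6/2.3 delta rules
  are conventions inherited from practice; they are exposed as
  configuration, and their scientific appropriateness depends on cohort
  sizes.
* The survival screen models overall survival only — no competing risks,
  time-varying covariates or proportional-hazards diagnostics.
* The pipeline correlates; it cannot establish causation, and the
  second-order correlation-vs-hazard analysis in particular inherits the
  noise of both inputs.
* Offline set intersection is provided for comparing against externally
  obtained co-expression lists; no web resources are queried.
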
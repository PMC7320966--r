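---
title: "Severity-subtype discovery with the 3C procedure: models and methods"
author: "threeC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity-subtype discovery with the 3C procedure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(threeC)
```

## The problem and the procedure

Symptom-based psychiatric diagnosis compresses a rich clinical picture into
a single scale. In recent trauma survivors, the Clinician-Administered PTSD
Scale (CAPS) total captures PTSD symptom severity but not co-expressed
depression, anxiety, or the patient's own global impression, and it is
only weakly linked to objective measurements such as cognitive test scores
or brain morphometry. **threeC** implements a semi-unsupervised
subtype-discovery procedure, 3C (categorize, cluster, classify), that
uses the assigned diagnosis to *supervise* which clinical measures matter,
lets the data decide how patients group on those measures, and then asks
which objective candidate biomarkers can *classify* the resulting groups:

1. **Categorize.** Every feature is assigned to one of three categories:
   the single *assigned diagnosis* score (here a CAPS-like severity total),
   *clinical* measurements (self-report symptom totals such as PCL, BDI,
   BAI, CGI), and *potential biomarkers* (cognitive, structural and
   functional features not in clinical use), the latter tagged by domain.
2. **Cluster.** Clinical features are screened against the assigned
   diagnosis by a correlation test with Benjamini–Hochberg adjustment at a
   deliberately permissive level $q = 0.2$; the survivors are standardized
   and the subjects are partitioned by $k$-medoids (PAM) under Manhattan
   distance, with $k$ selected by the gap statistic and the mean
   silhouette width.
3. **Classify.** The clusters are characterized on the biomarkers by three
   complementary views: random-forest importance (mean decrease in Gini
   impurity, with out-of-bag permutation importance alongside), a CART
   classification tree, and a marginal one-way ANOVA per biomarker with BH
   adjustment at $q = 0.05$ across all biomarkers jointly.

Evaluation adds a cluster–diagnosis association test (pooled two-proportion
$Z$ and a between-cluster ANOVA on the severity score), bootstrap cluster
profiles of the top biomarkers, and a train/validate stability procedure.

## Statistical components

**Screening.** For clinical feature $x_j$ and assigned diagnosis $y$ the
default test is the Pearson correlation $t$-test (Spearman optional).
P-values are BH-adjusted *within the clinical family only*; a feature is
retained when $p_{\mathrm{FDR}} \le 0.2$. A zero-variance feature has no
defined test and is flagged, never selected.

**PAM.** Partitioning Around Medoids with greedy BUILD initialization and
SWAP local search (via `cluster::pam`), under the Manhattan ($L_1$)
metric. PAM is deterministic, so the clustering itself never consumes
randomness; the stochastic budget is spent in the gap references and the
forest. The degenerate $k = n$ case (every point its own medoid, cost 0)
is handled explicitly. Unit tests verify PAM against exhaustive
medoid-subset search on small separated instances.

**Gap statistic.** $W_k$ is the total PAM cost at $k$ and
$\mathrm{gap}(k) = \tfrac1B\sum_b \log W_k(\mathrm{ref}_b) - \log W_k(X)$,
with the one-standard-error choice: the smallest $k$ with
$\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$,
$s_k = \mathrm{sd}_b(\log W_k)\sqrt{1 + 1/B}$. Reference datasets are
uniform over the observed ranges *in the principal-component rotation of
the data* (default `reference = "pca"`). The plain feature-range box
(`reference = "range"`) is available, but it is a poor null when features
are strongly correlated — exactly the situation with four clinical totals
that all load on severity — and in that regime it over-estimates $k$ on a
substantial fraction of cohorts; the rotated reference is the standard
remedy and selects $k = 2$ essentially always on the default cohort.

**Choosing $k$.** `choose_k()` defaults to the gap 1-SE choice with the
silhouette argmax recorded. The pipeline defaults to the stricter
`"consensus"` policy: when the two metrics disagree the silhouette argmax
is used, because the residual gap failure mode (over-picking $k$ on
elongated clusters) survives even the rotated reference on a few percent
of cohorts, while the silhouette is stable there. A fixed $k$ can be
forced by configuration, in which case both criteria are still computed
and reported.

**Forest importance.** 500 trees, feature subsample $\lfloor\sqrt p\rfloor$
per split, bootstrap resampling to $n$ — the conventional defaults of the
reference implementation (`randomForest`). Mean decrease Gini is the
primary index; OOB permutation importance (mean decrease in accuracy) is
reported alongside. Ranks break ties by column order.

**Tree.** CART via `rpart` with Gini impurity, `minsplit = 20`,
`minbucket = 7`, `cp = 0.01` (the reference implementation's defaults);
split thresholds are the exact midpoints of adjacent sorted values. Each
node carries its subject count, dominant cluster and dominant proportion,
and renders as `condition -> dominant cluster (count/total = %)`.
Single-class data yields a single pure leaf rather than an error.

**Marginal ANOVA.** Per-feature one-way $F$ with df $(k-1, n-k)$, computed
vectorized from sums of squares (cross-checked against `aov` to $10^{-9}$
in the tests), BH-adjusted across all biomarkers jointly. The companion
`anova_from_summary()` evaluates the algebraically identical $F$ from
per-group means, SDs and sizes, which lets published summary moments be
checked directly:

```{r}
anova_from_summary(means = c(61.91, 37.45), sds = c(18.16, 23.12),
                   ns = c(57, 44))$f
```

**Association tests.** The cluster-diagnosis link uses the pooled
two-proportion $Z$ without continuity correction,
$Z = (\hat p_1 - \hat p_2)/\sqrt{\bar p(1-\bar p)(1/n_1 + 1/n_2)}$, with
cluster 1 the higher-severity cluster, so positive $Z$ means the
high-severity cluster is enriched for diagnosed subjects.

**Stability.** For each training fraction $P \in \{20\%,\dots,90\%\}$ and
iteration (1000 by default): draw a simple random training sample, re-run
screening, clustering (fixed $k = 2$ by default) and the biomarker tree on
the training subjects only, classify the held-out subjects with the
training tree, and report the percentage that lands in their full-data
cluster after optimal label matching (exhaustive over label permutations)
computed on the validation set. Iteration seeds derive deterministically
from (base seed, fraction index, iteration index). Optionally $k$ is also
re-estimated per training sample and the fraction of runs choosing
$k = 2$ is tallied. Screening and the symmetrizing transforms are re-fit
within each training sample by default (`refit_transforms = FALSE`
freezes them from the full data); imputation is performed once on the
full table, since sub-percent missingness does not warrant per-iteration
re-imputation.

## Preprocessing

**Imputation** is 5-nearest-neighbour: each missing cell is replaced by
the unweighted mean of that feature among the 5 nearest subjects, with
subject distance Euclidean over jointly observed per-feature-standardized
columns and rescaled by the number of jointly observed features, so
subjects with different missingness patterns are comparable. Imputation
is idempotent and never touches observed cells.

**Symmetrizing transforms** replace the interactive transform selection an
analyst would perform: per feature, the member of
$\{\,x,\ \log(x+c),\ \sqrt{x+c},\ -1/(x+c)\,\}$ minimizing the absolute
sample skewness $g_1 = m_3/m_2^{3/2}$ (biased central moments) is chosen,
with shift $c = 1 - \min x$ when $\min x \le 0$ and $c = 0$ otherwise.
The reciprocal is negated so every candidate is strictly monotone
increasing — per-subject ranks within a feature are always preserved —
and ties go to the earlier family member (identity first), so the
post-transform $|g_1|$ can never exceed the pre-transform value. Constant
features are defined to have $g_1 = 0$ and keep the identity.

**Standardization** (mean 0, SD 1, denominator $n-1$) is applied to the
screened clinical features before clustering, since the four totals live
on different scales; it is configurable off.

## The synthetic cohort generator

`generate_dataset()` draws cohorts with the statistical structure the
analysis assumes, so every downstream stage is testable without any data
download. The default spec emulates a 101-subject, 256-feature cohort:
1 assigned-diagnosis score, 4 clinical totals, and 251 biomarkers
(11 cognitive, 192 structural, 48 functional).

* **Severity** is a two-component Gaussian mixture on the CAPS scale,
  truncated to $[0, 136]$ by rejection, with component weights 57:44 and
  moments $61.91 \pm 18.16$ (high) and $37.45 \pm 23.12$ (low) — the
  printed cluster moments of the motivating cohort.
* **Clinical totals** are
  $x_j = \lambda_j\,\mathrm{severity} + \delta_j\,\mathbf 1[\mathrm{hi}] +
  \varepsilon_j$ with loadings 1, noise SDs $(18, 21, 24, 27)$ and a
  component-linked offset $\delta_j = 70$. The offset is essential: the
  two severity components overlap heavily on the CAPS scale itself, so a
  model in which clinical totals carry *only* severity information cannot
  produce recoverable subtypes (matched agreement tops out near 0.67).
  The subtypes must differ on the broader clinical profile beyond the
  assigned diagnosis — which is precisely the phenomenon the procedure
  exists to detect. With these defaults the clinical totals correlate
  0.7–0.8 with severity (comfortably surviving the $q=0.2$ screen), the
  recovered clusters match the planted components at $\approx 0.95$, and
  the post-hoc cluster CAPS moments land near the configured component
  moments.
* **Biomarkers** are generated from independent standard-normal latents
  mapped monotonically onto domain scales: identity for cognitive
  $z$-scores, $\exp(\mu_j + 0.25 z)$ with $\mu_j \sim U(5.5, 8.5)$ for
  volume-like structural features, and $\tanh(0.6 z)$ for bounded
  correlation-like functional features — deliberately skewed/bounded so
  the symmetrizing stage is exercised realistically. A planted subset
  (default 10: 2 cognitive, 5 structural, 3 functional) receives a latent
  shift of `planted_effect` SD (default 4) between components; the rest
  are pure noise. The planted effect is sized so that the planted set
  reliably occupies the forest's top ranks and the training trees of the
  stability procedure reproduce the full-data clusters at the ≥90% level
  — the operating point the pipeline is specified to reach — after the
  attenuation caused by imperfect cluster labels. It is *stronger* than
  the marginal effects in typical clinical imaging cohorts; the
  weak-signal regime is represented separately by `planted_effect = 0`
  configurations in the tests (where BH at 0.05 correctly rejects
  nothing).
* **Missingness** is independent at rate 0.01 (guarded so imputation
  preconditions always hold); **diagnosis labels** threshold severity at
  45 and flip with probability 0.15, yielding roughly 58/101 positives
  with an imperfect cluster-diagnosis link.

What the generator does **not** emulate: item-level questionnaire
structure, correlations among biomarkers (each is independent given the
component), scanner/site effects, non-random missingness, and any
longitudinal structure. Tests passing on these cohorts therefore
establish the correctness and stability of the *procedure*, not the
clinical validity of any biomarker on real data.

## Numerical choices and degenerate inputs

* Written feature tables carry full double precision (`%.17g`); report
  JSON uses 17 significant digits, so read-back reproduces every numeric
  field exactly.
* PAM ties (equidistant medoids) resolve to the lowest row index; medoids
  are re-derived from the final clustering as the member minimizing total
  within-cluster distance.
* `log W_k` is guarded at $10^{-12}$ for degenerate zero-cost partitions;
  constant data is rejected by `gap_curve` with an explicit error.
* Transform arguments are clamped just above zero when a fitted transform
  log is applied to out-of-range validation data.
* Zero-variance features: flagged (never selected) in screening, $F$
  undefined (never significant) in the marginal ANOVA, importance exactly
  0 in the forest, and an explicit error in standardization.
* Cluster labels are ordered by decreasing mean assigned-diagnosis score,
  so "cluster 1" is always the high-severity cluster in reports.

## Problem sizes used in the tests and acceptance script

The packaged acceptance checks run PAM against brute force on 200
instances ($n \le 8$), BH against direct step-up on 1000 random vectors,
$k$-selection on 100 separated cohorts ($B = 50$ references), importance
recovery on 50 default cohorts (500 trees), the null marginal ANOVA on
100 effect-free cohorts, and the stability procedure at 100 iterations
per training fraction; `scripts/acceptance.R` uses the same sizes. These
are the package's chosen simulation sizes, balancing Monte-Carlo error
against routine-run convenience; the stability default in
`stability_config()` remains 1000 iterations per fraction.

## Known limitations

* Label matching is exhaustive over permutations and limited to $k \le 8$;
  the intended regime is small $k$.
* The gap statistic is computed from PAM costs, so its reference spread
  inherits PAM's local-search character on pathological geometries.
* The bootstrap profile interval is a plain percentile interval of the
  within-cluster median; its coverage runs a few points below nominal at
  $n \approx 50$ per cluster (≈92–93% observed for a nominal 95%), as is
  typical for percentile intervals of a median, and no BCa correction is
  applied.
* With `refit_transforms = TRUE` the stability procedure re-fits
  transforms on each training sample; a validation value far outside the
  training range is clamped rather than extrapolated.
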
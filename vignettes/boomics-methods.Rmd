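---
title: "Models and methods behind boomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boomics)
```

This vignette explains the statistical models the package implements, the
parameters that matter, the design decisions taken where the procedure was
genuinely open, and what the synthetic-data tests do and do not demonstrate
about real data.

## Study design and urodynamic stratification

The package targets a paired design: unobstructed controls (n = 6) plus two
groups of obstructed patients (n = 3 each) sampled before and 3 months after
surgical de-obstruction. Patients are stratified on the detrusor pressure at
maximal flow: `PdetQmax ≥ 90` cmH2O defines the high-pressure (HP) group
(boundary inclusive), below that the medium-pressure (MP) group. Derived
indices are `BCI = PdetQmax + 5·Qmax` (contractility, dimensionless;
PdetQmax in cmH2O, Qmax in ml/s) and `BOOI = PdetQmax − 2·Qmax`
(obstruction). BOOI below 20 is read as relief of obstruction; the 20–40
equivocal and > 40 obstructed bands follow the standard pressure-flow
nomogram. Only the `< 20` cut is intrinsic to the relief claim; the
upper bands are a documented convention and are configurable in
`classify_obstruction()`.

## Negative-binomial differential expression

Counts are normalized with median-of-ratios size factors: the reference is
the per-gene geometric mean over samples (genes with a zero anywhere are
excluded from the reference), and each sample's factor is the median of its
log count-to-reference ratios, exponentiated. Taking the median on the log
scale means an even number of usable genes averages the middle pair
geometrically; this matches the established implementation and is what the
package's cross-check test asserts.

Two NB procedures implement the decision contract "log2 fold change of
normalized group means, BH-adjusted p, significant at adjusted p < 0.1":

* **`nb_exact`** estimates a single common dispersion by method of moments on
  normalized counts (pooled within-group variances; per-gene moment
  estimates trimmed-averaged over genes where positive). Conditional on the
  total of the two group sums, the group-A sum under the common-dispersion
  NB model is beta-binomial with shape parameters `n_A/α` and `n_B/α`; the
  two-sided p sums the probabilities of all outcomes no likelier than the
  observed one. A mid-p correction (half the observed outcome's probability
  is subtracted) is applied: the test is discrete, and without the
  correction its null p-values are visibly super-uniform at typical depths,
  which would distort the downstream BH step. Totals above 10⁴ switch to a
  normal approximation of the beta-binomial tail with continuity correction.
* **`nb_wald`** uses per-gene moment dispersions shrunk 50/50 on the log
  scale toward a dispersion–mean trend. The trend is fitted log-linearly on
  *binned* moment estimates (20 mean-quantile bins, bin averages keeping the
  negative per-gene estimates): fitting on positive per-gene estimates
  directly selects for upward noise and then underestimates after the log
  transform, which we found biases the trend low by ~10% and mis-calibrates
  the test. The Wald ratio of the log2 fold change to its delta-method
  standard error, `Var(μ̂) = (μ̂ + α̂μ̂²)/n` per group, is referred to a t
  distribution with `2(n_A + n_B − 2)` degrees of freedom — the per-gene
  residual df plus an equal contribution for the trend the dispersion is
  shrunk against, mirroring how empirical-Bayes moderation adds prior df to
  the residual df. A standard normal reference is anti-conservative at these
  group sizes (≈6.5% rejections at nominal 5%), while `n_A + n_B − 2` df
  over-corrects and costs most of the power at n = 3 + 3.

Log2 fold changes use a +0.5 pseudo-count on normalized means, so they are
finite for all-zero groups. Features with zero counts across the contrast are
reported with `log2fc = 0, p = 1` and excluded from the BH universe.

The **consensus** set requires significance in both procedures with
concordant sign — two semi-independent errors must coincide, which is the
point of running two tools. **Bookkeeping** between timepoints partitions
features into normalized / persistent / de-novo; the totals obey
`|before| = |normalized| + |persistent|` and
`|after| = |persistent| + |de-novo|` for any inputs.

## Classifier-gene selection

PCA runs on `log2(normalized count + 1)` with samples as observations,
centered and not scaled. Log-transformed normalized counts, centered only,
are the conventional choice for count PCA; scaling is exposed but off by
default because it up-weights low-count noise. Whether to run PCA on all
genes or DEGs only is not fixed by the procedure's description; the package
runs it on all genes of the two contrasted groups (the selection step then
intersects with DEGs anyway, so the choice affects only the PCA-side pool).

Per principal component k with loading span `[lo, hi]`, features with
loading `≥ hi − 0.2·(hi − lo)` or `≤ lo + 0.2·(hi − lo)` are selected
(boundaries inclusive; "range" is read literally as the min–max span, not as
quantiles of the loading distribution). The union over the top six PCs is
intersected with the consensus DEGs. With six samples only five PCs exist;
the selection then uses all available PCs and warns. A zero-range PC selects
nothing. Selection is invariant to feature order and to the sign
indeterminacy of PCs, and grows monotonically in both the fraction and the
PC count.

Separation on a classifier panel is summarized by the mean silhouette width
of the group labels over the first two PC scores of the panel-restricted
PCA.

## Label-free proteomics

Proteins need ≥ 2 detections in at least one replicate group. Imputation is
two-tiered, reflecting two different reasons for missingness:

* **Tier 1 (left-censored):** a (protein, group) block with ≤ 1 observed
  value is treated as below the detection limit; its missing cells draw from
  `Normal(μ_s − 2.5·σ_s, (0.3·σ_s)²)`, where `μ_s, σ_s` are the *sample
  column's* observed mean and SD. The per-column reading (rather than
  per-protein) is the convention of the standard proteomics tooling, and the
  per-protein alternative is ill-defined exactly where tier 1 applies —
  single-detection proteins have no SD.
* **Tier 2 (sporadic):** blocks with ≥ 2 observed replicates take the normal
  maximum-likelihood mean of the observed values, deterministically. An
  exact MLE under an explicit censoring model is not recoverable from the
  procedure's description; the group-mean MLE is the simplest estimator
  consistent with it and keeps cycle-to-cycle variation confined to tier 1.

The moderated t-test shrinks the pooled per-protein variance `s_g²`
(`d_g = n_A + n_B − 2` df) toward a prior `s₀²` with `d₀` df estimated by
moment-matching `log s_g²` to its scaled log-chi-square model
(`d₀` via the inverse trigamma); the posterior is
`s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g)` and `t̃ = Δ/(s̃·√(1/n_A + 1/n_B))` on
`d₀ + d_g` df. With no excess spread in the log-variances, `d₀ = ∞` and every
protein uses the common variance; `d₀ = 0` recovers the ordinary t-test.

The significance curve declares a protein significant iff `|log2FC| > 1` and
`−log10(p_adj) ≥ −log10(0.05) + c/(|log2FC| − 1)`. This hyperbolic form is
the simplest satisfying both stated constraints — a hard fold-change
asymptote at 1 and a p-threshold approaching 0.05 only at asymptotically
high fold changes. The curvature constant `c` is not recoverable from the
procedure's description; the default 0.5 is configurable, and `c = 0`
degenerates to the rectangular rule.

The impute → test → BH → curve chain runs for 20 cycles with consecutive
seeds; reported statistics come from the first cycle and the `consistent`
flag marks proteins significant in all cycles, i.e. calls that do not depend
on the random tier-1 draws.

## Enrichment and semantic clustering

ORA is the one-sided hypergeometric upper tail per term, on a universe of
all detected genes (the universe is not fixed by the original description;
detected genes is the standard conservative choice). Retention uses the raw
p < 0.1 — deliberately not BH-adjusted, matching the stated threshold — with
an adjusted column emitted for transparency.

Information content is `ic(t) = −log(|genes(t)|/|genes(root)|)` on
true-path-closed annotations; Resnik similarity is the maximum ic over
common ancestors (terms count among their own ancestors), normalized by the
corpus maximum so the 0.7 redundancy threshold acts on a [0, 1] scale — the
original similarity scale is unstated, and an unnormalized ic would make any
fixed threshold corpus-dependent. Redundancy pruning is greedy by ascending
p with lexicographic tie-breaks, so the result is order-independent.

Binary cut recursively bipartitions the average-linkage dendrogram of
`1 − similarity`; a block becomes a cluster when its mean off-diagonal
similarity reaches 0.85 (the reference implementation's conventional
homogeneity cutoff, configurable) or it has fewer than 3 terms. Display
tables give treemap tiles (tile size = term gene count, cluster area = term
count), word frequencies (per gene, the number of enriched terms containing
it, signed by fold change), and per-term ridge rows with their mean log2FC.

## TF regulons

TFs found DE in ≥ 1 contrast (an "all contrasts" filter is also exposed) are
categorized from per-group before/after DE booleans: persistent if DE before
and after in some group; otherwise normalized-after if DE before anywhere
(by exclusion, in no such group after); otherwise de-novo. Target log2FC
profiles across the four contrasts are clustered with `d = 1 − pearson`,
average linkage, cut at k = 5 — the number of target clusters the analysis
design anticipates, exposed as a parameter since nothing in the procedure
derives it. Constant rows, where Pearson correlation is undefined, go to a
separate "flat" bucket rather than poisoning the distance matrix. Per-cluster
summaries report mean log2FC per contrast and a `down_after` flag (mean
drops from before to after in every group).

## Synthetic data: what it emulates and what it does not

`gen_counts()` draws NB counts with log-normal baseline means
(`log-mean log(100)`, sdlog 1), gamma per-gene dispersions (mean 0.1, shape
4; `shape = Inf` gives the common-dispersion regime the tests assume), and
log-normal(0, 0.2) library-size factors — modest depth variation typical of
a well-behaved bulk experiment. Planted genes (default 5%) get log2 effects
of fixed magnitude (default 2, sign split 50/50) in a random nonempty subset
of the non-reference groups, which produces normalized / persistent /
de-novo patterns in the five-group design. `gen_lfq()` draws log2
intensities around N(23, 2) baselines with replicate SD 0.5 and censors each
sample below its own intensity quantile (missing with probability 0.95,
plus 2% missing-completely-at-random so the tier-2 branch is exercised).
Urodynamic records use the study's printed group means and SDs for PdetQmax
and age, truncated at zero; Qmax and residual volume come from configured
plausible ranges (obstructed flow ~6–8 ml/s improving after surgery,
residual volume falling under ~50 ml), since only their qualitative behavior
is documented.

Passing parameter-recovery tests on these generators shows the procedures
are correctly implemented and calibrated *under their own model*: NB counts
with group-constant effects, normally distributed log intensities,
deterministic left censoring. Real data add gene–gene correlation, outlier
samples, composition effects, batch structure and dispersion–mean
relationships the generators do not emulate; the tests say nothing about
robustness to those.

Null-calibration checks use the common-dispersion regime because that is the
model both NB tests assume; under gene-varying dispersions the
common-dispersion exact test is mildly anti-conservative for
higher-than-average-dispersion genes (a known property of common-dispersion
testing, shared by its archetypes), which is noted here as a limitation
rather than hidden by the test design.

## Problem sizes and numerical choices

The test suite and acceptance script use 2 000-gene / 3-vs-3 matrices for
classifier recovery, 5 000 features for null calibration, 400 proteins at
4 vs 4 with 30% censoring and Δ = 3 log2 units for the 20-cycle consistency
check, and 10⁶ draws for the imputation distribution check — sizes at which
Monte-Carlo error is well below the tested tolerances while the whole suite
runs in well under a minute per file. Degenerate inputs are handled
explicitly: all-zero samples and features error or fall out of the BH
universe, zero-range PCs select nothing, constant cluster rows go to the
flat bucket, empty queries return empty enrichment tables, and every
stochastic step takes an explicit seed with bit-identical reruns.
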
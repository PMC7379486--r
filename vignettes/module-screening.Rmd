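---
title: "Marker-seeded gene modules and signature-reversal screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-seeded gene modules and signature-reversal screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfgm)
```

# The analysis in one paragraph

`cfgm` implements a module-based screen for drugs that oppose a disease
process at the transcriptional level. A small panel of *marker genes* — by
default POSTN, DDR2 and PDGFRA, the classical markers of activated cardiac
fibroblasts — seeds a *gene functional module*: the markers plus the genes
most strongly coexpressed with them in a tissue expression compendium. The
module is then scored against ranked differential-expression profiles with a
weighted Kolmogorov–Smirnov (KS) running-sum statistic. Disease contrasts
should concentrate the module at the *top* of the ranking (positive
enrichment score, ES); a drug whose profile concentrates the module at the
*bottom* (negative ES, small p) is a *signature-reversal candidate* — it
pushes the module's expression down and may oppose the process the module
represents. The leading-edge ("core") genes of each enrichment and their
cross-condition overlap (hypergeometric test) complete the screen.

# Module construction

Compendium-scale coexpression search services rank candidate genes over
thousands of curated datasets. `cfgm` instead uses a transparent local score. For each
candidate gene $g$ and marker set $M$,

$$\bar z(g) = \frac{1}{|M|} \sum_{m \in M} \operatorname{atanh} r(g, m),$$

the mean Fisher-z-transformed Pearson correlation across compendium samples.
The Fisher transform is variance-stabilizing, which is what makes averaging
across markers defensible. Correlations are clipped to $\pm 0.999999$ before
`atanh` so a gene duplicating a marker gets a large finite score rather than
infinity.

Significance is attached by a per-gene permutation null: the gene's sample
vector is permuted `n_null` times (default 999), $\bar z$ recomputed each
time, and the one-sided add-one p-value reported,
$p = (1 + \#\{\bar z_{null} \ge \bar z\})/(1 + n_{null})$. The null is
one-sided because the module collects the most strongly *positively*
coexpressed genes. Add-one counting bounds p below by $1/(n_{null}+1)$ — a
p-value of exactly 0 is never reported — and `n_null` below 99 is refused
because it cannot resolve the default threshold. Each gene receives its own
independent permutations, so background p-values are independent across genes
and uniformity checks are clean.

The module is the markers (always included, whatever their score) plus every
gene with $p$ *strictly* below the threshold (default 0.01). Selection is
monotone: relaxing the threshold can only grow the module. Note that with
$G$ background genes a calibrated null admits about $0.01\,G$ false members
at the default threshold; the module is a screening instrument, not a
finished gene list, and precision necessarily degrades as the compendium
universe grows relative to the true module.

# Ranking contrasts

Two-class contrasts are ranked by either the log fold change (difference of
class means; data assumed log-scale) or a moderated t statistic with a fixed
prior: the pooled within-class variance $s_g^2$ (on $d_g = n_1 + n_2 - 2$
df) is shrunk toward the median gene variance $s_0^2$ with prior weight
$d_0 = 4$,

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}.$$

This captures the essential benefit of empirical-Bayes moderation — genes
with accidentally tiny variance cannot dominate the ranking, and zero-variance
genes remain scorable — with two documented constants instead of a fitted
hyperprior. It is deliberately not a re-implementation of any specific
empirical-Bayes package, and exact equivalence with one is a non-goal.

The default direction is descending (most up-regulated first), so disease-like
contrasts give positive ES. Ascending is exposed as an option; with a signed
statistic the two conventions are mirror images. Tie-breaks are lexicographic
by gene symbol, and duplicate symbols (probe collapses) keep the score of
maximum absolute value — both rules chosen for cross-platform determinism.
Symbols are uppercased on ingestion so that human/mouse casing (Postn/POSTN)
cannot split a gene.

# The enrichment statistic

Walking the ranked list $g_1, \dots, g_N$ with gene set $S$ ($N_H = |S \cap
\text{list}|$), the running sum accumulates
$+|r_j|^p / N_R$ at members ($N_R = \sum_{g_j \in S} |r_j|^p$) and
$-1/(N - N_H)$ at non-members. ES is the running-sum value of largest
magnitude. For the weight exponent $p = 0$ this is exactly the classic
two-sample KS deviation between the member and non-member rank distributions
(tested against an independent brute-force implementation); $p = 1$ weights
members by their scores, the convention of the standard GSEA software, and is
the default. Both weights are first-class.

Numerical conventions, all load-bearing:

* The extremum position is the *first* index attaining the maximum for
  positive ES and the *last* index attaining the minimum for negative ES.
  These mirror-image rules make the leading edge invariant under list
  reversal.
* A tie in magnitude between the positive and negative extremum resolves in
  favor of the positive one. Extremum comparisons use an absolute tolerance
  of $10^{-9}$ so floating-point summation noise cannot flip an analytic tie;
  at list lengths where exact agreement is asserted the smallest genuine
  nonzero difference is orders of magnitude larger.
* The running sum terminates at 0 (hit and miss mass each total 1); this is
  verified to $10^{-12}$ on every test instance.
* Set members absent from the list are dropped with a warning rather than an
  error — expression platforms rarely cover a module completely.
* If every member score is zero at $p = 1$ (so $N_R = 0$), the set falls back
  to $p = 0$ with a warning.

Significance comes from the *gene-tag* (random-set) null: `n_perm` random
sets of the same size, positions drawn uniformly without replacement. This is
the appropriate null for preranked input, where a single differential profile
exists and phenotype permutation is unavailable. The signed convention
compares the observed ES only against same-sign null values, with add-one
counting (p is never 0; a reported $p \le 1/(n_{perm}+1)$ is the floor). NES
is ES divided by the mean magnitude of same-sign nulls. For a single gene
set the FDR estimator collapses to the nominal p; it is reported separately
only to keep the conventional ES/FDR result pair.

The null sampler uses a closed-form $O(N_H)$ evaluation per draw (extrema can
only occur at member positions, just before them, or at the terminal zero),
which is what makes hundreds of calibration replicates cheap; it is tested
for exact agreement with the full running-sum path.

# Overlap of core genes

Leading edges from different conditions are compared with the hypergeometric
upper tail $P(X \ge k)$, computed through R's stable log-space distribution
functions and verified against exhaustive enumeration for universes up to 12.
The default universe is the module itself, the smallest defensible choice
given that leading edges are subsets of the module; it is configurable, and
the universe used is always stated in the output. Symbols are compared after
case normalization only — no ortholog mapping is attempted.

# The synthetic-data generator

The generator exists so that every stage can be validated against planted
ground truth without downloads. It emulates three things: (i) a compendium in
which a module of genes coheres around the markers — a single latent factor
$f_s \sim N(0,1)$ per sample, module genes $x_{gs} = \beta f_s +
N(0,\sigma)$, background genes pure noise, giving the closed-form module-pair
correlation $\beta^2/(\beta^2 + \sigma^2)$; (ii) disease contrasts in which
effected module genes gain $+\delta$ in the case class; (iii) drug contrasts
in which they lose $\delta$ — signature reversal. All output is a pure
function of the configuration including its seed.

Reference conditions (the package defaults): a 50-gene module (3 markers) in
2000 genes; $\beta = 1$, $\sigma = 0.5$ (module-pair correlation 0.8, strong
tissue-level coexpression); compendium of 150 samples; contrasts of 20 vs 20
samples with $\delta = 1.5\sigma$, a moderate, realistically detectable bulk
effect. `effect_fraction` controls what share of the module carries the
shift (default 1; 0.5 is used to test leading-edge specificity at
$\delta = 2\sigma$).

What the model does *not* emulate: probe-level structure, batch and platform
effects, count noise (RNA-seq), correlated background, or multiple latent
factors. Passing tests therefore demonstrate correctness of the statistics
and calibration under exchangeable Gaussian noise, not robustness to real
microarray artifacts.

Two deliberate experiment-design choices:

* The *module recovery* experiment plants the 50-gene module in a 400-gene
  compendium. Precision at threshold $t$ is bounded by the calibrated false
  positive mass $t \cdot G_{background}$; at 2000 genes a perfectly calibrated
  procedure would admit ~19 background genes against 50 true ones, capping
  precision near 0.75. A 400-gene universe (~3 expected false positives)
  measures recovery quality rather than that arithmetic ceiling. The
  screening and calibration experiments keep the full 50/2000 design.
* Calibration and power runs use 199–499 permutations per test, which
  resolves the 0.05 level comfortably while keeping 500-replicate studies in
  tens of seconds on one core.

# Pipeline and reproducibility

`run_pipeline()` chains module construction, per-contrast ranking,
enrichment, leading-edge extraction and pairwise core-gene overlap, and
emits a machine-readable JSON summary plus a log. Every stochastic stage
receives a sub-seed derived deterministically from the single configured
seed; a configuration without a seed is refused, and a rerun of the same
configuration is byte-identical. A contrast is flagged `reversal_candidate`
when its ES is negative with $p$ below the configured alpha, and
`disease_like` when positive and significant.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)          # reference conditions
sim <- simulate_compendium(cfg)
pipe <- run_pipeline(pipeline_config(
  compendium = sim$dataset,
  contrasts = list(disease = simulate_contrast(cfg, sim$truth, "up"),
                   drug    = simulate_contrast(cfg, sim$truth, "down")),
  markers = sim$truth$marker_genes,
  n_perm = 499, n_null = 499, seed = 42))
pipe
```

# Known limitations

* The coexpression score is a local surrogate for compendium-search services;
  it sees one expression matrix, not thousands of curated datasets, and its
  p-values are defined by this package's permutation null.
* The single-set FDR is not a multi-collection FDR; screening many gene-set
  collections would require cross-set normalization that is out of scope.
* Phenotype permutation is not implemented (preranked input only).
* Cross-species comparisons rely on symbol-case normalization alone.
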
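---
title: "The oxidative-aging screening pipeline: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The oxidative-aging screening pipeline: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxaging)
```

# The scientific question

Type 2 diabetes mellitus (T2DM) risk rises with age, and oxidative stress
is a long-suspected intermediary: aging shifts the expression of
oxidative-stress genes, and those shifts in turn track disease genes.
`oxaging` implements an integrated screen for that hypothesis on gene
expression cohorts. The screen is *mediation-style*: an aging marker
plays the role of the instrument-like auxiliary variable, an
oxidative-stress gene the exposure, and a disease marker the outcome.
It is emphatically **not** Mendelian randomization — there are no
genetic instruments, and no causal claim is made; every step is a
statistical association filter.

The pipeline has seven stages, each exposed as ordinary R functions and
orchestrated by `run_pipeline()`:

1. **Preprocessing** (`preprocess_study()`): probe summarization,
   missingness filtering, a conditional log transform,
   control-referenced z-scoring, SVD control-component removal, and a
   stratified 2:1 train/test split.
2. **Marker prediction** (`train_predictor()`): ReliefF gene ranking
   plus a correlation-distance kNN classifier (k = 3), with the model
   size chosen by a 10-fold cross-validated learning curve over the top
   500 features.
3. **Triple screening** (`assemble_triples()`): differential
   coexpression, permutation, confounder and pleiotropy filters that
   emit aging–oxidative–disease gene triples.
4. **Sensitivity analysis** (`run_mh_chain()`, `triple_sensitivity()`):
   Metropolis–Hastings sampling of marker-space vectors per phenotype
   group, scored by a nearest-neighbour disease score, with each
   triple's correlation index compared between the two chains.
5. **Network stage** (`build_diffcoexp_network()`,
   `shortest_paths_for_pairs()`, `betweenness_null_p()`): sign-flip
   differential coexpression edges, deterministic unit-weight Dijkstra
   (breadth-first) shortest paths for oxidative→disease pairs, and
   interior-betweenness network markers with a permutation null.
6. **Enrichment** (`enrich_gene_lists()`): upper-tail hypergeometric
   tests of path genes against GMT gene sets, BH-adjusted per path.
7. **Pan-cancer stage** (`pancancer_run()`): tumor/normal differential
   expression, marker-score survival stratification with
   Kaplan–Meier/log-rank, and per-cancer reuse of the network and
   enrichment stages.

# The statistics, precisely

## Differential coexpression (the core screen)

For genes $x$ and $y$ measured on the same samples, the screen statistic
is the Kruskal–Wallis test of the per-sample product between phenotype
groups:

$$p = \mathrm{KW}(x \cdot y,\ \text{phenotype}).$$

If the coupling between $x$ and $y$ differs between T2DM and control,
the product's distribution shifts between the groups. Each screening
family (all aging × oxidative pairs; all oxidative × disease pairs) is
Benjamini–Hochberg adjusted as one battery, and a pair is retained when
$p < 0.05$ **and** FDR $< 0.1$. The KW p-value uses the chi-square
approximation with 1 df and tie correction at all sample sizes; an
all-tied product vector is defined as $H = 0, p = 1$ rather than an
error because degenerate vectors do occur on filtered data.

Two caveats matter for interpretation. First, the product statistic
responds to *marginal mean shifts* as well as to coupling: if both $x$
and $y$ have nonzero group-mean differences, $x \cdot y$ shifts between
groups even when $x \perp y$. Second, when a gene carries a constant
group shift $\delta$, the product acquires a $\delta \cdot x$ noise term
that dilutes the coupling signal. Both effects are visible in the
synthetic experiments below.

## The permutation filter

For each retained pair the observed statistic is
$\lvert \overline{xy}_{\mathrm{T2DM}} - \overline{xy}_{\mathrm{ctrl}} \rvert$.
Each of 1000 permutations replaces the *candidate* gene (the aging
marker in stage one, the oxidative marker in stage two) with a gene
drawn uniformly from the replaced marker's own candidate class, and the
p-value is the fraction of permutations at least as large as the
observed value — ties count, no add-one correction, so an exact 0 is
possible. Drawing replacements from the same class (rather than the
whole genome) calibrates the null against whatever background signal
the class shares, which is the point of simulating "markers" rather
than arbitrary genes; classes smaller than 12 genes fall back to the
genome. `permutation_pair_test()` exposes the pool as an argument.

## Confounder and pleiotropy filters

A triple's aging→disease relationship is dropped when any other
measured gene is differentially coexpressed with **both** the aging and
the disease marker (each at $p < 0.05$, FDR $< 0.1$ within that
marker's genome-wide scan; one BH family per scan). Scans are
precomputed once per marker.

The horizontal-pleiotropy filter compares the aging–disease relation
with and without the oxidative route, using OLS slopes fitted with
intercepts on all samples pooled:

$$
\begin{aligned}
\text{residual}_A &= d - b_1 o, &
\text{residual}_B &= a - b_2 o, \\
\text{residual}_C &= \text{residual}_A - b_3\,\text{residual}_B, &
\text{residual}_D &= d - b_4 a,
\end{aligned}
$$

and tests $\text{residual}_C - \text{residual}_D$ between phenotype
groups with the KW test. A **significant** difference means the direct
aging→disease path and the oxidative-routed path disagree in a
phenotype-dependent way — evidence of horizontal pleiotropy — so the
triple is *deleted*. The opposite convention (retain on significance)
is available via `retain_on_significance = TRUE`, but on planted
pure-mediation data it retains nothing: for a clean chain
$a \to o \to d$ the residual difference is location-null between groups
(both group means are zero), so a location test cannot be the signal
carrier. Deletion-on-significance matches the filter's stated purpose
and keeps planted mediation triples.

## MCMC sensitivity analysis

Per phenotype group, marker-space vectors $\theta$ are sampled from

$$\pi(\theta) \propto
  \mathrm{prior}(\theta)\,\exp\{s \cdot \beta \cdot
  \mathrm{score}(\theta)\},$$

where the prior is an independent normal per marker (group training
mean and sd), $s = +1$ for the T2DM-enriched chain and $-1$ for the
control chain, and the score is the nearest-neighbour disease score:
the summed Euclidean distance (over the disease markers) to the 7
nearest control training samples minus the same sum over the 7 nearest
T2DM training samples. The proposal is a symmetric Gaussian random walk
(so the transition-kernel ratio cancels), started at the prior mean.

Numerical choices worth stating:

* **States, not acceptance events.** The chain records every
  post-burn-in state, repeating the current state on rejection.
  Recording only acceptance events oversamples the target's tails (the
  escape probability is higher there) and measurably biases the sample
  sd upward by 5–8% at well-mixed step sizes.
* **Step size.** The application default is 0.25 × the per-marker prior
  sd, deliberately conservative for high-dimensional marker spaces.
  Validation runs that check the $\beta = 0$ case (where the target is
  the prior itself) use the standard optimal-scaling step
  $2.4\sigma/\sqrt{d}$, and recover the prior mean and sd within
  ±0.05 at 10,000 retained samples.
* **Thinning.** `mh_config(thin = )` keeps every thin-th state.
  Downstream, each triple's correlation index
  $(d - a)/(o - a)$ (denominator clipped at $10^{-8}$, values
  winsorized at each chain's 1st/99th percentiles) is compared between
  chains with the KW test, which assumes roughly independent draws.
  Unthinned random-walk samples have lag-1 autocorrelation near 0.9,
  which turns Monte-Carlo noise into spurious "sensitivity"; thin = 25
  restores calibration in the identical-target control experiment.

## Network, paths, betweenness

An edge joins two genes when their Pearson correlations have opposite
signs in the two groups and each group individually passes $p < 0.05$
and FDR $< 0.1$ (BH within each group's full pair family — the stricter
symmetric reading). Paths use unit edge weights, so Dijkstra reduces to
breadth-first search; neighbors are explored in lexicographic order so
exactly one deterministic path is reported per pair. Betweenness counts
*interior* occurrences only — an endpoint gene gets no credit for its
own query. The permutation null redraws the same number of random
source–target pairs, with endpoints excluding the evaluated gene
(a gene cannot occur inside a path it terminates); the all-pairs
correlation stage is capped at `max_genes` (default 3000) by variance
filtering because it is quadratic.

## Enrichment and survival

Enrichment uses the upper-tail hypergeometric probability
$P(X \ge k)$ for an overlap of $k$ between a path's genes and a gene
set, with the measured genes as the universe and BH within each path's
battery. The pan-cancer stage calls a gene differentially expressed
when the linear-scale fold change exceeds 2 (or falls below 1/2 — the
symmetric two-sided reading, with a switch for the literal one-sided
rule), the KW p-value is below 0.05 and the BH FDR below 0.1; inputs
are assumed log2(x+1)-scaled and de-logged before fold changes. Tumor
samples are split at the cohort *mean* of the per-sample mean marker
expression (a median switch is provided), and the two groups are
compared with the standard log-rank test via the survival package.

# The synthetic cohort generator

`generate_cohort()` emulates a multi-cohort T2DM expression study with
four subgroups (aged/young × T2DM/control). Defaults: 2,000 genes;
subgroup sizes 60/40/40/20; 20 mediation triples with
$\lambda = \gamma = 0.9$; classifier shift $\delta = 1.0$ z-units; 30
sign-flip pairs at $\rho = 0.7$; noise sd 0.5. These sizes keep every
experiment in this package at desk scale (the full test suite runs in
about two minutes) while leaving usable power for recovery tests.

Three planted structures, deliberately orthogonal:

* **Mediation triples**, planted on the baseline z-scale: in T2DM
  samples $o = \lambda a + \varepsilon$ and
  $d = \gamma o + \varepsilon$; in controls $a, o, d$ are mutually
  independent. In T2DM, $\mathrm{corr}(a, o) \to
  \lambda/\sqrt{\lambda^2 + \sigma^2} \approx 0.87$.
* **Classifier shifts**, overlaid afterwards: disease markers get
  $+\delta$ in T2DM samples, aging markers $+\delta$ in aged samples.
  Planting the mediation on the baseline scale (rather than on the
  shifted values) keeps each structure aimed at its own detector: the
  coupled alternative makes *every* shifted marker pair differentially
  coexpressed through mean products, which swamps the triple screen
  with hundreds of cross-triple artifacts.
* **Sign-flip pairs**: correlation $+\rho$ in controls, $-\rho$ in
  T2DM.

`generate_pancancer_cohort()` adds tumor/normal cohorts on the
log2(x+1) scale with planted fold changes and exponential survival
whose log-hazard is `hazard_beta` per unit of the standardized marker
score; censoring is uniform on (0, 2 × median event time), giving the
30–50% censoring typical of public tumor cohorts.

What the generator does **not** emulate: platform-specific probe
structure, count-based RNA-seq noise, correlated gene modules beyond
the planted pairs, batch effects, or age as a continuous confounder.
Passing recovery tests on this generator therefore demonstrates that
the machinery detects the structures it claims to detect — not that the
screen's operating characteristics transfer to any real cohort.

# Design points that were genuinely open

* **Probe summarization** is the mean over probes; symmetric and
  scale-preserving.
* **The log-transform trigger** ("contains outliers") is
  operationalized as cohort maximum > 50, separating linear-scale from
  already-logged data; the threshold is an argument.
* **SVD correction** removes the top 3 *gene-space* components of the
  control submatrix from all samples and re-applies control z-scoring.
  A side effect worth knowing: aged-vs-young variation among controls
  is exactly the kind of control-structure the step removes, so it
  partially absorbs the aging signal the aging predictor later looks
  for. The number of components is an argument (0 disables).
* **The aged/young boundary** is age > 50; the disease model's control
  class is young controls only (a switch adds aged controls).
* **ReliefF** is the deterministic all-anchors variant with 10
  neighbors per class, Manhattan distance on range-normalized features;
  determinism was preferred over stochastic anchor subsampling for
  testability. The kNN score for ROC purposes is the neighbour vote
  fraction (k = 3 gives scores in {0, 1/3, 2/3, 1}).
* **Single-feature models** in the learning curve fall back to absolute
  difference, since correlation distance is undefined on one feature.
* **The learning-curve search** evaluates every nested prefix of the
  ranked list up to 500 features via cumulative sums, so the full curve
  costs little more than the largest model; ties in CV accuracy go to
  the smallest model.
* **BH families**: one per screen stage, one per genome-wide scan, one
  per path battery; families are never pooled across stages.
* **Eq-level typography**: the residual recursion uses
  residual_C = residual_A − b3·residual_B, and the hypergeometric tail
  uses the standard C(N, n) denominator; the corrupted printed forms
  are not reproducible as formulas.

# Known limitations

* The KW-product screen cannot distinguish coupling from co-occurring
  marginal mean shifts; specificity against shifted marker sets comes
  from the class-calibrated permutation filter, not the screen itself.
* A constant disease-marker shift $\delta$ *reduces* the power of the
  oxidative×disease screen (the $\delta \cdot o$ product noise), so on
  the default generator roughly half the planted triples survive all
  filters — recovery, not specificity, is the binding constraint.
* Correlation distance is invariant to sample-wide additive shifts, so
  a classifier built on it sees only the *pattern* of a signature, not
  its overall level; on the default generator the disease predictor
  plateaus near 0.73 accuracy / 0.83 AUC where a Euclidean kNN would
  reach 0.95+. This mirrors the modest accuracies the method reports on
  real cohorts.
* The sensitivity stage's rank test treats chain samples as
  independent; use thinning when calibration matters.
* Exactly one shortest path is reported per pair, so betweenness counts
  depend on the deterministic tie-break; counting all tied paths would
  give different (larger) values.

# Reproducing the numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates the default
cohort, runs every stage, and writes the recovery rates, null
calibration rates, predictor accuracies and sampler-exactness errors as
JSON. The same quantities are asserted (at their design bounds) in
`tests/testthat/test-acceptance.R`.
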
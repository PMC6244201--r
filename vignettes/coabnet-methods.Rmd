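---
title: "Co-occurrence networks from compositional cohorts: models and choices"
author: "coabnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence networks from compositional cohorts: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

16S rRNA amplicon surveys report, for each stool sample, integer counts of
exact sequence variants (ESVs). Sequencing depth is arbitrary, so the counts
carry only *relative* information: they are compositional. Naive Pearson or
Spearman correlations between two taxa's relative abundances are biased by
the closure constraint (all fractions sum to one), which is the motivation
for log-ratio methods. `coabnet` implements an end-to-end pipeline for
cohort studies built around that constraint:

1. filtering and CSS normalization of the count table;
2. per-feature linear-model associations with host phenotype
   (site, BMI class, age, physiology), FDR-corrected;
3. basis-correlation inference in the SparCC family, with a bootstrap
   null model for per-pair significance;
4. co-occurrence network assembly by a dual criterion (FDR and a
   null-mode magnitude threshold);
5. network topology summaries and cross-cohort comparisons;
6. targeted node-attack robustness with a rewiring null ensemble;
7. jackknife random-forest feature ranking for cohort prediction.

# Basis correlation inference

For features $i,j$ with per-sample fractions $x_i, x_j$, the variation
statistic is

$$t_{ij} = \mathrm{Var}\!\left[\log \frac{x_i}{x_j}\right],$$

which is invariant to per-sample depth. Writing $\omega_i^2$ for the
variance of feature $i$'s unobserved absolute (basis) log-abundance and
$\rho_{ij}$ for the basis correlation,
$t_{ij} = \omega_i^2 + \omega_j^2 - 2\rho_{ij}\omega_i\omega_j$. Under the
sparsity assumption that most $\rho_{ij}\approx 0$, row sums of $t$ give a
linear system for $\omega^2$ whose coefficient matrix has $d-1$ on the
diagonal and 1 elsewhere; then

$$\hat\rho_{ij} = \frac{\hat\omega_i^2 + \hat\omega_j^2 - t_{ij}}
                       {2\hat\omega_i\hat\omega_j},$$

clipped to $[-1, 1]$. The most strongly correlated pair with
$|\hat\rho|$ above the exclusion threshold (default 0.1) is iteratively
removed from the system and the solve repeated, up to $\lfloor d/2\rfloor$
times — the classical guard against sparsity violations. At $d = 3$ the
system is exactly determined
($\omega_1^2 = (t_{12}+t_{13}-t_{23})/2$, and cyclically); $d<3$ is
rejected. Negative solved variances (possible in the linear algebra) are
clipped to $10^{-6}$ and counted.

Zeros are handled by the pseudocount policy: `add_one` (deterministic) or
`dirichlet_draw`, a draw of fractions from the per-sample Dirichlet
posterior under a uniform prior. `estimate_correlations()` averages the
estimate over `n_inner = 20` posterior draws. Note one consequence of any
pseudocount: multiplying a sample's counts by a constant no longer leaves
the estimate *exactly* unchanged, only up to the pseudocount's weight
(about $5\times10^{-3}$ at depth ~50 in our tests).

## Bootstrap significance and the null model

`bootstrap_edge_stats()` runs the estimator on 50 bootstrap resamples and,
for each, on the same resample with every feature's counts independently
permuted across samples. The per-pair statistic is the median bootstrap
$|\hat\rho|$; its p-value is the add-one permutation tail probability
against the pooled null ($50 \times \binom{d}{2}$ draws), and q-values are
Benjamini–Hochberg across pairs.

Two choices deserve justification:

* **Pooled null.** With 50 replicates a per-pair null cannot produce
  $p < 1/51 \approx 0.02$, so an FDR cut at 0.01 — the edge rule this
  pipeline exists to apply — could never fire. Permuted pairs are
  exchangeable, so pooling their null magnitudes is legitimate and gives
  the p-value resolution the threshold needs. `pool_null = FALSE` restores
  the per-pair convention.
* **Full-size resampling.** `boot_fraction` defaults to 1 (the classical
  bootstrap). Subsampling a small fraction of an already small cohort
  (e.g. 30% of 25 samples) produces 8-sample estimates whose permutation
  null spans nearly $[0,1]$; we measured that *no* pair — including planted
  $\rho = 0.8$ pairs — can then reach $q \le 0.01$. Small fractions remain
  available as an explicit parameter.

## Edge selection

An edge is kept iff $q \le 0.01$ *and* its median $|\hat\rho|$ exceeds the
mode of the pooled null magnitude distribution, estimated by a Gaussian
KDE (Silverman bandwidth, 512-point grid on $[0,1]$). The mode rule
operationalizes "above the most probable null magnitude" — the only
reading of a mode-based magnitude cut that yields a usable threshold. The
network keeps exactly the features incident to a selected edge; edge signs
are the sign of the correlation.

# Topology

All metrics are unweighted and undirected. Edge density is
$E/\binom{N}{2}$, transitivity is $3\times$triangles/connected triples,
diameter and mean path length are computed on the largest component (with
component coverage reported), betweenness is raw (unnormalized), and
eigenvector centrality is scaled to a maximum of 1. Freeman
centralization is computed for degree, closeness, eigenvector and
betweenness (star $=1$, complete graph $=0$). Communities come from
greedy modularity maximization, the deterministic default recorded in the
summary. Hub score equals eigenvector centrality on an undirected graph
and is reported as its own column only to mirror the conventional table
layout.

**Closeness on fragmented graphs.** Within a component, closeness is
$(r-1)/\sum d$ with $r$ the component size; we additionally multiply by
the Wasserman–Faust coverage factor $(r-1)/(N-1)$. On a connected graph
this is the textbook $(N-1)/\sum d$; on a fragmented graph the uncorrected
per-component version *rewards* fragmentation (a 3-node fragment scores
near 1), which would invert any dense-vs-fragile comparison. Cross-cohort
closeness comparisons additionally offer a per-cohort max normalization
(`normalize = TRUE` in `compare_cohort_metric()`), the convention used for
"normalized closeness" panels.

# Attack robustness

Nodes are removed in descending order of degree or betweenness computed on
the intact graph (static ordering, the classical formulation; a
`recompute` mode re-ranks after every removal). Ties break by ascending
node id. Connectivity loss uses the efficiency convention

$$E(f) = \sum_{u<v} \frac{1}{d_{uv}(f)}, \qquad
  \mathrm{loss}(f) = 1 - E(f)/E(0),$$

with unreachable or removed pairs contributing 0 — the one reading of "the
ratio of summed distances" that stays finite through disconnection. The
collapse fraction $f^\*$ is the first $f$ with loss $=1$, i.e. the point
at which no connected pair survives. The null ensemble moves 10% of edges
to uniformly chosen non-adjacent pairs (degree not preserved), 500 times,
records each rewired graph's $f^\*$, and cohorts are compared by a
two-sided Welch t-test on those samples.

A caveat discovered during validation: under the *static* betweenness
ordering every leaf ties at betweenness 0, so in very sparse fragmented
networks the tail of the attack is id-order rather than structure, and
$f^\*$ loses its discriminating power. The degree ordering does not suffer
from this at realistic sparsity, and the packaged study comparisons use
it; the structural dense-vs-fragile property holds for both orderings on
the planted graphs themselves.

# Normalization and associations

CSS (cumulative sum scaling) computes each sample's scaling factor as the
sum of its counts at or below a chosen quantile of its nonzero counts,
divided by the median factor across samples; values are
$\log_2(\mathrm{count}/\mathrm{factor} + 1)$. The default quantile is
adaptive: the smallest grid quantile (step 0.05) at which the median
factor's relative change between consecutive candidates exceeds 0.02.
At quantile 1 CSS reduces to total-sum scaling.

Associations are ordinary linear models of CSS-log2 abundance on one
covariate of interest at a time plus adjusters (site, BMI class, age by
default), with BH q-values per covariate across features. This
deliberately replaces zero-inflated Gaussian mixtures with a simpler,
adequately powered model at these cohort sizes; the substitution is a
design decision of this package. Features with site or BMI q ≤ 0.1 are
the handoff set for network inference, mirroring the study design where
only phenotype-associated sequences enter the networks.

# Random-forest feature ranking

The two-stage protocol: (1) grid-tune `mtry`, tree count, per-tree sample
size and node size on a stratified 70/30 split, minimizing held-out error
(ties to the earliest grid point); (2) choose the variable count by
recursive elimination over a halving schedule under 10-fold CV, taking the
smallest count whose error is within one standard error of the minimum.
We use the candidate's own fold-to-fold SE (the caret-style variant):
with a coarse halving schedule and flat error curves, comparing against
the minimizer's SE alone makes the chosen count unstable, and an inflated
count makes the downstream significance rule vacuous. (3) 1000 jackknife
iterations (tests and the desk-scale analysis run 100–200), each on 70%
of variables and 70% of samples, ranking included variables by permutation
importance. A variable's score is the geometric mean of its ranks; its
p-value is a one-sided binomial test of how often it ranked worse than the
cutoff (the CV-chosen count) against 0.5, BH-adjusted; selection requires
q ≤ 0.001 and geometric mean rank below the cutoff. Overall model
significance is a permutation test on out-of-bag error with add-one
p-values.

# The synthetic-data generator

No sequence data are deposited for the study this pipeline re-implements,
so every downstream stage is validated against a logistic-normal
multinomial simulator that plants known structure:

* **Latent model.** Per sample, log basis abundances are multivariate
  normal with a planted correlation matrix (unit per-feature log-SD by
  default), exponentiated, closed to fractions, and observed as one
  multinomial draw per sample at ~15,000 reads — the compositional
  process the estimator assumes.
* **Rank abundance.** A common core (36% of features,
  $\log$-mean $\sim N(3, 0.25)$) carries ~97% of reads over a rare tail
  ($N(-1,1)$). This mirrors real 16S rank-abundance curves closely enough
  that the study's own filters (10,100-read sample floor, max-count ≥ 10,
  mean relative abundance > 1%) retain all samples and a core of ~50
  features, the scale of the published cohort networks.
* **Archetypes.** `dense_robust` plants factor-model cliques of 25
  features at $|\rho| = 0.8$ (35% of loadings flipped negative, giving
  ~45% inhibitory edges); the planted correlation density among the
  retained core is ~0.5 — the magnitudes reported for the dense cohort.
  `sparse_fragile` plants 7-leaf single-factor hubs at $\rho = 0.7$
  (capped there so leaf–leaf correlations, $\rho^2 \approx 0.5$, stay
  below detection at 25 samples), a hub-and-spoke structure that
  fragments under targeted attack.
* **Cohort design.** Four cohorts (2 sites × 2 BMI classes), 25 samples
  each by default with the study's 29/21/13/37 imbalance as a preset; the
  lean site-A cohort carries the dense archetype. Cohorts share baseline
  abundances, effects and the covariate link — only correlation structure
  differs. Site and BMI log-fold-changes (1.2 and 0.8 natural-log units
  on a third and a fifth of features) are applied symmetrically (±half)
  so group means straddle the baseline; one-sided application of
  multi-fold shifts to most of the core would skew whole-sample
  composition enough that the depth filter removes entire cohorts.
  An SCFA-like covariate is a linear link on designated features' latent
  log abundances plus Gaussian noise.

What the generator does *not* emulate: sequencing error and chimeras,
taxonomy, overdispersion beyond the logistic-normal, zero-inflation beyond
sampling zeros, and real ecological network motifs. Passing tests
therefore demonstrate correctness of the statistical machinery under the
assumed generative model, not that the biological conclusions of any
particular cohort would replicate.

# Numerical and procedural choices

* All stochastic functions take a `seed` and restore the caller's RNG
  state; child seeds for replicate streams are drawn once up front.
* Filtering iterates its three rules to a fixed point so the operation is
  idempotent (dropping features lowers sample depths, so a single pass is
  not).
* KDE mode threshold: degenerate (all-equal) nulls return that value
  directly; fewer than 10 null values is an error.
* Attack tie-breaks are ascending node id everywhere; the removal grid is
  one node at a time with fractions $k/N$.
* Problem sizes in the tests and the acceptance script — 150-feature
  studies, 50-feature recovery cohorts, 200 jackknife iterations —
  are the package's chosen desk scale; every count is a parameter and the
  study-scale defaults (1000 jackknife iterations, 500 rewirings) remain
  the documented defaults.
* Bit-level determinism holds for all outputs except eigenvector
  centralities, where ARPACK iteration is deterministic only to ~1e-14.

# Known limitations

* SparCC's sparsity assumption is violated by design in the dense
  archetype (half of all core pairs correlated); estimates there are
  attenuated (planted 0.8 recovered around 0.55–0.7 at $n=25$), which is
  why edge recovery, not unbiasedness, is the validated property.
* At 25 samples per cohort, edges near the significance boundary
  teeter with the bootstrap seed; cohort-level edge counts are stable
  only to within a few tens of edges.
* The rewiring null preserves edge count but not degree sequence.
* The GLM stage models CSS-log2 values as Gaussian; strongly zero-inflated
  features at low depth are better served by mixture models.
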
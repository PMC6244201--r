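# coabnet

Co-occurrence network analysis of compositional microbiome cohorts.

Amplicon surveys give feature-by-sample count tables (ESVs/OTUs) whose
counts are compositional: sequencing depth is arbitrary, so only relative
information survives, and naive correlations between taxa are biased by
closure. `coabnet` is for microbiome researchers who want to compare
*co-occurrence network structure* between cohorts — e.g. lean vs obese
participants at two study sites — and to say whether one community is more
densely connected and more robust to the loss of its central taxa.

The core pieces:

* **Basis correlations (SparCC family).** From the log-ratio variation
  statistic `t_ij = Var[log(x_i/x_j)]`, basis variances `w_i^2` solve the
  sparsity-assumption linear system and
  `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, with iterative
  strong-pair exclusion, Dirichlet-posterior pseudocounts, and an exact
  closed form at d = 3.
* **Bootstrap null edges.** 50 bootstrap replicates, each paired with a
  feature-permuted null; per-pair add-one permutation p-values against the
  pooled null, Benjamini–Hochberg q-values, and a dual selection rule:
  q ≤ 0.01 *and* |rho| above the kernel-density mode of the null
  magnitudes.
* **Topology.** Density, transitivity, diameter, Freeman centralization
  (degree/closeness/eigenvector/betweenness), greedy-modularity
  communities, and rank-sum cohort comparisons of node metrics.
* **Attack robustness.** Targeted node removal (degree/betweenness),
  efficiency-based connectivity loss, the collapse fraction f\* at which no
  connected pair survives, a 10%-edge rewiring null ensemble, and Welch
  t-tests between cohorts' f\* distributions.
* **Associations & feature ranking.** CSS normalization, per-feature
  linear models with FDR, and the two-stage-tuned, cross-validated,
  jackknifed random-forest variable ranking (geometric mean rank,
  binomial significance).
* **Synthetic cohorts.** A logistic-normal multinomial generator that
  plants dense/robust or sparse/fragile correlation networks with known
  effects, so the whole pipeline is testable without any sequence
  download.

## Worked example

The `analysis/` scripts run the full study on a simulated four-cohort
dataset (25 samples each, ~15,000 reads/sample, 150 features; the lean
site-A cohort carries a dense planted network, the rest hub-and-spoke
fragile ones):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_per_cohort_networks.R
Rscript analysis/03_rf_feature_ranking.R
Rscript analysis/04_cohort_comparisons.R
```

`02_per_cohort_networks.R` prints the per-cohort network table (seed 1):

```
      cohort total_nodes number_of_edges edge_density transitivity
  siteA_lean          51             524   0.41098039    0.8502393
  siteB_lean          23              20   0.07905138    0.3600000
 siteA_obese          23              21   0.08300395    0.2195122
 siteB_obese          24              17   0.06159420    0.0000000
```

and `04_cohort_comparisons.R` the headline contrasts: the dense cohort's
normalized closeness beats each fragile cohort (rank-sum p ≤ 1.2e-06) and
its collapse fraction under degree-targeted attack is larger
(f\* = 0.961 vs 0.826–0.958, Welch p ≤ 3.6e-73 on the rewiring-null
samples), i.e. the planted "dense/robust vs sparse/fragile" contrast is
recovered end to end:

```
Dense cohort dominates density, degree, closeness and f*: yes
```

`03_rf_feature_ranking.R` tunes the forest, picks the variable count by
10-fold CV, and ranks features over 200 jackknife iterations; on seed 1 it
selects 37 features, all of which carry a planted site effect, with model
permutation p = 0.010.

In code, the same pipeline is one call:

```r
library(coabnet)
study <- generate_study(seed = 1)
res <- run_pipeline(list(counts = study$table, metadata = study$metadata,
                         seed = 1), out_dir = "results/run")
res$comparisons$summary_table
```

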
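---
title: "Estimating depression-anxiety symptom networks from ordinal screening items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating depression-anxiety symptom networks from ordinal screening items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symptomnet)
```

## The model

symptomnet treats the 17 items of two screening instruments — the CESD-10
depression scale (10 items, 0–3 each) and the GAD-7 anxiety scale (7 items,
0–3 each) — as nodes of an undirected network and estimates the network as a
Gaussian graphical model (GGM). In a GGM the edge between items $i$ and $j$
is their *partial correlation*

$$ w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii} K_{jj}}}, $$

where $K$ is the precision (inverse covariance) matrix: the association
between two symptoms after statistically controlling for all other symptoms.
A zero entry means conditional independence.

Because the items are ordinal and strongly right-skewed, the correlation
input is the pairwise **Spearman** matrix (average ranks for ties) rather
than Pearson or polychoric correlations; polychoric estimates become
unstable when cross tables have near-empty cells, which is exactly the
situation for rarely endorsed anxiety items. A Spearman matrix of ordinal
data is not guaranteed positive semidefinite, so `repair_psd()` clips
negative eigenvalues (at $10^{-4}$) and rescales back to unit diagonal
before estimation; valid inputs pass through untouched.

Sparsity comes from the **graphical lasso**: maximize

$$ \log\det K - \mathrm{tr}(SK) - \lambda \sum_{i \ne j} |K_{ij}| $$

with the diagonal unpenalised, implemented in compiled code as block
coordinate descent over the working covariance (the standard algorithm for
this problem; an independent proximal-gradient maximizer is used as a test
oracle). The penalty $\lambda$ is chosen by minimizing the **extended BIC**

$$ \mathrm{EBIC}_\gamma = -2\,\hat\ell + E \log n + 4 E \gamma \log p, $$

over a path of 100 log-spaced penalties from $\lambda_{\max}$ (the largest
absolute off-diagonal correlation, at which the network is empty) down to
$\lambda_{\max}/100$. $E$ is the number of nonzero off-diagonal pairs and
$\gamma = 0.5$ by default, the conventional value that favours sparse,
interpretable networks. Exact EBIC ties break toward the larger penalty.
Estimated weights below $10^{-8}$ in absolute value are set exactly to zero
so the reported edge count is well defined in floating point.

## Centrality

Two node-level statistics summarise influence, both keeping edge signs:

* **Expected influence (EI)**: $\mathrm{EI}_i = \sum_j w_{ij}$, the signed
  one-step sum of a node's edges. High-EI nodes are candidate *central
  symptoms* that activate the rest of the network.
* **Bridge expected influence (BEI)**:
  $\mathrm{BEI}_i = \sum_{j : c(j) \ne c(i)} w_{ij}$, the signed sum
  restricted to edges crossing the depression/anxiety community boundary.
  High-BEI nodes are candidate *bridge symptoms* mediating comorbidity.

Node strength ($\sum_j |w_{ij}|$) is also reported. Raw values are the
primary output; z-scores are offered for plotting only. Exact identities —
EI equals the signed row sum, BEI plus within-community EI equals EI,
strength bounds |EI| — are enforced by tests for arbitrary networks.

## Accuracy and stability

`edge_bootstrap()` draws case resamples with replacement and re-runs the
*entire* estimation chain (Spearman, repair, penalty path, EBIC selection)
per replicate, so the percentile confidence intervals reflect
model-selection variability, not just sampling noise around a fixed
$\lambda$. Intervals are inverse-ECDF (type 1) percentiles of the draws.
These are bootstrap stability intervals in the usual network-psychometrics
sense: lasso shrinkage biases the draws toward zero, so they should be read
as accuracy diagnostics rather than exact frequentist intervals.

`difference_test()` declares two edges (or two centralities) different at
level $\alpha$ when the $(\alpha/2, 1-\alpha/2)$ percentile interval of the
paired per-replicate differences excludes zero. Tests are unadjusted for
multiplicity, matching the standard procedure for these networks; treat the
pairwise flags as descriptive.

`case_dropping()` re-estimates the network on subsamples with 5%–75% of
cases removed and correlates subsample centralities with the full-sample
values. The **CS-coefficient** is the largest drop proportion at which at
least 95% of correlations stay ≥ 0.7; values below 0.25 indicate
instability and above 0.5 ideal stability. The grid caps the coefficient at
0.75. Replicates whose subsample network is empty (constant statistic) have
no defined correlation and are counted against stability.

All bootstrap replicates derive their seeds from the master seed by a
counter scheme, so any subset of replicates is reproducible independently
of execution order, and every seeded run is byte-identical when repeated.

## The synthetic study generator

Real item-level survey microdata cannot be redistributed with the package,
so `simulate_study()` generates a stand-in with the statistical structure
the analysis assumes:

* **True network** (`make_true_network()`): a two-community (10 + 7)
  partial-correlation matrix. Within-community edges are placed at density
  0.40 with weights drawn from 0.10–0.39; six weak bridge edges
  (0.05–0.10), dominated by GAD1, connect the communities. If the implied
  precision matrix $I - W$ is not positive definite with minimum eigenvalue
  ≥ 0.05, all weights are shrunk by the exact closed-form factor
  $(1-0.05)/\mu_{\max}$ — uniform shrinkage preserves the relative edge
  structure, unlike per-edge clipping.
* **Latent-Gaussian thresholds**: items are discretised cuts of a latent
  multivariate normal (a Gaussian copula), the generative model under which
  Spearman-based GGM estimation is meaningful. Default thresholds are
  calibrated by moment matching (`calibrate_thresholds()`, Nelder-Mead on
  squared mean/SD error) to a right-skewed marginal profile typical of
  older community samples: depression item means 0.50–1.45, anxiety item
  means 0.12–0.32. At $n = 10{,}000$ simulated means land within ±0.05 of
  the targets.
* **Missingness** (`inject_missing()`): independent per-cell Bernoulli
  replacement with survey-style tokens ("not able to answer", "don't
  know", "not applicable"). Missingness is completely at random; since the
  analysis is complete-case, the mechanism does not affect pipeline
  correctness, only the eligible sample size.
* **Eligibility covariates**: validated ages from a truncated normal
  (mean 80.5, SD 10, range 65–109) and a diabetes-diagnosis flag, the two
  fields the eligibility filter uses (age ≥ 65, diagnosis present,
  complete items).

What the generator deliberately does **not** emulate: multi-stage survey
sampling designs and weights, household clustering, informative
missingness, demographic covariates beyond age and the diagnosis flag, and
any latent-variable structure other than the Gaussian copula. Passing
parameter-recovery tests therefore demonstrates correctness of the
estimation pipeline under its own assumptions, not robustness of the
scientific conclusions to violations of those assumptions on real data.

## Numerical choices

* Solver: parameter-change tolerance $10^{-6}$ (relative to the mean
  absolute off-diagonal of $S$), at most 500 outer sweeps, deterministic
  cyclic sweep order; non-convergence is an error, never a silent result.
* Penalty path: 100 points, min-ratio 0.01 — the ecosystem convention;
  both are arguments.
* $\lambda = 0$ is allowed when $S$ is positive definite and reproduces
  the unregularized partial correlations.
* Degenerate inputs: constant items are an error naming the item (their
  rank correlation is undefined); an all-zero correlation matrix yields a
  degenerate single-point path with a warning.
* Bootstrap replicates that fail estimation are skipped and counted;
  more than 10% failures aborts.

## Problem sizes used in the shipped checks

The package's own validation uses reduced but honest scales chosen to keep
the full suite quick: parameter recovery at $n = 2000$ from a 17-node
chain-plus-bridges network with strong weights spanning 0.25–0.39;
null-network false-edge checks at $n = 2000$; edge-CI coverage over 20
replications of $n = 300$ with $B = 100$ bootstrap samples (aggregate
coverage of true weights, all 136 pairs); difference-test calibration on
simulated bootstrap-world null draws ($m = 40$, $B = 800$); case-dropping
comparisons at $n = 2000$ versus $n = 150$ with $B = 12$. The
`scripts/acceptance.R` reproduction runs the full default study
($n = 1685$) with $B = 200$ edge bootstraps and $B = 50$ case-dropping
samples per proportion.

## A worked example

```{r example, eval = FALSE}
raw <- simulate_study(n = 1685, seed = 1)
eligible <- filter_eligible(raw)
prevalence(score_scales(eligible))

net <- select_network(eligible, gamma = 0.5)
net
head(centrality_table(net)[order(-centrality_table(net)$EI), ])

eb <- edge_bootstrap(eligible, B = 200, seed = 1)
cd <- case_dropping(eligible, "EI", B = 50, seed = 1)
cs_coefficient(cd)
```

## Limitations

The estimator assumes a monotone latent-Gaussian dependence structure;
networks are group-level cross-sectional summaries and support no causal or
within-person claims. EI/BEI are one-step statistics; two-step variants,
polychoric inputs, Ising/mixed models, and node-dropping stability are out
of scope. Cronbach's alpha is reported descriptively using the n−1
variance convention throughout.
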
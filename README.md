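# symptomnet

Symptom-level network analysis of depression and anxiety screening items in
R. The package is aimed at psychometric and epidemiological researchers who
study comorbidity at the level of individual symptoms rather than sum
scores: each of the 17 items of the CESD-10 (depression, 10 items) and
GAD-7 (anxiety, 7 items) becomes a node of an undirected network, and edges
are the regularized partial correlations between symptoms after controlling
for all others.

## The method

The network is a Gaussian graphical model estimated from ordinal 0–3 Likert
items:

1. **Correlation input** — pairwise Spearman correlations (appropriate for
   skewed ordinal items), with an eigenvalue-clipping repair if the matrix
   is not positive semidefinite.
2. **Sparse estimation** — the graphical lasso: maximize
   `log det K − tr(SK) − λ Σ_{i≠j} |K_ij|` over precision matrices `K`
   (compiled block coordinate descent), along a path of 100 log-spaced
   penalties.
3. **Model selection** — extended BIC with hyperparameter γ = 0.5
   (`EBIC = −2ℓ̂ + E log n + 4 E γ log p`), ties toward the sparser model.
   Edge weights are `w_ij = −K_ij / √(K_ii K_jj)`.
4. **Centrality** — expected influence `EI_i = Σ_j w_ij` (central
   symptoms) and bridge expected influence
   `BEI_i = Σ_{j in other community} w_ij` (bridge symptoms mediating
   comorbidity), plus node strength.
5. **Accuracy & stability** — non-parametric bootstrap CIs for edge
   weights, bootstrapped difference tests, case-dropping bootstrap and the
   correlation-stability (CS) coefficient (acceptable ≥ 0.25, ideal
   ≥ 0.5).

A latent-Gaussian (copula) generator simulates ordinal survey data from a
known true network with right-skewed marginals and survey-style missing
codes, so the whole pipeline is testable by parameter recovery without
restricted survey microdata. Screening utilities score both scales
(CESD-10 total 0–30, depression at ≥ 10; GAD-7 total 0–21, severity bands
at 5/10/15) and compute prevalence, comorbidity and Cronbach's alpha.

## Worked example

```r
library(symptomnet)

raw <- simulate_study(n = 1685, seed = 1)   # synthetic survey extract
eligible <- filter_eligible(raw)            # age >= 65, diagnosis, complete items
round(prevalence(score_scales(eligible)), 3)
#> depression    anxiety   comorbid
#>      0.505      0.058      0.036

net <- select_network(eligible, gamma = 0.5)
net
#> Regularized partial correlation network
#>   nodes: 17  possible edges: 136  nonzero edges: 61
#>   n = 1685  gamma = 0.5  selected lambda = 0.04566  EBIC = 21812

ct <- centrality_table(net)
head(ct[order(-ct$EI), c("name", "community", "EI", "BEI", "strength")], 5)
#>    name  community    EI     BEI strength
#> 6 CESD6 depression 1.085 0.05117    1.085
#> 7 CESD7 depression 1.068 0.00000    1.068
#> 2 CESD2 depression 1.061 0.00282    1.061
#> 1 CESD1 depression 0.976 0.03101    0.976
#> 3 CESD3 depression 0.942 0.01294    0.942
```

Half the simulated sample screens positive for depression while anxiety is
much rarer, reflecting the calibrated right-skewed marginals; EBIC keeps 61
of 136 possible edges, and the highest-EI nodes are the candidate central
symptoms of this synthetic network. `edge_bootstrap()`, `case_dropping()`
and `cs_coefficient()` then quantify how trustworthy those orderings are;
`run_pipeline(run_config(...))` executes everything end to end and writes
edge lists, node metrics, GraphML, bootstrap summaries and a JSON manifest.
A thin CLI (`exec/symptomnet`) exposes `simulate`, `screen`, `estimate`,
`centrality`, `stability` and `run-all` subcommands.

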
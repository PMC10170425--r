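# clpnet — cross-lagged panel networks for ordinal symptom data

`clpnet` estimates **directed cross-lagged panel networks (CLPN)** from
two-wave panel data of ordinal mental-health items — the design used to ask
which symptoms *drive* later psychological distress and which symptoms are
its *recipients*. It was built for 13-node distress batteries (the 12 GHQ-12
items, 0–3 Likert, plus a single loneliness item, 1–3), but works for any
ordinal item set.

For items $y_1,\dots,y_p$ at waves $t$ and $t+1$, each wave-$(t+1)$ item is
LASSO-regressed on **all** wave-$t$ items:

$$\hat W_{j\cdot} = \arg\min_\beta\ \tfrac{1}{2n}\lVert y_j^{(t+1)} - X^{(t)}\beta\rVert_2^2 + \lambda_j\lVert\beta\rVert_1,$$

so $W_{jj}$ is the autoregressive path and $W_{ji}$ the cross-lagged path
$i \to j$, adjusted for all other symptoms; $\lambda_j$ is chosen per node by
10-fold cross-validation. Node importance is **expected influence**: the
signed sum of outgoing (out-EI) or incoming (in-EI) cross-lagged weights.

The package covers the full workflow:

* data model and IO for ordinal panels (long/wide CSV, sentinel codes,
  explicit missingness mask), GHQ-12 scoring with the sum > 11 caseness
  rule, reverse-coding, and descriptive psychometrics (α, ω total,
  bias-adjusted skewness/kurtosis, paired *t*, Hedges's *g*);
* single-dataset **predictive mean matching** imputation (chained
  equations, 5 donors) with auxiliary covariates, plus a complete-case
  filter for sensitivity analyses;
* CLPN estimation by an exact coordinate-descent LASSO path solver
  (compiled, active-set KKT refinement) with hash-based, order-invariant CV
  folds;
* in-/out-expected-influence centrality with z-standardization;
* nonparametric bootstrap edge CIs, edge- and centrality-difference tests,
  case-drop bootstrap stability with the CS-coefficient;
* cross-network comparison (edge-list correlations, non-zero edge counts,
  strongest-edge tables) and a manifest-stamped, bit-reproducible pipeline;
* a **synthetic cohort generator** (sparse latent VAR(1), ordinal
  thresholds, covariate-dependent MAR attrition) standing in for the
  restricted survey data every stage was designed around.

## Worked example

```r
library(clpnet)

model <- default_true_model()          # 13 items, loneliness = out-hub
data  <- simulate_panel(model, simulation_config(
           n_subjects = 2000, n_waves = 3, seed = 101, missingness_on = TRUE))
#> MAR missingness applied: 24.6% of post-baseline cells missing

imputed <- pmm_impute(data, imputation_config(seed = 7))
net     <- estimate_clpn(imputed, c("1", "2"))
print(net)
#> clpn_network: 13 nodes, wave 1 -> 2, n = 2000, 101 non-zero cross-lagged edges

top_edges(net, k = 3)
#>        from         to    weight rank
#> 1 worthless confidence 0.1725478    1
#> 2 loneliness depressed 0.1634714    2
#> 3 loneliness  worthless 0.1330213    3

ei <- expected_influence(net)
ei$node[which.max(ei$out_ei)]
#> [1] "loneliness"
```

The strongest edge (worthless → confidence, 0.17) and the top out-expected-
influence node (loneliness) are exactly the hubs planted in the generating
model; with 2,000 subjects the estimated standardized weights sit slightly
below the generating values because 4-category skewed items attenuate
correlations. `bootstrap_edges()` then gives percentile CIs and difference
tests, `casedrop_stability()` the CS-coefficient (0.6 for out-EI in this
run), and `compare_networks()` the wave-pair comparison.

The `analysis/` directory holds the same study as numbered scripts
(simulate → impute → estimate → centrality/stability → compare), each
writing its tables under `results/`.

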
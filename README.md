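# psychonet

Psychometric network analysis for binary survey indicators: estimate a
sparse signed association network among dichotomized items, characterize
its structure, and test that structure against null models — the workflow
used to study how two health constructs (for example physical functioning
and social connection in older adults) interlock at the item level.

## What it does

Given a complete-case respondent × indicator table of 0/1 items, per-node
metadata (which construct and which measure type each item belongs to),
categorical covariates, survey weights, and a list of skip-logic pairs,
the package:

1. **Estimates the network (eLasso).** Each node is regressed on all other
   nodes by L1-penalized logistic regression (`glmnet`), with covariates
   entering unpenalized and respondent log-likelihood contributions
   weighted by survey weight. Each nodewise model is selected by the
   extended Bayesian information criterion

   EBIC = −2ℓ + k·ln(n) + 2γ·k·ln(p),

   with γ = 0.25 by default. An edge a–b is kept under the and-rule only
   if both directed coefficients are nonzero; its weight is their mean.
   Skip-logic pairs are excluded from predictor sets so tautological
   associations can never appear.
2. **Characterizes structure.** Newman's categorical assortativity on
   absolute edge mass (by construct and by measure type), strength
   (Σ|w|), normalized weighted betweenness (distances 1/|w|), and
   spin-glass community detection on the signed network by simulated
   annealing.
3. **Tests it.** Configuration-model null networks (degree-preserving
   double-edge swaps with the weight multiset permuted), node-ablation
   tests (drop the node from the *data*, re-estimate, compare construct
   assortativity), survey-weighted bootstrap percentile CIs and one-tailed
   add-one p-values with Bonferroni adjustment, and a γ-stability sweep
   over 0–1 in steps of 0.05.
4. **Simulates its own test bed.** A planted-structure Ising simulator
   (Gibbs sampler in C++) generates datasets with two construct blocks,
   designated bridge couplings, covariate-shifted thresholds,
   deterministic skip logic, and lognormal survey weights, so the entire
   pipeline is verifiable against known ground truth.

## Worked example

```r
library(psychonet)

# a 34-node instrument: 14 physical-functioning indicators (2 objective,
# 12 subjective) and 20 social-connection indicators (9 objective, 11
# subjective), with two planted bridges and three skip-logic pairs
design  <- demo_design()
dataset <- simulate_dataset(design, n = 1500, seed = 1)

config  <- estimation_config(gamma = 0.25, rule = "and")
network <- estimate_network(dataset, config)
network
#> Weighted network: 34 nodes, 55 edges (47 positive, 8 negative)

assortativity_categorical(network, "construct")
#> Assortativity by construct: r = 0.7995
assortativity_categorical(network, "measure")
#> Assortativity by measure: r = -0.048

head(sort(node_betweenness(network), decreasing = TRUE), 3)
#>            feel_isolated incomplete_balance_tests        low_grip_strength
#>                0.3181818                0.2784091                0.2689394

ablate_and_compare(dataset, "incomplete_balance_tests", config)
#> Ablation of 'incomplete_balance_tests': assortativity 0.7995 -> 0.8949
#>   (difference 0.0954)
```

The construct assortativity (0.80) far exceeds the measure assortativity
(−0.05): edges follow the constructs, not the objective/subjective divide.
The two highest-betweenness nodes are the endpoints of a planted bridge
(`feel_isolated`, `incomplete_balance_tests`), and ablating a bridge node
decouples the constructs — assortativity rises — which is exactly how a
bridging indicator should behave.

The same analysis runs end to end from a config file:

```r
run_full_analysis(system.file("extdata", "demo_config.json",
                              package = "psychonet"),
                  out_dir = "report")
```

or from a shell via `Rscript inst/scripts/psychonet.R --config ... --out ...`.

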
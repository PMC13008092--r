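---
title: "Methods: estimating and testing psychometric Ising networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and testing psychometric Ising networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model, the estimators, the null models, and every place where a design
choice had to be made. It states no empirical result that the test suite
and `scripts/acceptance.R` do not themselves compute.

## The model

The analysis treats p binary survey indicators as a pairwise Markov
random field (an Ising model in 0/1 coding):

$$P(x) \propto \exp\Big(\sum_i \tau_i x_i + \sum_{i<j} \Omega_{ij} x_i x_j\Big),
\qquad x \in \{0,1\}^p .$$

The threshold $\tau_i$ is the log-odds of endorsing item i when all other
items are 0; the coupling $\Omega_{ij}$ is the conditional log-odds-ratio
between items i and j given all other items. The estimated network's edge
weights are estimates of $\Omega$: a nonzero weight means a *partial*
association that survives conditioning on every other indicator, which is
what distinguishes this analysis from a correlation matrix.

The conditional distribution of each node given the rest is logistic,

$$\mathrm{logit}\, P(x_i = 1 \mid x_{-i}) = \tau_i + \sum_{j \ne i} \Omega_{ij} x_j,$$

which grounds both the Gibbs sampler and the nodewise estimation.

## Estimation: eLasso

`estimate_network()` regresses each node on all other admissible nodes by
L1-penalized logistic regression over a geometric path of 100 penalty
values from $\lambda_{max}$ (the smallest penalty at which every node
coefficient is zero) down to $0.01\,\lambda_{max}$ (both configurable).
The path is fit by `glmnet`; coordinate-descent tolerance and iteration
caps are glmnet's defaults (relative change $10^{-7}$, $10^5$ updates),
which match standard lasso practice.

Each nodewise model is selected by the extended BIC,
$\mathrm{EBIC} = -2\ell + k \ln n + 2\gamma k \ln p_{cand}$, where $\ell$
is the weighted log-likelihood of the penalized fit, k counts nonzero
*node* coefficients, and $p_{cand}$ is the number of candidate node
predictors. Ties are broken toward the larger penalty (the sparser
model). Three conventions deserve note:

* **Covariates never count toward k.** Categorical covariates are
  expanded to reference-coded indicators and enter every candidate model
  with penalty factor 0, so they are common to all models being compared
  and their dimensionality cancels.
* **The likelihood is the penalized fit's.** EBIC is evaluated on the
  lasso solution itself, not on an unpenalized refit of its support. This
  follows the established eLasso convention. The practical consequence,
  verified by the test suite's exhaustive-subset oracle, is that when a
  non-neighbor is marginally correlated with the target (for example the
  second neighbor along a chain), path selection occasionally keeps one
  extra predictor that a refit-based exhaustive search would drop: the
  strong coefficient is still shrunk at the penalty where the correct
  support appears, and the criterion buys back likelihood by moving
  further down the path. Users who need exact best-subset behavior at
  tiny p should refit manually.
* **$\gamma = 0.25$ by default**, the value at which EBIC-based Ising
  selection is reported to perform consistently well; $\gamma = 0$
  recovers the classical BIC and larger values give sparser networks
  (monotonicity is asserted by a test).

**Symmetrization.** The and-rule keeps edge a–b only when both directed
coefficients are nonzero (the or-rule keeps either); the kept weight is
their mean by default, or the larger-in-magnitude one behind
`weight_combination = "max"`. And-rule support is always a subset of
or-rule support.

**Survey weights.** The sampling design enters as a weighted
log-likelihood with weights normalized to sum to n (so the effective
sample size and BIC scale are unchanged). A post-hoc weighting
alternative was considered and rejected: the weighted likelihood keeps
selection and estimation consistent with each other.

**Skip logic.** Forbidden pairs are removed from each other's predictor
sets before fitting — not zeroed afterwards — so a tautological partner
cannot absorb variance during selection.

**Degenerate inputs.** A constant node raises an error naming the node;
near-separation at tiny penalties is handled by capping coefficients at
|15| with a warning.

## Structural metrics

* **Strength** is $\sum_j |w_{ij}|$. The network is signed but sign
  handling for centralities is not standardized across applied work;
  the absolute-value convention (standard in psychometric networks) is
  the default, with a signed variant behind a flag.
* **Betweenness** uses edge lengths $1/|w|$ — strong associations are
  short — Brandes' algorithm with fractional credit for tied shortest
  paths (via igraph), normalized by $(p-1)(p-2)/2$ so values lie in
  [0, 1]. Tests verify it against exhaustive path enumeration on all
  graphs up to 8 nodes.
* **Assortativity** is Newman's categorical coefficient computed on
  absolute edge-weight mass: with mixing matrix e and marginals a,
  $r = (\sum_g e_{gg} - \sum_g a_g^2)/(1 - \sum_g a_g^2)$. It is 1 when
  all mass stays within categories, negative for disassortative mixing,
  and invariant to global rescaling of the weights.

## Spin-glass communities

`spinglass_partition()` minimizes the signed spin-glass Hamiltonian

$$H = -\sum_{i<j}\big[w^+_{ij} - \gamma^+ p^+_{ij}\big]\,\delta(c_i,c_j)
      + \sum_{i<j}\big[w^-_{ij} - \gamma^- p^-_{ij}\big]\,\delta(c_i,c_j),$$

where $w^\pm$ are the positive/negative parts of the weight matrix and
$p^\pm_{ij} = s^\pm_i s^\pm_j / 2m^\pm$ are configuration-model
expectations per sign layer. Negative edges inside a community are
penalized; this is the package's resolution of negative-edge handling,
which published analyses rarely state. $\gamma^+ = \gamma^- = 1$ by
default.

The optimizer is simulated annealing in C++: Metropolis single-node moves
over at most `max_communities` (default 10) spin states, geometric
cooling from T = 1.0 to 0.01 with factor 0.99 and 50·p moves per
temperature, 10 restarts keeping the best partition, and a final greedy
descent. The all-singleton (H = 0) and one-block partitions are always
evaluated as guards, so the returned H never exceeds either. Connected
components are partitioned separately; labels are canonicalized by
smallest member index, making results comparable across runs; everything
is reproducible under a fixed seed. On networks of ≤ 8 nodes the
annealer's optimum is checked against exhaustive enumeration of all
partitions.

## Null models and ablation

The configuration null preserves each node's degree exactly: the observed
topology is rewired by double-edge swaps (100 attempted swaps per edge;
no self-loops or multi-edges — the reason swaps were chosen over
stub-matching, which must reject or collapse multi-edges on dense nodes),
and the observed multiset of signed weights is then permuted onto the
rewired edges. Null-model weight assignment is rarely specified in
applied work; permuting the observed multiset conserves total absolute
weight by construction. Observed strength and betweenness are compared to the
ensemble mean over (by default) 100 nulls.

Ablation removes a node's column from the *data* and re-estimates the
whole network — re-estimation, not graph surgery — rather than deleting
the vertex from a fixed graph; a test asserts the two genuinely differ.
If ablating a bridge node decouples the two constructs, construct
assortativity rises.

## Bootstrap inference

Each of B replicates resamples n respondents with replacement with
probability proportional to survey weight, then re-estimates the network
and all requested statistics — plus, per replicate, a configuration null
and/or ablated networks for the paired comparisons. Because the
resampling probabilities already carry the design, within-replicate
estimation is unweighted; with uniform weights the scheme reduces exactly
to the ordinary bootstrap. Weighted multinomial resampling was chosen
over Rao–Wu-type rescaling for transparency; the alternative would need
stratum information the data model does not carry.

Confidence intervals are percentile intervals at the Bonferroni-adjusted
level $1 - 0.05/m$ (m is the comparison family size, a required choice);
one-tailed p-values use the add-one estimator
$p = (1 + \#\{\text{replicates contradicting the alternative}\})/(B+1)$,
whose minimum is $1/(B+1)$, then Bonferroni adjustment
$\min(1, m\,p)$. The tested directions follow the substantive
hypotheses: observed centrality *higher* than the null's, original
assortativity *lower* than the ablated network's. B defaults to 10,000
for fidelity runs; the test suite and the packaged demo use B = 200 and
50 nulls, sizes at which every distributional property under test is
already stable.

**Known limitation.** Percentile intervals inherit the penalized
estimator's shrinkage bias: strength estimates at moderate n sit
systematically below their large-n limits, so nominal-95% intervals
undercover asymptotic plug-in values (empirically ~85% for a planted hub
at n = 1000). This is a property of bootstrapping a regularized
estimator, well documented in the psychometric-network literature, not of
the resampling machinery; the paired null/ablation comparisons, which
difference out the shrinkage, are unaffected.

## Sensitivity sweep

`gamma_sweep()` re-estimates the network over γ ∈ {0, 0.05, …, 1} and
reports, against the base network: the assortativity difference, the
fraction of nodes remaining in the same community, and Spearman
correlations of strength and betweenness (all nodes, average-rank ties;
identical vectors count as 1 even when constant). "Same community" is
made well-defined by maximum-weight bipartite matching on the partition
confusion matrix, since raw community labels are arbitrary. Networks that lose every edge at high γ are flagged degenerate with
NA metrics rather than dropped. Edge count is non-increasing along the
grid.

## The synthetic test bed

`planted_design()` + `simulate_dataset()` generate data with known
structure: two construct blocks (the packaged `demo_design()` mirrors a
34-indicator instrument — 14 physical-functioning nodes, 2 objective and
12 subjective; 20 social-connection nodes, 9 objective and 11
subjective), couplings of fixed magnitude placed with density
`within_density` (default 0.3) inside blocks and `between_density`
(default 0.05) across, designated always-present bridge pairs at
`bridge_coupling` ≥ `within_coupling`, a 10% negative-coupling fraction,
thresholds Normal(−1, 0.25) (endorsement is the rarer state, as for
difficulty and loneliness items), categorical covariates that shift
thresholds per level, skip-logic pairs whose child is forced to 0 when
the parent is 1 (mirroring "no children → contact question not asked";
0-coding keeps the complete-case contract and the pair is emitted as
forbidden — an assumption, since surveys differ in how routed-past items
are coded),
and lognormal(0, 0.5²) survey weights normalized to mean 1 (strictly
positive and right-skewed, like real design weights).

Sampling is single-chain Gibbs in C++: 1000 burn-in sweeps, then one
recorded row every 10 sweeps, each row drawn under its own respondent's
covariate-shifted thresholds. Chain output is validated against exact
partition-function enumeration at p ≤ 4.

What the simulator does *not* emulate: real multistage sampling designs
and attrition, missing data (the analysis is complete-case by contract),
item-level measurement error beyond the Ising likelihood, and ordinal
response scales (dichotomization utilities are provided for those, with
the lower-sample-median convention: strictly-below-median → 1, ties to
the non-event class — configurable, since tie policy is rarely reported).
Passing tests therefore demonstrate correctness of the machinery on data
that satisfy the model, not robustness to model violation.

## Problem sizes used in routine checks

The shipped tests run the full pipeline at p = 20–34 and n = 1500–2000,
recovery benchmarks over 20 seeds, exhaustive oracles at p ≤ 8, bootstrap
checks at B = 200, and the Gibbs-vs-enumeration check at n = 50,000 —
sizes chosen so each check's Monte-Carlo error is far below the margins
being asserted while a complete run stays in the minutes range on a
single CPU.
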
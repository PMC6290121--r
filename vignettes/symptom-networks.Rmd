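---
title: "Estimating and comparing developmental symptom networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating and comparing developmental symptom networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`symptomnets` analyzes panels of binary symptom indicators — for example,
parent-reported depression and anxiety items scored present/absent at several
ages — as networks of pairwise conditional associations. The generative model
is the Ising distribution on $x \in \{0,1\}^p$:

$$P(x) \propto \exp\Big(\sum_j \tau_j x_j + \sum_{j<k} \omega_{jk} x_j x_k\Big),$$

where $\tau_j$ is a threshold on the log-odds scale (how readily symptom $j$
is endorsed on its own) and $\omega_{jk}$ is a symmetric pairwise interaction
(an *edge*: the conditional association between symptoms $j$ and $k$ given
all others). The $\{0,1\}$ coding, rather than $\{-1,+1\}$, is deliberate: it
makes the full conditional of each node a logistic regression on the other
nodes with slopes equal to the $\omega_{jk}$, which is the identity the
estimator relies on.

## Estimation: eLasso

`estimate_network()` implements the eLasso procedure: each item is regressed
on all other items with an $\ell_1$ penalty, the penalty is chosen per node
by minimizing the extended Bayesian information criterion

$$\mathrm{EBIC}_\gamma = -2\ell + k\log n + 2\gamma k \log(p-1),$$

with $k$ the number of nonzero slopes, and the two directed coefficients per
pair are combined into one undirected edge. Estimated edges can be read
analogously to regularized partial correlations.

Tunable parameters, defaults, and why:

* **`gamma = 0.25`** — the customary EBIC weight for network estimation from
  binary data; `gamma = 0` reduces to the BIC and selects denser networks.
  Exposed because the cited methodology leaves it to the user.
* **`rule = "AND"`** — an edge is kept only when both nodewise regressions
  select it; its weight is the arithmetic mean of the two slopes. The `"OR"`
  rule keeps an edge when either regression selects it (still averaging,
  counting the unselected slope as zero). AND is the conservative default.
* **path of 100 penalties, `lambda_ratio = 0.01`** — the conventional lasso
  path: the first value is the smallest penalty with an all-zero solution
  ($\lambda_{max} = \max_k |\sum_i x_{ik}(y_i-\bar y)|/n$), log-spaced down to
  $0.01\,\lambda_{max}$.
* **optimizer** — cyclic coordinate descent on a local quadratic
  approximation of the logistic loss, tolerance $10^{-6}$ on the largest
  coefficient change, at most $10^4$ sweeps, coefficients clamped to
  $|\beta| \le 20$. The clamp is a guard against perfect separation, which
  rare items (prevalence around 1%) can produce at small penalties; a warning
  reports when it binds. Because predictors are binary, duplicate response
  patterns are collapsed to weighted counts before fitting, which changes
  nothing statistically and much runtime-wise.

Items with zero variance cannot be regressed on; they are retained in the
network as isolated nodes (all incident edges zero) with a warning, matching
the practice of keeping rare items in the panel.

Two degenerate behaviors worth knowing: exact duplicate columns split one
effect between them in an arbitrary (penalty-invariant-total) way, and ties
in EBIC along the path resolve to the sparser solution.

## Community structure: walktrap and modularity

Whether depression and anxiety items form separate clusters is tested
empirically, not visually. `walktrap()` runs short random walks on the
estimated network: with transition matrix $P$ (row-normalized absolute
weights) and walk length $t$, nodes are compared through
$r_{ij} = \sqrt{\sum_k (P^t_{ik} - P^t_{jk})^2 / s_k}$, where $s_k$ is node
strength. Communities are merged agglomeratively, each step choosing the
adjacent pair whose merger least increases the mean squared walk distance
(a Ward-style criterion), and the final partition is the cut of the merge
sequence with maximal modularity

$$Q = \frac{1}{2m}\sum_{ij}\Big(A_{ij} - \frac{s_i s_j}{2m}\Big)\,
\delta(c_i, c_j), \qquad A = |\omega|.$$

Design choices where the method leaves room:

* walk length `t = 4`, the customary walktrap setting;
* ties in the best-$Q$ cut resolve toward fewer communities (parsimony);
* negative edges enter as absolute values with a warning (random walks need
  nonnegative weights; estimated symptom networks here are typically
  all-positive);
* isolated nodes stay singleton communities and take no part in the walk;
* the implementation is fully deterministic — no random restarts.

$Q > 0.3$ is read, conventionally, as nonrandom community structure
(`interpret_q()`, threshold exposed). Although practitioners often describe
$Q$ as ranging from 0 to 1, the index is negative for partitions worse than
chance (the all-singleton cut of two disconnected triangles scores $-1/6$);
the standard formula is used as is. Note also that *sparse* networks of any
provenance tend to score high $Q$: near the detection limit, an estimate
that keeps only a few scattered strong edges can appear modular even when
the generating model has no block structure at all. $Q$ answers "are the
detected edges arranged in blocks", not "is the generator blocky".

Walktrap is a heuristic: on well-separated fixtures it attains the exhaustive
best-modularity partition (the test suite verifies this against a
Bell-enumeration oracle at $p \le 6$), but equality is not guaranteed in
general, only $Q \le Q_{\mathrm{opt}}$.

A combinatorial caveat for unbalanced panels: with a 12 + 6 item split and
roughly equal edge weights, even the *perfectly* recovered two-block
partition scores only $Q = \frac{66}{81} - (\frac{66}{81})^2 +
\frac{15}{81} - (\frac{15}{81})^2 \approx 0.301$ — right on the conventional
threshold. A near-0.3 value on an 18-item panel of 12 + 6 items is therefore
compatible with *clean* diagnostic separation; the $Q > 0.3$ reading is
sharp only for balanced blocks (where clean separation scores about 0.5).
The validation suite keeps the two questions apart: exact block recovery is
demonstrated on the 12 + 6 geometry, the $Q$ threshold on balanced blocks.

## Comparing waves: permutation test of connectivity

`nct()` tests whether two waves differ in overall connectivity (global
strength $S = \sum_{i<j}|\omega_{ij}|$) and in individual edges. Both
networks are estimated, the absolute differences computed, and cases are
repeatedly swapped between groups with full re-estimation per swap; the
p-value is the proportion of permuted statistics at least as large as the
observed one, computed as $(1+\#\{\cdot\ge\mathrm{obs}\})/(1+B)$ so it is
never zero. Per-edge p-values are Holm-adjusted.

Two swap schemes are first-class. `"independent"` reshuffles the pooled rows
into two groups of the original sizes — the classical two-sample scheme.
`"paired"` is the default for longitudinal waves on the same children: each
subject's two rows are swapped with probability $1/2$, respecting the
repeated-measures dependence. With identical paired panels the permutation
distribution is degenerate at zero and $p = 1$ exactly. The default of 1,000
permutations is the fidelity setting; desk-scale analyses and the test suite
use 200 or fewer, which only coarsens the p-value grid. Re-estimation inside
permutations reuses the exact estimation configuration of the observed fit,
so the whole pipeline is exchangeable under the null.

## Reliability: bootstrap and case-dropping stability

`bootstrap_edges()` gives percentile confidence intervals for every edge from
case resampling; `edge_difference_test()` declares two edges different when
the bootstrap interval of their difference excludes zero (unadjusted for
multiplicity, as is common practice — interpret across many pairs with
caution). `cs_coefficient()` computes the correlation-stability coefficient
of a centrality index: the largest proportion of cases that can be dropped
while the subsample centralities still correlate at least 0.7 (Spearman; a
rank-stability question calls for a rank correlation) with the full-sample
values in at least 95% of subsamples. The drop grid defaults to
$\{0.1,\dots,0.7\}$; the statistic is forced monotone by requiring every
smaller drop fraction to pass as well. Below about 0.25 the ranking should
not be interpreted; 0.5 and above is conventionally stable.

## Centrality

Strength $s_i = \sum_j |\omega_{ij}|$, closeness (inverse total
shortest-path distance with edge lengths $1/|\omega_{ij}|$ — strong edges
are short), and betweenness (fractional shortest-path counts) are computed
per wave and reported raw and as z-scores over the $p$ nodes (population SD;
switchable to sample SD). Constant columns z-score to zero with a warning.
In disconnected networks closeness sums over the reachable set only and the
result is flagged; isolated nodes score zero. Because only z-scores are
compared across waves, any size normalization constant would cancel.

## The synthetic generator: what it emulates and what it does not

Access-restricted cohort data cannot ship with a package, so every stage is
exercised against a generator whose conditions mirror the emulated study: 18
binary items (12 tagged depression, 6 anxiety), $N = 1{,}147$ subjects, 7
waves labelled ages 5–14, marginal prevalences in the 1–40% range of the
published frequency table (`cbcl_prevalences`), planted two-block structure
with bridge edges, and a per-wave connectivity gradient (true global strength
exactly proportional to the wave scale, by linearity of $\sum|\omega|$).

Generator defaults: block sizes 12 + 6, within-block edge density 0.35 at
weight 0.9, between-block density 0.15 at weight 0.6, age-5 prevalence
targets. Sampling is single-site Gibbs (burn-in 1,000 sweeps, thinning 10 —
adequate mixing for $|\omega| \le 2$ at $p = 18$, verified against exact
enumeration at small $p$, where the sampler must reproduce the enumerated
distribution to total-variation 0.01 at $n = 10^5$). Threshold calibration
to target prevalences is a damped fixed-point iteration
$\tau_j \leftarrow \tau_j + \kappa \log\frac{t_j(1-m_j)}{m_j(1-t_j)}$
($\kappa = 0.7$) with exact marginals by enumeration for $p \le 14$ and
Monte-Carlo marginals beyond (standard error at most $0.5/\sqrt{n_{mc}}$,
tolerance floored at twice that). Calibration adjusts thresholds only, never
interactions.

One physical constraint shapes what the generator can emulate. With
all-positive interactions the model is ferromagnetic: once the spectral
radius of $\mathrm{diag}(m_j(1-m_j))\,\Omega$ approaches 1, the distribution
bifurcates into "few symptoms" and "many symptoms" modes, marginals respond
discontinuously to thresholds, and calibration to low prevalences becomes
impossible. A generative Ising model therefore cannot be simultaneously
dense, strongly weighted, and calibrated to 1–40% prevalences — which is why
empirical networks whose *estimated* density reaches 65–78% at this sample
size cannot be reproduced by any well-posed all-positive Ising truth. The
emulation scenario stays in the subcritical regime; consequences for
validation are below.

Real data differ from this generator in ways that matter for extrapolation:
real symptom panels are not exactly Ising (informant effects, item overlap,
latent severity gradients), item marginals drift with age in correlated
ways, and missingness is handled upstream (this package is strictly
complete-case; the emulated study's EM-with-bootstrapping imputation is out
of scope). Passing tests certify the machinery — estimation consistency,
test calibration, determinism — not that any particular empirical network is
correctly specified.

## Validation regimes and problem sizes

Recovery of a planted truth is assessed where recovery is statistically
possible. Edges incident to items of 1–3% prevalence are information-limited
at $n = 1{,}147$ (about ten endorsements carry all the signal), so the
recovery benchmark uses the moderate band of the published prevalence range
(targets spread over 0.10–0.40) with the default block densities and weights
0.7 / 0.45 — the strongest weights that keep every random support draw
subcritical at those prevalences — where the truth-estimate correlation over
all 153 pairs is expected around 0.8.
Under the full age-5 profile, with eight items below 8% prevalence, the same
correlation drops to roughly 0.5 — a property of the information in the
data, not of the estimator, and the reason the emulation scenario and the
recovery benchmark are distinct. The test suite also checks specificity
(independence data yield almost no false edges) and EBIC-oracle agreement at
$p \le 3$.

Simulation sizes used by the tests and the acceptance script were chosen as
desk-scale versions of the emulated study: null calibration of the
permutation test with 200 permutations × 200 replicates at $n = 300$,
$p = 8$; power against ×1.5 connectivity scaling at $n = 1{,}000$, $p = 8$;
recovery and modularity at the full $n = 1{,}147$, $p = 18$; bootstrap and
CS diagnostics with reduced replicate counts. Fidelity settings (1,000
permutations, 1,000 bootstrap replicates) remain the documented defaults.

## Numerical and reproducibility choices

* All randomness flows from R's RNG; every stochastic function takes a
  `seed` argument and scenario generation derives per-wave seeds from the
  single scenario seed, so a whole multi-wave study is reproducible from one
  integer.
* `run_analysis()` reports carry a config hash, seed and package version —
  deliberately no timestamps — so `write_report()` output is byte-identical
  across re-runs of the same analysis.
* Edge lists are written at 15 significant digits and GraphML via igraph at
  full double precision; both round-trip below $10^{-9}$.
* Degenerate inputs: empty networks have undefined modularity (error) and
  trivial singleton partitions; constant centrality vectors z-score to zero
  with a warning; asymmetric weight matrices are rejected everywhere.

## Known limitations

Only binary data and the Ising parameterization are supported (no ordinal or
Gaussian variants); community detection offers walktrap only; the comparison
test covers global strength and individual edges, not centrality
differences; and CS coefficients from a single cohort-sized sample are
expected to be low and should be read qualitatively. Temporal (lag-1)
network models from intensive longitudinal data are outside the package's
scope.
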
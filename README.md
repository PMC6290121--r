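# symptomnets

Developmental symptom-network analysis with Ising models.

## What this is for

Childhood depression and anxiety co-occur so tightly that whether they are
distinct constructs at all — and whether they differentiate or entangle
further as children grow — is an open question. Instead of aggregate scale
scores, `symptomnets` works at the symptom level: binary (present/absent)
symptom indicators at one or more measurement waves are modeled as a
network, nodes being symptoms and edges regularized conditional
associations. The package is aimed at researchers running longitudinal
item-level psychopathology analyses, and at methodologists who need a fully
simulatable version of that pipeline.

The workflow, per wave and across waves:

1. **Estimation** — the Ising model
   `P(x) ∝ exp(Σ τ_j x_j + Σ_{j<k} ω_jk x_j x_k)` fitted by *eLasso*:
   nodewise L1-penalized logistic regression, per-node penalty chosen by the
   extended BIC (`EBIC_γ = −2ℓ + k log n + 2γ k log(p−1)`), directed
   coefficients combined under the AND rule.
2. **Clustering** — walktrap community detection and the modularity index
   `Q = (1/2m) Σ_ij (A_ij − s_i s_j / 2m) δ(c_i, c_j)`, with `Q > 0.3` read
   as nonrandom structure: an empirical test of whether diagnostic
   boundaries are visible in the data.
3. **Comparison** — permutation tests (paired or independent swapping, full
   re-estimation per permutation) of global-strength invariance
   `S = Σ_{i<j} |ω_ij|` and of individual edges, Holm-adjusted.
4. **Reliability** — bootstrap edge CIs, bootstrapped edge-difference tests,
   and case-dropping correlation-stability (CS) coefficients for centrality.
5. **Centrality** — strength, closeness, betweenness (z-standardized) per
   wave, for symptom-importance trajectories.

A synthetic-data module (exact enumeration for `p ≤ 14`, Gibbs sampling
beyond, planted two-block structure, threshold calibration to target
prevalences, per-wave connectivity scaling) makes every stage testable
without access to restricted cohort data.

## Worked example

Simulate a two-wave developmental scenario (6 items for brevity; the
package-default scenario is the full 18-item, 7-wave emulation) and run the
whole pipeline:

```r
library(symptomnets)

targets <- setNames(seq(0.15, 0.35, length.out = 6), paste0("it", 1:6))
spec <- scenario_spec(p1 = 4, p2 = 2, density_within = 0.9,
                      density_between = 0.3, w_within = 1.1, w_between = 0.5,
                      prevalence_targets = targets,
                      wave_scales = c(1, 1.3), wave_labels = c("5", "14"),
                      seed = 51)
sc  <- developmental_scenario(spec, n = 150, burnin = 300, thin = 3)
rep <- run_analysis(sc$panel, pipeline_config(n_perm = 200, seed = 3))
rep
```

```
<run_report> 2 wave(s), seed 3
  wave q interpretation global_strength nonzero_edges possible_edges
1    5 0         random           3.515             5             15
2   14 0         random          12.729             9             15
wave comparisons (global strength):
  5 vs 14: |diff| = 9.215, p = 0.004975
```

Reading this: each wave's estimated network retains 5–9 of the 15 possible
edges; walktrap finds no better-than-chance clustering (`Q = 0`: the best
cut is a single community — the two small planted blocks are bridged enough
to blur at this size); and the paired permutation test flags the wave-2
connectivity increase (the generator scaled true connectivity by 1.3, and
lasso selection amplifies the estimated contrast) at `p ≈ 0.005` with 200
permutations.
Individual pieces are available as `estimate_network()`, `walktrap()`,
`modularity_q()`, `nct()`, `bootstrap_edges()`, `cs_coefficient()`,
`centrality_table()`, and `write_report()` exports every artifact
(edge lists, memberships, centrality long table, Q-by-wave,
global-strength trajectory, comparisons, layout) as deterministic CSV/JSON.

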
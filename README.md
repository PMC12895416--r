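# rptraj

Random-projection compression and kinetic analysis of molecular-dynamics
trajectory features.

## What it does

High-dimensional MD featurizations (all backbone contacts, all aligned
positions, ...) are expensive and unstable inputs for kinetic analyses,
even though the slow conformational dynamics are low-dimensional. `rptraj`
compresses a feature matrix `X` (`T` frames × `N` features) with
**untrained** random feed-forward networks and provides the downstream
machinery to check, quantitatively, that the compressed space still
resolves the slow processes:

* **Featurization** from PDB topologies: pair distances, exponential
  contacts `c_ij = exp(-d_ij/d0)`, backbone dihedrals (φ/ψ, optionally
  with per-angle branch-cut shifting), and Kabsch-aligned flattened
  positions.
* **Random compression**: `n` independent multilayer ELU networks with
  random depth (5–20) and widths (2–`N`), Xavier-uniform weights, uniform
  biases, min–max standardized outputs — or a single `n`-output network,
  or the classical linear Gaussian random map `x = X Mᵀ`. A one-layer
  zero-bias network reproduces the linear map exactly.
* **TICA** (generalized eigenproblem `C0τ v = λ C00 v`) with a PCA
  baseline, implied timescales `t = -τ/ln λ`.
* **Markov state models**: k-means(++) state assignment on TICA
  components, symmetrized transition counts, implied timescales versus
  lag with the assignment held fixed, cluster populations, mean fraction
  of native contacts per cluster, and grouping of clusters across trials
  by contact fraction.
* **A synthetic generator** — hidden reversible Markov chains observed
  through a frozen nonlinear embedding with noise, plus a toy folded /
  unfolded backbone — with closed-form relaxation timescales, so every
  claim is testable without external trajectory data.

## Worked example

Two-state metastable dynamics with switching probability 0.01 per step has
an analytic slowest relaxation timescale `t2 = -1/ln(0.98) ≈ 49.50` steps.
Embed it in 50 noisy nonlinear features, compress to 10 random functions,
and re-estimate the timescale:

```r
library(rptraj)

model  <- two_state_model()                  # lambda_2 = 0.98
analytic_timescales(model)
#> [1] 49.49832

states <- simulate_chain(model, 2e5, seed = 1)
feats  <- embed_states(states, embedding_spec(2, 50, warp_seed = 1), seed = 1)

comp <- compress(feats, compression_config(10, "multi_net", seed = 1))
tm   <- fit_tica(estimate_covariances(comp$values, 10))
asg  <- assign_states(tica_project(tm, comp$values, 1), 2, seed = 1)
implied_timescale(estimate_msm(asg, 10)$eigenvalues[2], 10)
#> [1] 49.42417
```

The ten random functions preserve the slow process: the recovered
timescale (49.42 steps) is within 0.2% of the analytic value, and — as the
variational principle requires — does not exceed it beyond stochastic
error. `run_trials()` repeats this over many fresh random compressions and
reports mean ± SD per relaxation process; `run_pipeline()` persists every
stage (with per-stage child seeds and a manifest) for a single-command
reproducible run, also available from the shell via `inst/cli/rptraj`.

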
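---
title: "Random nonlinear compression of trajectory features: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random nonlinear compression of trajectory features: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rptraj)
```

## The problem

Molecular-dynamics trajectories of folding proteins are routinely featurized
into thousands of coordinates — all pairwise backbone contacts, all aligned
atom positions — even though the slow conformational kinetics live on a
manifold of far lower dimension. Kinetic analysis tools (TICA, Markov state
models, neural state decompositions) become expensive, and in repeated trials
unstable, when fed such feature sets. `rptraj` implements a pragmatic
alternative: compress the feature space with *untrained* random
feed-forward networks before any kinetic analysis, and verify on synthetic
data with analytically known relaxation times that the compression retains
the slow processes.

## The compression model

Let $X$ be the feature matrix with $N$ features observed over $T$ frames
(stored frame-major, $T \times N$ — the transpose of the column-per-frame
convention common in the kinetics literature; frame-major matches streaming
I/O and R's BLAS layout, and every function in the package documents it).

The classical *linear random mapping* is $x = XM^\top$ with
$M \in \mathbb{R}^{n\times N}$ a random matrix with mean-free entries of
variance $1/n$. For sufficiently large $n$ it preserves all pairwise
distances with bounded relative distortion (Johnson–Lindenstrauss), which
the acceptance suite checks directly at $N = 1000$, $n = 300$.

The nonlinear variant pushes $X$ through an untrained multilayer
perceptron. One random function $g^{(h)}$ with $h$ hidden layers is

$$g^{(0)} = W^{(0)} X + B^{(0)}, \qquad
  g^{(i)} = \phi\!\left(W^{(i)} g^{(i-1)} + B^{(i)}\right)\ (1 \le i < h),
  \qquad g^{(h)} = W^{(h)} g^{(h-1)} + B^{(h)},$$

where $\phi$ is the ELU activation
($\phi(v)=v$ for $v \ge 0$, $\alpha(e^v-1)$ otherwise, $\alpha = 1$ by
default). The input map and the output map are affine without activation;
with $h = 1$ there is no nonlinearity anywhere and the network is exactly
the linear random mapping — an identity the test suite asserts to machine
precision.

An $n$-dimensional compressed space is built either from $n$ independent
single-output networks (`multi_net`, the default) or from one network with
$n$ output neurons (`single_net`). Multi-network ensembles tend to produce
less mutually correlated functions, which the package quantifies with the
mean absolute off-diagonal correlation (`feature_correlations()`) and tests
as a seed-majority property.

Randomness is structured:

* **architecture** — depth uniform on $[5, 20]$ hidden layers and each
  hidden width uniform on $[2, N]$ by default (both ranges configurable);
* **weights** — Xavier-uniform, entries on
  $[\pm\sqrt{6/(\mathrm{fan_{in}}+\mathrm{fan_{out}})}]$, which keeps layer
  output variance comparable across depths (the uniform Xavier variant was
  chosen as the most common convention; the bound is documented and
  asserted in tests);
* **biases** — uniform on $[-1, 1]$ by default. No canonical support
  exists for bias initialization in untrained networks, so the range is a
  configurable parameter rather than a constant;
* **seeds** — a master seed spawns one child seed per random function
  (`derive_seeds()`), all recorded in the output, so any compressed space
  is bit-reproducible from one integer.

Each output function is min–max standardized to $[0, 1]$ over the full
supplied dataset in one pass. A constant (degenerate) function carries no
information, so it is flagged and resampled with a fresh child seed, up to
10 attempts. Applying a fitted normalization to *new* frames can exceed
$[0, 1]$; the package does not clamp, and documents this.

## Judging compression: TICA, MSMs, and native contacts

TICA solves $C_{0\tau} v = \lambda C_{00} v$ for the mean-free features,
where $C_{00}$ is the instantaneous covariance and $C_{0\tau}$ the
time-lagged covariance at lag $\tau$, symmetrized as $(C + C^\top)/2$.
Estimation pools lagged pairs across trajectories without straddling
boundaries and uses the symmetric head/tail mean. Whitening uses an
eigenvalue floor $\varepsilon = 10^{-6}$ relative to the largest $C_{00}$
eigenvalue; directions below the floor are discarded as rank-deficient
(duplicated features are handled this way, and a test pins the behaviour).
The reversible-weighted estimator and Koopman reweighting are out of scope.
Each eigenvalue maps to an implied timescale $t = -\tau / \ln\lambda$;
$\lambda \ge 1$ is reported as `Inf`, $\lambda \le 0$ as `NA`.

State decomposition uses k-means (with k-means++ seeding, Lloyd iterations)
on the leading TICA components, with labels canonicalized by descending
population so that clusters are comparable across independent trials.
This TICA + k-means + MSM stack deliberately stands in for trained
soft-clustering networks: every downstream quantity consumes only a
per-frame label vector, so externally produced assignments plug in
unchanged (`estimate_msm()` accepts plain integer vectors).

MSMs are estimated by sliding-window transition counts at lag $\tau$,
symmetrized (detailed balance enforced, spectrum real in $[-1,1]$) and
row-normalized. `timescales_vs_lag()` varies the counting lag while keeping
the assignment fixed — flat curves indicate Markovian states. By the
variational principle, timescales estimated from any state decomposition
underestimate the true relaxation times, so estimates above the analytic
truth beyond stochastic error indicate a defect; the acceptance suite
checks this direction explicitly.

Folding states are characterized by the fraction of native contacts $Q$.
The native set is all heavy-atom pairs at residue separation $\ge 3$
closer than 4.5 Å in the reference structure; a contact is *formed* in a
frame when its distance is below 1.2 × its native distance (a hard count).
Soft switching functions are a known alternative; the hard count with a
configurable margin was chosen for transparency, and both cutoff and margin
are parameters. Cluster summaries report per-cluster population and mean
$Q$, and `group_by_contact_fraction()` bins clusters across trials by mean
$Q$ (a value exactly on a boundary joins the higher-$Q$ group).

## The synthetic generator

All quantitative claims are validated against a generator whose ground
truth is closed-form:

* **Hidden kinetics** — a reversible K-state Markov chain; analytic
  timescales are $-\Delta t/\ln \lambda_i$ from the transition-matrix
  spectrum. The two-state preset uses switching probability 0.01 per step
  ($\lambda_2 = 0.98$, $t_2 = -1/\ln 0.98 \approx 49.5$ steps). The
  four-state preset is a nearest-neighbour chain with a slow middle
  bottleneck giving timescales of roughly 500, 60 and 20 steps — a
  folded/intermediate/unfolded-like hierarchy. Only reversible matrices
  are accepted, matching equilibrium MD.
* **Observation** — state $k$ sits at anchor $4\,e_k$ in a K-dimensional
  latent space (anchor separation $4\sqrt2$); frames add within-state
  latent jitter (SD 0.25, i.i.d. per frame so it carries no slow
  dynamics), pass through a *frozen* random shallow ELU network with a
  linear skip term into $N$ dimensions, and receive i.i.d. observation
  noise (SD 0.25). The warp reuses the compressor machinery under its own
  seed; the linear skip keeps distinct anchors separated in expectation.
  These defaults model well-separated metastable basins — the regime of
  two-state folders — and were fixed once from the requirement that plain
  TICA on the uncompressed embedding recovers $t_2$ within 10%, which is
  the generator's own fidelity contract in the test suite.
* **Toy protein** — an N/CA/C backbone whose folded conformation is a
  tight helical coil (native contacts at residue separation 3–4) and whose
  unfolded conformation is an extended chain; frames interpolate by hidden
  state. It supplies geometry for the native-contact tests and reproduces
  the pair-count accounting (39 residues → 117 backbone atoms → 6786
  pairs).

What the generator does *not* emulate: anharmonic within-basin dynamics,
hierarchies of fast sub-basin relaxations, non-Markovian memory from
projected degrees of freedom, and experimentally realistic contact maps.
Passing tests therefore demonstrate that the compression machinery
preserves *cleanly separated* slow processes, not that it resolves subtle
intermediates in real folding data.

## Benchmark problem sizes and numerical choices

The standard benchmark runs the full pipeline — embed ($N = 50$,
$T = 2\times10^5$ frames) → multi-net compress ($n = 10$) → TICA (lag 10)
→ 2-state k-means → MSM (lag 10) — over 25 master seeds, and recovers the
analytic $t_2$ within 10% in the large majority of seeds. The
under-compression comparison ($n = 2$ versus $n = 30$, slowest eigenvalue)
uses $T = 10^5$ and 9 seeds, and the decorrelation comparison uses
$T = 5\times10^3$ and 20 seeds; these sizes give stable majorities while
keeping a full test run fast on one CPU. The forward pass is implemented
in C++ (RcppArmadillo) because the per-layer affine+ELU update on
frame-major matrices is memory-bound in pure R.

Other numerical choices: covariance matrices are always explicitly
symmetrized before `eigen(symmetric = TRUE)`; k-means ties and label order
are resolved by descending population; `minmax_normalize()` treats a range
below $10^{-12}$ relative to the data magnitude as degenerate; dihedral
angles use the atan2 formulation (IUPAC sign) and the optional "shifted"
convention relocates each angle's branch cut to the centre of the sparsest
bin of a 36-bin circular histogram, removing wrap artifacts for basins
straddling $\pm\pi$. Backbone means atoms named N, CA, C — excluding the
carbonyl O — which is the convention under which a 39-residue chain has
exactly $\binom{117}{2} = 6786$ backbone pairs. Residue and atom indices
are 1-based throughout.

## Worked example

```{r example, eval = FALSE}
model <- two_state_model()            # lambda_2 = 0.98
analytic_timescales(model)            # 49.498 steps

states <- simulate_chain(model, 2e5, seed = 1)
feats <- embed_states(states, embedding_spec(2, 50, warp_seed = 1), seed = 1)

comp <- compress(feats, compression_config(10, "multi_net", seed = 1))
tm <- fit_tica(estimate_covariances(comp$values, 10))
asg <- assign_states(tica_project(tm, comp$values, 1), 2, seed = 1)
implied_timescale(estimate_msm(asg, 10)$eigenvalues[2], 10)
```

## Known limitations

* Deep untrained networks occasionally produce near-constant functions;
  the resample-with-fresh-seed policy caps at 10 retries and then errors.
* Min–max statistics are global, not streaming; very long trajectories
  must fit in memory.
* The k-means surrogate gives hard state assignments; fuzzy membership
  (and with it VAMP-style scores) is outside the package's scope, though
  external assignments can be supplied.
* No trajectory-format readers beyond delimited text and Feather tables;
  topology comes from PDB ATOM records only.
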
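# Synthetic metastable dynamics with analytically known relaxation
# timescales: a hidden K-state Markov jump process observed through a
# frozen nonlinear embedding into many noisy dimensions, plus a toy
# "protein" backbone generator with distinct folded/unfolded geometries.
# Every downstream claim of the package (timescale recovery, compression
# fidelity, native-contact summaries) is testable against this generator's
# closed-form ground truth, with no external trajectory data.

#' Define a metastable K-state model
#'
#' @param transition K x K row-stochastic transition matrix per step. Must
#'   be irreducible and reversible (the generator is restricted to
#'   detailed-balance dynamics so analytic timescales are real, matching
#'   equilibrium MD).
#' @param step_time physical time per step in ns (default 1).
#' @return object of class `metastable_model`: `transition`, `K`,
#'   `step_time`, `stationary`, `eigenvalues` (descending),
#'   `timescales` (analytic, for processes i >= 2).
#' @export
metastable_model <- function(transition, step_time = 1) {
  transition <- as.matrix(transition)
  K <- nrow(transition)
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-10)) {
    stop_rptraj("transition matrix must be row-stochastic",
                "rptraj_invalid_model")
  }
  # stationary distribution: left eigenvector for eigenvalue 1
  ev <- eigen(t(transition))
  i1 <- which.min(abs(ev$values - 1))
  pi_vec <- Re(ev$vectors[, i1])
  pi_vec <- pi_vec / sum(pi_vec)
  if (any(pi_vec <= 1e-12)) {
    stop_rptraj("transition matrix must be irreducible",
                "rptraj_invalid_model")
  }
  flux <- pi_vec * transition
  if (max(abs(flux - t(flux))) > 1e-8) {
    stop_rptraj("transition matrix must satisfy detailed balance",
                "rptraj_invalid_model")
  }
  # reversible: symmetrize with pi^(1/2) for a real spectrum
  s <- sqrt(pi_vec)
  sym <- diag(s) %*% transition %*% diag(1 / s)
  lambda <- sort(eigen((sym + t(sym)) / 2, symmetric = TRUE,
                       only.values = TRUE)$values, decreasing = TRUE)
  structure(
    list(
      transition = transition, K = K, step_time = step_time,
      stationary = pi_vec, eigenvalues = lambda,
      timescales = implied_timescale(lambda[-1L], step_time)
    ),
    class = "metastable_model"
  )
}

#' @export
print.metastable_model <- function(x, ...) {
  cat(sprintf("metastable_model: %d states, step %.3g ns\n", x$K, x$step_time))
  cat("analytic timescales (ns):",
      paste(sprintf("%.4g", x$timescales), collapse = ", "), "\n")
  invisible(x)
}

#' Two-state metastable preset
#'
#' Symmetric two-state chain with switching probability `p` per step, so
#' lambda_2 = 1 - 2p and the single relaxation timescale is
#' `-step / log(1 - 2p)`. The default `p = 0.01` gives lambda_2 = 0.98,
#' t_2 = -1/log(0.98) ~ 49.5 steps.
#'
#' @param p per-step switching probability (default 0.01).
#' @param step_time ns per step.
#' @return a [metastable_model()].
#' @export
two_state_model <- function(p = 0.01, step_time = 1) {
  stopifnot(p > 0, p < 0.5)
  metastable_model(matrix(c(1 - p, p, p, 1 - p), 2L, 2L), step_time)
}

#' Four-state hierarchical preset
#'
#' Symmetric nearest-neighbour chain 1-2-3-4 with a slow bottleneck in the
#' middle and progressively faster exchange at the ends, giving a timescale
#' hierarchy of roughly (500, 60, 20) steps — a folded / intermediate /
#' unfolded-like separation of processes. Exact values come from
#' [analytic_timescales()].
#'
#' @param rates per-step hop probabilities `c(p12, p23, p34)`.
#' @param step_time ns per step.
#' @return a [metastable_model()].
#' @export
four_state_model <- function(rates = c(0.008, 0.0022, 0.025), step_time = 1) {
  stopifnot(length(rates) == 3L, all(rates > 0), sum(rates) < 0.5)
  a <- rates[1L]; b <- rates[2L]; c_ <- rates[3L]
  transition <- rbind(
    c(1 - a, a, 0, 0),
    c(a, 1 - a - b, b, 0),
    c(0, b, 1 - b - c_, c_),
    c(0, 0, c_, 1 - c_)
  )
  metastable_model(transition, step_time)
}

#' Simulate the hidden Markov chain
#'
#' @param model a [metastable_model()], or a plain row-stochastic
#'   transition matrix (not necessarily irreducible; the initial state is
#'   then drawn uniformly instead of from the stationary distribution).
#' @param n_steps trajectory length.
#' @param seed RNG seed; the initial state is drawn from the stationary
#'   distribution.
#' @return integer vector of states in 1..K.
#' @export
simulate_chain <- function(model, n_steps, seed = 1L) {
  stopifnot(n_steps >= 1L)
  if (is.matrix(model)) {
    if (any(model < 0) || any(abs(rowSums(model) - 1) > 1e-10)) {
      stop_rptraj("transition matrix must be row-stochastic",
                  "rptraj_invalid_model")
    }
    model <- list(transition = model, K = nrow(model),
                  stationary = rep(1 / nrow(model), nrow(model)))
  }
  cum <- t(apply(model$transition, 1L, cumsum))
  with_seed(seed, {
    u <- stats::runif(n_steps)
    states <- integer(n_steps)
    states[1L] <- sample.int(model$K, 1L, prob = model$stationary)
    if (n_steps > 1L) {
      for (t in 2L:n_steps) {
        states[t] <- findInterval(u[t], cum[states[t - 1L], ]) + 1L
      }
    }
    states
  })
}

#' Analytic implied timescales of a metastable model
#'
#' Closed-form ground truth `t_i = -step_time / log(lambda_i)` for the
#' nontrivial eigenvalues (i >= 2, descending) of the one-step transition
#' matrix.
#'
#' @param model a [metastable_model()].
#' @return numeric vector of length K - 1.
#' @export
analytic_timescales <- function(model) {
  model$timescales
}

#' Observation model: embed hidden states in a noisy feature space
#'
#' @param K number of hidden states.
#' @param n_features observed dimension N (>= K).
#' @param anchor_scale scale of the per-state latent anchors; state k sits
#'   at `anchor_scale * e_k` in a K-dimensional latent space, so every
#'   anchor pair is `anchor_scale * sqrt(2)` apart (default 4: basins well
#'   separated relative to the jitter, the regime of distinct folded /
#'   unfolded conformations).
#' @param jitter_sd within-state latent jitter SD (default 0.25); i.i.d.
#'   per frame, so it carries no slow dynamics.
#' @param noise_sd additive observation noise SD in feature space
#'   (default 0.25).
#' @param warp_seed seed freezing the nonlinear warp (a fixed random
#'   shallow ELU network with a linear skip term, built with the
#'   compressor machinery), so repeated embeddings agree.
#' @param anchors optional explicit K x d latent anchor matrix.
#' @return object of class `embedding_spec`.
#' @export
embedding_spec <- function(K, n_features = 50L, anchor_scale = 4,
                           jitter_sd = 0.25, noise_sd = 0.25,
                           warp_seed = 1L, anchors = NULL) {
  if (n_features < K) {
    stop_rptraj("n_features must be at least K", "rptraj_parameter_error")
  }
  stopifnot(jitter_sd >= 0, noise_sd >= 0)
  anchors <- anchors %||% (anchor_scale * diag(K))
  stopifnot(nrow(anchors) == K)
  d <- ncol(anchors)
  m <- 32L
  warp <- with_seed(warp_seed, list(
    A = matrix(stats::rnorm(n_features * d, sd = 1 / sqrt(d)),
               nrow = n_features),
    W1 = matrix(stats::runif(m * d, -sqrt(6 / (d + m)), sqrt(6 / (d + m))),
                nrow = m),
    b1 = stats::runif(m, -1, 1),
    W2 = matrix(stats::runif(n_features * m,
                             -sqrt(6 / (m + n_features)),
                             sqrt(6 / (m + n_features))),
                nrow = n_features)
  ))
  structure(
    list(
      K = as.integer(K), n_features = as.integer(n_features),
      anchors = anchors, jitter_sd = jitter_sd, noise_sd = noise_sd,
      warp = warp, warp_seed = as.integer(warp_seed)
    ),
    class = "embedding_spec"
  )
}

apply_warp <- function(spec, z) {
  hidden <- elu(sweep(z %*% t(spec$warp$W1), 2L, spec$warp$b1, "+"))
  z %*% t(spec$warp$A) + hidden %*% t(spec$warp$W2)
}

#' Embed a hidden state sequence into observed features
#'
#' Each frame's latent position is its state anchor plus i.i.d. Gaussian
#' jitter; the latent point is pushed through the spec's frozen nonlinear
#' warp into N dimensions and i.i.d. Gaussian observation noise is added.
#' Only the hidden chain carries temporal correlation, so the embedded
#' data's slow processes are exactly the chain's.
#'
#' @param states integer state sequence from [simulate_chain()].
#' @param spec an [embedding_spec()].
#' @param seed RNG seed for jitter and noise.
#' @return T x N feature matrix.
#' @export
embed_states <- function(states, spec, seed = 1L) {
  if (max(states) > spec$K) {
    stop_rptraj("state sequence exceeds the spec's K anchors",
                "rptraj_parameter_error")
  }
  T_len <- length(states)
  d <- ncol(spec$anchors)
  with_seed(seed, {
    z <- spec$anchors[states, , drop = FALSE]
    if (spec$jitter_sd > 0) {
      z <- z + matrix(stats::rnorm(T_len * d, sd = spec$jitter_sd),
                      nrow = T_len)
    }
    y <- apply_warp(spec, z)
    if (spec$noise_sd > 0) {
      y <- y + matrix(stats::rnorm(T_len * spec$n_features,
                                   sd = spec$noise_sd), nrow = T_len)
    }
    feature_matrix(y, paste0("f_", seq_len(spec$n_features)))
  })
}

# Idealized toy backbone geometries. Folded: a tight helical coil whose
# residue pairs at separation 3-4 sit inside a 4.5 Angstrom contact
# cutoff. Unfolded: a straight extended chain with all long-range pairs
# far apart. Atoms per residue: N, CA, C (no carbonyl O), so R residues
# expose 3R backbone atoms.
toy_backbone <- function(n_residues, folded = TRUE) {
  i <- seq_len(n_residues)
  if (folded) {
    theta <- i * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.0 * i)
    tangent <- cbind(-sin(theta), cos(theta), rep(0.4, n_residues))
  } else {
    ca <- cbind(3.5 * i, 0, 0)
    tangent <- matrix(rep(c(1, 0, 0), each = n_residues), ncol = 3L)
  }
  tangent <- tangent / sqrt(rowSums(tangent^2))
  coords <- matrix(NA_real_, nrow = 3L * n_residues, ncol = 3L)
  coords[seq(1L, by = 3L, length.out = n_residues), ] <- ca - 1.2 * tangent
  coords[seq(2L, by = 3L, length.out = n_residues), ] <- ca
  coords[seq(3L, by = 3L, length.out = n_residues), ] <- ca + 1.2 * tangent
  coords
}

#' Toy protein trajectory with folded/unfolded geometries
#'
#' Builds an N/CA/C backbone (3 atoms per residue, all heavy) whose
#' "folded" conformation is a compact helical coil (native contacts at
#' residue separation >= 3 inside 4.5 Angstrom) and whose "unfolded"
#' conformation is a fully extended chain (all such pairs far beyond any
#' formation margin). A frame in hidden state s interpolates between the
#' two geometries with folding fraction `(K - s) / (K - 1)` (state 1 fully
#' folded, state K fully unfolded), plus small Gaussian coordinate jitter.
#'
#' @param n_residues number of residues (>= 5). 39 residues expose
#'   117 backbone atoms and hence 6786 backbone pairs downstream.
#' @param state_sequence integer states in 1..K per frame.
#' @param K number of states (default: max of the sequence).
#' @param jitter_sd coordinate jitter SD in Angstrom (default 0.1).
#' @param seed RNG seed.
#' @return list: `frames` (T x A x 3 array), `reference` (folded mean
#'   structure), `topology`.
#' @export
make_toy_protein <- function(n_residues, state_sequence, K = NULL,
                             jitter_sd = 0.1, seed = 1L) {
  stopifnot(n_residues >= 5L)
  K <- K %||% max(state_sequence)
  folded <- toy_backbone(n_residues, folded = TRUE)
  unfolded <- toy_backbone(n_residues, folded = FALSE)
  n_atoms <- nrow(folded)
  frac <- if (K == 1L) rep(1, length(state_sequence)) else {
    (K - state_sequence) / (K - 1)
  }
  frames <- with_seed(seed, {
    arr <- array(NA_real_, dim = c(length(state_sequence), n_atoms, 3L))
    noise <- array(stats::rnorm(length(arr), sd = jitter_sd), dim = dim(arr))
    for (t in seq_along(state_sequence)) {
      arr[t, , ] <- frac[t] * folded + (1 - frac[t]) * unfolded
    }
    arr + noise
  })
  topo <- topology(
    atom_name = rep(c("N", "CA", "C"), n_residues),
    residue_index = rep(seq_len(n_residues), each = 3L),
    heavy = rep(TRUE, n_atoms)
  )
  list(frames = frames, reference = folded, topology = topo)
}
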
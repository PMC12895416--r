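# Random nonlinear (and baseline linear) compression of feature matrices.
#
# An n-dimensional compressed space is built from untrained feed-forward
# networks applied to the T x N feature matrix: either n independent
# networks with one output neuron each ("multi_net", the default and the
# construction used throughout the downstream analyses) or a single network
# with n output neurons ("single_net"). Weights use Xavier-uniform
# initialization, biases are uniform on a configurable range, hidden layers
# use ELU activations, and each output function is min-max standardized to
# [0, 1]. A network with no nonlinear activation reduces exactly to the
# classical linear random mapping, which is also available directly
# ("linear").

#' Configuration for random compression
#'
#' @param n target dimension (number of random functions), >= 1.
#' @param mode `"multi_net"` (n independent single-output networks, often
#'   the least correlated construction), `"single_net"` (one network with n
#'   output neurons) or `"linear"` (Gaussian random matrix projection).
#' @param depth_range integer range \[h_min, h_max\] for the number of
#'   hidden layers, sampled uniformly per network. Default 5..20.
#' @param width_range integer range for hidden-layer widths, sampled
#'   uniformly per layer. The upper end may be `NA` meaning "the input
#'   dimension". Default c(2, NA).
#' @param elu_alpha ELU saturation parameter alpha > 0 (default 1).
#' @param bias_range support of the uniform bias initialization
#'   (default c(-1, 1)).
#' @param seed master seed; spawns one child seed per random function.
#' @param max_retries how many fresh seeds to try when a random function is
#'   degenerate (constant output carries no information), default 10.
#' @return object of class `compression_config`.
#' @export
compression_config <- function(n,
                               mode = c("multi_net", "single_net", "linear"),
                               depth_range = c(5L, 20L),
                               width_range = c(2L, NA),
                               elu_alpha = 1,
                               bias_range = c(-1, 1),
                               seed = 1L,
                               max_retries = 10L) {
  mode <- match.arg(mode)
  stopifnot(
    n >= 1L,
    length(depth_range) == 2L, depth_range[1L] >= 1L,
    depth_range[1L] <= depth_range[2L],
    length(width_range) == 2L,
    is.na(width_range[1L]) || width_range[1L] >= 2L,
    elu_alpha > 0,
    length(bias_range) == 2L, bias_range[1L] < bias_range[2L]
  )
  structure(
    list(
      n = as.integer(n), mode = mode,
      depth_range = as.integer(depth_range),
      width_range = as.integer(width_range),
      elu_alpha = elu_alpha, bias_range = bias_range,
      seed = as.integer(seed), max_retries = as.integer(max_retries)
    ),
    class = "compression_config"
  )
}

#' Sample a random network architecture
#'
#' Depth is uniform on the configured depth range and each hidden-layer
#' width is independently uniform on \[w_min, min(w_max, input_dim)\].
#' Uses the current RNG state (seed at the call site for reproducibility).
#'
#' @param config a [compression_config()].
#' @param input_dim number of input features N (>= 2).
#' @param output_dim number of output neurons (1 for multi-net members).
#' @return object of class `network_architecture` with fields `input_dim`,
#'   `depth`, `widths`, `output_dim`.
#' @export
sample_architecture <- function(config, input_dim, output_dim = 1L) {
  stopifnot(input_dim >= 2L)
  w_lo <- config$width_range[1L]
  w_hi <- config$width_range[2L]
  if (is.na(w_hi)) w_hi <- input_dim
  w_hi <- min(w_hi, input_dim)
  if (w_lo > w_hi) {
    warning(sprintf(
      "width range clamped to [2, %d] for input dimension %d", w_hi, input_dim
    ))
    w_lo <- 2L
  }
  depth <- if (config$depth_range[1L] == config$depth_range[2L]) {
    config$depth_range[1L]
  } else {
    sample(seq(config$depth_range[1L], config$depth_range[2L]), 1L)
  }
  widths <- if (w_lo == w_hi) {
    rep(w_lo, depth)
  } else {
    sample(seq(w_lo, w_hi), depth, replace = TRUE)
  }
  structure(
    list(
      input_dim = as.integer(input_dim), depth = as.integer(depth),
      widths = as.integer(widths), output_dim = as.integer(output_dim)
    ),
    class = "network_architecture"
  )
}

#' Initialize an untrained random network
#'
#' Layer weights are Xavier-uniform: entries uniform on
#' \[-sqrt(6/(fan_in+fan_out)), +sqrt(6/(fan_in+fan_out))\]. Biases are
#' uniform on the configured bias range. Uses the current RNG state.
#'
#' The network applies, in order: an affine input layer (no activation),
#' `depth - 1` ELU-activated affine hidden maps, and an affine output layer
#' (no activation). With `depth = 1` there is no activation anywhere and
#' the network is an affine map.
#'
#' @param architecture a [sample_architecture()] result.
#' @param config a [compression_config()].
#' @return object of class `random_network`: list of layers (each with
#'   weight matrix `W` (out x in) and bias vector `b`), the architecture
#'   and the ELU alpha.
#' @export
init_network <- function(architecture, config) {
  dims <- c(architecture$input_dim, architecture$widths,
            architecture$output_dim)
  layers <- vector("list", length(dims) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    fan_out <- dims[l + 1L]
    bound <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_out * fan_in, -bound, bound),
                 nrow = fan_out, ncol = fan_in),
      b = stats::runif(fan_out, config$bias_range[1L], config$bias_range[2L])
    )
  }
  structure(
    list(layers = layers, architecture = architecture,
         elu_alpha = config$elu_alpha),
    class = "random_network"
  )
}

#' Exponential linear unit
#'
#' `elu(x) = x` for `x >= 0` and `alpha * (exp(x) - 1)` for `x < 0`;
#' continuous and monotone.
#'
#' @param x numeric vector/matrix.
#' @param alpha saturation parameter > 0.
#' @return transformed values, same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  stopifnot(alpha > 0)
  neg <- x < 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

#' Forward propagation through a random network
#'
#' The input layer and the output layer are affine without activation;
#' every intermediate hidden map is followed by an ELU.
#'
#' @param network a [init_network()] result.
#' @param x T x N feature matrix (frame-major).
#' @return T x output_dim matrix of raw (un-normalized) outputs.
#' @export
net_forward <- function(network, x) {
  x <- as.matrix(x)
  if (ncol(x) != network$architecture$input_dim) {
    stop_rptraj(
      sprintf("input has %d features but network expects %d",
              ncol(x), network$architecture$input_dim),
      "rptraj_dim_mismatch"
    )
  }
  cpp_forward(
    x,
    lapply(network$layers, `[[`, "W"),
    lapply(network$layers, `[[`, "b"),
    network$elu_alpha
  )
}

#' Min-max standardization to \[0, 1\]
#'
#' @param x numeric vector of length >= 2.
#' @return `(x - min) / (max - min)`, attaining both 0 and 1.
#'   A constant input is degenerate and raises a condition of class
#'   `rptraj_degenerate` (callers resample the random function).
#' @export
minmax_normalize <- function(x) {
  stopifnot(length(x) >= 2L)
  rng <- range(x)
  span <- rng[2L] - rng[1L]
  if (!is.finite(span) || span <= 0 ||
      span < 1e-12 * max(abs(rng[2L]), abs(rng[1L]), 1)) {
    stop_rptraj("constant (degenerate) function output", "rptraj_degenerate")
  }
  (x - rng[1L]) / span
}

#' Linear random mapping (Gaussian random projection)
#'
#' Projects the T x N feature matrix with a random n x N matrix M whose
#' entries are i.i.d. mean-free Gaussian scaled by 1/sqrt(n), so squared
#' pairwise distances are preserved in expectation (Johnson-Lindenstrauss).
#' Uses the current RNG state.
#'
#' @param feature_matrix T x N matrix.
#' @param n target dimension; a warning is issued if `n > N`.
#' @param M optional projection matrix to use instead of sampling (for
#'   testing and for reproducing a stored projection).
#' @return T x n matrix of raw projections.
#' @export
linear_random_map <- function(feature_matrix, n, M = NULL) {
  x <- as.matrix(feature_matrix)
  N <- ncol(x)
  if (is.null(M)) {
    if (n > N) warning("target dimension n exceeds input dimension N")
    M <- matrix(stats::rnorm(n * N, sd = 1 / sqrt(n)), nrow = n, ncol = N)
  }
  stopifnot(ncol(M) == N)
  x %*% t(M)
}

#' Compress a feature matrix with random projections
#'
#' Builds an n-dimensional compressed feature space from the T x N input,
#' according to `config$mode`:
#' \describe{
#'   \item{multi_net}{n independent networks, each with a freshly sampled
#'     architecture and initialization and one output neuron;}
#'   \item{single_net}{one network with n output neurons;}
#'   \item{linear}{a Gaussian linear random map.}
#' }
#' Every output column is min-max standardized to \[0, 1\] independently.
#' Degenerate (constant) functions are resampled with a fresh child seed,
#' up to `config$max_retries` attempts.
#'
#' @param feature_matrix T x N matrix, T >= 2.
#' @param config a [compression_config()].
#' @return object of class `compressed_features`: list with `values`
#'   (T x n matrix in \[0, 1\]), `config`, `seeds` (child seed per
#'   function or network), and `architectures` (per network).
#' @export
compress <- function(feature_matrix, config) {
  x <- as.matrix(feature_matrix)
  stopifnot(nrow(x) >= 2L)
  n <- config$n
  out <- switch(config$mode,
    multi_net = compress_multi_net(x, config),
    single_net = compress_single_net(x, config),
    linear = compress_linear(x, config)
  )
  colnames(out$values) <- paste0("g_", seq_len(n))
  attr(out$values, "time_step") <- attr(feature_matrix, "time_step")
  structure(
    c(out, list(config = config, source_dim = ncol(x))),
    class = "compressed_features"
  )
}

compress_multi_net <- function(x, config) {
  n <- config$n
  # one child per function plus a shared pool of retry seeds
  seeds <- derive_seeds(config$seed, n + n * config$max_retries)
  retry_pool <- matrix(seeds[-seq_len(n)], nrow = n)
  values <- matrix(NA_real_, nrow = nrow(x), ncol = n)
  used_seeds <- integer(n)
  archs <- vector("list", n)
  for (j in seq_len(n)) {
    tried <- integer(0)
    candidates <- c(seeds[j], retry_pool[j, ])
    done <- FALSE
    for (s in candidates) {
      res <- with_seed(s, {
        arch <- sample_architecture(config, ncol(x), output_dim = 1L)
        net <- init_network(arch, config)
        list(arch = arch, raw = net_forward(net, x))
      })
      tried <- c(tried, s)
      norm <- tryCatch(minmax_normalize(drop(res$raw)),
                       rptraj_degenerate = function(e) NULL)
      if (!is.null(norm)) {
        values[, j] <- norm
        used_seeds[j] <- s
        archs[[j]] <- res$arch
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop_rptraj(
        sprintf("random function %d degenerate after %d seeds (%s)",
                j, length(tried), paste(tried, collapse = ", ")),
        "rptraj_retry_exhausted"
      )
    }
  }
  list(values = values, seeds = used_seeds, architectures = archs)
}

compress_single_net <- function(x, config) {
  candidates <- derive_seeds(config$seed, 1L + config$max_retries)
  tried <- integer(0)
  for (s in candidates) {
    res <- with_seed(s, {
      arch <- sample_architecture(config, ncol(x), output_dim = config$n)
      net <- init_network(arch, config)
      list(arch = arch, raw = net_forward(net, x))
    })
    tried <- c(tried, s)
    norm <- tryCatch(
      apply(res$raw, 2L, minmax_normalize),
      rptraj_degenerate = function(e) NULL
    )
    if (!is.null(norm)) {
      return(list(values = norm, seeds = s, architectures = list(res$arch)))
    }
  }
  stop_rptraj(
    sprintf("single-net compression degenerate after %d seeds (%s)",
            length(tried), paste(tried, collapse = ", ")),
    "rptraj_retry_exhausted"
  )
}

compress_linear <- function(x, config) {
  candidates <- derive_seeds(config$seed, 1L + config$max_retries)
  tried <- integer(0)
  for (s in candidates) {
    raw <- with_seed(s, linear_random_map(x, config$n))
    tried <- c(tried, s)
    norm <- tryCatch(
      apply(raw, 2L, minmax_normalize),
      rptraj_degenerate = function(e) NULL
    )
    if (!is.null(norm)) {
      if (config$n == 1L) norm <- matrix(norm, ncol = 1L)
      return(list(values = norm, seeds = s, architectures = list()))
    }
  }
  stop_rptraj(
    sprintf("linear compression degenerate after %d seeds (%s)",
            length(tried), paste(tried, collapse = ", ")),
    "rptraj_retry_exhausted"
  )
}

#' @export
print.compressed_features <- function(x, ...) {
  cat(sprintf(
    "compressed_features: %d frames x %d functions (mode %s, from %d features)\n",
    nrow(x$values), ncol(x$values), x$config$mode, x$source_dim
  ))
  invisible(x)
}

#' Mean absolute off-diagonal feature correlation
#'
#' Diagnostic for how redundant a feature set is: the mean of |Pearson r|
#' over all off-diagonal pairs. Multi-network compressed spaces typically
#' score lower (less correlated) than single-network ones.
#'
#' @param matrix T x n matrix with at least 2 non-constant columns.
#' @return list with `correlation` (n x n matrix) and `mean_abs_offdiag`.
#' @export
feature_correlations <- function(matrix) {
  x <- as.matrix(matrix)
  stopifnot(ncol(x) >= 2L)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop_rptraj(
      sprintf("constant column(s): %s",
              paste(which(sds == 0), collapse = ", ")),
      "rptraj_degenerate"
    )
  }
  r <- stats::cor(x)
  off <- abs(r[upper.tri(r)])
  list(correlation = r, mean_abs_offdiag = mean(off))
}
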
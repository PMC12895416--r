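# Time-lagged independent component analysis (TICA) and a PCA baseline.
#
# TICA solves the generalized eigenproblem C0t v = lambda C00 v, where C00
# is the instantaneous covariance of the mean-free features and C0t the
# symmetrized time-lagged covariance at lag tau. The leading eigenvalues
# are autocorrelations of the slowest linearly resolvable processes; each
# maps to an implied relaxation timescale t = -tau / log(lambda).

#' Estimate instantaneous and time-lagged covariances
#'
#' Pools mean-free pairs (x_t, x_(t+tau)) across one or more trajectories;
#' pairs never straddle a trajectory boundary. The estimator is the
#' symmetric one: means and C00 average the head and tail samples, and
#' C0t is symmetrized as (C + t(C)) / 2, so C00 is symmetric positive
#' semidefinite and C0t symmetric.
#'
#' @param x T x N feature matrix, or a list of such matrices (one per
#'   trajectory).
#' @param lag_frames lag tau in frames (>= 1); every used trajectory must
#'   be longer than the lag.
#' @param time_step frame spacing in ns (optional bookkeeping).
#' @return object of class `covariance_pair`: `means`, `C00`, `C0t`,
#'   `lag_frames`, `lag_time`, `n_pairs`.
#' @export
estimate_covariances <- function(x, lag_frames, time_step = NA_real_) {
  stopifnot(lag_frames >= 1L)
  trajs <- if (is.list(x)) x else list(x)
  trajs <- lapply(trajs, as.matrix)
  usable <- vapply(trajs, nrow, 0L) > lag_frames
  if (!any(usable)) {
    stop_rptraj(
      sprintf("no trajectory longer than lag %d", lag_frames),
      "rptraj_lag_too_large"
    )
  }
  trajs <- trajs[usable]
  heads <- lapply(trajs, function(m) m[seq_len(nrow(m) - lag_frames), , drop = FALSE])
  tails <- lapply(trajs, function(m) m[(lag_frames + 1L):nrow(m), , drop = FALSE])
  X0 <- do.call(rbind, heads)
  Xt <- do.call(rbind, tails)
  m <- nrow(X0)
  mu <- (colSums(X0) + colSums(Xt)) / (2 * m)
  X0 <- sweep(X0, 2L, mu)
  Xt <- sweep(Xt, 2L, mu)
  C00 <- (crossprod(X0) + crossprod(Xt)) / (2 * m)
  C0t_raw <- crossprod(X0, Xt) / m
  C0t <- (C0t_raw + t(C0t_raw)) / 2
  structure(
    list(means = mu, C00 = C00, C0t = C0t,
         lag_frames = as.integer(lag_frames),
         lag_time = lag_frames * time_step, n_pairs = m),
    class = "covariance_pair"
  )
}

#' Fit a TICA model from estimated covariances
#'
#' Whitens with the eigendecomposition of C00 (components whose C00
#' eigenvalue is below `epsilon` relative to the largest are discarded as
#' numerically rank-deficient), then diagonalizes the whitened symmetrized
#' time-lagged covariance. Eigenvalues are returned in descending order;
#' eigenvectors are C00-orthonormal, so projections of the training data
#' have unit variance per component.
#'
#' @param covariances a [estimate_covariances()] result.
#' @param epsilon relative eigenvalue floor on C00 (default 1e-6).
#' @return object of class `tica_model`: `eigenvalues`, `eigenvectors`
#'   (N x k), `means`, `lag_frames`, `lag_time`, `epsilon`, `rank`.
#' @export
fit_tica <- function(covariances, epsilon = 1e-6) {
  C00 <- covariances$C00
  e0 <- eigen(C00, symmetric = TRUE)
  floor_val <- epsilon * max(e0$values)
  if (max(e0$values) <= 0 || all(e0$values < floor_val)) {
    stop_rptraj("C00 has no eigenvalue above the regularization floor",
                "rptraj_rank_error")
  }
  keep <- e0$values >= floor_val
  W <- e0$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e0$values[keep]), sum(keep))
  M <- t(W) %*% covariances$C0t %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  ord <- order(em$values, decreasing = TRUE)
  structure(
    list(
      eigenvalues = em$values[ord],
      eigenvectors = W %*% em$vectors[, ord, drop = FALSE],
      means = covariances$means,
      lag_frames = covariances$lag_frames,
      lag_time = covariances$lag_time,
      epsilon = epsilon,
      rank = sum(keep)
    ),
    class = "tica_model"
  )
}

#' @export
print.tica_model <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("tica_model: lag %d frames, rank %d\n", x$lag_frames, x$rank))
  cat("leading eigenvalues:",
      paste(sprintf("%.4f", x$eigenvalues[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Project features onto the leading TICA components
#'
#' @param model a [fit_tica()] result.
#' @param feature_matrix T x N matrix in the model's input feature space.
#' @param k number of components (<= retained rank).
#' @return T x k projection matrix.
#' @export
tica_project <- function(model, feature_matrix, k = 2L) {
  x <- as.matrix(feature_matrix)
  if (k > ncol(model$eigenvectors)) {
    stop_rptraj(
      sprintf("k = %d exceeds the %d retained components",
              k, ncol(model$eigenvectors)),
      "rptraj_parameter_error"
    )
  }
  sweep(x, 2L, model$means) %*% model$eigenvectors[, seq_len(k), drop = FALSE]
}

#' Implied relaxation timescale from a propagator eigenvalue
#'
#' `t = -tau / log(lambda)`, in the units of `tau`. Eigenvalues >= 1 map to
#' `Inf` (process slower than resolvable); eigenvalues <= 0 are undefined
#' and map to `NA`.
#'
#' @param lambda eigenvalue(s) of a propagator estimated at lag `tau`.
#' @param tau lag time (any time unit; result shares it).
#' @return implied timescale(s), same length as `lambda`.
#' @export
implied_timescale <- function(lambda, tau) {
  stopifnot(tau > 0)
  out <- rep(NA_real_, length(lambda))
  out[lambda >= 1] <- Inf
  ok <- lambda > 0 & lambda < 1
  out[ok] <- -tau / log(lambda[ok])
  out
}

#' Principal component analysis baseline
#'
#' Eigendecomposition of the instantaneous covariance C00 (no time
#' information), as the standard variance-based baseline for TICA.
#'
#' @param feature_matrix T x N matrix, T >= 2.
#' @param k number of components to retain (default: all).
#' @return object of class `pca_model`: `means`, `components` (N x k),
#'   `variances` (descending), `total_variance`.
#' @export
fit_pca <- function(feature_matrix, k = NULL) {
  x <- as.matrix(feature_matrix)
  stopifnot(nrow(x) >= 2L)
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  C00 <- crossprod(xc) / nrow(x)
  e <- eigen(C00, symmetric = TRUE)
  k <- k %||% ncol(x)
  structure(
    list(
      means = mu,
      components = e$vectors[, seq_len(k), drop = FALSE],
      variances = e$values[seq_len(k)],
      total_variance = sum(diag(C00))
    ),
    class = "pca_model"
  )
}
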
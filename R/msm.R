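# State assignment and Markov-state-model estimation: k-means microstates
# on a TICA projection, symmetrized transition-count MSMs, implied
# timescales versus lag time with a fixed assignment.
#
# This layer is a deliberate surrogate for trained soft-clustering state
# decompositions: every downstream quantity (implied timescales, cluster
# populations, mean fraction of native contacts) is computed from a
# per-frame label vector, so externally produced assignments can be
# plugged in unchanged.

# k-means++ seeding (stats::kmeans only offers random starts).
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, nrow = K, ncol = ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (k in seq_len(K)[-1L]) {
    p <- d2 / sum(d2)
    centers[k, ] <- x[sample.int(n, 1L, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[k, ])^2))
  }
  centers
}

#' Assign frames to K states by k-means on a projection
#'
#' Runs Lloyd's k-means with k-means++ seeding on the (typically TICA)
#' projection. Labels are canonicalized by descending state population
#' (state 1 is always the most populated), which makes labels comparable
#' across independent trials.
#'
#' @param projection T x k numeric matrix.
#' @param K number of states (>= 2, <= number of distinct frames).
#' @param seed RNG seed for the k-means++ initialization.
#' @param assignment_lag lag (in frames) recorded as the lag the assignment
#'   is associated with (bookkeeping for [timescales_vs_lag()]).
#' @return object of class `state_assignment`: `labels` (integer 1..K),
#'   `K`, `centers`, `seed`, `assignment_lag`.
#' @export
assign_states <- function(projection, K, seed = 1L, assignment_lag = NA_integer_) {
  x <- as.matrix(projection)
  if (K < 2L) {
    stop_rptraj("K must be at least 2", "rptraj_parameter_error")
  }
  if (nrow(unique(x)) < K) {
    stop_rptraj(
      sprintf("fewer than K = %d distinct points", K),
      "rptraj_parameter_error"
    )
  }
  km <- with_seed(seed, {
    centers <- kmeanspp_centers(x, K)
    stats::kmeans(x, centers = centers, iter.max = 100L,
                  algorithm = "Lloyd")
  })
  pop_order <- order(tabulate(km$cluster, nbins = K), decreasing = TRUE)
  relabel <- integer(K)
  relabel[pop_order] <- seq_len(K)
  structure(
    list(
      labels = relabel[km$cluster],
      K = as.integer(K),
      centers = km$centers[pop_order, , drop = FALSE],
      seed = as.integer(seed),
      assignment_lag = as.integer(assignment_lag)
    ),
    class = "state_assignment"
  )
}

as_labels <- function(assignment) {
  if (inherits(assignment, "state_assignment")) assignment$labels
  else as.integer(assignment)
}

#' Estimate a Markov state model at a given lag
#'
#' Counts transitions with a sliding window within each trajectory,
#' symmetrizes the count matrix as (C + t(C)) / 2 (enforcing detailed
#' balance, so the spectrum is real and in \[-1, 1\]) and row-normalizes
#' to a transition matrix.
#'
#' @param assignment a [assign_states()] result, an integer label vector,
#'   or a list of label vectors (one per trajectory).
#' @param lag_frames lag in frames (>= 1).
#' @param K number of states (default: max label).
#' @param time_step frame spacing in ns.
#' @return object of class `msm`: `counts` (raw), `transition`
#'   (row-stochastic), `eigenvalues` (descending), `stationary`,
#'   `lag_frames`, `lag_time`.
#' @export
estimate_msm <- function(assignment, lag_frames, K = NULL,
                         time_step = NA_real_) {
  stopifnot(lag_frames >= 1L)
  labs <- if (is.list(assignment) && !inherits(assignment, "state_assignment")) {
    lapply(assignment, as_labels)
  } else {
    list(as_labels(assignment))
  }
  K <- K %||% max(unlist(labs))
  if (K < 2L) {
    stop_rptraj("need at least 2 states to estimate an MSM",
                "rptraj_parameter_error")
  }
  counts <- matrix(0, K, K)
  for (l in labs) {
    if (length(l) <= lag_frames) next
    from <- l[seq_len(length(l) - lag_frames)]
    to <- l[(lag_frames + 1L):length(l)]
    tab <- table(factor(from, levels = seq_len(K)),
                 factor(to, levels = seq_len(K)))
    counts <- counts + unclass(tab)
  }
  if (sum(counts) == 0) {
    stop_rptraj("no transition pairs at this lag", "rptraj_lag_too_large")
  }
  sym <- (counts + t(counts)) / 2
  rows <- rowSums(sym)
  empty <- which(rows == 0)
  if (length(empty) > 0L) {
    stop_rptraj(
      sprintf("state(s) never visited: %s", paste(empty, collapse = ", ")),
      "rptraj_empty_state"
    )
  }
  transition <- sym / rows
  # symmetric similarity transform: real spectrum of the reversible chain
  s <- 1 / sqrt(rows)
  sym_t <- diag(s) %*% sym %*% diag(s)
  ev <- sort(eigen((sym_t + t(sym_t)) / 2, symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  structure(
    list(
      counts = counts, transition = transition,
      eigenvalues = ev, stationary = rows / sum(rows),
      lag_frames = as.integer(lag_frames),
      lag_time = lag_frames * time_step
    ),
    class = "msm"
  )
}

#' @export
print.msm <- function(x, ...) {
  cat(sprintf("msm: %d states at lag %d frames\n",
              nrow(x$transition), x$lag_frames))
  cat("eigenvalues:",
      paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  invisible(x)
}

#' Implied timescales versus lag time with a fixed assignment
#'
#' Re-estimates the MSM at each lag in `lag_list` on the *same* per-frame
#' labels (the assignment is fixed; only the counting lag varies) and
#' reports the implied timescale of each nontrivial process,
#' `-lag / log(lambda_i)`, i >= 2. For Markovian dynamics the curves are
#' flat in lag; nonpositive eigenvalues yield `NA` with a warning.
#'
#' @param assignment labels (see [estimate_msm()]).
#' @param lag_list integer vector of lags in frames.
#' @param K number of states (default: max label).
#' @param time_step frame spacing in ns; timescales are reported in ns
#'   when given, else in frames.
#' @return data.frame with columns `lag_frames`, `lag_time`, `process`
#'   (2 = slowest), `eigenvalue`, `timescale`.
#' @export
timescales_vs_lag <- function(assignment, lag_list, K = NULL,
                              time_step = NA_real_) {
  step <- if (is.na(time_step)) 1 else time_step
  rows <- lapply(lag_list, function(lag) {
    m <- estimate_msm(assignment, lag, K = K, time_step = time_step)
    lam <- m$eigenvalues[-1L]
    if (any(lam <= 0)) {
      warning(sprintf("nonpositive eigenvalue(s) at lag %d; reported as NA", lag))
    }
    data.frame(
      lag_frames = lag,
      lag_time = lag * step,
      process = seq_along(lam) + 1L,
      eigenvalue = lam,
      timescale = implied_timescale(lam, lag * step)
    )
  })
  do.call(rbind, rows)
}
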
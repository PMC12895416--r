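# Multi-trial aggregation: the compressed feature space is random, so all
# downstream quantities are assessed over repeated trials with fresh random
# functions, and reported as mean +/- SD across trials.

#' Run repeated compression-to-MSM trials
#'
#' For each trial a fresh compression seed is drawn from the master seed,
#' then the full pipeline runs: compress -> TICA at `lag` -> k-means state
#' assignment (K states, on the leading `K - 1` TICA components) -> MSM
#' implied timescales over `lag_list` with the assignment fixed ->
#' cluster summary (with mean native-contact fraction when `Q` is given).
#' Failed trials are recorded and excluded with a warning; if more than
#' half fail the run aborts.
#'
#' @param features T x N feature matrix shared by all trials.
#' @param n_trials number of trials (>= 1).
#' @param config a [compression_config()] template; its seed field is
#'   replaced by a per-trial child seed.
#' @param lag TICA/assignment lag in frames.
#' @param K number of states.
#' @param lag_list lags (frames) for [timescales_vs_lag()] (default: just
#'   `lag`).
#' @param Q optional per-frame fraction of native contacts.
#' @param seed master seed for the whole run.
#' @param time_step frame spacing in ns.
#' @return object of class `trial_results`: `timescales` (data.frame with
#'   per-trial implied timescales), `aggregate` (mean, SD and trial count
#'   per process and lag), `summaries` (list of [cluster_summary()]
#'   tables), `seeds`, `failures`.
#' @export
run_trials <- function(features, n_trials, config, lag, K,
                       lag_list = NULL, Q = NULL, seed = 1L,
                       time_step = NA_real_) {
  stopifnot(n_trials >= 1L)
  lag_list <- lag_list %||% lag
  seeds <- derive_seeds(seed, n_trials)
  ts_rows <- list()
  summaries <- list()
  failures <- list()
  for (trial in seq_len(n_trials)) {
    res <- tryCatch({
      cfg <- config
      cfg$seed <- seeds[trial]
      comp <- compress(features, cfg)
      cov <- estimate_covariances(comp$values, lag, time_step)
      model <- fit_tica(cov)
      k_proj <- min(K - 1L, ncol(model$eigenvectors))
      proj <- tica_project(model, comp$values, k = k_proj)
      assign <- assign_states(proj, K, seed = seeds[trial],
                              assignment_lag = lag)
      ts <- timescales_vs_lag(assign, lag_list, K = K,
                              time_step = time_step)
      ts$trial <- trial
      list(ts = ts, summary = cluster_summary(assign, Q, trial = trial))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(trial = trial,
                                                message = conditionMessage(res))
      warning(sprintf("trial %d failed: %s", trial, conditionMessage(res)))
    } else {
      ts_rows[[length(ts_rows) + 1L]] <- res$ts
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }
  if (length(failures) > n_trials / 2) {
    stop_rptraj(
      sprintf("%d of %d trials failed", length(failures), n_trials),
      "rptraj_trials_failed"
    )
  }
  timescales <- do.call(rbind, ts_rows)
  agg <- stats::aggregate(
    timescale ~ lag_frames + process, data = timescales,
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)),
    na.action = stats::na.omit
  )
  aggregate <- data.frame(
    lag_frames = agg$lag_frames, process = agg$process,
    mean = agg$timescale[, "mean"], sd = agg$timescale[, "sd"],
    n_trials = agg$timescale[, "n"]
  )
  structure(
    list(timescales = timescales, aggregate = aggregate,
         summaries = summaries, seeds = seeds, failures = failures),
    class = "trial_results"
  )
}

#' @export
print.trial_results <- function(x, ...) {
  cat(sprintf("trial_results: %d trials (%d failed)\n",
              length(x$seeds), length(x$failures)))
  print(x$aggregate)
  invisible(x)
}
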
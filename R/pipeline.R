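# End-to-end orchestration: synth -> featurize -> compress -> tica -> msm
# with persisted intermediate tables, per-stage child seeds derived from a
# single master seed, a JSON manifest, and stage-level resume.

#' Configuration for an end-to-end pipeline run
#'
#' @param preset synthetic source: `"two-state"`, `"four-state"` or
#'   `"toy-protein"` (a 39-residue toy backbone whose features are
#'   exponential backbone contacts).
#' @param n_steps trajectory length in steps.
#' @param n_features observed feature dimension N (chain presets).
#' @param noise_sd observation noise SD (chain presets).
#' @param n compressed dimension.
#' @param mode compression mode (see [compression_config()]).
#' @param lag TICA/MSM lag in frames.
#' @param K number of states for the assignment.
#' @param lag_list lags for the implied-timescale table (default:
#'   `lag * c(0.5, 1, 2, 3)`, rounded, unique, >= 1).
#' @param d0 contact length in Angstrom for the toy-protein featurization
#'   (always explicit; default 1.0).
#' @param seed master seed; every stage derives its own child seed.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(preset = c("two-state", "four-state", "toy-protein"),
                            n_steps = 20000L, n_features = 50L,
                            noise_sd = 0.25, n = 10L,
                            mode = "multi_net", lag = 10L, K = NULL,
                            lag_list = NULL, d0 = 1.0, seed = 1L) {
  preset <- match.arg(preset)
  K <- K %||% switch(preset, "two-state" = 2L, "four-state" = 4L,
                     "toy-protein" = 2L)
  lag_list <- lag_list %||% unique(pmax(1L, as.integer(round(lag * c(0.5, 1, 2, 3)))))
  structure(
    list(preset = preset, n_steps = as.integer(n_steps),
         n_features = as.integer(n_features), noise_sd = noise_sd,
         n = as.integer(n), mode = mode, lag = as.integer(lag),
         K = as.integer(K), lag_list = as.integer(lag_list), d0 = d0,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes synth -> featurize -> compress -> tica -> msm in order, writing
#' each stage's tables under `outdir` and a `manifest.json` listing every
#' artifact and seed. With `resume = TRUE`, stages whose outputs already
#' exist are skipped and only missing (downstream) stages are recomputed.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param resume skip stages whose outputs already exist.
#' @return the manifest, invisibly: list of stages with their files and
#'   seeds.
#' @export
run_pipeline <- function(config, outdir, resume = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 5L)
  names(seeds) <- c("synth", "featurize", "compress", "tica", "msm")
  manifest <- list(master_seed = config$seed, preset = config$preset,
                   stages = list())
  path_of <- function(...) file.path(outdir, paste0(...))
  # once any stage reruns, everything downstream reruns too
  dirty <- FALSE
  stage_done <- function(files) resume && !dirty && all(file.exists(files))
  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      files = unname(files), seed = unname(seeds[stage]))
    write_manifest()
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run_stage <- function(stage, files, fun) {
    if (!stage_done(files)) {
      dirty <<- TRUE
      tryCatch(fun(), error = function(e) {
        write_manifest()
        stop_rptraj(
          sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          "rptraj_pipeline_error"
        )
      })
    }
    record(stage, files)
  }

  # stage 1: synthetic trajectory with ground truth
  model <- switch(config$preset,
    "two-state" = two_state_model(),
    "four-state" = four_state_model(),
    "toy-protein" = two_state_model()
  )
  states_file <- path_of("states.tsv")
  truth_file <- path_of("truth.json")
  run_stage("synth", c(states_file, truth_file), function() {
    states <- simulate_chain(model, config$n_steps, seed = seeds["synth"])
    write_table(states_file, matrix(states, ncol = 1L), labels = "state")
    jsonlite::write_json(
      list(transition = model$transition, stationary = model$stationary,
           analytic_timescales = analytic_timescales(model),
           seed = unname(seeds["synth"])),
      truth_file, auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
    )
  })
  states <- as.integer(read_table(states_file)[, 1L])

  # stage 2: featurization (nonlinear embedding or toy-protein contacts)
  features_file <- path_of("features.tsv")
  run_stage("featurize", features_file, function() {
    feats <- if (config$preset == "toy-protein") {
      toy <- make_toy_protein(39L, states, K = model$K,
                              seed = seeds["featurize"])
      pairs <- enumerate_pairs(toy$topology, "backbone")
      exponential_contacts(pairwise_distances(toy$frames, pairs), config$d0)
    } else {
      spec <- embedding_spec(model$K, config$n_features,
                             noise_sd = config$noise_sd,
                             warp_seed = seeds["featurize"])
      embed_states(states, spec, seed = seeds["featurize"])
    }
    write_table(features_file, feats,
                sidecar = list(seed = unname(seeds["featurize"]),
                               preset = config$preset))
  })
  features <- read_table(features_file)

  # stage 3: random compression
  compressed_file <- path_of("compressed.tsv")
  run_stage("compress", compressed_file, function() {
    cfg <- compression_config(config$n, config$mode,
                              seed = seeds["compress"])
    comp <- compress(features, cfg)
    write_table(compressed_file, comp$values,
                sidecar = list(mode = config$mode, n = config$n,
                               seeds = comp$seeds))
  })
  compressed <- read_table(compressed_file)

  # stage 4: TICA
  eig_file <- path_of("tica_eigenvalues.tsv")
  proj_file <- path_of("tica_projection.tsv")
  run_stage("tica", c(eig_file, proj_file), function() {
    cov <- estimate_covariances(compressed, config$lag)
    model_t <- fit_tica(cov)
    k <- min(max(config$K - 1L, 1L), ncol(model_t$eigenvectors))
    write_table(eig_file, matrix(model_t$eigenvalues, ncol = 1L),
                labels = "eigenvalue")
    write_table(proj_file, tica_project(model_t, compressed, k = k),
                labels = paste0("tic_", seq_len(k)))
  })
  projection <- read_table(proj_file)

  # stage 5: states + MSM + implied timescales
  ts_file <- path_of("timescales.tsv")
  pop_file <- path_of("populations.tsv")
  run_stage("msm", c(ts_file, pop_file), function() {
    assign <- assign_states(projection, config$K, seed = seeds["msm"],
                            assignment_lag = config$lag)
    ts <- timescales_vs_lag(assign, config$lag_list, K = config$K)
    write_table(ts_file, as.matrix(ts))
    summ <- cluster_summary(assign)
    write_table(pop_file, as.matrix(summ[, c("cluster", "population")]))
  })

  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"),
                                  simplifyVector = TRUE)
  invisible(manifest)
}
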
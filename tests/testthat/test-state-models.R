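test_that("k-means assignment recovers well-separated states deterministically", {
  set.seed(33)
  truth <- rep(c(1L, 2L), times = c(700L, 300L))
  pts <- cbind(rnorm(1000, mean = ifelse(truth == 1L, -4, 4), sd = 0.5),
               rnorm(1000, sd = 0.5))
  asg <- assign_states(pts, 2L, seed = 7L)
  # labels canonicalized by population: state 1 is the bigger blob
  expect_gte(mean(asg$labels == truth), 0.99)
  expect_equal(sort(unique(asg$labels)), 1:2)

  asg2 <- assign_states(pts, 2L, seed = 7L)
  expect_identical(asg$labels, asg2$labels)

  expect_error(assign_states(pts, 1L), class = "rptraj_parameter_error")
  expect_error(assign_states(matrix(1, 10L, 2L), 2L),
               class = "rptraj_parameter_error")
})

test_that("MSM estimation matches hand enumeration and generator truth", {
  # labels (1,1,2,2) at lag 1: counts [[1,1],[0,1]], symmetrized
  # [[1,.5],[.5,1]], T = [[2/3,1/3],[1/3,2/3]], lambda_2 = 1/3
  m <- estimate_msm(c(1L, 1L, 2L, 2L), 1L)
  expect_equal(m$counts, rbind(c(1, 1), c(0, 1)), ignore_attr = TRUE)
  expect_equal(m$transition, rbind(c(2, 1), c(1, 2)) / 3, ignore_attr = TRUE)
  expect_equal(m$eigenvalues, c(1, 1 / 3))
  expect_equal(rowSums(m$transition), c(1, 1), tolerance = 1e-12,
               ignore_attr = TRUE)

  # constant label sequence: single state is rejected
  expect_error(estimate_msm(rep(1L, 50L), 1L),
               class = "rptraj_parameter_error")
  # a state that never appears is named
  expect_error(estimate_msm(c(1L, 1L, 3L, 3L), 1L, K = 3L), "2",
               class = "rptraj_empty_state")

  # long simulation from a known 3-state chain recovers the matrix
  truth3 <- rbind(c(0.95, 0.04, 0.01),
                  c(0.04, 0.92, 0.04),
                  c(0.01, 0.04, 0.95))
  model3 <- metastable_model(truth3)
  states <- simulate_chain(model3, 1e6, seed = 44L)
  est <- estimate_msm(states, 1L)
  expect_lt(max(abs(est$transition - truth3)), 0.02)

  # symmetrized estimator: real spectrum within [-1, 1]
  set.seed(45)
  rand_labels <- sample.int(4L, 5000L, replace = TRUE)
  mr <- estimate_msm(rand_labels, 2L)
  expect_true(all(mr$eigenvalues >= -1 - 1e-12 & mr$eigenvalues <= 1 + 1e-12))
  expect_true(is.numeric(mr$eigenvalues))
})

test_that("implied timescales are flat in lag for Markovian labels", {
  # two-state chain with t2 = 100 steps
  lambda2 <- exp(-1 / 100)
  p <- (1 - lambda2) / 2
  model <- two_state_model(p = p)
  expect_equal(analytic_timescales(model)[1L], 100, tolerance = 1e-10)

  states <- simulate_chain(model, 5e5, seed = 55L)
  tab <- timescales_vs_lag(states, c(1L, 5L, 10L, 25L, 50L))
  t2 <- tab$timescale[tab$process == 2L]
  # within 10% of truth at lag 10 (spec'd operating point), flat overall
  expect_equal(t2[tab$lag_frames[tab$process == 2L] == 10L], 100,
               tolerance = 0.1)
  expect_lt(diff(range(t2)) / mean(t2), 0.1)

  # lag equal to the assignment lag reproduces the direct composition
  msm10 <- estimate_msm(states, 10L)
  expect_equal(t2[tab$lag_frames[tab$process == 2L] == 10L],
               implied_timescale(msm10$eigenvalues[2L], 10))
})

test_that("native contacts match a brute-force oracle and handle edge geometries", {
  # all-far linear chain: no contacts below the cutoff
  n <- 10L
  line <- cbind(10 * seq_len(3L * n), 0, 0)
  topo <- topology(rep(c("N", "CA", "C"), n), rep(seq_len(n), each = 3L))
  expect_error(native_contacts(line, topo, cutoff = 4.5),
               class = "rptraj_empty_contacts")

  # compact toy fold: nonempty, all stored distances below cutoff
  toy <- make_toy_protein(20L, c(1L, 1L), K = 1L, seed = 2L)
  nc <- native_contacts(toy$reference, toy$topology)
  expect_gt(nrow(nc$pairs), 0L)
  expect_true(all(nc$native_dist < nc$cutoff))

  # brute-force double loop on a random 30-atom structure
  set.seed(46)
  coords <- matrix(runif(30L * 3L, 0, 12), ncol = 3L)
  topo30 <- topology(rep("CA", 30L), 1:30)
  cutoff <- 8
  nc30 <- native_contacts(coords, topo30, cutoff = cutoff,
                          min_residue_separation = 3L)
  count <- 0L
  for (i in 1:29) {
    for (j in (i + 1L):30L) {
      if (j - i >= 3L && sqrt(sum((coords[i, ] - coords[j, ])^2)) < cutoff) {
        count <- count + 1L
      }
    }
  }
  expect_equal(nrow(nc30$pairs), count)
})

test_that("fraction of native contacts behaves at its extremes and scales", {
  toy <- make_toy_protein(20L, c(1L, 1L), K = 1L, seed = 2L)
  nc <- native_contacts(toy$reference, toy$topology)

  expect_equal(fraction_native(one_frame(toy$reference), nc), 1)

  ext <- make_toy_protein(20L, c(2L, 2L), K = 2L, jitter_sd = 0, seed = 2L)
  expect_equal(fraction_native(ext$frames, nc), c(0, 0))

  # Q nonincreasing under uniform coordinate scaling >= 1
  q_at <- vapply(c(1, 1.1, 1.3, 1.8, 3), function(s) {
    fraction_native(one_frame(toy$reference * s), nc)
  }, 0)
  expect_true(all(diff(q_at) <= 0))
})

test_that("cluster summaries aggregate populations and mean Q", {
  # single cluster
  s1 <- cluster_summary(rep(1L, 8L), Q = seq(0, 1, length.out = 8L))
  expect_equal(s1$population, 1)
  expect_equal(s1$mean_Q, mean(seq(0, 1, length.out = 8L)))

  # hand-computed 6-frame example
  labels <- c(1L, 1L, 2L, 2L, 2L, 3L)
  Q <- c(0.9, 0.8, 0.5, 0.4, 0.3, 1.0)
  s <- cluster_summary(labels, Q)
  expect_equal(s$cluster, c(2L, 1L, 3L))       # by descending population
  expect_equal(s$population, c(3, 2, 1) / 6)
  expect_equal(s$mean_Q, c(0.4, 0.85, 1.0))
  expect_equal(sum(s$population), 1, tolerance = 1e-12)

  # populations always form a partition
  set.seed(47)
  rl <- sample.int(5L, 400L, replace = TRUE)
  expect_equal(sum(cluster_summary(rl)$population), 1, tolerance = 1e-12)
})

test_that("contact-fraction grouping bins clusters and recovers known structure", {
  a <- cluster_summary(rep(c(1L, 2L), c(9, 1)), Q = rep(c(0.9, 0.1), c(9, 1)))
  g <- group_by_contact_fraction(a, boundaries = 0.5)
  expect_equal(g$n_clusters, c(1L, 1L))

  # a mean Q exactly on a boundary joins the higher-Q group
  b <- data.frame(cluster = 1:2, population = c(0.5, 0.5),
                  mean_Q = c(0.5, 0.2), trial = 1L)
  gb <- group_by_contact_fraction(b, boundaries = 0.5)
  expect_equal(gb$n_clusters, c(1L, 1L))

  expect_error(group_by_contact_fraction(b, boundaries = c(0.3, 0.8)),
               class = "rptraj_parameter_error")

  # 50 synthetic trials with known group structure
  set.seed(48)
  true_pops <- c(0.5, 0.3, 0.2)
  true_q <- c(0.9, 0.7, 0.2)
  trials <- lapply(1:50, function(i) {
    data.frame(
      cluster = 1:3,
      population = true_pops,
      mean_Q = pmin(0.99, pmax(0.01, true_q + rnorm(3, sd = 0.03))),
      trial = i
    )
  })
  gg <- group_by_contact_fraction(trials, boundaries = c(0.8, 0.5))
  expect_equal(gg$total_population, true_pops, tolerance = 0.02)
  expect_equal(gg$median_population, true_pops, tolerance = 0.02)
})

test_that("multi-trial runs are deterministic and consistent across trials", {
  model <- two_state_model()
  states <- simulate_chain(model, 5e4, seed = 61L)
  feats <- embed_states(states, embedding_spec(2L, 50L, warp_seed = 61L),
                        seed = 61L)
  cfg <- compression_config(10L, "multi_net")

  # a single trial equals the pipeline run with the derived child seed
  r1 <- run_trials(feats, 1L, cfg, lag = 10L, K = 2L, seed = 9L)
  child <- derive_seeds(9L, 1L)
  cfg1 <- cfg; cfg1$seed <- child
  comp <- compress(feats, cfg1)
  tm <- fit_tica(estimate_covariances(comp$values, 10L))
  asg <- assign_states(tica_project(tm, comp$values, k = 1L), 2L,
                       seed = child, assignment_lag = 10L)
  direct <- timescales_vs_lag(asg, 10L, K = 2L)
  expect_equal(r1$timescales$timescale, direct$timescale)

  # same master seed twice: identical aggregates
  r2 <- run_trials(feats, 3L, cfg, lag = 10L, K = 2L, seed = 9L)
  r3 <- run_trials(feats, 3L, cfg, lag = 10L, K = 2L, seed = 9L)
  expect_identical(r2$aggregate, r3$aggregate)

  # 25 trials: slowest timescale consistent across trials (SD < 15% of mean)
  r25 <- run_trials(feats, 25L, cfg, lag = 10L, K = 2L, seed = 10L)
  slow <- r25$aggregate[r25$aggregate$process == 2L, ]
  expect_lt(slow$sd / slow$mean, 0.15)
  expect_equal(length(r25$failures), 0L)
})
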
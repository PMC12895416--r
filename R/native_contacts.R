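# Fraction-of-native-contact machinery and cluster summaries used to
# characterize folding states: which heavy-atom contacts exist in the
# native (reference) structure, what fraction of them is formed per frame,
# and how that fraction distributes over kinetic clusters and trials.

#' Native contact set from a reference structure
#'
#' Heavy-atom pairs with residue separation at least
#' `min_residue_separation` whose distance in the reference (native)
#' conformation is below `cutoff`.
#'
#' @param reference A x 3 reference coordinates (Angstrom).
#' @param topology a [topology()].
#' @param cutoff native-distance cutoff in Angstrom (default 4.5).
#' @param min_residue_separation minimum residue separation (default 3,
#'   excluding trivially close intra-/near-residue pairs).
#' @param margin formation margin used by [fraction_native()]: a contact
#'   counts as formed in a frame when its distance is below
#'   `margin * native distance` (default 1.2).
#' @return object of class `native_contact_set`: `pairs`, `native_dist`,
#'   `cutoff`, `margin`.
#' @export
native_contacts <- function(reference, topology, cutoff = 4.5,
                            min_residue_separation = 3L, margin = 1.2) {
  pairs <- enumerate_pairs(topology, "heavy", min_residue_separation)
  d <- drop(pairwise_distances(reference, pairs))
  keep <- d < cutoff
  if (!any(keep)) {
    stop_rptraj(
      sprintf("no native contacts below %.2f Angstrom; try a larger cutoff",
              cutoff),
      "rptraj_empty_contacts"
    )
  }
  structure(
    list(
      pairs = pairs[keep, , drop = FALSE],
      native_dist = d[keep],
      cutoff = cutoff,
      margin = margin
    ),
    class = "native_contact_set"
  )
}

#' Per-frame fraction of native contacts Q
#'
#' Hard-count definition: Q(frame) = (number of native contacts whose
#' frame distance is below `margin` times the native distance) / (number
#' of native contacts). Q = 1 for the reference itself (margin > 1) and
#' Q = 0 for fully extended geometries.
#'
#' @param frames T x A x 3 coordinate array.
#' @param contact_set a [native_contacts()] result.
#' @param margin override of the stored formation margin.
#' @return numeric vector of length T with values in \[0, 1\].
#' @export
fraction_native <- function(frames, contact_set, margin = NULL) {
  margin <- margin %||% contact_set$margin
  d <- pairwise_distances(frames, contact_set$pairs)
  formed <- sweep(d, 2L, margin * contact_set$native_dist, "<")
  rowMeans(formed)
}

#' Per-cluster population and mean fraction of native contacts
#'
#' @param assignment labels (a [assign_states()] result or integer vector).
#' @param Q per-frame fraction of native contacts (same length), optional.
#' @param trial optional trial identifier carried into the output.
#' @return data.frame of class `cluster_summary` with one row per cluster,
#'   ordered by descending population: `cluster`, `population`, `mean_Q`,
#'   `trial`. Populations sum to 1.
#' @export
cluster_summary <- function(assignment, Q = NULL, trial = NA_integer_) {
  labels <- as_labels(assignment)
  if (!is.null(Q) && length(Q) != length(labels)) {
    stop_rptraj("Q and assignment lengths differ", "rptraj_dim_mismatch")
  }
  K <- max(labels)
  pop <- tabulate(labels, nbins = K) / length(labels)
  mean_q <- if (is.null(Q)) {
    rep(NA_real_, K)
  } else {
    vapply(seq_len(K), function(k) mean(Q[labels == k]), 0)
  }
  out <- data.frame(
    cluster = seq_len(K), population = pop, mean_Q = mean_q,
    trial = trial
  )
  out <- out[order(-out$population), ]
  rownames(out) <- NULL
  class(out) <- c("cluster_summary", "data.frame")
  out
}

#' Group clusters across trials by their mean native-contact fraction
#'
#' Bins every cluster (from a list of per-trial [cluster_summary()]
#' tables) by its mean Q into the intervals delimited by strictly
#' decreasing `boundaries`; group 1 is the highest-Q (most native) group.
#' A mean Q exactly on a boundary is assigned to the higher-Q group.
#' Reports per-group population statistics across trials.
#'
#' @param summaries list of [cluster_summary()] data.frames (or a single
#'   one).
#' @param boundaries strictly decreasing contact-fraction boundaries, e.g.
#'   `c(0.93, 0.84, 0.77, 0.73)`.
#' @return data.frame with one row per group: `group`, `q_range`,
#'   `n_clusters`, `median_population`, `iqr_population`,
#'   `total_population` (summed within trial, then averaged).
#' @export
group_by_contact_fraction <- function(summaries, boundaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (is.unsorted(rev(boundaries), strictly = TRUE)) {
    stop_rptraj("boundaries must be strictly decreasing",
                "rptraj_parameter_error")
  }
  all_rows <- do.call(rbind, lapply(seq_along(summaries), function(i) {
    s <- summaries[[i]]
    s$trial_id <- if (all(is.na(s$trial))) i else s$trial
    s
  }))
  if (any(is.na(all_rows$mean_Q))) {
    stop_rptraj("cluster summaries lack mean_Q values",
                "rptraj_invalid_input")
  }
  grp <- vapply(all_rows$mean_Q,
                function(q) 1L + sum(q < boundaries), 0L)
  all_rows$group <- grp
  n_groups <- length(boundaries) + 1L
  edges <- c(Inf, boundaries, -Inf)
  out <- do.call(rbind, lapply(seq_len(n_groups), function(g) {
    rows <- all_rows[all_rows$group == g, , drop = FALSE]
    per_trial <- if (nrow(rows)) {
      tapply(rows$population, rows$trial_id, sum)
    } else {
      numeric(0)
    }
    data.frame(
      group = g,
      q_range = sprintf("[%.3g, %.3g)", edges[g + 1L], edges[g]),
      n_clusters = nrow(rows),
      median_population = if (nrow(rows)) stats::median(rows$population) else NA_real_,
      iqr_population = if (nrow(rows)) stats::IQR(rows$population) else NA_real_,
      total_population = if (length(per_trial)) mean(per_trial) else 0
    )
  }))
  rownames(out) <- NULL
  out
}
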
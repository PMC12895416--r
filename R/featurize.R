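# Featurization of trajectory coordinates: topology bookkeeping, pair
# enumeration, distances, exponential contacts, backbone dihedrals, and
# aligned flattened positions.
#
# Conventions used throughout:
#   * coordinates are in Angstrom, trajectories are frame-major arrays
#     (T x A x 3); a single A x 3 matrix is accepted wherever a trajectory
#     is, and treated as one frame,
#   * feature matrices are frame-major (T rows, one column per feature)
#     with descriptive column names and a "time_step" attribute in ns,
#   * residue indices are 1-based (PDB convention) and atom indices are
#     1-based everywhere (R convention).

#' Construct an atom-level topology
#'
#' Minimal bookkeeping needed for featurization: one row per atom with its
#' PDB atom name, 1-based residue index and a heavy-atom flag.
#'
#' @param atom_name character vector of PDB atom names (e.g. "CA").
#' @param residue_index integer vector, nondecreasing, 1-based.
#' @param heavy logical vector; `TRUE` for non-hydrogen atoms. Defaults to
#'   a name-based guess (leading digits stripped; names starting with "H"
#'   are hydrogens).
#' @return object of class `topology`: a data.frame with columns
#'   `atom_name`, `residue_index`, `heavy`.
#' @export
topology <- function(atom_name, residue_index, heavy = NULL) {
  if (length(atom_name) < 1L) {
    stop_rptraj("topology must contain at least one atom", "rptraj_empty_input")
  }
  residue_index <- as.integer(residue_index)
  stopifnot(length(residue_index) == length(atom_name))
  if (is.unsorted(residue_index)) {
    stop_rptraj("residue indices must be nondecreasing", "rptraj_invalid_topology")
  }
  if (is.null(heavy)) {
    stripped <- sub("^[0-9]+", "", toupper(atom_name))
    heavy <- substr(stripped, 1L, 1L) != "H"
  }
  out <- data.frame(
    atom_name = as.character(atom_name),
    residue_index = residue_index,
    heavy = as.logical(heavy),
    stringsAsFactors = FALSE
  )
  class(out) <- c("topology", "data.frame")
  out
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(
    "topology: %d atoms, %d residues (%d heavy atoms)\n",
    nrow(x), length(unique(x$residue_index)), sum(x$heavy)
  ))
  invisible(x)
}

#' Read a PDB structure into a topology and reference coordinates
#'
#' Parses ATOM records (via [bio3d::read.pdb]) into a [topology()] plus the
#' file's coordinates, used as the reference (native) conformation.
#' HETATM records are ignored.
#'
#' @param pdb_path path to a PDB file.
#' @return list with elements `topology` and `coords` (atoms x 3 matrix, in
#'   Angstrom).
#' @export
read_structure <- function(pdb_path) {
  pdb <- bio3d::read.pdb(pdb_path)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop_rptraj(
      sprintf("no ATOM records found in '%s'", pdb_path),
      "rptraj_empty_input"
    )
  }
  if (anyDuplicated(atoms$eleno)) {
    stop_rptraj(
      sprintf("duplicate atom serial numbers in '%s'", pdb_path),
      "rptraj_parse_error"
    )
  }
  elesy <- atoms$elesy
  heavy <- if (!is.null(elesy) && !all(is.na(elesy) | elesy == "")) {
    toupper(trimws(elesy)) != "H"
  } else {
    NULL
  }
  topo <- topology(trimws(atoms$elety), atoms$resno, heavy)
  coords <- cbind(atoms$x, atoms$y, atoms$z)
  colnames(coords) <- c("x", "y", "z")
  list(topology = topo, coords = coords)
}

#' Write a topology + coordinates to a PDB file
#'
#' Convenience inverse of [read_structure()] (used mainly to persist
#' synthetic reference structures); delegates to [bio3d::write.pdb].
#'
#' @param topology a [topology()].
#' @param coords atoms x 3 coordinate matrix in Angstrom.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, coords, path) {
  stopifnot(nrow(coords) == nrow(topology), ncol(coords) == 3L)
  n <- nrow(topology)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(coords)),
    resno = topology$residue_index,
    resid = rep("ALA", n),
    eleno = seq_len(n),
    elety = topology$atom_name
  )
  invisible(path)
}

select_atoms <- function(topology, selection = c("heavy", "backbone", "calpha", "all")) {
  selection <- match.arg(selection)
  idx <- switch(selection,
    heavy = which(topology$heavy),
    backbone = which(topology$atom_name %in% c("N", "CA", "C")),
    calpha = which(topology$atom_name == "CA"),
    all = seq_len(nrow(topology))
  )
  if (length(idx) == 0L) {
    stop_rptraj(
      sprintf("selection '%s' matches no atoms", selection),
      "rptraj_empty_selection"
    )
  }
  idx
}

#' Enumerate atom pairs for distance/contact features
#'
#' All unordered atom pairs (i < j) within a named selection whose residue
#' separation is at least `min_residue_separation`, in deterministic
#' lexicographic order. With selection `"backbone"` (atoms named N, CA, C)
#' a 39-residue chain yields choose(117, 2) = 6786 pairs and a 35-residue
#' chain choose(105, 2) = 5460; selection `"calpha"` on 35 residues yields
#' choose(35, 2) = 595.
#'
#' @param topology a [topology()].
#' @param selection one of `"heavy"`, `"backbone"`, `"calpha"`, `"all"`.
#' @param min_residue_separation minimum `|resi - resj|` (default 0: all
#'   pairs).
#' @return integer matrix with columns `i`, `j` (1-based atom indices).
#' @export
enumerate_pairs <- function(topology, selection = "heavy",
                            min_residue_separation = 0L) {
  idx <- select_atoms(topology, selection)
  if (length(idx) < 2L) {
    stop_rptraj(
      sprintf("selection '%s' has fewer than 2 atoms", selection),
      "rptraj_empty_selection"
    )
  }
  pairs <- t(utils::combn(idx, 2L))
  colnames(pairs) <- c("i", "j")
  if (min_residue_separation > 0L) {
    sep <- abs(topology$residue_index[pairs[, 2L]] -
                 topology$residue_index[pairs[, 1L]])
    pairs <- pairs[sep >= min_residue_separation, , drop = FALSE]
  }
  pairs
}

as_frames <- function(frames) {
  if (is.matrix(frames)) {
    frames <- array(frames, dim = c(1L, nrow(frames), ncol(frames)))
  }
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] == 3L)
  if (any(!is.finite(frames))) {
    stop_rptraj("trajectory coordinates contain non-finite values",
                "rptraj_invalid_input")
  }
  frames
}

feature_matrix <- function(values, labels, time_step = NA_real_) {
  colnames(values) <- labels
  attr(values, "time_step") <- time_step
  values
}

#' Pairwise Euclidean distances per frame
#'
#' @param frames T x A x 3 coordinate array (or a single A x 3 frame), in
#'   Angstrom.
#' @param pairs pair matrix from [enumerate_pairs()].
#' @param time_step frame spacing in ns (carried as an attribute).
#' @return T x P feature matrix of distances in Angstrom; column order
#'   matches the pair order.
#' @export
pairwise_distances <- function(frames, pairs, time_step = NA_real_) {
  frames <- as_frames(frames)
  n_atoms <- dim(frames)[2L]
  if (any(pairs < 1L) || any(pairs > n_atoms)) {
    stop_rptraj(
      sprintf("pair indices out of range [1, %d]", n_atoms),
      "rptraj_index_error"
    )
  }
  i <- pairs[, 1L]
  j <- pairs[, 2L]
  dx <- frames[, i, 1L, drop = FALSE] - frames[, j, 1L, drop = FALSE]
  dy <- frames[, i, 2L, drop = FALSE] - frames[, j, 2L, drop = FALSE]
  dz <- frames[, i, 3L, drop = FALSE] - frames[, j, 3L, drop = FALSE]
  d <- sqrt(dx^2 + dy^2 + dz^2)
  dim(d) <- c(dim(frames)[1L], nrow(pairs))
  feature_matrix(d, paste0("d_", i, "_", j), time_step)
}

#' Exponential contact features c = exp(-d / d0)
#'
#' Transforms pair distances into contact weights `c_ij = exp(-d_ij / d0)`,
#' with `d0` a characteristic length in Angstrom. Values lie in (0, 1];
#' coincident atoms give 1.
#'
#' @param distance_matrix distances from [pairwise_distances()].
#' @param d0 characteristic length in Angstrom (> 0). No canonical default
#'   exists, so it must always be given explicitly.
#' @return feature matrix of the same shape.
#' @export
exponential_contacts <- function(distance_matrix, d0) {
  if (!is.numeric(d0) || length(d0) != 1L || d0 <= 0) {
    stop_rptraj("d0 must be a single positive length (Angstrom)",
                "rptraj_parameter_error")
  }
  if (any(distance_matrix < 0)) {
    stop_rptraj("distances must be nonnegative", "rptraj_invalid_input")
  }
  out <- exp(-distance_matrix / d0)
  lbl <- colnames(distance_matrix)
  if (!is.null(lbl)) colnames(out) <- sub("^d_", "c_", lbl)
  attr(out, "time_step") <- attr(distance_matrix, "time_step")
  out
}

# Signed dihedral for four atom positions, vectorized over frames.
# p* are T x 3 matrices. IUPAC sign convention via the atan2 form.
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cross <- function(a, b) {
    cbind(
      a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
      a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
      a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
    )
  }
  n1 <- cross(b1, b2)
  n2 <- cross(b2, b3)
  m1 <- cross(n1, b2 / sqrt(rowSums(b2^2)))
  x <- rowSums(n1 * n2)
  y <- rowSums(m1 * n2)
  atan2(y, x)
}

wrap_angle <- function(theta) {
  ((theta + pi) %% (2 * pi)) - pi
}

#' Backbone dihedral features (phi/psi)
#'
#' Computes phi (C(i-1)-N(i)-CA(i)-C(i)) for residues 2..R and psi
#' (N(i)-CA(i)-C(i)-N(i+1)) for residues 1..R-1, in radians in \[-pi, pi).
#'
#' With `shifted = TRUE` each angle's branch cut is relocated to the centre
#' of the sparsest bin of a 36-bin circular histogram of that angle, which
#' removes periodic wrap artifacts when well-populated basins straddle
#' +/-pi (angles are then reported relative to the new cut, still spanning
#' an interval of width 2*pi).
#'
#' @param frames T x A x 3 coordinate array.
#' @param topology a [topology()]; every residue contributing to an angle
#'   must contain atoms N, CA and C.
#' @param shifted logical; apply the per-angle branch-cut shift.
#' @param time_step frame spacing in ns.
#' @return T x (2R - 2) feature matrix with columns `phi_2..phi_R`,
#'   `psi_1..psi_(R-1)`, in radians.
#' @export
backbone_dihedrals <- function(frames, topology, shifted = FALSE,
                               time_step = NA_real_) {
  frames <- as_frames(frames)
  res_ids <- sort(unique(topology$residue_index))
  atom_of <- function(res, name) {
    k <- which(topology$residue_index == res & topology$atom_name == name)
    if (length(k) != 1L) {
      stop_rptraj(
        sprintf("residue %d lacks a unique backbone atom '%s'", res, name),
        "rptraj_missing_atom"
      )
    }
    k
  }
  get_xyz <- function(k) frames[, k, , drop = TRUE]
  as_mat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1L)
  cols <- list()
  labels <- character(0)
  n_res <- length(res_ids)
  for (r in seq_len(n_res)[-1L]) {
    ri <- res_ids[r]; rp <- res_ids[r - 1L]
    cols[[length(cols) + 1L]] <- dihedral_angle(
      as_mat(get_xyz(atom_of(rp, "C"))),
      as_mat(get_xyz(atom_of(ri, "N"))),
      as_mat(get_xyz(atom_of(ri, "CA"))),
      as_mat(get_xyz(atom_of(ri, "C")))
    )
    labels <- c(labels, sprintf("phi_%d", ri))
  }
  for (r in seq_len(n_res - 1L)) {
    ri <- res_ids[r]; rn <- res_ids[r + 1L]
    cols[[length(cols) + 1L]] <- dihedral_angle(
      as_mat(get_xyz(atom_of(ri, "N"))),
      as_mat(get_xyz(atom_of(ri, "CA"))),
      as_mat(get_xyz(atom_of(ri, "C"))),
      as_mat(get_xyz(atom_of(rn, "N")))
    )
    labels <- c(labels, sprintf("psi_%d", ri))
  }
  values <- do.call(cbind, cols)
  if (shifted) {
    for (k in seq_len(ncol(values))) {
      values[, k] <- shift_branch_cut(values[, k])
    }
  }
  feature_matrix(values, labels, time_step)
}

# Relocate an angle column's branch cut to the centre of the sparsest bin
# of a 36-bin circular histogram (ties broken toward the first such bin).
shift_branch_cut <- function(theta, n_bins = 36L) {
  breaks <- seq(-pi, pi, length.out = n_bins + 1L)
  counts <- tabulate(findInterval(theta, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  sparsest <- which.min(counts)
  cut_at <- (breaks[sparsest] + breaks[sparsest + 1L]) / 2
  ((theta - cut_at) %% (2 * pi)) - pi
}

#' Rigid-body alignment to a reference plus coordinate flattening
#'
#' Each frame is superposed onto the reference conformation by the
#' least-squares (Kabsch) rotation + translation computed on the alignment
#' selection (proper rotations only, via [bio3d::fit.xyz]), then all atom
#' coordinates are flattened to 3A features per frame. A 577-atom structure
#' yields 1731 feature columns.
#'
#' @param frames T x A x 3 coordinate array.
#' @param reference A x 3 reference coordinates.
#' @param selection integer vector of atom indices used for the fit
#'   (at least 3 non-collinear atoms; default: all atoms).
#' @param time_step frame spacing in ns.
#' @return T x 3A feature matrix with columns `x_1, y_1, z_1, x_2, ...`.
#' @export
align_and_flatten <- function(frames, reference, selection = NULL,
                              time_step = NA_real_) {
  frames <- as_frames(frames)
  n_atoms <- dim(frames)[2L]
  stopifnot(nrow(reference) == n_atoms, ncol(reference) == 3L)
  selection <- selection %||% seq_len(n_atoms)
  if (length(selection) < 3L) {
    stop_rptraj("alignment needs at least 3 atoms", "rptraj_invalid_selection")
  }
  ref_sel <- reference[selection, , drop = FALSE]
  sv <- svd(scale(ref_sel, scale = FALSE))$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1)) {
    stop_rptraj("alignment selection is collinear", "rptraj_invalid_selection")
  }
  # bio3d xyz layout: frames as rows of (x1, y1, z1, x2, ...)
  traj_xyz <- t(apply(frames, 1L, function(fr) as.vector(t(fr))))
  if (dim(frames)[1L] == 1L) traj_xyz <- matrix(traj_xyz, nrow = 1L)
  ref_xyz <- as.vector(t(reference))
  xyz_inds <- bio3d::atom2xyz(selection)
  fitted <- bio3d::fit.xyz(
    fixed = ref_xyz, mobile = traj_xyz,
    fixed.inds = xyz_inds, mobile.inds = xyz_inds
  )
  fitted <- matrix(fitted, nrow = dim(frames)[1L])
  labels <- as.vector(t(outer(seq_len(n_atoms), c("x", "y", "z"),
                              function(i, a) paste0(a, "_", i))))
  feature_matrix(fitted, labels, time_step)
}

#' Root-mean-square deviation between a frame and a reference
#'
#' @param frame A x 3 coordinates.
#' @param reference A x 3 coordinates.
#' @param selection optional atom indices.
#' @return RMSD in Angstrom.
#' @export
rmsd_to_reference <- function(frame, reference, selection = NULL) {
  selection <- selection %||% seq_len(nrow(reference))
  d <- frame[selection, , drop = FALSE] - reference[selection, , drop = FALSE]
  sqrt(mean(rowSums(d^2)))
}
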
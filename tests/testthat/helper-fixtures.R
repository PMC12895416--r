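# Shared fixtures and independent oracles, built in code at test time.

# Independent stepwise dihedral oracle: recomputes the signed angle from
# explicit cross/dot products for a single 4-point geometry.
oracle_dihedral <- function(p) {
  cr <- function(a, b) {
    c(a[2] * b[3] - a[3] * b[2],
      a[3] * b[1] - a[1] * b[3],
      a[1] * b[2] - a[2] * b[1])
  }
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# Apply a rigid rotation (about z by theta) plus translation to every
# frame of a T x A x 3 array.
rigid_motion <- function(frames, theta = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3L, 3L, byrow = TRUE)
  out <- frames
  for (t in seq_len(dim(frames)[1L])) {
    out[t, , ] <- frames[t, , ] %*% t(R) +
      matrix(shift, nrow = dim(frames)[2L], ncol = 3L, byrow = TRUE)
  }
  out
}

# Build a frame-major array from a single A x 3 matrix.
one_frame <- function(coords) {
  array(coords, dim = c(1L, nrow(coords), 3L))
}

# Path to the bundled idealized alanine dipeptide (synthetic coordinates).
ala2_path <- function() {
  system.file("extdata", "ala2_synthetic.pdb", package = "rptraj")
}

# Write a temporary PDB from a topology + coordinates, return its path.
temp_pdb <- function(topology, coords) {
  path <- tempfile(fileext = ".pdb")
  write_structure(topology, coords, path)
  path
}
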
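test_that("read_structure parses ATOM records and flags heavy atoms", {
  s <- read_structure(ala2_path())
  expect_s3_class(s$topology, "topology")
  expect_equal(nrow(s$topology), 22L)
  expect_equal(sum(s$topology$heavy), 10L)
  expect_equal(length(unique(s$topology$residue_index)), 3L)
  expect_equal(dim(s$coords), c(22L, 3L))

  # minimal 2-atom structure round-trips through PDB
  topo <- topology(c("N", "CA"), c(1L, 1L))
  path <- temp_pdb(topo, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  s2 <- read_structure(path)
  expect_equal(nrow(s2$topology), 2L)
  expect_equal(length(unique(s2$topology$residue_index)), 1L)

  # generated 39-residue backbone exposes 117 N/CA/C atoms
  toy <- make_toy_protein(39L, c(1L, 1L), K = 1L, seed = 1L)
  path39 <- temp_pdb(toy$topology, toy$reference)
  s39 <- read_structure(path39)
  expect_equal(nrow(s39$topology), 117L)
  expect_equal(sum(s39$topology$atom_name %in% c("N", "CA", "C")), 117L)

  # a file with only HETATM records has no atoms to work with
  het <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"
  ), het)
  expect_error(read_structure(het), class = "rptraj_empty_input")
})

test_that("enumerate_pairs matches closed-form counts and orders pairs", {
  # C(k, 2) for k selected atoms at separation 0
  for (k in c(2L, 7L, 50L, 117L, 200L)) {
    topo <- topology(rep("CA", k), seq_len(k))
    p <- enumerate_pairs(topo, "calpha")
    expect_equal(nrow(p), choose(k, 2L))
    expect_true(all(p[, 1L] < p[, 2L]))
    # deterministic lexicographic order
    expect_true(all(diff(p[, 1L] * (k + 1) + p[, 2L]) > 0))
  }

  # residue-separation filter
  topo <- topology(rep("CA", 5L), 1:5)
  p3 <- enumerate_pairs(topo, "calpha", min_residue_separation = 3L)
  expect_equal(nrow(p3), 3L)  # (1,4), (1,5), (2,5)

  # empty selection names the selection
  no_ca <- topology(c("N", "C"), c(1L, 1L))
  expect_error(enumerate_pairs(no_ca, "calpha"), "calpha",
               class = "rptraj_empty_selection")
})

test_that("pairwise_distances agrees with direct per-pair computation", {
  # 3-4-5 triangle and coincident atoms
  coords <- rbind(c(0, 0, 0), c(3, 4, 0), c(0, 0, 0))
  topo <- topology(rep("CA", 3L), 1:3)
  d <- pairwise_distances(one_frame(coords), enumerate_pairs(topo, "calpha"))
  expect_equal(drop(d), c(d_1_2 = 5, d_1_3 = 0, d_2_3 = 5),
               ignore_attr = "time_step")

  # random 5-atom, 4-frame trajectory versus a brute-force loop
  set.seed(11)
  frames <- array(rnorm(4 * 5 * 3), dim = c(4L, 5L, 3L))
  pairs <- enumerate_pairs(topology(rep("CA", 5L), 1:5), "calpha")
  d <- pairwise_distances(frames, pairs)
  for (t in 1:4) {
    for (p in seq_len(nrow(pairs))) {
      expect_equal(
        d[t, p],
        sqrt(sum((frames[t, pairs[p, 1L], ] - frames[t, pairs[p, 2L], ])^2)),
        tolerance = 1e-12, ignore_attr = TRUE
      )
    }
  }

  expect_error(
    pairwise_distances(frames, matrix(c(1L, 9L), 1L)),
    class = "rptraj_index_error"
  )
})

test_that("exponential contacts follow c = exp(-d/d0) and reject bad d0", {
  d <- matrix(c(0, 2, 4, 10), 1L)
  expect_equal(drop(exponential_contacts(d, 2))[1], 1)
  expect_equal(drop(exponential_contacts(d, 2))[2], exp(-1))
  # monotonically decreasing in distance
  set.seed(4)
  dr <- matrix(sort(runif(20, 0, 30)), 1L)
  cc <- drop(exponential_contacts(dr, 1.7))
  expect_true(all(diff(cc) < 0))
  expect_true(all(cc > 0 & cc <= 1))
  expect_error(exponential_contacts(d, 0), class = "rptraj_parameter_error")
  expect_error(exponential_contacts(d, -1), class = "rptraj_parameter_error")
})

test_that("backbone dihedrals match the stepwise oracle and conventions", {
  topo2 <- topology(rep(c("N", "CA", "C"), 2L), rep(1:2, each = 3L))

  # planar cis arrangement of psi_1 atoms (N1, CA1, C1, N2) -> 0 rad
  base <- rbind(
    c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),   # N1 CA1 C1
    c(1, 1, 0), c(3, 1, 0), c(4, 1, 1)    # N2 CA2 C2
  )
  dih <- backbone_dihedrals(one_frame(base), topo2)
  expect_equal(dih[1, "psi_1"], 0, tolerance = 1e-12, ignore_attr = TRUE)

  # trans arrangement -> the +/- pi boundary
  trans <- base
  trans[4L, ] <- c(1, -1, 0)
  dih_t <- backbone_dihedrals(one_frame(trans), topo2)
  expect_equal(abs(dih_t[1, "psi_1"]), pi, tolerance = 1e-12,
               ignore_attr = TRUE)

  # random geometries agree with the independent stepwise oracle
  set.seed(21)
  toy <- make_toy_protein(6L, c(1L, 2L, 1L), K = 2L, jitter_sd = 0.3,
                          seed = 9L)
  dihs <- backbone_dihedrals(toy$frames, toy$topology)
  # phi_2 uses atoms C(res1), N(res2), CA(res2), C(res2) = atoms 3:6
  for (t in 1:3) {
    expect_equal(dihs[t, "phi_2"], oracle_dihedral(toy$frames[t, 3:6, ]),
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(dihs[t, "psi_1"], oracle_dihedral(toy$frames[t, c(1:3, 4), ]),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  # invariance under rigid motion of the whole frame
  dihs_moved <- backbone_dihedrals(rigid_motion(toy$frames), toy$topology)
  expect_equal(dihs, dihs_moved, tolerance = 1e-10)

  # missing backbone atom names the residue
  topo_bad <- topology(c("N", "CA", "C", "N", "CA"), c(1L, 1L, 1L, 2L, 2L))
  expect_error(
    backbone_dihedrals(one_frame(base[1:5, ]), topo_bad),
    "residue 2", class = "rptraj_missing_atom"
  )
})

test_that("shifted dihedrals move the branch cut away from populated basins", {
  # angles clustered at the +/- pi wrap: raw values are bimodal, shifted
  # values contiguous (much smaller spread)
  topo2 <- topology(rep(c("N", "CA", "C"), 2L), rep(1:2, each = 3L))
  set.seed(5)
  thetas <- pi + rnorm(200, sd = 0.2)   # near the cut
  frames <- array(NA_real_, dim = c(200L, 6L, 3L))
  for (t in seq_along(thetas)) {
    frames[t, , ] <- rbind(
      c(0, cos(0), sin(0)), c(0, 0, 0), c(1, 0, 0),
      c(1, -cos(thetas[t] - pi), sin(thetas[t] - pi)),
      c(3, 1, 0), c(4, 1, 1)
    )
  }
  raw <- backbone_dihedrals(frames, topo2)[, "psi_1"]
  shifted <- backbone_dihedrals(frames, topo2, shifted = TRUE)[, "psi_1"]
  expect_true(sd(shifted) < sd(raw) / 2)
  expect_true(all(shifted >= -pi & shifted < pi))
})

test_that("alignment recovers rigid motions and never increases RMSD", {
  toy <- make_toy_protein(10L, c(1L, 2L, 2L, 1L), K = 2L, seed = 3L)
  ref <- toy$reference

  # frame identical to reference: features equal reference coordinates
  flat <- align_and_flatten(one_frame(ref), ref)
  expect_equal(drop(flat), as.vector(t(ref)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(ncol(flat), 3L * nrow(ref))

  # rotated + translated reference is recovered exactly
  moved <- rigid_motion(one_frame(ref))
  rec <- align_and_flatten(moved, ref)
  expect_lt(max(abs(drop(rec) - as.vector(t(ref)))), 1e-8)

  # 577-atom structure flattens to 1731 columns
  set.seed(12)
  big <- matrix(rnorm(577 * 3), ncol = 3L)
  out <- align_and_flatten(one_frame(big + 0.1), big)
  expect_equal(ncol(out), 1731L)

  # alignment never increases RMSD to the reference
  for (t in seq_len(dim(toy$frames)[1L])) {
    before <- rmsd_to_reference(toy$frames[t, , ], ref)
    fitted <- align_and_flatten(toy$frames[t, , , drop = FALSE], ref)
    after <- rmsd_to_reference(matrix(fitted[1L, ], ncol = 3L, byrow = TRUE),
                               ref)
    expect_lte(after, before + 1e-10)
  }

  expect_error(align_and_flatten(one_frame(ref), ref, selection = 1:2),
               class = "rptraj_invalid_selection")
})

test_that("contact features are invariant under rigid motion", {
  toy <- make_toy_protein(8L, c(1L, 2L), K = 2L, seed = 6L)
  pairs <- enumerate_pairs(toy$topology, "backbone")
  c1 <- exponential_contacts(pairwise_distances(toy$frames, pairs), 1.0)
  c2 <- exponential_contacts(
    pairwise_distances(rigid_motion(toy$frames), pairs), 1.0
  )
  expect_equal(c1, c2, tolerance = 1e-10)
})
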
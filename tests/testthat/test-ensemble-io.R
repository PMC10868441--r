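# Reading, writing and reduced representations of conformer ensembles.

test_that("single-model PDB reads as a degenerate one-conformer ensemble", {
  f <- withr::local_tempfile(fileext = ".pdb")
  conf <- build_backbone("AGT", runif(3, -pi, pi), runif(3, -pi, pi))
  write_ensemble(new_ensemble(attr(conf, "atoms"), conf), f)
  ens <- read_ensemble(f)
  expect_equal(n_conformers(ens), 1)
  expect_equal(ens$weights, 1)
  expect_equal(ens$sequence, "AGT")
})

test_that("weights sidecar is normalized on load and round-trips", {
  set.seed(1)
  ens <- random_ca_ensemble(3, 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  wf <- paste0(f, ".weights")
  write_ensemble(ens, f)
  writeLines(c("# relative populations", "2 1 1"), wf)
  back <- read_ensemble(f, weights_path = wf)
  expect_equal(back$weights, c(0.5, 0.25, 0.25))
  expect_lt(abs(sum(back$weights) - 1), 1e-12)

  ens2 <- random_ca_ensemble(2, 5, weights = c(0.7, 0.3))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens2, f2)                 # sidecar written automatically
  back2 <- read_ensemble(f2)
  expect_equal(back2$weights, c(0.7, 0.3), tolerance = 1e-9)
})

test_that("round trip preserves coordinates and author residue numbering", {
  set.seed(2)
  coords <- array(0, dim = c(2, 6, 3))
  for (c in 1:2) coords[c, , ] <- random_trace(6)
  ens <- ca_ensemble(coords, resno = 188:193)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  back <- read_ensemble(f)
  expect_equal(back$atoms$resno[1], 188)
  expect_equal(ca_trace(back)$coords, ens$xyz, tolerance = 1e-3)
  expect_equal(ca_trace(back)$resno, 188:193)
})

test_that("models with mismatched atom counts are rejected by name", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, f)
  expect_error(read_ensemble(f), "model 2")
})

test_that("weight-file errors are caught", {
  set.seed(3)
  ens <- random_ca_ensemble(3, 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble(ens, f)
  wf <- withr::local_tempfile()
  writeLines("1 2", wf)
  expect_error(read_ensemble(f, weights_path = wf), "weights count")
  writeLines("0 0 0", wf)
  expect_error(read_ensemble(f, weights_path = wf), "all-zero")
})

test_that("ca_trace extracts CA positions and flags missing CA", {
  p <- matrix(c(1.2, -0.4, 2.2), 1, 3)
  ens <- ca_ensemble(p)
  tr <- ca_trace(ens)
  expect_equal(dim(tr$coords), c(1, 1, 3))
  expect_equal(tr$coords[1, 1, ], p[1, ])

  atoms <- data.frame(resno = c(1, 2), resid = "ALA",
                      elety = c("CA", "N"), element = c("C", "N"),
                      het = FALSE)
  bad <- new_ensemble(atoms, matrix(rnorm(6), 2, 3))
  expect_error(ca_trace(bad), "residue 2")
})

test_that("internal CA distances are invariant under rigid motion", {
  set.seed(4)
  base <- random_trace(7)
  coords <- array(0, dim = c(3, 7, 3))
  coords[1, , ] <- base
  for (c in 2:3) coords[c, , ] <- apply_rigid(base, random_rigid())
  tr <- ca_trace(ca_ensemble(coords))
  d1 <- dist(matrix(tr$coords[1, , ], 7, 3))
  for (c in 2:3) {
    expect_false(isTRUE(all.equal(tr$coords[c, , ], tr$coords[1, , ])))
    expect_equal(as.numeric(dist(matrix(tr$coords[c, , ], 7, 3))),
                 as.numeric(d1), tolerance = 1e-9)
  }
})

test_that("build/measure dihedral round trip is exact to 1e-6 rad", {
  set.seed(5)
  for (rep in 1:3) {
    n <- sample(4:9, 1)
    phi <- runif(n, -pi, pi)
    psi <- runif(n, -pi, pi)
    conf <- build_backbone(paste(rep("A", n), collapse = ""), phi, psi)
    ens <- new_ensemble(attr(conf, "atoms"), conf)
    dh <- backbone_dihedrals(ens)
    expect_equal(dh$phi[1, 2:n], phi[2:n], tolerance = 1e-6)
    expect_equal(dh$psi[1, 1:(n - 1)], psi[1:(n - 1)], tolerance = 1e-6)
    # constant (-60, -45) chain as a fixed reference case
  }
  conf <- build_backbone("AAAA", rep(-60 * pi / 180, 4),
                         rep(-45 * pi / 180, 4))
  dh <- backbone_dihedrals(new_ensemble(attr(conf, "atoms"), conf))
  expect_equal(dh$phi[1, 2:4], rep(-60 * pi / 180, 3), tolerance = 1e-6)
})

test_that("dihedral conventions: termini undefined, mirror negates", {
  conf <- build_backbone("AA", c(0.3, -1.1), c(2.0, 0.4))
  ens <- new_ensemble(attr(conf, "atoms"), conf)
  dh <- backbone_dihedrals(ens)
  expect_true(is.na(dh$phi[1, 1]))
  expect_false(is.na(dh$phi[1, 2]))
  expect_false(is.na(dh$psi[1, 1]))
  expect_true(is.na(dh$psi[1, 2]))

  mir <- conf
  mir[, 1] <- -mir[, 1]
  dhm <- backbone_dihedrals(new_ensemble(attr(conf, "atoms"), mir))
  expect_equal(dhm$phi[1, 2], -dh$phi[1, 2], tolerance = 1e-9)
  expect_equal(dhm$psi[1, 1], -dh$psi[1, 1], tolerance = 1e-9)
})

test_that("dihedral signs agree with the bio3d torsion convention", {
  set.seed(6)
  conf <- build_backbone("AAAA", runif(4, -pi, pi), runif(4, -pi, pi))
  bb <- conf[rep(0:3 * 4, each = 3) + c(1, 2, 3), ]  # N, CA, C only
  tor <- bio3d::torsion.xyz(as.numeric(t(bb)), atm.inc = 1)
  dh <- backbone_dihedrals(new_ensemble(attr(conf, "atoms"), conf))
  # bio3d indexes torsions by their second atom: phi_2 is tor[4] (C1,N2,CA2,C2)
  expect_equal(dh$phi[1, 2] * 180 / pi, tor[4], tolerance = 1e-4)
  expect_equal(dh$psi[1, 2] * 180 / pi, tor[5], tolerance = 1e-4)
  expect_equal(dh$phi[1, 3] * 180 / pi, tor[7], tolerance = 1e-4)
})

test_that("chain breaks flag spanning dihedrals as undefined", {
  conf <- build_backbone("AAAA", runif(4, -pi, pi), runif(4, -pi, pi))
  broken <- conf
  broken[9:16, ] <- broken[9:16, ] + 25      # displace residues 3-4
  expect_warning(
    dh <- backbone_dihedrals(new_ensemble(attr(conf, "atoms"), broken)),
    "chain break")
  expect_true(is.na(dh$psi[1, 2]))   # psi_2 spans the 2|3 bond
  expect_true(is.na(dh$phi[1, 3]))
  expect_false(is.na(dh$phi[1, 4]))  # residues 3-4 are intact again
})

test_that("unknown elements error instead of silently getting zero mass", {
  expect_error(element_mass("XX"), "unknown element")
  expect_equal(element_mass(c("C", "N")), c(12.011, 14.007))
})
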
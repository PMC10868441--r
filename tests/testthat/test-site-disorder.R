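# Site-specific order (bond-vector correlations) and flexibility profiles.

test_that("bond vectors are unit length and reflect trace geometry", {
  col <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(7.6, 0, 0))
  v <- bond_vectors(ca_ensemble(col) |> ca_trace())
  expect_equal(v[1, 1, ], v[1, 2, ])
  ra <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(3.8, 3.8, 0))
  vr <- bond_vectors(ca_trace(ca_ensemble(ra)))
  expect_equal(sum(vr[1, 1, ] * vr[1, 2, ]), 0, tolerance = 1e-12)
  set.seed(20)
  ens <- generate_ensemble("AGAGA", 3, seed = 21)
  vg <- bond_vectors(ca_trace(ens))
  expect_equal(as.numeric(sqrt(vg[, , 1]^2 + vg[, , 2]^2 + vg[, , 3]^2)),
               rep(1, 3 * 4), tolerance = 1e-12)
  expect_error(bond_vectors(ca_ensemble(rbind(c(0, 0, 0), c(0, 0, 0)))),
               "zero-length")
})

test_that("pair correlation hits its analytic endpoints", {
  # identical conformers: sigma = 0, K = 1 everywhere
  set.seed(22)
  base <- random_trace(6)
  coords <- array(rep(base, each = 4), dim = c(4, 6, 3))
  K <- pair_correlation(bond_vectors(ca_trace(ca_ensemble(coords))))
  expect_equal(as.numeric(K), rep(1, 25), tolerance = 1e-9)

  # theta uniform on [0, pi]: var(cos) = 1/2, so K -> 0 (closed form)
  n <- 4000
  theta <- (seq_len(n) - 0.5) * pi / n
  vecs <- array(0, dim = c(n, 2, 3))
  vecs[, 1, 1] <- 1
  vecs[, 2, 1] <- cos(theta); vecs[, 2, 2] <- sin(theta)
  K2 <- pair_correlation(vecs)
  expect_equal(K2[1, 2], 0, tolerance = 1e-3)

  # antipodal two-conformer case: sigma^2 = 1, K clipped at 0
  vecs3 <- array(0, dim = c(2, 2, 3))
  vecs3[, 1, 1] <- 1
  vecs3[1, 2, 1] <- 1; vecs3[2, 2, 1] <- -1
  K3 <- pair_correlation(vecs3, weights = c(0.5, 0.5))
  expect_equal(K3[1, 2], 0)

  # independent isotropic vectors: K -> 1 - sqrt(2/3)
  set.seed(23)
  n <- 6000
  vi <- array(rnorm(n * 2 * 3), dim = c(n, 2, 3))
  len <- sqrt(vi[, , 1]^2 + vi[, , 2]^2 + vi[, , 3]^2)
  for (d in 1:3) vi[, , d] <- vi[, , d] / len
  Ki <- pair_correlation(vi)
  expect_equal(Ki[1, 2], 1 - sqrt(2 / 3), tolerance = 0.02)
})

test_that("order parameter is 1 for rigid ensembles and averages K rows", {
  set.seed(24)
  base <- random_trace(8)
  coords <- array(0, dim = c(3, 8, 3))
  for (c in 1:3) coords[c, , ] <- apply_rigid(base, random_rigid())
  op <- order_parameter(ca_ensemble(coords))
  expect_equal(op$o, rep(1, 7), tolerance = 1e-9)

  K <- matrix(0.3, 4, 4); diag(K) <- 1
  expect_equal(order_parameter(K)$o, rep((1 + 3 * 0.3) / 4, 4))
})

test_that("circular resultant endpoints and NA handling", {
  expect_equal(circular_resultant(rep(1.1, 5)), 1, tolerance = 1e-12)
  expect_equal(circular_resultant(c(0, pi), c(0.5, 0.5)), 0,
               tolerance = 1e-12)
  set.seed(25)
  expect_lt(circular_resultant(runif(20000, -pi, pi)), 0.02)
  expect_equal(circular_resultant(c(NA, 0.7, 0.7)), 1, tolerance = 1e-12)
  expect_true(is.na(circular_resultant(c(NA_real_, NA_real_))))
})

test_that("flexibility endpoints: rigid 0, uniform 1, termini partial", {
  C <- 6; N <- 5
  mk <- function(phi, psi) structure(
    list(phi = phi, psi = psi, resno = seq_len(N),
         sequence = paste(rep("A", N), collapse = ""), weights = NULL),
    class = "dihedral_set")
  phi <- matrix(rep(runif(N, -pi, pi), each = C), C, N); phi[, 1] <- NA
  psi <- matrix(rep(runif(N, -pi, pi), each = C), C, N); psi[, N] <- NA
  fp <- flexibility(mk(phi, psi))
  expect_equal(fp$f, rep(0, N), tolerance = 1e-12)
  expect_true(fp$partial[1] && fp$partial[N])
  expect_false(any(fp$partial[2:(N - 1)]))

  set.seed(26)
  Cu <- 20000
  phiu <- matrix(runif(Cu * N, -pi, pi), Cu, N); phiu[, 1] <- NA
  psiu <- matrix(runif(Cu * N, -pi, pi), Cu, N); psiu[, N] <- NA
  fu <- flexibility(structure(
    list(phi = phiu, psi = psiu, resno = seq_len(N),
         sequence = paste(rep("A", N), collapse = ""), weights = NULL),
    class = "dihedral_set"))
  expect_gt(min(fu$f), 0.98)
})

test_that("order and flexibility are invariant under conformer duplication", {
  ens <- generate_ensemble("QGPTSYA", 8, seed = 27)
  dup <- new_ensemble(ens$atoms, ens$xyz[rep(1:8, 2), , ],
                      weights = rep(ens$weights / 2, 2))
  o1 <- order_parameter(ens)$o
  o2 <- order_parameter(dup)$o
  expect_equal(o1, o2, tolerance = 1e-12)
  f1 <- flexibility(backbone_dihedrals(ens))$f
  f2 <- flexibility(backbone_dihedrals(dup))$f
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("order and flexibility are invariant under per-conformer rigid motion", {
  set.seed(28)
  ens <- generate_ensemble("QGSTA", 5, seed = 29)
  moved <- ens
  for (c in 1:5) {
    rt <- random_rigid()
    moved$xyz[c, , ] <- apply_rigid(matrix(ens$xyz[c, , ], 20, 3), rt)
  }
  expect_equal(order_parameter(moved)$o, order_parameter(ens)$o,
               tolerance = 1e-9)
  expect_equal(flexibility(backbone_dihedrals(moved))$f,
               flexibility(backbone_dihedrals(ens))$f, tolerance = 1e-9)
})

test_that("random-coil reference bands are deterministic and class-ordered", {
  ref1 <- random_coil_reference(sequence_length = 68, C = 150, seed = 30)
  ref2 <- random_coil_reference(sequence_length = 68, C = 150, seed = 30)
  expect_identical(ref1, ref2)
  fc <- ref1$f_class
  expect_gt(fc$lower[fc$class == "Gly"], fc$upper[fc$class == "other"])
  expect_warning(random_coil_reference(sequence_length = 40, C = 50,
                                       seed = 1), "noisy")
})
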
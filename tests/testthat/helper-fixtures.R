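# Fixtures and independent oracles shared across the suite.

# random CA trace with realistic consecutive spacing
random_trace <- function(n, spread = 3.8) {
  steps <- matrix(rnorm(3 * (n - 1)), n - 1, 3)
  steps <- steps / sqrt(rowSums(steps^2)) * spread
  apply(rbind(c(0, 0, 0), steps), 2, cumsum)
}

random_ca_ensemble <- function(C, N, weights = NULL, label = "rand") {
  coords <- array(0, dim = c(C, N, 3))
  for (c in seq_len(C)) coords[c, , ] <- random_trace(N)
  ca_ensemble(coords, weights = weights, label = label)
}

# rigid motion: random proper rotation + translation
random_rigid <- function() {
  A <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(A)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 10))
}

apply_rigid <- function(m, rt) sweep(m %*% rt$R, 2, rt$t, "+")

# --- conformer-space oracles -----------------------------------------------

# Euclidean embedding of a conformer: scaled internal-distance vector
embed_conformer <- function(trace) {
  d <- as.numeric(dist(trace))
  d / sqrt(length(d))
}

# brute-force Delta_kl by the double loop over conformer pairs
delta_oracle <- function(traces_k, w_k, traces_l, w_l) {
  tot <- 0
  for (a in seq_along(traces_k)) for (b in seq_along(traces_l)) {
    u <- embed_conformer(traces_k[[a]])
    v <- embed_conformer(traces_l[[b]])
    tot <- tot + w_k[a] * w_l[b] * sum((u - v)^2)
  }
  tot
}

# weighted mean embedded point of an ensemble
mean_embedding <- function(traces, w) {
  U <- sapply(traces, embed_conformer)
  as.numeric(U %*% w)
}

trace_list <- function(ens) {
  tr <- ca_trace(ens)
  lapply(seq_len(dim(tr$coords)[1]), function(c)
    matrix(tr$coords[c, , ], dim(tr$coords)[2], 3))
}

# --- shared coil ensemble for the heavier statistical checks ----------------

.fixture_env <- new.env()

coil_fixture <- function() {
  if (is.null(.fixture_env$coil)) {
    .fixture_env$coil <- generate_ensemble(
      coil_reference_sequence(267), n_conformers = 1000, seed = 20260920)
  }
  .fixture_env$coil
}

# backbone ensemble with one charged side-chain atom appended per conformer
lysine_probe_ensemble <- function() {
  conf <- build_backbone("GKG", rep(-1.2, 3), rep(2.4, 3))
  atoms <- attr(conf, "atoms")
  # append an NZ atom to the lysine (residue 2), displaced from its CA
  nz <- conf[6, ] + c(0, 0, 4)
  atoms <- rbind(atoms, data.frame(resno = 2, resid = "LYS", elety = "NZ",
                                   element = "N", het = FALSE))
  xyz <- rbind(conf, nz)
  ord <- order(atoms$resno)   # keep residues contiguous and ascending
  new_ensemble(atoms[ord, ], xyz[ord, ], label = "lys-probe")
}
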
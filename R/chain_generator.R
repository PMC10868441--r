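# Monte-Carlo backbone generator: residue-type-specific Ramachandran
# sampling, ideal-geometry chain building, optional excluded-volume and
# distance-restraint rejection, and synthetic PAE matrices.

# ideal trans-peptide geometry (Angstrom / degrees)
.geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.0, ang_ca_c_n = 116.6,
  ang_ca_c_o = 120.8, omega = 180
)

#' Default residue-class Ramachandran library
#'
#' A compact stand-in for residue-specific random-coil Ramachandran
#' statistics: each flexibility class (Gly, Pro, Thr, general) is a mixture
#' of 2-D wrapped-Gaussian basins over (phi, psi).  The general class mixes
#' beta, polyproline-II, alpha-R and a small alpha-L basin; Pro is
#' restricted to phi near -65 deg with a polyproline-II-dominated psi; Thr
#' is restricted to phi < 0 (Ramachandran quadrants II and III); Gly adds
#' mirrored basins with positive phi.  Basin weights were chosen so that an
#' unrestrained coil reproduces published random-coil flexibility
#' statistics per class.
#'
#' @return object of class `ramachandran_library`: named list of classes,
#'   each with `weights`, `centers` (basins x 2 matrix, degrees) and
#'   `sigma` (basins x 2, degrees).
#' @export
default_ramachandran_library <- function() {
  basin <- function(w, centers, sigma) {
    list(weights = w / sum(w),
         centers = matrix(centers, ncol = 2, byrow = TRUE),
         sigma = matrix(sigma, ncol = 2, byrow = TRUE))
  }
  lib <- list(
    general = basin(
      w = c(0.42, 0.33, 0.21, 0.04),
      centers = c(-135, 135,    # beta
                  -75, 150,     # PPII
                  -65, -45,     # alpha-R
                  55, 45),      # alpha-L
      sigma = c(25, 25, 20, 20, 15, 15, 15, 15)),
    Pro = basin(
      w = c(0.77, 0.23),
      centers = c(-65, 150,     # PPII
                  -65, -30),    # alpha-like
      sigma = c(10, 20, 10, 15)),
    Thr = basin(
      w = c(0.40, 0.35, 0.25),
      centers = c(-120, 140,    # beta (quadrant II)
                  -75, 145,     # PPII (quadrant II)
                  -65, -45),    # alpha-R (quadrant III)
      sigma = c(20, 20, 18, 18, 15, 15)),
    Gly = basin(
      w = c(0.34, 0.20, 0.16, 0.09, 0.15, 0.06),
      centers = c(-90, 160,
                  -90, -10,
                  -90, -160,
                  90, -160,
                  90, 10,
                  90, 160),
      sigma = c(30, 30, 30, 30, 30, 30, 30, 30, 30, 30, 30, 30))
  )
  structure(lib, class = "ramachandran_library")
}

.wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a <= -pi] <- pi
  a
}

#' Sample backbone dihedrals from a residue-class Ramachandran distribution
#'
#' Draws a basin by weight, then a wrapped-Gaussian (phi, psi) pair within
#' the basin.  Uses the current RNG state.
#'
#' @param residue_class one of the library class names ("Gly", "Pro",
#'   "Thr", "general"); unknown classes fall back to "general" with a
#'   warning.
#' @param n number of draws.
#' @param library a `ramachandran_library`.
#' @return n x 2 matrix of (phi, psi) in radians, in (-pi, pi].
#' @export
sample_ramachandran <- function(residue_class, n = 1,
                                library = default_ramachandran_library()) {
  if (residue_class == "other") residue_class <- "general"
  if (!residue_class %in% names(library)) {
    warning("unknown residue class '", residue_class,
            "'; using the general library")
    residue_class <- "general"
  }
  cl <- library[[residue_class]]
  nb <- length(cl$weights)
  b <- sample.int(nb, n, replace = TRUE, prob = cl$weights)
  deg <- pi / 180
  phi <- rnorm(n, cl$centers[b, 1] * deg, cl$sigma[b, 1] * deg)
  psi <- rnorm(n, cl$centers[b, 2] * deg, cl$sigma[b, 2] * deg)
  cbind(phi = .wrap_angle(phi), psi = .wrap_angle(psi))
}

# place atom d given a-b-c, bond |cd|, angle b-c-d (rad), torsion a-b-c-d
# (rad); standard internal-to-Cartesian (NeRF) step
.place_atom <- function(a, b, c, bond, angle, torsion) {
  bc <- c - b
  bc <- bc / sqrt(sum(bc * bc))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n * n))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle), bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Build a backbone conformer from prescribed dihedrals
#'
#' Places N, CA, C and O atoms for every residue with ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A), ideal angles, and omega = 180 deg
#' (trans).  phi of residue 1 and psi of the last residue do not affect the
#' backbone (psi of the last residue still orients its carbonyl O).
#'
#' @param sequence 1-letter amino-acid string.
#' @param phi,psi numeric vectors (radians), one per residue.
#' @return A x 3 coordinate matrix (A = 4 N atoms) with attribute `atoms`,
#'   the matching atom table.
#' @export
build_backbone <- function(sequence, phi, psi) {
  aa <- strsplit(sequence, "")[[1]]
  N <- length(aa)
  stopifnot(length(phi) == N, length(psi) == N)
  g <- .geom
  deg <- pi / 180
  xyz <- matrix(0, 4 * N, 3)
  # residue i atom rows: N = 4i-3, CA = 4i-2, C = 4i-1, O = 4i
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(g$b_n_ca, 0, 0)
  th <- g$ang_n_ca_c * deg
  xyz[3, ] <- xyz[2, ] + g$b_ca_c * c(-cos(th), sin(th), 0)
  xyz[4, ] <- .place_atom(xyz[1, ], xyz[2, ], xyz[3, ], g$b_c_o,
                          g$ang_ca_c_o * deg, psi[1] - pi)
  if (N > 1) {
    for (i in 2:N) {
      r <- 4 * (i - 1)
      xyz[r + 1, ] <- .place_atom(xyz[r - 3, ], xyz[r - 2, ], xyz[r - 1, ],
                                  g$b_c_n, g$ang_ca_c_n * deg, psi[i - 1])
      xyz[r + 2, ] <- .place_atom(xyz[r - 2, ], xyz[r - 1, ], xyz[r + 1, ],
                                  g$b_n_ca, g$ang_c_n_ca * deg,
                                  g$omega * deg)
      xyz[r + 3, ] <- .place_atom(xyz[r - 1, ], xyz[r + 1, ], xyz[r + 2, ],
                                  g$b_ca_c, g$ang_n_ca_c * deg, phi[i])
      xyz[r + 4, ] <- .place_atom(xyz[r + 1, ], xyz[r + 2, ], xyz[r + 3, ],
                                  g$b_c_o, g$ang_ca_c_o * deg, psi[i] - pi)
    }
  }
  resid3 <- suppressWarnings(bio3d::aa123(aa))
  resid3[is.na(resid3)] <- "UNK"
  atoms <- data.frame(resno = rep(seq_len(N), each = 4),
                      resid = rep(resid3, each = 4),
                      elety = rep(c("N", "CA", "C", "O"), N),
                      element = rep(c("N", "C", "C", "O"), N),
                      het = FALSE)
  attr(xyz, "atoms") <- atoms
  xyz
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# restraint acceptance probability: min(1, p(r) / (max(p) * a))
.restraint_accept_prob <- function(restraint, r) {
  p <- stats::approx(restraint$r, restraint$p, xout = r, yleft = 0,
                     yright = 0)$y
  min(1, p / (max(restraint$p) * restraint$acceptance_fraction))
}

#' Generate an unrestrained or restrained backbone ensemble
#'
#' Monte-Carlo construction of `n_conformers` backbone conformers of
#' `sequence`: per-residue (phi, psi) pairs are drawn from the
#' residue-class Ramachandran library and the chain is built with ideal
#' trans-peptide geometry.  With `clash_mode = "ca_excluded_volume"`,
#' conformers with any Calpha pair (|i - j| >= 3) closer than
#' `ca_clash_distance` are rejected and resampled (whole-conformer
#' restart).  Distance restraints are applied by von Neumann rejection: a
#' conformer is accepted with probability min(1, p(r) / (max(p) a)), where
#' p is the restraint distance histogram evaluated at the conformer's
#' Calpha-Calpha distance and a the configured acceptance fraction.
#'
#' @param sequence 1-letter amino-acid string.
#' @param n_conformers number of accepted conformers (uniform weights).
#' @param seed RNG seed for reproducible ensembles (the global RNG state is
#'   restored afterwards).
#' @param library a `ramachandran_library`.
#' @param clash_mode "off" (default) or "ca_excluded_volume".
#' @param ca_clash_distance Calpha excluded-volume diameter in Angstrom
#'   (default 4.0; pairs with |i - j| >= 3 are checked).
#' @param restraints optional list of restraints, each a list with residue
#'   indices `i`, `j`, histogram support `r` (Angstrom) and densities `p`,
#'   and `acceptance_fraction`.
#' @param max_restarts_per_conformer sampling attempts allowed per accepted
#'   conformer before an acceptance-starvation error (default 1000).
#' @param label ensemble label.
#' @return an `ensemble` with N/CA/C/O backbone atoms and uniform weights.
#' @export
generate_ensemble <- function(sequence, n_conformers, seed = NULL,
                              library = default_ramachandran_library(),
                              clash_mode = c("off", "ca_excluded_volume"),
                              ca_clash_distance = 4.0, restraints = NULL,
                              max_restarts_per_conformer = 1000,
                              label = "generated") {
  clash_mode <- match.arg(clash_mode)
  stopifnot(n_conformers >= 1, ca_clash_distance > 0)
  aa <- strsplit(sequence, "")[[1]]
  N <- length(aa)
  classes <- residue_class(aa)
  class_idx <- split(seq_len(N), classes)

  .with_seed(seed, {
    A <- 4 * N
    xyz <- array(NA_real_, dim = c(n_conformers, A, 3))
    atoms <- NULL
    attempts <- 0L
    ca_rows <- 4 * seq_len(N) - 2
    far <- abs(outer(seq_len(N), seq_len(N), "-")) >= 3
    for (c in seq_len(n_conformers)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_restarts_per_conformer)
          stop("acceptance starvation: ", max_restarts_per_conformer,
               " restarts without an accepted conformer (overall ",
               "acceptance rate ",
               signif(c / (attempts + tries), 3), ")")
        phi <- numeric(N); psi <- numeric(N)
        for (cl in names(class_idx)) {
          idx <- class_idx[[cl]]
          ang <- sample_ramachandran(cl, length(idx), library)
          phi[idx] <- ang[, 1]; psi[idx] <- ang[, 2]
        }
        conf <- build_backbone(sequence, phi, psi)
        if (clash_mode == "ca_excluded_volume" && N >= 4) {
          ca <- conf[ca_rows, , drop = FALSE]
          d <- as.matrix(stats::dist(ca))
          if (any(d[far] < ca_clash_distance)) next
        }
        ok <- TRUE
        if (!is.null(restraints)) {
          ca <- conf[ca_rows, , drop = FALSE]
          for (rs in restraints) {
            r <- sqrt(sum((ca[rs$i, ] - ca[rs$j, ])^2))
            if (runif(1) > .restraint_accept_prob(rs, r)) { ok <- FALSE; break }
          }
        }
        if (ok) {
          if (is.null(atoms)) atoms <- attr(conf, "atoms")
          xyz[c, , ] <- conf
          attempts <- attempts + tries
          break
        }
      }
    }
    new_ensemble(atoms, xyz, rep(1 / n_conformers, n_conformers),
                 label = label)
  })
}

#' Deterministic QGSY-rich reference sequence
#'
#' A fixed low-complexity sequence emulating the composition of a
#' QGSY-rich prion-like N-terminal IDP domain (rich in Gln, Gly, Ser and
#' Tyr, with some Thr and Pro so that all four flexibility classes are
#' represented).  Used as the default random-coil reference chain.
#'
#' @param n sequence length (default 267).
#' @return 1-letter string of length `n`.
#' @export
coil_reference_sequence <- function(n = 267) {
  unit <- "QGSYGQSQSGYGQPSQTGYGQSSYGQQSSYGGQT"  # 34-residue repeat
  paste(rep(strsplit(unit, "")[[1]], length.out = n), collapse = "")
}

#' Synthetic PAE matrix with planted folded-domain blocks
#'
#' Builds an N x N PAE-like matrix: pairs within a planted domain score
#' `within` + noise, all other pairs `between` + noise; pairs with
#' |i - j| < `band_halfwidth` are ramped linearly from 0 at the diagonal
#' toward the background (the near-diagonal PAE is low even in disordered
#' proteins); the result is symmetrized and clipped to \[0, cap\].
#'
#' @param N chain length.
#' @param domains list of c(start, end) 1-based inclusive intervals (must
#'   not overlap).
#' @param within,between PAE levels (Angstrom) inside / outside domains
#'   (defaults 4 and 22).
#' @param band_halfwidth near-diagonal ramp width in residues (default 10).
#' @param noise_sd Gaussian noise sd in Angstrom (default 1).
#' @param seed RNG seed.
#' @param cap PAE cap (default 31.75).
#' @return a `pae_matrix`.
#' @export
synthetic_pae <- function(N, domains = list(), within = 4, between = 22,
                          band_halfwidth = 10, noise_sd = 1, seed = NULL,
                          cap = PAE_CAP) {
  if (length(domains) > 1) {
    iv <- domains[order(vapply(domains, `[`, numeric(1), 1))]
    for (k in seq_len(length(iv) - 1))
      if (iv[[k + 1]][1] <= iv[[k]][2])
        stop("planted domain intervals overlap")
  }
  for (d in domains)
    if (d[1] < 1 || d[2] > N || d[1] > d[2])
      stop("domain interval out of range")
  .with_seed(seed, {
    M <- matrix(between, N, N)
    for (d in domains) {
      idx <- d[1]:d[2]
      M[idx, idx] <- within
    }
    M <- M + matrix(rnorm(N * N, 0, noise_sd), N, N)
    sep <- abs(outer(seq_len(N), seq_len(N), "-"))
    band <- sep < band_halfwidth
    M[band] <- M[band] * sep[band] / band_halfwidth
    M <- (M + t(M)) / 2
    M[M < 0] <- 0
    M[M > cap] <- cap
    structure(list(values = M, cap = cap), class = "pae_matrix")
  })
}
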
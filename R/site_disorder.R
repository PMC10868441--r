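# Site-specific order (bond-vector correlations) and Ramachandran
# flexibility (circular variance of backbone dihedrals).

#' Unit C-alpha to C-alpha bond vectors of a trace
#'
#' @param trace a `ca_trace` (or C x N x 3 array) with N >= 2 residues.
#' @return C x (N-1) x 3 array of unit vectors r_{i,i+1}.
#' @export
bond_vectors <- function(trace) {
  if (inherits(trace, "ensemble")) trace <- ca_trace(trace)
  coords <- if (inherits(trace, "ca_trace")) trace$coords else trace
  stopifnot(length(dim(coords)) == 3)
  N <- dim(coords)[2]
  if (N < 2) stop("need at least 2 residues")
  v <- coords[, -1, , drop = FALSE] - coords[, -N, , drop = FALSE]
  len <- sqrt(v[, , 1]^2 + v[, , 2]^2 + v[, , 3]^2)
  if (any(len < 1e-12)) stop("zero-length bond vector")
  for (d in 1:3) v[, , d] <- v[, , d] / len
  v
}

#' Site-pair correlation matrix K of bond-vector orientations
#'
#' For every pair of bond vectors (i, j) the ensemble variance sigma^2_ij of
#' cos(theta_ij) is computed with conformer weights.  The correlation
#' parameter is K_ij = 1 - sqrt(2) sigma_ij, clipped to \[0, 1\]: it is 1 if
#' theta_ij is identical in all conformers and approaches 0 for uniformly
#' distributed theta_ij (where sigma^2 -> 1/2).
#'
#' @param vectors C x Nv x 3 array of unit bond vectors ([bond_vectors()]).
#' @param weights normalized conformer weights.
#' @return Nv x Nv symmetric matrix K with unit diagonal.
#' @export
pair_correlation <- function(vectors, weights = NULL) {
  C <- dim(vectors)[1]; Nv <- dim(vectors)[2]
  weights <- normalize_weights(if (is.null(weights)) rep(1, C) else weights, C)
  # two-pass weighted variance of cos(theta): avoids the cancellation of
  # E[x^2] - E[x]^2 for nearly rigid ensembles
  m1 <- matrix(0, Nv, Nv)
  for (c in seq_len(C)) {
    V <- matrix(vectors[c, , ], Nv, 3)
    m1 <- m1 + weights[c] * tcrossprod(V)
  }
  sig2 <- matrix(0, Nv, Nv)
  for (c in seq_len(C)) {
    V <- matrix(vectors[c, , ], Nv, 3)
    sig2 <- sig2 + weights[c] * (tcrossprod(V) - m1)^2
  }
  K <- 1 - sqrt(2) * sqrt(sig2)
  K <- pmin(pmax(K, 0), 1)
  diag(K) <- 1
  K
}

#' Site-specific order parameter profile
#'
#' o_i = (1/Nv) sum_j K_ij, the mean correlation of bond vector i with all
#' bond vectors of the chain (including j = i).  o_i is 1 for a rigid
#' ensemble and approaches a small random-coil baseline for a fully
#' disordered chain.
#'
#' @param K site-pair correlation matrix from [pair_correlation()], or a
#'   `ca_trace` / `ensemble` from which it is computed.
#' @param weights conformer weights (used only when `K` is a trace/ensemble).
#' @param reference_band optional numeric c(low, high) random-coil band
#'   (see [random_coil_reference()]).
#' @return object of class `order_profile`: list with `o` (vector over bond
#'   vectors), `K`, and `reference_band`.
#' @export
order_parameter <- function(K, weights = NULL, reference_band = NULL) {
  if (inherits(K, "ensemble")) K <- ca_trace(K)
  if (inherits(K, "ca_trace")) {
    if (is.null(weights)) weights <- K$weights
    K <- pair_correlation(bond_vectors(K), weights)
  }
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  structure(list(o = rowMeans(K), K = K, reference_band = reference_band),
            class = "order_profile")
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("order profile: %d sites, mean o = %.4f (sd %.4f)\n",
              length(x$o), mean(x$o), stats::sd(x$o)))
  invisible(x)
}

#' Circular resultant length of an angle sample
#'
#' R = sqrt((sum w cos a)^2 + (sum w sin a)^2) in \[0, 1\]: 1 for identical
#' angles, 0 in the limit of a uniform circular distribution.  Undefined
#' (NA) angles are excluded with weight renormalization; if all angles are
#' undefined the result is NA.
#'
#' @param angles numeric vector of angles in radians (may contain NA).
#' @param weights weights over the sample (normalized internally).
#' @return resultant length R in \[0, 1\], or NA.
#' @export
circular_resultant <- function(angles, weights = NULL) {
  n <- length(angles)
  if (is.null(weights)) weights <- rep(1, n)
  ok <- !is.na(angles)
  if (!any(ok)) return(NA_real_)
  w <- weights[ok] / sum(weights[ok])
  a <- angles[ok]
  min(sqrt(sum(w * cos(a))^2 + sum(w * sin(a))^2), 1)
}

# residue flexibility classes used throughout: Gly / Pro / Thr / other
residue_class <- function(aa1) {
  cl <- rep("other", length(aa1))
  cl[aa1 == "G"] <- "Gly"
  cl[aa1 == "P"] <- "Pro"
  cl[aa1 == "T"] <- "Thr"
  cl
}

#' Site-specific Ramachandran flexibility profile
#'
#' f_i = 1 - R(phi_i)/2 - R(psi_i)/2, where R is the circular resultant
#' length of the dihedral distribution over conformers: 0 for identical
#' dihedrals in all conformers, 1 in the uniform limit.  At chain termini
#' (or across chain breaks) where only one of the two dihedrals is defined,
#' f is computed from the defined one alone and flagged.
#'
#' @param dihedrals a `dihedral_set` from [backbone_dihedrals()].
#' @param weights conformer weights (default: the set's own weights).
#' @param reference optional per-class reference table from
#'   [random_coil_reference()].
#' @return object of class `flexibility_profile`: data-frame-like list with
#'   `f`, `resultant_phi`, `resultant_psi`, `class` (Gly/Pro/Thr/other),
#'   `partial` (logical: only one dihedral defined), `resno`, `reference`.
#' @export
flexibility <- function(dihedrals, weights = NULL, reference = NULL) {
  stopifnot(inherits(dihedrals, "dihedral_set"))
  if (is.null(weights)) weights <- dihedrals$weights
  N <- ncol(dihedrals$phi)
  C <- nrow(dihedrals$phi)
  weights <- normalize_weights(if (is.null(weights)) rep(1, C) else weights, C)
  Rphi <- vapply(seq_len(N), function(i)
    circular_resultant(dihedrals$phi[, i], weights), numeric(1))
  Rpsi <- vapply(seq_len(N), function(i)
    circular_resultant(dihedrals$psi[, i], weights), numeric(1))
  partial <- xor(is.na(Rphi), is.na(Rpsi))
  f <- ifelse(partial,
              1 - ifelse(is.na(Rphi), Rpsi, Rphi),
              1 - Rphi / 2 - Rpsi / 2)
  cls <- if (nzchar(dihedrals$sequence))
    residue_class(strsplit(dihedrals$sequence, "")[[1]])
  else rep("other", N)
  structure(list(f = f, resultant_phi = Rphi, resultant_psi = Rpsi,
                 class = cls, partial = partial, resno = dihedrals$resno,
                 reference = reference),
            class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat(sprintf("flexibility profile: %d residues, mean f = %.4f\n",
              length(x$f), mean(x$f, na.rm = TRUE)))
  for (cl in c("Gly", "Pro", "Thr", "other")) {
    i <- x$class == cl
    if (any(i))
      cat(sprintf("  %-5s mean f = %.4f (n = %d)\n", cl,
                  mean(x$f[i], na.rm = TRUE), sum(i)))
  }
  invisible(x)
}

#' As-data-frame view of a flexibility profile
#' @param x a `flexibility_profile`.
#' @param ... unused.
#' @export
as.data.frame.flexibility_profile <- function(x, ...) {
  data.frame(resno = x$resno, f = x$f, resultant_phi = x$resultant_phi,
             resultant_psi = x$resultant_psi, class = x$class,
             partial = x$partial)
}

#' Random-coil reference bands for order and flexibility
#'
#' Generates an unrestrained ensemble by residue-specific Ramachandran
#' sampling ([generate_ensemble()]) and summarizes it into 95% confidence
#' bands: per-residue-class mean +/- 1.96 sd of the flexibility f, and a
#' global mean +/- 1.96 sd band of the site order o.  The bands depend on
#' the Ramachandran library and are regenerated (seeded) rather than
#' hard-coded.
#'
#' @param sequence_length chain length of the reference coil (default 267).
#' @param library Ramachandran library (default
#'   [default_ramachandran_library()]).
#' @param C number of conformers (>= 100 recommended; smaller C warns).
#' @param seed RNG seed (required for reproducible bands).
#' @param sequence optional explicit 1-letter sequence; by default a
#'   QGSY-rich composition covering all four flexibility classes
#'   ([coil_reference_sequence()]).
#' @param cache_dir optional directory; if given, the result is cached as an
#'   RDS file keyed by the parameters and reused on recomputation.
#' @return list with `f_class` (data.frame: class, mean, sd, lower, upper),
#'   `o_band` (c(lower, upper)), `mean_o`, `sd_o`, and the generation
#'   parameters.
#' @export
random_coil_reference <- function(sequence_length = 267, library = NULL,
                                  C = 1000, seed = 1,
                                  sequence = NULL, cache_dir = NULL) {
  if (C < 100) warning("C < 100 gives a noisy random-coil reference")
  if (is.null(library)) library <- default_ramachandran_library()
  if (is.null(sequence)) sequence <- coil_reference_sequence(sequence_length)
  if (!is.null(cache_dir)) {
    key <- sprintf("coilref_N%d_C%d_seed%d.rds", nchar(sequence), C, seed)
    f <- file.path(cache_dir, key)
    if (file.exists(f)) return(readRDS(f))
  }
  ens <- generate_ensemble(sequence, n_conformers = C, seed = seed,
                           library = library)
  op <- order_parameter(ens)
  fp <- flexibility(backbone_dihedrals(ens))
  fc <- do.call(rbind, lapply(c("Gly", "Pro", "Thr", "other"), function(cl) {
    v <- fp$f[fp$class == cl & !fp$partial]
    data.frame(class = cl, mean = mean(v), sd = stats::sd(v),
               lower = mean(v) - 1.96 * stats::sd(v),
               upper = mean(v) + 1.96 * stats::sd(v))
  }))
  out <- list(f_class = fc,
              o_band = c(mean(op$o) - 1.96 * stats::sd(op$o),
                         mean(op$o) + 1.96 * stats::sd(op$o)),
              mean_o = mean(op$o), sd_o = stats::sd(op$o),
              sequence_length = nchar(sequence), C = C, seed = seed)
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(out, f)
  }
  out
}
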
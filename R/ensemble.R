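# Weighted conformer ensembles: container, PDB I/O, reduced representations.

#' Construct a weighted conformer ensemble
#'
#' An `ensemble` holds C conformers of one molecule: a shared atom table and a
#' C x A x 3 coordinate array, together with normalized statistical weights
#' w_c (w_c >= 0, sum w_c = 1).
#'
#' @param atoms data.frame with columns `resno` (author residue numbering),
#'   `resid` (3-letter residue code), `elety` (atom name), `element`
#'   (element symbol) and optionally `het` (logical, heteroatom/ligand flag).
#'   A `mass` column is derived from `element` if absent.
#' @param xyz numeric array of dimension C x A x 3 (Angstrom), or an A x 3
#'   matrix for a single conformer.
#' @param weights numeric vector of C non-negative weights; normalized to sum
#'   one.  Default uniform.
#' @param label character label for the ensemble.
#' @return object of class `ensemble` with elements `atoms`, `xyz`,
#'   `weights`, `sequence` (1-letter string over non-hetero residues) and
#'   `label`.
#' @export
new_ensemble <- function(atoms, xyz, weights = NULL, label = "ensemble") {
  stopifnot(is.data.frame(atoms))
  req <- c("resno", "resid", "elety", "element")
  if (!all(req %in% names(atoms)))
    stop("atoms must have columns ", paste(req, collapse = ", "))
  if (is.null(atoms$het)) atoms$het <- FALSE
  if (is.null(atoms$mass)) atoms$mass <- element_mass(atoms$element)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0))
    stop("all atomic masses must be positive and finite")

  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(1L, nrow(xyz), 3L))
  if (length(dim(xyz)) != 3L || dim(xyz)[3] != 3L)
    stop("xyz must be a C x A x 3 array")
  if (dim(xyz)[2] != nrow(atoms))
    stop("xyz has ", dim(xyz)[2], " atoms but the atom table has ",
         nrow(atoms))
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  C <- dim(xyz)[1]

  # residues must appear in ascending author numbering (within the polymer)
  rn <- atoms$resno[!atoms$het]
  if (is.unsorted(rn)) stop("residues must appear in ascending residue_index")

  weights <- normalize_weights(if (is.null(weights)) rep(1, C) else weights, C)

  seq1 <- {
    ca <- !atoms$het & atoms$elety == "CA"
    if (any(ca)) paste(.aa321(atoms$resid[ca]), collapse = "") else ""
  }
  structure(list(atoms = atoms, xyz = xyz, weights = weights,
                 sequence = seq1, label = label),
            class = "ensemble")
}

.aa321 <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out)] <- "X"
  out
}

normalize_weights <- function(w, C) {
  w <- as.numeric(w)
  if (length(w) != C)
    stop("weights count (", length(w), ") does not match the number of ",
         "conformers (", C, ")")
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s <= 0) stop("all-zero weights")
  w / s
}

#' @export
print.ensemble <- function(x, ...) {
  cat("ensemble '", x$label, "': ", dim(x$xyz)[1], " conformer(s), ",
      nchar(x$sequence), " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param ensemble an `ensemble`.
#' @return integer count C.
#' @export
n_conformers <- function(ensemble) dim(ensemble$xyz)[1]

#' Build a C-alpha-only ensemble from a coordinate array
#'
#' Convenience constructor used for toy ensembles and tests: each residue is
#' represented by a single CA atom (residue type ALA).
#'
#' @param coords C x N x 3 array (or N x 3 matrix for one conformer) of CA
#'   positions in Angstrom.
#' @param weights optional conformer weights.
#' @param label ensemble label.
#' @param resno optional residue numbering (default 1:N).
#' @return an `ensemble`.
#' @export
ca_ensemble <- function(coords, weights = NULL, label = "ca", resno = NULL) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(1L, nrow(coords), 3L))
  N <- dim(coords)[2]
  if (is.null(resno)) resno <- seq_len(N)
  atoms <- data.frame(resno = resno, resid = "ALA", elety = "CA",
                      element = "C", het = FALSE)
  new_ensemble(atoms, coords, weights, label)
}

# ---- PDB input / output ----------------------------------------------------

# Count ATOM/HETATM records per MODEL block; used to give a clear error for
# deposits whose models disagree (bio3d would silently recycle).
.model_atom_counts <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0) return(sum(is_atom))
  model_ends <- which(startsWith(lines, "ENDMDL"))
  if (length(model_ends) != length(model_starts))
    stop("unbalanced MODEL/ENDMDL records")
  vapply(seq_along(model_starts), function(m)
    sum(is_atom[model_starts[m]:model_ends[m]]), integer(1))
}

#' Read a weighted conformer ensemble from a multi-model PDB file
#'
#' Models delimited by MODEL/ENDMDL become conformers.  Conformer weights are
#' read from a plain-text sidecar file (one non-negative number per model,
#' `#` comments allowed) and normalized to sum one; without a sidecar,
#' uniform weights 1/C are assigned.  If `weights_path` is not given but a
#' file `<path>.weights` exists, it is used.
#'
#' Alternate locations other than blank/'A' are dropped with a warning;
#' HETATM records are kept but flagged `het` and excluded from the reduced
#' representations ([ca_trace()], [backbone_dihedrals()]).
#'
#' @param path PDB file (single model or MODEL/ENDMDL-delimited models).
#' @param weights_path optional sidecar weight file.
#' @param label ensemble label (default: file name).
#' @return an `ensemble`.
#' @export
read_ensemble <- function(path, weights_path = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  counts <- .model_atom_counts(readLines(path, warn = FALSE))
  if (length(counts) > 1 && length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    stop("model ", bad, " has ", counts[bad], " atoms but model 1 has ",
         counts[1], "; all models of an ensemble must match")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)

  keep <- is.na(atom$alt) | atom$alt %in% c("", "A")
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " alternate-location atom(s)")
    xyz <- xyz[, bio3d::atom2xyz(which(keep)), drop = FALSE]
    atom <- atom[keep, , drop = FALSE]
  }

  A <- nrow(atom)
  C <- nrow(xyz)
  coords <- aperm(array(t(xyz), dim = c(3L, A, C)), c(3L, 2L, 1L))

  elesy <- atom$elesy
  if (is.null(elesy) || all(is.na(elesy) | trimws(elesy) == ""))
    elesy <- substr(trimws(atom$elety), 1, 1)
  atoms <- data.frame(resno = atom$resno, resid = atom$resid,
                      elety = trimws(atom$elety),
                      element = trimws(elesy),
                      het = atom$type == "HETATM")

  if (is.null(weights_path)) {
    side <- paste0(path, ".weights")
    if (file.exists(side)) weights_path <- side
  }
  w <- if (!is.null(weights_path)) {
    scan(weights_path, comment.char = "#", quiet = TRUE)
  } else rep(1, C)

  new_ensemble(atoms, coords, w,
               label = if (is.null(label)) basename(path) else label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Non-uniform weights are stored in a plain-text sidecar file (one weight
#' per model) so that `read_ensemble(write_ensemble(E))` reproduces
#' coordinates and weights.
#'
#' @param ensemble an `ensemble`.
#' @param path output PDB path.
#' @param weights_path sidecar path for the weights; default
#'   `<path>.weights`, written only when weights are non-uniform (set to a
#'   path to force writing, or `NA` to suppress).
#' @return invisibly, `path`.
#' @export
write_ensemble <- function(ensemble, path,
                           weights_path = paste0(path, ".weights")) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  C <- n_conformers(ensemble)
  A <- nrow(at)
  xyz <- matrix(aperm(ensemble$xyz, c(3L, 2L, 1L)), nrow = C, byrow = TRUE)
  bio3d::write.pdb(file = path, xyz = bio3d::as.xyz(xyz),
                   type = ifelse(at$het, "HETATM", "ATOM"),
                   resno = at$resno, resid = at$resid, eleno = seq_len(A),
                   elety = at$elety, elesy = at$element, end = TRUE)
  w <- ensemble$weights
  uniform <- max(abs(w - 1 / C)) < 1e-12
  if (!is.null(weights_path) && !is.na(weights_path) && !uniform)
    writeLines(format(w, digits = 15), weights_path)
  invisible(path)
}

# ---- reduced representations ----------------------------------------------

#' Extract the C-alpha trace of an ensemble
#'
#' @param ensemble an `ensemble`; every (non-hetero) residue must have a CA
#'   atom.
#' @return object of class `ca_trace`: list with `coords` (C x N x 3 array),
#'   `weights`, `resno` and `sequence`.
#' @export
ca_trace <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  poly <- which(!at$het)
  resno <- unique(at$resno[poly])
  ca_idx <- integer(length(resno))
  for (r in seq_along(resno)) {
    i <- poly[at$resno[poly] == resno[r] & at$elety == "CA"]
    if (length(i) == 0)
      stop("residue ", resno[r], " has no CA atom")
    ca_idx[r] <- i[1]
  }
  structure(list(coords = ensemble$xyz[, ca_idx, , drop = FALSE],
                 weights = ensemble$weights, resno = resno,
                 sequence = ensemble$sequence),
            class = "ca_trace")
}

# Row-wise cross product for C x 3 matrices.
.cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

# Torsion angle (radians, IUPAC sign) for four C x 3 point sets.
.torsion4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  atan2(rowSums(.cross3(n1, n2) * b2n), rowSums(n1 * n2))
}

#' Backbone dihedral angles of an ensemble
#'
#' Computes phi_i = C(i-1)-N(i)-CA(i)-C(i) and psi_i = N(i)-CA(i)-C(i)-N(i+1)
#' (radians, IUPAC convention) for every conformer.  phi is undefined at the
#' first residue and psi at the last; entries spanning a chain break
#' (C(i)-N(i+1) distance > `break_dist`) are flagged NA with a warning.
#'
#' @param ensemble an `ensemble` whose residues all have N, CA and C atoms.
#' @param break_dist chain-break detection threshold in Angstrom (default
#'   2.5).
#' @return object of class `dihedral_set`: list with `phi` and `psi`
#'   (C x N matrices, radians, NA where undefined), `resno` and `sequence`.
#' @export
backbone_dihedrals <- function(ensemble, break_dist = 2.5) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  poly <- which(!at$het)
  resno <- unique(at$resno[poly])
  N <- length(resno)
  idx <- function(name) {
    out <- integer(N)
    for (r in seq_len(N)) {
      i <- poly[at$resno[poly] == resno[r] & at$elety == name]
      if (length(i) == 0)
        stop("residue ", resno[r], " has no ", name, " atom")
      out[r] <- i[1]
    }
    out
  }
  iN <- idx("N"); iCA <- idx("CA"); iC <- idx("C")
  X <- ensemble$xyz
  C <- dim(X)[1]
  P <- function(i) X[, i, , drop = FALSE][, 1, ]
  asmat <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)

  phi <- matrix(NA_real_, C, N)
  psi <- matrix(NA_real_, C, N)
  # peptide-bond continuity between residue i and i+1, per conformer
  intact <- matrix(TRUE, C, max(N - 1, 1))
  if (N >= 2) {
    for (i in seq_len(N - 1)) {
      d <- sqrt(rowSums((asmat(P(iC[i])) - asmat(P(iN[i + 1])))^2))
      intact[, i] <- d <= break_dist
    }
    if (!all(intact))
      warning("chain break(s) detected; dihedrals spanning the break are NA")
    for (i in 2:N) {
      v <- .torsion4(asmat(P(iC[i - 1])), asmat(P(iN[i])),
                     asmat(P(iCA[i])), asmat(P(iC[i])))
      v[!intact[, i - 1]] <- NA_real_
      phi[, i] <- v
    }
    for (i in 1:(N - 1)) {
      v <- .torsion4(asmat(P(iN[i])), asmat(P(iCA[i])),
                     asmat(P(iC[i])), asmat(P(iN[i + 1])))
      v[!intact[, i]] <- NA_real_
      psi[, i] <- v
    }
  }
  structure(list(phi = phi, psi = psi, resno = resno,
                 sequence = ensemble$sequence, weights = ensemble$weights),
            class = "dihedral_set")
}
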
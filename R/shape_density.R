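# Inertia-tensor principal-axes superposition, pseudo-electron density
# grids, and Debye-screened electrostatic surface coloring.

#' Inertia tensor of a conformer
#'
#' I = sum_a m_a (|r_a|^2 delta - r_a r_a^T), computed about the center of
#' mass (coordinates are re-centered first).
#'
#' @param xyz A x 3 coordinate matrix (Angstrom).
#' @param mass atomic masses (Da); must be positive.
#' @return 3 x 3 symmetric matrix in Da Angstrom^2.
#' @export
inertia_tensor <- function(xyz, mass) {
  xyz <- as.matrix(xyz)
  if (sum(mass) <= 0) stop("zero total mass")
  com <- colSums(xyz * mass) / sum(mass)
  r <- sweep(xyz, 2, com)
  x <- r[, 1]; y <- r[, 2]; z <- r[, 3]
  matrix(c(sum(mass * (y^2 + z^2)), -sum(mass * x * y), -sum(mass * x * z),
           -sum(mass * x * y), sum(mass * (x^2 + z^2)), -sum(mass * y * z),
           -sum(mass * x * z), -sum(mass * y * z), sum(mass * (x^2 + y^2))),
         3, 3)
}

# the three proper pi-rotations about principal axes (pairs of sign flips)
.pi_flips <- list(diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))

#' Principal-axes-system transform of a conformer
#'
#' Diagonalizes the inertia tensor, orders the eigenvalues increasingly
#' (I_x <= I_y <= I_z), and rotates the centered coordinates into the
#' principal axes system (PAS) with a proper rotation (determinant +1, so
#' handedness is preserved).  If the first atom of the N-terminal residue
#' then has a larger x- or z-coordinate than the last atom of the
#' C-terminal residue, a pi-rotation about a principal axis (two sign
#' flips) is applied, choosing the flip that minimizes x_N + z_N; ties are
#' broken toward the rotation about y.
#'
#' @param xyz A x 3 coordinate matrix.
#' @param mass atomic masses.
#' @param n_atom,c_atom row indices of the orientation reference atoms
#'   (first atom of the N-terminal residue, last atom of the C-terminal
#'   residue; defaults 1 and A).
#' @return object of class `pas_transform`: list with `rotation` (3 x 3,
#'   det +1), `translation` (the applied shift, i.e. minus the center of
#'   mass), `eigenvalues` (increasing, Da Angstrom^2) and `coords` (the
#'   transformed A x 3 matrix).
#' @export
pas_transform <- function(xyz, mass, n_atom = 1, c_atom = nrow(xyz)) {
  xyz <- as.matrix(xyz)
  I <- inertia_tensor(xyz, mass)
  ev <- eigen(I, symmetric = TRUE)
  ord <- order(ev$values)
  vals <- ev$values[ord]
  if (vals[3] > 0 && (vals[2] - vals[1]) / vals[3] < 1e-6)
    warning("near-degenerate inertia spectrum; PAS orientation is unstable")
  R <- ev$vectors[, ord]
  if (det(R) < 0) R[, 3] <- -R[, 3]
  com <- colSums(xyz * mass) / sum(mass)
  coords <- sweep(xyz, 2, com) %*% R
  if (coords[n_atom, 1] > coords[c_atom, 1] ||
      coords[n_atom, 3] > coords[c_atom, 3]) {
    scores <- vapply(.pi_flips, function(Fm) {
      p <- coords[n_atom, ] %*% Fm
      p[1] + p[3]
    }, numeric(1))
    # prefer the y-axis rotation (flips x and z) on ties
    best <- order(round(scores, 9), c(2, 1, 3))[1]
    Fm <- .pi_flips[[best]]
    coords <- coords %*% Fm
    R <- R %*% Fm
  }
  structure(list(rotation = R, translation = -com, eigenvalues = vals,
                 coords = coords),
            class = "pas_transform")
}

#' Superimpose all conformers of an ensemble in their principal axes
#'
#' Applies [pas_transform()] conformer-wise: the compact superposition used
#' for visualizing fully disordered ensembles, where coordinate-RMSD
#' superposition is meaningless.
#'
#' @param ensemble an `ensemble`.
#' @param include_het include heteroatoms in the inertia tensor (default
#'   FALSE; they are transformed along either way).
#' @return the ensemble with transformed coordinates.
#' @export
pas_align <- function(ensemble, include_het = FALSE) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  sel <- if (include_het) seq_len(nrow(at)) else which(!at$het)
  poly <- which(!at$het)
  n_ref <- match(poly[1], sel)
  c_ref <- match(poly[length(poly)], sel)
  for (c in seq_len(n_conformers(ensemble))) {
    X <- matrix(ensemble$xyz[c, , ], nrow(at), 3)
    tr <- pas_transform(X[sel, , drop = FALSE], at$mass[sel],
                        n_atom = n_ref, c_atom = c_ref)
    ensemble$xyz[c, , ] <- sweep(X, 2, -tr$translation) %*% tr$rotation
  }
  ensemble
}

.sigma_for <- function(element) ifelse(toupper(element) %in% c("H", "D"),
                                       0.7, 1.0)

#' Weighted pseudo-electron density of an ensemble on a regular grid
#'
#' Each atom contributes an isotropic Gaussian with amplitude equal to its
#' electron count (sigma 1.0 A for heavy atoms, 0.7 A for hydrogens);
#' conformer densities are combined with the conformer weights.  Values are
#' stored as electrons per voxel, so the grid total approximates the
#' weighted electron count.  The isolevel is the largest value tau such
#' that voxels with density >= tau enclose at least `fraction` of the
#' total.
#'
#' Conformers are expected to be superimposed already (see [pas_align()]).
#'
#' @param ensemble an `ensemble` (PAS-aligned for the intended use).
#' @param spacing grid spacing in Angstrom (default 1.0).
#' @param pad padding around the bounding box in Angstrom (default 5.0).
#' @param fraction enclosed density fraction defining the isolevel
#'   (default 0.999).
#' @param include_het include heteroatoms (default FALSE).
#' @param max_voxels error guard on grid size (default 2e7).
#' @return object of class `density_grid`: list with `origin`, `spacing`,
#'   `values` (3-D array, electrons/voxel), `isolevel`, `total`,
#'   `fraction`.
#' @export
ensemble_density <- function(ensemble, spacing = 1.0, pad = 5.0,
                             fraction = 0.999, include_het = FALSE,
                             max_voxels = 2e7) {
  stopifnot(inherits(ensemble, "ensemble"))
  at <- ensemble$atoms
  sel <- if (include_het) seq_len(nrow(at)) else which(!at$het)
  elec <- element_electrons(at$element[sel])
  sig <- .sigma_for(at$element[sel])
  C <- n_conformers(ensemble)

  lo <- apply(ensemble$xyz[, sel, , drop = FALSE], 3, min) - pad
  hi <- apply(ensemble$xyz[, sel, , drop = FALSE], 3, max) + pad
  nx <- ceiling((hi - lo) / spacing) + 1L
  if (prod(nx) > max_voxels)
    stop("density grid would have ", prod(nx),
         " voxels; increase `spacing`")
  ax <- lapply(1:3, function(d) lo[d] + spacing * (seq_len(nx[d]) - 1L))
  vals <- array(0, dim = nx)
  cut <- 4  # Gaussian support in sigmas

  for (c in seq_len(C)) {
    w <- ensemble$weights[c]
    if (w == 0) next
    X <- matrix(ensemble$xyz[c, sel, ], length(sel), 3)
    for (a in seq_along(sel)) {
      s <- sig[a]
      idx <- lapply(1:3, function(d) {
        which(abs(ax[[d]] - X[a, d]) <= cut * s)
      })
      if (any(lengths(idx) == 0)) next
      g <- lapply(1:3, function(d) {
        dx <- ax[[d]][idx[[d]]] - X[a, d]
        exp(-dx^2 / (2 * s^2))
      })
      amp <- w * elec[a] * spacing^3 / ((2 * pi)^1.5 * s^3)
      vals[idx[[1]], idx[[2]], idx[[3]]] <-
        vals[idx[[1]], idx[[2]], idx[[3]]] +
        amp * (g[[1]] %o% g[[2]] %o% g[[3]])
    }
  }
  total <- sum(vals)
  sv <- sort(as.numeric(vals), decreasing = TRUE)
  k <- which(cumsum(sv) >= fraction * total)[1]
  isolevel <- sv[k]
  structure(list(origin = lo, spacing = spacing, values = vals,
                 isolevel = isolevel, total = total, fraction = fraction),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf(
    "density grid %s voxels, spacing %.2f A, total %.1f e, isolevel %.3g\n",
    paste(dim(x$values), collapse = " x "), x$spacing, x$total, x$isolevel))
  invisible(x)
}

#' Extract isosurface vertices from a density grid
#'
#' Marches over voxel edges: wherever the density crosses `level` between
#' two grid neighbours (along x, y or z), a vertex is placed on the edge by
#' linear interpolation.
#'
#' @param grid a `density_grid`.
#' @param level isolevel (default: the grid's own).
#' @return V x 3 matrix of vertex coordinates (Angstrom).
#' @export
isosurface_vertices <- function(grid, level = grid$isolevel) {
  v <- grid$values
  nx <- dim(v)
  verts <- list()
  for (d in 1:3) {
    n <- nx[d]
    lo_idx <- switch(d,
      v[-n, , , drop = FALSE], v[, -n, , drop = FALSE],
      v[, , -n, drop = FALSE])
    hi_idx <- switch(d,
      v[-1, , , drop = FALSE], v[, -1, , drop = FALSE],
      v[, , -1, drop = FALSE])
    cross <- (lo_idx - level) * (hi_idx - level) < 0
    if (!any(cross)) next
    w <- which(cross, arr.ind = TRUE)
    t <- (level - lo_idx[cross]) / (hi_idx[cross] - lo_idx[cross])
    pos <- (w - 1)
    pos[, d] <- pos[, d] + t
    verts[[length(verts) + 1]] <-
      sweep(pos * grid$spacing, 2, grid$origin, "+")
  }
  if (!length(verts)) return(matrix(numeric(0), 0, 3))
  do.call(rbind, verts)
}

#' Debye screening length of an electrolyte
#'
#' lambda_D = 0.304 / sqrt(I) nm for ionic strength I in mol/L (monovalent
#' salt, 25 C), returned in Angstrom.
#'
#' @param ionic_strength_mM ionic strength in mM (default 150).
#' @return Debye length in Angstrom.
#' @export
debye_length <- function(ionic_strength_mM = 150) {
  3.04 / sqrt(ionic_strength_mM / 1000)
}

# side-chain pKa table (standard free-amino-acid values)
.pka <- c(ASP = 3.65, GLU = 4.25, LYS = 10.53, ARG = 12.48, HIS = 6.08)

# locate the charge site of a residue; returns position or NULL (+ warning)
.charge_site <- function(X, at, rows, names_needed, label) {
  hit <- rows[at$elety[rows] %in% names_needed]
  if (length(hit) < length(names_needed)) {
    warning("residue ", label, ": missing side-chain atom(s) ",
            paste(setdiff(names_needed, at$elety[rows]), collapse = ","),
            "; charge skipped")
    return(NULL)
  }
  colMeans(X[hit, , drop = FALSE])
}

# per-conformer list of (position, charge) for titratable side chains
.conformer_charges <- function(X, at, pH, include_termini = FALSE) {
  pos <- list(); q <- numeric(0)
  add <- function(p, charge) {
    if (!is.null(p)) {
      pos[[length(pos) + 1]] <<- p
      q[length(q) + 1] <<- charge
    }
  }
  for (rn in unique(at$resno[!at$het])) {
    rows <- which(at$resno == rn & !at$het)
    resid <- at$resid[rows[1]]
    lab <- paste0(resid, rn)
    if (resid == "ASP")
      add(.charge_site(X, at, rows, c("OD1", "OD2"), lab),
          -1 / (1 + 10^(.pka[["ASP"]] - pH)))
    else if (resid == "GLU")
      add(.charge_site(X, at, rows, c("OE1", "OE2"), lab),
          -1 / (1 + 10^(.pka[["GLU"]] - pH)))
    else if (resid == "LYS")
      add(.charge_site(X, at, rows, "NZ", lab),
          1 / (1 + 10^(pH - .pka[["LYS"]])))
    else if (resid == "ARG")
      add(.charge_site(X, at, rows, c("NH1", "NH2"), lab),
          1 / (1 + 10^(pH - .pka[["ARG"]])))
    else if (resid == "HIS")
      add(.charge_site(X, at, rows, c("ND1", "NE2"), lab),
          1 / (1 + 10^(pH - .pka[["HIS"]])))
    else if (resid %in% c("SEP", "TPO", "PTR")) {
      nm <- if (any(at$elety[rows] %in% c("O1P", "O2P", "O3P")))
        c("O1P", "O2P", "O3P") else c("OP1", "OP2", "OP3")
      add(.charge_site(X, at, rows, nm, lab), -2)
    }
  }
  list(positions = if (length(pos)) do.call(rbind, pos)
                   else matrix(numeric(0), 0, 3),
       charges = q)
}

#' Screened electrostatic potential on a density isosurface
#'
#' Titratable side chains carry Henderson-Hasselbalch fractional charges:
#' Asp/Glu carboxylates (charge at the O-pair midpoint), Lys (NZ), Arg
#' (NH1/NH2 midpoint), His (ND1/NE2 midpoint); phosphorylated Ser/Thr/Tyr
#' (SEP/TPO/PTR) carry -2 at the midpoint of the terminal phosphate
#' oxygens.  The potential at each isosurface vertex is the Debye-Hueckel
#' sum over charges q exp(-d / lambda_D) / d, averaged over conformers with
#' the ensemble weights.  Blue = positive, red = negative by convention.
#'
#' @param ensemble an `ensemble` (aligned consistently with `grid`).
#' @param grid a `density_grid` from [ensemble_density()].
#' @param pH solution pH (default 7.0).
#' @param ionic_strength_mM ionic strength in mM for the Debye length
#'   (default 150).
#' @return object of class `surface_potential`: list with `points`
#'   (isosurface vertices), `potential` (signed, arbitrary units),
#'   `charges` (data.frame of the last conformer's charge sites),
#'   `lambda_D`.
#' @export
surface_potential <- function(ensemble, grid, pH = 7.0,
                              ionic_strength_mM = 150) {
  stopifnot(inherits(ensemble, "ensemble"), inherits(grid, "density_grid"))
  at <- ensemble$atoms
  verts <- isosurface_vertices(grid)
  lam <- debye_length(ionic_strength_mM)
  phi <- numeric(nrow(verts))
  last_charges <- NULL
  for (c in seq_len(n_conformers(ensemble))) {
    X <- matrix(ensemble$xyz[c, , ], nrow(at), 3)
    ch <- .conformer_charges(X, at, pH)
    last_charges <- ch
    if (length(ch$charges) == 0 || nrow(verts) == 0) next
    for (k in seq_along(ch$charges)) {
      d <- sqrt(rowSums(sweep(verts, 2, ch$positions[k, ])^2))
      d <- pmax(d, 1e-6)
      phi <- phi + ensemble$weights[c] * ch$charges[k] * exp(-d / lam) / d
    }
  }
  charges_df <- if (!is.null(last_charges) && length(last_charges$charges))
    data.frame(x = last_charges$positions[, 1],
               y = last_charges$positions[, 2],
               z = last_charges$positions[, 3],
               charge = last_charges$charges)
  else data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                  charge = numeric(0))
  structure(list(points = verts, potential = phi, charges = charges_df,
                 lambda_D = lam, pH = pH),
            class = "surface_potential")
}

#' Write a density grid as a CCP4/MRC map
#'
#' Minimal mode-2 (32-bit float) MRC writer with orthogonal axes and the
#' grid spacing as the voxel size.
#'
#' @param grid a `density_grid`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_mrc <- function(grid, path) {
  nx <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(nx)                      # NX NY NZ
  wi(2)                       # MODE 2 = float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(nx)                      # MX MY MZ
  wf(nx * grid$spacing)       # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  v <- grid$values
  wf(c(min(v), max(v), mean(v)))
  wi(c(0, 0))                 # ISPG NSYMBT
  writeBin(raw(100), con)     # EXTRA (25 words)
  wf(grid$origin)             # ORIGIN
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # MACHST little-endian
  wf(stats::sd(as.numeric(v)))
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  writeBin(as.numeric(aperm(v, c(1, 2, 3))), con, size = 4,
           endian = "little")
  invisible(path)
}
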
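# Random-coil deviation analysis: section end-to-end distances, Flory
# scaling fit, and the proximity / compactness / section-deviation matrices.

#' Root-mean-square section end-to-end distances
#'
#' r_ee(i, j) = sqrt(sum_c w_c r_{i,j,c}^2): the ensemble (weight-) RMS
#' Calpha-Calpha distance between residues i and j, for all j > i.
#'
#' @param trace a `ca_trace` (or `ensemble`).
#' @param weights conformer weights (default: the trace's own).
#' @return object of class `section_ree`: list with `ree` (N x N symmetric
#'   matrix, NA diagonal) and `resno`.
#' @export
section_ree <- function(trace, weights = NULL) {
  if (inherits(trace, "ensemble")) trace <- ca_trace(trace)
  stopifnot(inherits(trace, "ca_trace"))
  coords <- trace$coords
  C <- dim(coords)[1]; N <- dim(coords)[2]
  if (N < 2) stop("need at least 2 residues")
  weights <- normalize_weights(
    if (is.null(weights)) trace$weights else weights, C)
  acc <- matrix(0, N, N)
  for (c in seq_len(C)) {
    d <- as.matrix(stats::dist(matrix(coords[c, , ], N, 3)))
    acc <- acc + weights[c] * d^2
  }
  ree <- sqrt(acc)
  diag(ree) <- NA_real_
  structure(list(ree = ree, resno = trace$resno), class = "section_ree")
}

.ree_matrix <- function(x) {
  if (inherits(x, "section_ree")) x$ree
  else if (is.matrix(x)) x
  else stop("expected a section_ree or a matrix")
}

#' Fit the Flory scaling law to section end-to-end distances
#'
#' Minimizes sum_{i<j} (r_ee(i,j) - b0 (j-i)^nu)^2 over the Kuhn length b0
#' and the scaling exponent nu (constrained to \[0.1, 1\]), in linear r
#' space with equal weight for all sections.  b0 is profiled out in closed
#' form for fixed nu, leaving a 1-D minimization.
#'
#' @param ree a `section_ree` or N x N matrix of section RMS end-to-end
#'   distances.
#' @return object of class `flory_fit`: list with `b0` (Angstrom), `nu`,
#'   `rss`, and `n_sections`.
#' @export
fit_flory <- function(ree) {
  M <- .ree_matrix(ree)
  N <- nrow(M)
  iu <- which(upper.tri(M), arr.ind = TRUE)
  r <- M[iu]
  dn <- iu[, 2] - iu[, 1]
  ok <- is.finite(r)
  r <- r[ok]; dn <- dn[ok]
  if (length(r) < 10) stop("need at least 10 sections for the fit")
  sse <- function(nu) {
    x <- dn^nu
    b0 <- sum(r * x) / sum(x * x)
    sum((r - b0 * x)^2)
  }
  opt <- stats::optimize(sse, interval = c(0.1, 1), tol = 1e-10)
  nu <- opt$minimum
  x <- dn^nu
  b0 <- sum(r * x) / sum(x * x)
  if (!is.finite(b0) || b0 <= 0)
    stop("Flory fit failed: b0 = ", b0, ", nu = ", nu)
  structure(list(b0 = b0, nu = nu, rss = opt$objective,
                 n_sections = length(r)),
            class = "flory_fit")
}

#' @export
print.flory_fit <- function(x, ...) {
  cat(sprintf("Flory fit over %d sections: b0 = %.4f A, nu = %.4f (rss %.4g)\n",
              x$n_sections, x$b0, x$nu, x$rss))
  invisible(x)
}

#' Mean section end-to-end distance by sequence length
#'
#' rbar_ee(DN) = mean over the N - DN sections with j - i = DN of
#' r_ee(i, j), for DN = 1 ... N-1.
#'
#' @param ree a `section_ree` or matrix.
#' @return numeric vector of length N-1, indexed by DN.
#' @export
mean_ree_by_length <- function(ree) {
  M <- .ree_matrix(ree)
  N <- nrow(M)
  vapply(seq_len(N - 1), function(dn) {
    i <- seq_len(N - dn)
    mean(M[cbind(i, i + dn)])
  }, numeric(1))
}

# RMS section gyration radii rg(i,j) over the ensemble, via prefix sums:
# Rg^2 of points i..j = mean |r|^2 - |mean r|^2 over the section.
.section_rg <- function(coords, weights) {
  C <- dim(coords)[1]; N <- dim(coords)[2]
  acc <- matrix(0, N, N)
  for (c in seq_len(C)) {
    P <- matrix(coords[c, , ], N, 3)
    cs <- apply(rbind(0, P), 2, cumsum)            # (N+1) x 3
    cq <- cumsum(c(0, rowSums(P^2)))               # length N+1
    for (dn in 1:(N - 1)) {
      i <- seq_len(N - dn)
      j <- i + dn
      n <- dn + 1
      mx <- (cs[j + 1, 1] - cs[i, 1]) / n
      my <- (cs[j + 1, 2] - cs[i, 2]) / n
      mz <- (cs[j + 1, 3] - cs[i, 3]) / n
      msq <- (cq[j + 1] - cq[i]) / n
      rg2 <- pmax(msq - (mx^2 + my^2 + mz^2), 0)
      acc[cbind(i, j)] <- acc[cbind(i, j)] + weights[c] * rg2
    }
  }
  rg <- sqrt(acc + t(acc))
  diag(rg) <- NA_real_
  rg
}

#' Proximity, compactness and section-deviation matrices
#'
#' P_ij = (r_ee(i,j) - b0 (j-i)^nu) / (b0 (j-i)^nu) measures the relative
#' deviation of every section from the fitted Flory scaling law; S_ij =
#' r_ee(i,j) - rbar_ee(j-i) is the absolute deviation from the mean over
#' sections of equal length (red = expanded, blue = compacted).  If a trace
#' is supplied, the analogous compactness matrix Cmat is built from the
#' ensemble-RMS section gyration radii with its own scaling-law fit.
#'
#' @param ree a `section_ree` or matrix.
#' @param fit a `flory_fit` (default: fitted from `ree`).
#' @param trace optional `ca_trace`/`ensemble` for the gyration-radius-based
#'   compactness matrix.
#' @param weights conformer weights for the gyration radii.
#' @return object of class `section_deviation`: list with `P`, `S` (and
#'   `Cmat`, `fit_rg` when a trace is given), plus `fit` and
#'   `ree_mean_by_length`.
#' @export
deviation_matrices <- function(ree, fit = NULL, trace = NULL,
                               weights = NULL) {
  M <- .ree_matrix(ree)
  N <- nrow(M)
  if (is.null(fit)) fit <- fit_flory(M)
  dn_mat <- abs(outer(seq_len(N), seq_len(N), "-"))
  model <- fit$b0 * dn_mat^fit$nu
  diag(model) <- NA_real_
  P <- (M - model) / model
  rbar <- mean_ree_by_length(M)
  Sm <- M - matrix(rbar[pmax(dn_mat, 1)], N, N)
  diag(Sm) <- NA_real_
  out <- list(P = P, S = Sm, fit = fit, ree_mean_by_length = rbar)
  if (!is.null(trace)) {
    if (inherits(trace, "ensemble")) trace <- ca_trace(trace)
    C <- dim(trace$coords)[1]
    w <- normalize_weights(
      if (is.null(weights)) trace$weights else weights, C)
    rg <- .section_rg(trace$coords, w)
    fit_rg <- fit_flory(rg)
    model_rg <- fit_rg$b0 * dn_mat^fit_rg$nu
    diag(model_rg) <- NA_real_
    out$Cmat <- (rg - model_rg) / model_rg
    out$fit_rg <- fit_rg
    out$rg <- rg
  }
  structure(out, class = "section_deviation")
}

#' @export
print.section_deviation <- function(x, ...) {
  cat(sprintf("section deviation matrices (N = %d): b0 = %.3f A, nu = %.3f\n",
              nrow(x$P), x$fit$b0, x$fit$nu))
  cat(sprintf("  |S| range: 0 to %.2f A\n", max(abs(x$S), na.rm = TRUE)))
  invisible(x)
}
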
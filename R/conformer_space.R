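# Conformer-space geometry: weight entropy, DRMSD metric, ensemble
# mean-square distances and the similarity measure s_kl.

#' Shannon entropy of conformer weights
#'
#' s = -sum_c w_c log10 w_c (decadic logarithm, 0 log 0 = 0).  Lower entropy
#' means a more parsimonious ensemble description.
#'
#' @param weights normalized weight vector (sum 1 within 1e-8).
#' @return dimensionless entropy.
#' @export
shannon_entropy <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < 0))
    stop("weights must be non-negative and normalized to sum 1")
  nz <- weights > 0
  -sum(weights[nz] * log10(weights[nz]))
}

# pair-distance vector (length N(N-1)/2) of one N x 3 trace
.pairdist <- function(m) as.numeric(stats::dist(m))

#' Distance root-mean-square deviation between two C-alpha traces
#'
#' DRMSD is the root-mean-square difference of all internal Calpha-Calpha
#' distances of the two conformers.  It is invariant under rigid motion and
#' reflection of either trace and is a metric on conformer space.
#'
#' @param trace_a,trace_b N x 3 coordinate matrices (Angstrom), equal N >= 2.
#' @return DRMSD in Angstrom.
#' @export
drmsd <- function(trace_a, trace_b) {
  trace_a <- as.matrix(trace_a); trace_b <- as.matrix(trace_b)
  if (nrow(trace_a) != nrow(trace_b))
    stop("traces differ in residue count (", nrow(trace_a), " vs ",
         nrow(trace_b), ")")
  if (nrow(trace_a) < 2) stop("need at least 2 residues")
  da <- .pairdist(trace_a); db <- .pairdist(trace_b)
  sqrt(mean((da - db)^2))
}

# Coerce ensembles/ca_traces to a list of ca_trace objects
.as_traces <- function(ensembles) {
  lapply(ensembles, function(e) {
    if (inherits(e, "ca_trace")) e
    else if (inherits(e, "ensemble")) ca_trace(e)
    else stop("expected ensemble or ca_trace objects")
  })
}

#' Pooled DRMSD distance matrix over one or more ensembles
#'
#' Conformers of all ensembles (which must share the residue count N) are
#' pooled and all pairwise DRMSD values arranged in a symmetric matrix with
#' block bookkeeping recording, for every row, the source ensemble and the
#' conformer index within it.
#'
#' @param ensembles list of `ensemble` (or `ca_trace`) objects.
#' @param labels optional ensemble labels (default: ensemble `label`s or
#'   positional names).
#' @return object of class `conformer_dmat`: list with `values` (pooled
#'   symmetric matrix, Angstrom), `ensemble` (integer block index per row),
#'   `conformer` (index within block), `weights` (list of weight vectors)
#'   and `labels`.
#' @export
distance_matrix <- function(ensembles, labels = NULL) {
  if (inherits(ensembles, "ensemble") || inherits(ensembles, "ca_trace"))
    ensembles <- list(ensembles)
  traces <- .as_traces(ensembles)
  Ns <- vapply(traces, function(t) dim(t$coords)[2], integer(1))
  if (length(unique(Ns)) != 1)
    stop("ensembles differ in residue count: ", paste(Ns, collapse = ", "))
  N <- Ns[1]
  if (N < 2) stop("need at least 2 residues")
  Cs <- vapply(traces, function(t) dim(t$coords)[1], integer(1))
  if (is.null(labels)) {
    labels <- vapply(seq_along(ensembles), function(i) {
      l <- ensembles[[i]]$label
      if (is.null(l)) paste0("ensemble", i) else l
    }, character(1))
  }

  npair <- N * (N - 1) / 2
  # column c of X holds the internal-distance vector of pooled conformer c
  X <- matrix(0, npair, sum(Cs))
  col <- 0L
  for (t in traces) {
    for (c in seq_len(dim(t$coords)[1])) {
      col <- col + 1L
      X[, col] <- .pairdist(t$coords[c, , ])
    }
  }
  G <- crossprod(X)
  sq <- diag(G)
  D2 <- (outer(sq, sq, "+") - 2 * G) / npair
  D <- sqrt(pmax(D2, 0))
  diag(D) <- 0
  structure(list(values = D,
                 ensemble = rep(seq_along(Cs), Cs),
                 conformer = unlist(lapply(Cs, seq_len)),
                 weights = lapply(traces, function(t) t$weights),
                 labels = labels),
            class = "conformer_dmat")
}

#' @export
print.conformer_dmat <- function(x, ...) {
  cat("conformer distance matrix: ", nrow(x$values), " pooled conformers, ",
      length(x$weights), " ensemble(s)\n", sep = "")
  invisible(x)
}

.block_id <- function(D, id) {
  if (is.character(id)) {
    i <- match(id, D$labels)
    if (is.na(i)) stop("unknown ensemble label '", id, "'")
    i
  } else {
    i <- as.integer(id)
    if (i < 1 || i > length(D$weights)) stop("ensemble index out of range")
    i
  }
}

#' Mean square distance between two ensembles in conformer space
#'
#' Delta_kl = sum_{ck} sum_{cl} w_k,ck w_l,cl D^2(ck, cl), the
#' weight-averaged squared DRMSD over all conformer pairs of ensembles k and
#' l.  Delta_kk is the squared width of ensemble k (zero for a single
#' conformer or identical conformers); self-pairs are included.
#'
#' @param D a `conformer_dmat` from [distance_matrix()].
#' @param k,l ensemble index or label.
#' @return Delta_kl in Angstrom^2.
#' @export
ensemble_msd <- function(D, k, l = k) {
  stopifnot(inherits(D, "conformer_dmat"))
  ik <- .block_id(D, k); il <- .block_id(D, l)
  rows <- which(D$ensemble == ik)
  cols <- which(D$ensemble == il)
  wk <- D$weights[[ik]]; wl <- D$weights[[il]]
  as.numeric(wk %*% (D$values[rows, cols, drop = FALSE]^2) %*% wl)
}

#' Similarity of two weighted conformer ensembles
#'
#' s_kl = sqrt(Delta_kk Delta_ll) / Delta_kl, a dimensionless measure in
#' \[0, 1\]: 0 for two distinct single-conformer ensembles, 1 for identical
#' ensembles.  The degenerate case Delta_kl = 0 (identical point sets) gives
#' s = 1 by continuity.
#'
#' @inheritParams ensemble_msd
#' @return object of class `similarity_result`: list with `delta_kk`,
#'   `delta_ll`, `delta_kl` (Angstrom^2), `s`, and the Shannon entropies of
#'   the two weight vectors.
#' @export
similarity <- function(D, k, l) {
  stopifnot(inherits(D, "conformer_dmat"))
  ik <- .block_id(D, k); il <- .block_id(D, l)
  dkk <- ensemble_msd(D, ik, ik)
  dll <- ensemble_msd(D, il, il)
  dkl <- ensemble_msd(D, ik, il)
  s <- if (dkl <= .Machine$double.eps) {
    # identical weighted point sets: widths must agree
    stopifnot(abs(dkk - dll) < 1e-9)
    1
  } else sqrt(dkk * dll) / dkl
  structure(list(delta_kk = dkk, delta_ll = dll, delta_kl = dkl, s = s,
                 entropy_k = shannon_entropy(D$weights[[ik]]),
                 entropy_l = shannon_entropy(D$weights[[il]]),
                 labels = D$labels[c(ik, il)]),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf(
    "ensemble similarity %s vs %s\n  Delta_kk = %.4g A^2, Delta_ll = %.4g A^2, Delta_kl = %.4g A^2\n  s_kl = %.4f\n",
    x$labels[1], x$labels[2], x$delta_kk, x$delta_ll, x$delta_kl, x$s))
  invisible(x)
}

#' Pairwise similarity matrix of a set of ensembles
#'
#' @param ensembles list of >= 2 ensembles with a common residue count.
#' @param labels optional labels.
#' @return symmetric matrix of s values with unit diagonal, labelled by
#'   ensemble; attribute `dmat` holds the pooled `conformer_dmat`.
#' @export
similarity_matrix <- function(ensembles, labels = NULL) {
  if (length(ensembles) < 2) stop("need at least 2 ensembles")
  D <- distance_matrix(ensembles, labels)
  K <- length(D$weights)
  S <- diag(1, K)
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    S[i, j] <- S[j, i] <- similarity(D, i, j)$s
  dimnames(S) <- list(D$labels, D$labels)
  attr(S, "dmat") <- D
  S
}
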
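# Folded-domain / IDR partitioning from AlphaFold PAE matrices or
# per-residue disorder tracks, and F / Sf / Mf / D protein classification.

PAE_CAP <- 31.75

#' Load a predicted aligned error (PAE) matrix
#'
#' Accepts the AlphaFold database JSON dialect (key
#' `predicted_aligned_error`, possibly wrapped in a one-element list) or a
#' plain CSV/whitespace matrix.  The matrix is symmetrized by the
#' element-wise mean of M and its transpose; entries above the cap are
#' clipped with a warning.
#'
#' @param path JSON or CSV file, or a numeric matrix.
#' @param cap PAE cap in Angstrom (default 31.75).
#' @return object of class `pae_matrix`: list with `values` (N x N symmetric
#'   matrix) and `cap`.
#' @export
load_pae <- function(path, cap = PAE_CAP) {
  if (is.matrix(path)) {
    M <- path
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::fromJSON(path)
    if (is.data.frame(j) && "predicted_aligned_error" %in% names(j)) {
      M <- j$predicted_aligned_error[[1]]
    } else if (!is.null(names(j)) &&
               "predicted_aligned_error" %in% names(j)) {
      M <- j$predicted_aligned_error
      if (is.list(M) && !is.matrix(M)) M <- M[[1]]
    } else if (is.list(j) && length(j) >= 1 &&
               "predicted_aligned_error" %in% names(j[[1]])) {
      M <- j[[1]]$predicted_aligned_error
    } else stop("no 'predicted_aligned_error' key in ", path)
    M <- as.matrix(M)
  } else {
    M <- as.matrix(read.csv(path, header = FALSE))
  }
  storage.mode(M) <- "double"
  if (nrow(M) != ncol(M))
    stop("PAE matrix is not square: ", nrow(M), " x ", ncol(M))
  if (any(M > cap)) {
    warning("PAE entries above the cap (", cap, " A) were clipped")
    M[M > cap] <- cap
  }
  M[M < 0] <- 0
  M <- (M + t(M)) / 2
  dimnames(M) <- NULL
  structure(list(values = M, cap = cap), class = "pae_matrix")
}

.pae_values <- function(x) {
  if (inherits(x, "pae_matrix")) x$values
  else if (is.matrix(x)) (x + t(x)) / 2
  else stop("expected a pae_matrix or matrix")
}

#' Mean long-range PAE disorder parameter
#'
#' Mean of the symmetrized PAE over residue pairs with sequence separation
#' |i - j| >= `min_seqsep`; near-diagonal pairs are excluded because the
#' PAE is reduced there even in fully disordered proteins.
#'
#' @param pae a `pae_matrix` (or matrix).
#' @param min_seqsep minimum sequence separation (default 10).
#' @return mean PAE in Angstrom.
#' @export
mean_pae_disorder <- function(pae, min_seqsep = 10) {
  M <- .pae_values(pae)
  N <- nrow(M)
  if (N <= min_seqsep) stop("chain shorter than min_seqsep")
  sep <- abs(outer(seq_len(N), seq_len(N), "-"))
  mean(M[sep >= min_seqsep])
}

# centered moving average with window shrinking at the termini,
# rounded half-away-from-zero to integers
.smooth_runs <- function(e, window) {
  N <- length(e)
  h <- (window - 1) %/% 2
  out <- numeric(N)
  for (i in seq_len(N)) {
    lo <- max(1, i - h); hi <- min(N, i + h)
    out[i] <- mean(e[lo:hi])
  }
  floor(out + 0.5)
}

.intervals_to_partition <- function(domains, N, t_domain, min_domain,
                                    idr_min = 10) {
  if (length(domains)) {
    o <- order(vapply(domains, `[`, numeric(1), 1))
    domains <- domains[o]
  }
  linkers <- list()
  n_idr <- NULL; c_idr <- NULL
  if (length(domains)) {
    first <- domains[[1]][1]; last <- domains[[length(domains)]][2]
    if (first > 1) n_idr <- c(1, first - 1)
    if (last < N) c_idr <- c(last + 1, N)
    if (length(domains) > 1) {
      for (d in seq_len(length(domains) - 1)) {
        gs <- domains[[d]][2] + 1; ge <- domains[[d + 1]][1] - 1
        if (ge >= gs) linkers[[length(linkers) + 1]] <- c(gs, ge)
      }
    }
  }
  part <- structure(list(domains = domains, linkers = linkers,
                         n_terminal_idr = n_idr, c_terminal_idr = c_idr,
                         protein_class = NA_character_, t_domain = t_domain,
                         min_domain = min_domain, N = N),
                    class = "domain_partition")
  part$protein_class <- classify(part, N, idr_min = idr_min)
  part
}

#' Partition a protein into folded domains from its PAE matrix
#'
#' Implements iterative domain detection on the symmetrized PAE matrix M:
#' M is thresholded into a binary matrix B (B_ij = 1 where M_ij <
#' `t_domain`); for each residue i the run length e_i is the largest DN
#' such that B_ij = 1 for all j = i+1 ... i+DN; e is smoothed by a centered
#' moving average of width `window` (shrinking at the termini) and rounded.
#' Repeatedly, the maximal e seeds a preliminary domain (i_max, i_max +
#' e_max) when e_max >= `min_domain`; boundaries grow outward while the mean
#' PAE of the adjacent residue to the current members stays below
#' `t_domain`; accepted members are removed from e and masked in M (rows and
#' columns set to 1e6).  Finally, domains separated by a linker of fewer
#' than `merge_gap` residues are combined.
#'
#' @param pae a `pae_matrix` (or matrix).
#' @param t_domain domain PAE threshold in Angstrom (default 10.58, one
#'   third of the 31.75 A cap).
#' @param min_domain minimum folded-domain size in residues (default 25).
#' @param merge_gap domains separated by a linker shorter than this many
#'   residues are merged (default 3).
#' @param window moving-average window for the run-length vector (default
#'   5).
#' @param idr_min minimum length of a terminal IDR for classification
#'   (default 10).
#' @return object of class `domain_partition`: 1-based inclusive `domains`
#'   and `linkers`, terminal IDR intervals, and `protein_class` in
#'   F / Sf / Mf / D.
#' @export
partition_pae <- function(pae, t_domain = 10.58, min_domain = 25,
                          merge_gap = 3, window = 5, idr_min = 10) {
  M <- .pae_values(pae)
  N <- nrow(M)
  if (N < min_domain) stop("chain shorter than min_domain")
  B <- M < t_domain

  e <- integer(N)
  for (i in seq_len(N)) {
    if (i == N) { e[i] <- 0L; next }
    run <- which(!B[i, (i + 1):N])
    e[i] <- if (length(run)) run[1] - 1L else N - i
  }
  e <- .smooth_runs(e, window)

  assigned <- logical(N)
  domains <- list()
  repeat {
    emax <- max(e)
    if (emax < min_domain) break
    i0 <- which.max(e)
    hi <- min(i0 + emax, N)
    members <- i0:hi
    # keep the seed an interval: truncate at previously assigned residues
    if (any(assigned[members])) {
      cut <- which(assigned[members])[1]
      members <- if (cut > 1) members[seq_len(cut - 1)] else integer(0)
    }
    if (length(members) < min_domain) {
      e[i0:hi] <- 0L   # exhausted seed; prevent re-selection
      next
    }
    # contiguous outward refinement by mean PAE to current members
    repeat {
      grew <- FALSE
      lo <- members[1]; hi <- members[length(members)]
      if (lo > 1 && !assigned[lo - 1] &&
          mean(M[lo - 1, members]) < t_domain) {
        members <- c(lo - 1, members); grew <- TRUE
      }
      hi <- members[length(members)]
      if (hi < N && !assigned[hi + 1] &&
          mean(M[hi + 1, members]) < t_domain) {
        members <- c(members, hi + 1); grew <- TRUE
      }
      if (!grew) break
    }
    domains[[length(domains) + 1]] <- c(members[1], members[length(members)])
    assigned[members] <- TRUE
    e[members] <- 0L
    M[members, ] <- 1e6
    M[, members] <- 1e6
  }
  domains <- .merge_intervals(domains, merge_gap)
  .intervals_to_partition(domains, N, t_domain, min_domain, idr_min)
}

.merge_intervals <- function(domains, merge_gap) {
  if (length(domains) < 2) return(domains)
  o <- order(vapply(domains, `[`, numeric(1), 1))
  domains <- domains[o]
  out <- list(domains[[1]])
  for (d in domains[-1]) {
    last <- out[[length(out)]]
    gap <- d[1] - last[2] - 1
    if (gap < merge_gap) out[[length(out)]] <- c(last[1], max(last[2], d[2]))
    else out[[length(out) + 1]] <- d
  }
  out
}

#' Classify a protein from its domain partition
#'
#' D if no folded domain was found; Mf if two or more; otherwise Sf if a
#' terminal segment outside the single domain has at least `idr_min`
#' residues, else F.
#'
#' @param partition a `domain_partition`.
#' @param N chain length (default: taken from the partition).
#' @param idr_min minimum terminal IDR length (default 10).
#' @return class label, one of "F", "Sf", "Mf", "D".
#' @export
classify <- function(partition, N = partition$N, idr_min = 10) {
  nd <- length(partition$domains)
  if (nd == 0) return("D")
  if (nd >= 2) return("Mf")
  dom <- partition$domains[[1]]
  n_tail <- dom[1] - 1
  c_tail <- N - dom[2]
  if (n_tail >= idr_min || c_tail >= idr_min) "Sf" else "F"
}

#' @export
print.domain_partition <- function(x, ...) {
  cat("domain partition (N = ", x$N, "): class ", x$protein_class, "\n",
      sep = "")
  if (length(x$domains))
    for (d in x$domains) cat("  domain ", d[1], "-", d[2], "\n", sep = "")
  else cat("  no folded domains\n")
  invisible(x)
}

#' Partition from a one-dimensional disorder track
#'
#' Residues are classified as ordered by a strict threshold rule (eSpritz
#' style: ordered when score < threshold; CheZOD style: ordered when score
#' >= threshold is expressed as `ordered_when = "above"` with threshold 8).
#' Folded domains are runs of at least `min_domain` ordered residues;
#' domains separated by a linker of fewer than `merge_gap` residues are
#' merged.
#'
#' @param scores numeric per-residue disorder (or order) scores.
#' @param threshold decision threshold (default 0.15, eSpritz style).
#' @param ordered_when `"below"` (ordered when score < threshold; default)
#'   or `"above"` (ordered when score > threshold).
#' @param min_domain,merge_gap,idr_min as in [partition_pae()].
#' @return a `domain_partition`.
#' @export
partition_disorder_track <- function(scores, threshold = 0.15,
                                     ordered_when = c("below", "above"),
                                     min_domain = 25, merge_gap = 3,
                                     idr_min = 10) {
  ordered_when <- match.arg(ordered_when)
  N <- length(scores)
  ordered <- if (ordered_when == "below") scores < threshold
             else scores > threshold
  r <- rle(ordered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  domains <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] && r$lengths[k] >= min_domain)
      domains[[length(domains) + 1]] <- c(starts[k], ends[k])
  }
  domains <- .merge_intervals(domains, merge_gap)
  .intervals_to_partition(domains, N, threshold, min_domain, idr_min)
}

#' Threshold sensitivity sweep of the domain partition
#'
#' Re-partitions the input for every threshold in `values` and summarizes
#' the class assignment across the sweep, exposing how sensitive the
#' classification is to the threshold choice.
#'
#' @param x a `pae_matrix` (threshold = t_domain) or a numeric disorder
#'   track (threshold = t_disorder).
#' @param values thresholds to sweep; defaults: 8.58 to 12.58 A in steps of
#'   0.1 for PAE, 0.14 to 0.16 in steps of 0.001 for tracks.
#' @param ... passed to [partition_pae()] or [partition_disorder_track()].
#' @return object of class `threshold_sweep`: list with `per_threshold`
#'   (data.frame: threshold, class, n_domains, domain_residues) and
#'   `class_fraction` (fraction of sweep values yielding each class).
#' @export
sweep_threshold <- function(x, values = NULL, ...) {
  is_pae <- inherits(x, "pae_matrix") || is.matrix(x)
  if (is.null(values))
    values <- if (is_pae) seq(8.58, 12.58, by = 0.1)
              else seq(0.14, 0.16, by = 0.001)
  rows <- lapply(values, function(t) {
    p <- if (is_pae) partition_pae(x, t_domain = t, ...)
         else partition_disorder_track(x, threshold = t, ...)
    data.frame(threshold = t, class = p$protein_class,
               n_domains = length(p$domains),
               domain_residues = sum(vapply(
                 p$domains, function(d) d[2] - d[1] + 1, numeric(1))))
  })
  per <- do.call(rbind, rows)
  frac <- table(factor(per$class, levels = c("F", "Sf", "Mf", "D")))
  frac <- as.numeric(frac) / nrow(per)
  names(frac) <- c("F", "Sf", "Mf", "D")
  structure(list(per_threshold = per, class_fraction = frac),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("threshold sweep over", nrow(x$per_threshold), "values\n")
  print(round(x$class_fraction, 3))
  invisible(x)
}

#' Export a domain partition as BED intervals
#'
#' @param partition a `domain_partition`.
#' @param path output BED path; 1-based inclusive domains are converted to
#'   0-based half-open intervals.
#' @param name sequence name for the first BED column.
#' @return invisibly, the data.frame written.
#' @export
write_partition_bed <- function(partition, path, name = "protein") {
  doms <- partition$domains
  df <- if (length(doms)) {
    data.frame(chrom = name,
               start = vapply(doms, `[`, numeric(1), 1) - 1,
               end = vapply(doms, `[`, numeric(1), 2),
               name = sprintf("domain_%d", seq_along(doms)))
  } else data.frame(chrom = character(), start = numeric(),
                    end = numeric(), name = character())
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(df)
}
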
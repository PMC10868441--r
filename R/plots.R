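# ggplot2 figures for the analysis results.

#' Plot section end-to-end distances against section length
#'
#' Gray band: min/max of r_ee over sections of each length; green line:
#' mean over equal-length sections; red line: the fitted Flory scaling law
#' b0 DN^nu.
#'
#' @param ree a `section_ree`.
#' @param fit a `flory_fit` (default: fitted from `ree`).
#' @return a ggplot object.
#' @export
plot_ree_scaling <- function(ree, fit = fit_flory(ree)) {
  M <- .ree_matrix(ree)
  N <- nrow(M)
  dn <- seq_len(N - 1)
  band <- t(vapply(dn, function(d) {
    i <- seq_len(N - d)
    v <- M[cbind(i, i + d)]
    c(min(v), max(v))
  }, numeric(2)))
  df <- data.frame(dn = dn, lo = band[, 1], hi = band[, 2],
                   mean = mean_ree_by_length(M),
                   fit = fit$b0 * dn^fit$nu)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dn)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "gray70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), color = "darkgreen") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "red") +
    ggplot2::labs(
      x = expression(Delta * N),
      y = expression(r[ee] ~ "(Å)"),
      title = sprintf("b0 = %.2f Å, nu = %.3f", fit$b0, fit$nu)) +
    ggplot2::theme_minimal()
}

.matrix_df <- function(M) {
  data.frame(i = rep(seq_len(nrow(M)), ncol(M)),
             j = rep(seq_len(ncol(M)), each = nrow(M)),
             value = as.numeric(M))
}

#' Heat map of a section deviation (or proximity/compactness) matrix
#'
#' Diverging colormap: blue = compact, red = expanded.
#'
#' @param dev a `section_deviation` (or a matrix).
#' @param which which matrix to draw: "S" (default), "P" or "Cmat".
#' @return a ggplot object.
#' @export
plot_deviation_matrix <- function(dev, which = c("S", "P", "Cmat")) {
  which <- match.arg(which)
  M <- if (inherits(dev, "section_deviation")) dev[[which]] else dev
  df <- .matrix_df(M)
  lim <- max(abs(df$value), na.rm = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-lim, lim),
                                  na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue i", y = "residue j", fill = which) +
    ggplot2::theme_minimal()
}

#' Heat map of an ensemble similarity matrix
#'
#' @param S matrix from [similarity_matrix()].
#' @return a ggplot object.
#' @export
plot_similarity_matrix <- function(S) {
  df <- .matrix_df(S)
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "ensemble", y = "ensemble", fill = "s") +
    ggplot2::theme_minimal()
}

.class_colors <- c(Gly = "red", Pro = "green3", Thr = "blue",
                   other = "black")

#' Plot a site-specific flexibility profile
#'
#' Residues are color-coded Gly red / Pro green / Thr blue / other black;
#' when a random-coil reference is attached, its per-class 95% bands are
#' drawn as horizontal ranges.
#'
#' @param profile a `flexibility_profile`.
#' @return a ggplot object.
#' @export
plot_flexibility <- function(profile) {
  df <- as.data.frame(profile)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$resno, .data$f,
                                        color = .data$class)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = .class_colors) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "residue", y = "flexibility f") +
    ggplot2::theme_minimal()
  if (!is.null(profile$reference)) {
    rf <- profile$reference$f_class
    rf$class <- factor(rf$class, levels = names(.class_colors))
    p <- p + ggplot2::geom_rect(
      data = rf, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = -Inf, xmax = Inf, ymin = .data$lower,
                   ymax = .data$upper, fill = .data$class)) +
      ggplot2::scale_fill_manual(values = .class_colors)
  }
  p
}

#' Plot a site-specific order profile
#'
#' @param profile an `order_profile`.
#' @param resno optional site numbering.
#' @return a ggplot object.
#' @export
plot_order <- function(profile, resno = seq_along(profile$o)) {
  df <- data.frame(resno = resno, o = profile$o)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$resno, .data$o)) +
    ggplot2::geom_point(color = "steelblue", size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "site", y = "order o") +
    ggplot2::theme_minimal()
  if (!is.null(profile$reference_band))
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = profile$reference_band[1],
                               ymax = profile$reference_band[2],
                               alpha = 0.2, fill = "gray40")
  p
}

#' Plot a PAE matrix with detected domains overlaid
#'
#' Detected folded domains are drawn as red squares on the PAE heat map.
#'
#' @param pae a `pae_matrix`.
#' @param partition optional `domain_partition` to overlay.
#' @return a ggplot object.
#' @export
plot_pae <- function(pae, partition = NULL) {
  df <- .matrix_df(.pae_values(pae))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue", y = "residue", fill = "PAE (Å)") +
    ggplot2::theme_minimal()
  if (!is.null(partition) && length(partition$domains)) {
    doms <- data.frame(
      xmin = vapply(partition$domains, `[`, numeric(1), 1) - 0.5,
      xmax = vapply(partition$domains, `[`, numeric(1), 2) + 0.5)
    doms$ymin <- doms$xmin; doms$ymax <- doms$xmax
    p <- p + ggplot2::geom_rect(
      data = doms, inherit.aes = FALSE, fill = NA, color = "red",
      linewidth = 0.6,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax))
  }
  p
}
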
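#' Plot a density profile
#'
#' Density against distance from the membrane center, optionally with the
#' bound/unbound cutoff marked.
#'
#' @param object A [density_profile()].
#' @param cutoff Optional `cutoff_result` (or numeric, nm) to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, cutoff = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$z_nm,
                                            y = .data$rho_per_nm)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance from membrane center z (nm)",
                  y = expression(rho ~ (nm^-1))) +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    zc <- if (is.numeric(cutoff)) cutoff else cutoff$z_cut
    p <- p + ggplot2::geom_vline(xintercept = zc, linetype = "dashed")
  }
  p
}

#' Plot a 2-D free-energy surface
#'
#' Filled raster with contours at -5, -10 and -15 kJ/mol (explored cells
#' only).
#'
#' @param object A [fes2d()].
#' @param contours Contour levels in kJ/mol.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fes2d <- function(object, contours = c(-5, -10, -15), ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df[!is.na(df$free_energy), ],
                       ggplot2::aes(x = .data$cv1, y = .data$cv2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$free_energy)) +
    ggplot2::scale_fill_viridis_c(name = "F (kJ/mol)") +
    ggplot2::labs(x = "peptide 1 - membrane distance (nm)",
                  y = "peptide 2 - membrane distance (nm)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
  if (length(contours) > 0) {
    p <- p + ggplot2::geom_contour(ggplot2::aes(z = .data$free_energy),
                                   breaks = contours, color = "white",
                                   linewidth = 0.3)
  }
  p
}

#' Plot a correlation curve
#'
#' `G(tau)` on a logarithmic lag axis.
#'
#' @param object A [correlate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$tau_s, y = .data$g)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  title = unique(object$pair)) +
    ggplot2::theme_minimal()
}

#' Plot a Langmuir isotherm fit
#'
#' Measured occupancies against free concentration with the fitted isotherm;
#' optionally normalized so the fit converges to 1 at saturation.
#'
#' @param object A [fit_langmuir()] result.
#' @param normalized Plot `n_p / n_max` instead of `n_p` (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.langmuir_fit <- function(object, normalized = TRUE, ...) {
  pts <- object$points
  grid <- tibble::tibble(
    c_p_free = 10^seq(log10(min(pts$c_p_free[pts$c_p_free > 0])),
                      log10(max(pts$c_p_free)), length.out = 200)
  )
  grid$n_p <- object$n_max * grid$c_p_free / (object$kd + grid$c_p_free)
  if (normalized) {
    pts$y <- pts$n_p / object$n_max
    grid$y <- grid$n_p / object$n_max
    ylab <- expression(N[P] / N[max])
  } else {
    pts$y <- pts$n_p
    grid$y <- grid$n_p
    ylab <- expression(N[P] ~ "per vesicle")
  }
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$c_p_free, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = object$kd, linetype = "dotted") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(C[P]^free ~ "(M)"), y = ylab) +
    ggplot2::theme_minimal()
}
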
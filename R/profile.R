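#' Symmetrized number-density profile along the membrane normal
#'
#' Histograms particle distances from the membrane center along z, folded
#' across the center (`|z|`, i.e. averaged over the two leaflets), and
#' normalizes to unit integral over `[0, z_max]`. The resulting density
#' `rho(z)` (in 1/nm) is the quantity whose Boltzmann inversion yields the
#' adsorption free energy.
#'
#' An initial equilibration span is excluded via `discard_ns` (frames with
#' `time_ns >= discard_ns` are kept).
#'
#' @param traj A [z_trajectory()], or a plain data frame with `time_ns` and
#'   `z_nm` columns.
#' @param bin_width Histogram bin width in nm (default 0.02).
#' @param discard_ns Equilibration span to discard, in ns (default 500).
#' @param fold Fold the profile across the membrane center (default `TRUE`);
#'   set to `FALSE` only for diagnosing leaflet asymmetry (the profile then
#'   spans signed z and is not suitable for [binding_probabilities()]).
#' @param z_max Upper edge of the profile in nm; defaults to half the largest
#'   box height for a [z_trajectory()], else the largest observed `|z|`.
#'
#' @return A tibble of class `density_profile` with columns `z_nm` (bin
#'   midpoints) and `rho_per_nm`, and attributes `bin_edges`, `symmetrized`,
#'   `n_frames_used`, `equilibration_discarded`, `z_max`.
#' @export
density_profile <- function(traj, bin_width = 0.02, discard_ns = 500,
                            fold = TRUE, z_max = NULL) {
  .check_scalar_pos(bin_width, "bin_width")
  .check_columns(traj, c("time_ns", "z_nm"), "trajectory")
  kept <- traj[traj$time_ns >= discard_ns, , drop = FALSE]
  if (nrow(kept) == 0L) {
    abort("no frames survive the equilibration discard")
  }
  if (is.null(z_max)) {
    frames <- attr(traj, "frames")
    z_max <- if (!is.null(frames)) max(frames$box_z) / 2 else max(abs(kept$z_nm))
  }
  z <- if (fold) abs(kept$z_nm) else kept$z_nm
  lo <- if (fold) 0 else -ceiling(z_max / bin_width) * bin_width
  edges <- seq(lo, by = bin_width,
               length.out = ceiling((z_max - lo) / bin_width - 1e-9) + 1L)
  if (edges[length(edges)] < z_max - 1e-12) {
    edges <- c(edges, edges[length(edges)] + bin_width)
  }
  idx <- findInterval(z, edges, left.open = FALSE)
  idx[idx > length(edges) - 1L] <- length(edges) - 1L # z == z_max edge case
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  rho <- counts / (sum(counts) * bin_width)
  out <- tibble::tibble(
    z_nm = (edges[-length(edges)] + edges[-1]) / 2,
    rho_per_nm = rho
  )
  class(out) <- c("density_profile", class(out))
  attr(out, "bin_edges") <- edges
  attr(out, "symmetrized") <- fold
  attr(out, "n_frames_used") <- length(unique(kept$time_ns))
  attr(out, "equilibration_discarded") <- discard_ns
  attr(out, "z_max") <- z_max
  out
}

#' Locate the bound/unbound cutoff from a density profile
#'
#' The cutoff separating the membrane-bound from the bulk region is the
#' position of the density minimum between the interfacial binding peak and
#' the bulk plateau. A peak only counts as interfacial if it lies below
#' `default_cut` and exceeds the bulk plateau level (mean density over the
#' outermost `bulk_window` nm) by at least `prominence` (relative). Profiles
#' with no such peak (typically the weakly adsorbing species) fall back to
#' the fixed default cutoff of 3.5 nm.
#'
#' Ties in the minimum are broken toward the smallest z.
#'
#' @param profile A [density_profile()].
#' @param default_cut Fallback cutoff in nm (default 3.5).
#' @param prominence Minimum relative excess of the interfacial peak over the
#'   bulk plateau (default 0.1, i.e. 10 percent).
#' @param bulk_window Width of the outer window defining the bulk plateau, nm.
#'
#' @return A list of class `cutoff_result` with elements `z_cut`, `method`
#'   (`"detected_minimum"` or `"default_fallback"`), and `rho_min` (`NA` for
#'   the fallback).
#' @export
find_cutoff <- function(profile, default_cut = 3.5, prominence = 0.1,
                        bulk_window = 1.0) {
  .check_columns(profile, c("z_nm", "rho_per_nm"), "profile")
  z <- profile$z_nm
  rho <- profile$rho_per_nm
  if (max(z) < default_cut) {
    abort("profile extent is smaller than the default cutoff")
  }
  fallback <- structure(
    list(z_cut = default_cut, method = "default_fallback", rho_min = NA_real_),
    class = "cutoff_result"
  )
  bulk_start <- max(z) - bulk_window
  bulk_level <- mean(rho[z > bulk_start])
  n <- length(rho)
  if (n < 3L) return(fallback)
  is_peak <- c(FALSE, rho[2:(n - 1)] >= rho[1:(n - 2)] &
                 rho[2:(n - 1)] >= rho[3:n], FALSE)
  cand <- which(is_peak & z < default_cut &
                  rho > bulk_level * (1 + prominence))
  if (length(cand) == 0L) return(fallback)
  peak <- cand[which.max(rho[cand])]
  region <- which(z > z[peak] & z <= bulk_start)
  if (length(region) == 0L) return(fallback)
  i_min <- region[which.min(rho[region])] # which.min takes the first = smallest z
  structure(
    list(z_cut = z[i_min], method = "detected_minimum", rho_min = rho[i_min]),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("<cutoff_result> z_cut = %.3f nm (%s)\n", x$z_cut, x$method))
  invisible(x)
}

#' Bound and unbound probabilities from a density profile
#'
#' Integrates the normalized density over `[0, z_cut]` (bound) and
#' `[z_cut, z_max]` (unbound). The density is piecewise constant over the
#' histogram bins; the bin containing the cutoff is split by linear
#' interpolation, which removes the bin-width sensitivity of the result.
#' The two probabilities sum to one by construction.
#'
#' @param profile A [density_profile()] (folded/symmetrized).
#' @param cutoff A `cutoff_result` from [find_cutoff()], or a single cutoff
#'   distance in nm.
#'
#' @return A list of class `binding_probabilities` with elements `p_bound`,
#'   `p_unbound` and `cutoff`.
#' @export
binding_probabilities <- function(profile, cutoff) {
  .check_columns(profile, c("z_nm", "rho_per_nm"), "profile")
  if (is.numeric(cutoff)) {
    cutoff <- structure(list(z_cut = cutoff, method = "user",
                             rho_min = NA_real_), class = "cutoff_result")
  }
  z_cut <- cutoff$z_cut
  edges <- attr(profile, "bin_edges")
  if (is.null(edges)) {
    w <- diff(profile$z_nm)
    w <- c(w, w[length(w)])
    edges <- c(profile$z_nm - w / 2, profile$z_nm[length(w)] + w[length(w)] / 2)
  }
  if (z_cut <= edges[1] || z_cut >= edges[length(edges)]) {
    abort("cutoff must lie strictly inside the profile range")
  }
  widths <- diff(edges)
  mass <- profile$rho_per_nm * widths
  i <- findInterval(z_cut, edges, left.open = FALSE)
  frac <- (z_cut - edges[i]) / widths[i]
  p_bound <- sum(mass[seq_len(i - 1L)]) + mass[i] * frac
  p_unbound <- mass[i] * (1 - frac)
  if (i < length(mass)) {
    p_unbound <- p_unbound + sum(mass[(i + 1L):length(mass)])
  }
  structure(
    list(p_bound = p_bound, p_unbound = p_unbound, cutoff = cutoff),
    class = "binding_probabilities"
  )
}

#' @export
print.binding_probabilities <- function(x, ...) {
  cat(sprintf(
    "<binding_probabilities> P_bound = %.4f, P_unbound = %.4f (z_cut = %.3f nm)\n",
    x$p_bound, x$p_unbound, x$cutoff$z_cut
  ))
  invisible(x)
}

#' Adsorption free energy by Boltzmann inversion
#'
#' Computes `dG = -kB T log(P_bound / P_unbound)` in kJ/mol from the bound
#' and unbound probabilities. Negative values mean adsorption is favored.
#' Exactly one of the probabilities being zero signals a divergent free
#' energy (no sampling of one region) and is raised as an error.
#'
#' @param probs A [binding_probabilities()] object (or a list with
#'   `p_bound`/`p_unbound`).
#' @param temperature Absolute temperature in K (default 310).
#'
#' @return A list of class `binding_free_energy` with elements `delta_g`
#'   (kJ/mol), `temperature`, `probabilities` and `kB`.
#' @export
#' @examples
#' p <- structure(list(p_bound = 0.9, p_unbound = 0.1,
#'                     cutoff = list(z_cut = 3.5)),
#'                class = "binding_probabilities")
#' adsorption_dg(p)$delta_g # about -5.66 kJ/mol at 310 K
adsorption_dg <- function(probs, temperature = 310) {
  .check_scalar_pos(temperature, "temperature")
  if (probs$p_bound <= 0 || probs$p_unbound <= 0) {
    abort(paste0(
      "divergent free energy: one of the regions has zero probability ",
      "(no bound/unbound sampling)"
    ))
  }
  dg <- -.kB * temperature * log(probs$p_bound / probs$p_unbound)
  structure(
    list(delta_g = dg, temperature = temperature, probabilities = probs,
         kB = .kB),
    class = "binding_free_energy"
  )
}

#' @export
print.binding_free_energy <- function(x, ...) {
  cat(sprintf(
    "<binding_free_energy> dG = %.3f kJ/mol at %g K (P_bound = %.4f)\n",
    x$delta_g, x$temperature, x$probabilities$p_bound
  ))
  invisible(x)
}

#' One-call adsorption free energy from a trajectory
#'
#' Convenience pipeline: [density_profile()] then [find_cutoff()],
#' [binding_probabilities()] and [adsorption_dg()], returning a one-row tidy
#' summary.
#'
#' @inheritParams density_profile
#' @inheritParams find_cutoff
#' @inheritParams adsorption_dg
#'
#' @return A one-row tibble with `delta_g_kj_mol`, `p_bound`, `p_unbound`,
#'   `z_cut_nm`, `cutoff_method`, `n_frames_used`.
#' @export
adsorption_free_energy <- function(traj, bin_width = 0.02, discard_ns = 500,
                                   temperature = 310, default_cut = 3.5,
                                   prominence = 0.1, z_max = NULL) {
  prof <- density_profile(traj, bin_width = bin_width,
                          discard_ns = discard_ns, z_max = z_max)
  cut <- find_cutoff(prof, default_cut = default_cut, prominence = prominence)
  probs <- binding_probabilities(prof, cut)
  dg <- adsorption_dg(probs, temperature = temperature)
  tibble::tibble(
    delta_g_kj_mol = dg$delta_g,
    p_bound = probs$p_bound,
    p_unbound = probs$p_unbound,
    z_cut_nm = cut$z_cut,
    cutoff_method = cut$method,
    n_frames_used = attr(prof, "n_frames_used")
  )
}
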
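#' Membrane-like potential of mean force along the membrane normal
#'
#' A smooth analytic stand-in for the potential of mean force a cationic
#' peptide experiences along the membrane normal: a steep exponential
#' repulsion below `wall_pos` (the bilayer core), a Gaussian adsorption well
#' at `well_pos` (the interfacial binding site, by default at 2.2 nm where
#' the adsorbed-peptide density peaks), a small Gaussian barrier at
#' `barrier_pos` separating the well from the bulk (this creates the density
#' minimum that defines the bound/unbound cutoff), and zero in the bulk.
#' All parameters in nm and kJ/mol.
#'
#' @param well_depth Depth of the adsorption well, kJ/mol (>0 = attractive).
#' @param well_pos Well position (default 2.2 nm).
#' @param well_width Gaussian sigma of the well (default 0.25 nm).
#' @param barrier_height Height of the desorption barrier (default 2 kJ/mol).
#' @param barrier_pos Barrier position (default 3.0 nm).
#' @param barrier_width Gaussian sigma of the barrier (default 0.2 nm).
#' @param wall_pos Onset of the repulsive wall (default 1.5 nm).
#' @param wall_amp Wall energy at `wall_pos` (default 5 kJ/mol).
#' @param wall_steep Exponential decay length of the wall (default 0.05 nm).
#' @param box_half Half box height; the bulk extends to here (default 4.5 nm).
#'
#' @return An object of class `membrane_pmf`.
#' @export
membrane_pmf <- function(well_depth = 20, well_pos = 2.2, well_width = 0.25,
                         barrier_height = 2, barrier_pos = 3.0,
                         barrier_width = 0.2, wall_pos = 1.5, wall_amp = 5,
                         wall_steep = 0.05, box_half = 4.5) {
  if (!(0 < wall_pos && wall_pos < well_pos && well_pos < barrier_pos &&
        barrier_pos < box_half)) {
    abort("require 0 < wall_pos < well_pos < barrier_pos < box_half")
  }
  if (well_depth < 0) abort("`well_depth` must be >= 0 (positive = attractive)")
  structure(
    list(well_depth = well_depth, well_pos = well_pos, well_width = well_width,
         barrier_height = barrier_height, barrier_pos = barrier_pos,
         barrier_width = barrier_width, wall_pos = wall_pos,
         wall_amp = wall_amp, wall_steep = wall_steep, box_half = box_half),
    class = "membrane_pmf"
  )
}

#' @export
print.membrane_pmf <- function(x, ...) {
  cat(sprintf(
    "<membrane_pmf> well %.1f kJ/mol at %.2f nm, barrier %.1f kJ/mol at %.2f nm, wall at %.2f nm, box_half %.2f nm\n",
    x$well_depth, x$well_pos, x$barrier_height, x$barrier_pos, x$wall_pos,
    x$box_half
  ))
  invisible(x)
}

#' Evaluate a membrane PMF (and its gradient)
#'
#' `pmf_value` returns U(z) in kJ/mol; `pmf_gradient` its analytic derivative
#' dU/dz. Both are vectorized over `z` (signed, nm; the potential is even
#' in z).
#'
#' @param pmf A [membrane_pmf()].
#' @param z Positions in nm, `|z| <= box_half`.
#' @return Numeric vector, kJ/mol (or kJ/mol/nm for the gradient).
#' @export
pmf_value <- function(pmf, z) {
  if (any(abs(z) > pmf$box_half + 1e-9)) abort("|z| must be <= box_half")
  az <- abs(z)
  pmf$wall_amp * exp(-(az - pmf$wall_pos) / pmf$wall_steep) -
    pmf$well_depth * exp(-0.5 * ((az - pmf$well_pos) / pmf$well_width)^2) +
    pmf$barrier_height * exp(-0.5 * ((az - pmf$barrier_pos) / pmf$barrier_width)^2)
}

#' @rdname pmf_value
#' @export
pmf_gradient <- function(pmf, z) {
  if (any(abs(z) > pmf$box_half + 1e-9)) abort("|z| must be <= box_half")
  az <- abs(z)
  s <- ifelse(z >= 0, 1, -1)
  d <- -pmf$wall_amp / pmf$wall_steep * exp(-(az - pmf$wall_pos) / pmf$wall_steep) +
    pmf$well_depth * (az - pmf$well_pos) / pmf$well_width^2 *
      exp(-0.5 * ((az - pmf$well_pos) / pmf$well_width)^2) -
    pmf$barrier_height * (az - pmf$barrier_pos) / pmf$barrier_width^2 *
      exp(-0.5 * ((az - pmf$barrier_pos) / pmf$barrier_width)^2)
  s * d
}

#' Exact adsorption free energy of a membrane PMF
#'
#' Reference value for the sampled estimators: the Boltzmann-weighted length
#' ratio of bound and unbound regions, evaluated by adaptive quadrature on
#' the one-sided profile,
#' `dG = -kB T log( int_0^zcut exp(-U/kBT) dz / int_zcut^box_half exp(-U/kBT) dz )`.
#'
#' @param pmf A [membrane_pmf()].
#' @param z_cut Cutoff distance (nm), inside `(0, box_half)`.
#' @param temperature Temperature in K (default 310).
#' @return Free energy in kJ/mol.
#' @export
analytic_dg <- function(pmf, z_cut, temperature = 310) {
  .check_scalar_pos(temperature, "temperature")
  if (z_cut <= 0 || z_cut >= pmf$box_half) {
    abort("`z_cut` must lie in (0, box_half)")
  }
  kT <- .kB * temperature
  f <- function(z) exp(-pmf_value(pmf, z) / kT)
  ib <- stats::integrate(f, 0, z_cut, rel.tol = 1e-10,
                         subdivisions = 1000L)$value
  iu <- stats::integrate(f, z_cut, pmf$box_half, rel.tol = 1e-10,
                         subdivisions = 1000L)$value
  -kT * log(ib / iu)
}

#' Sample a membrane PMF by Markov chain Monte Carlo
#'
#' Draws an equilibrium z trajectory from the Boltzmann distribution of a
#' membrane PMF over the signed interval `(-box_half, box_half)`, either by
#' Metropolis Monte Carlo with uniform proposals (default) or by overdamped
#' Langevin dynamics with reflecting boundaries. Fully reproducible from the
#' integer seed (the sampler carries its own generator and does not touch
#' R's RNG state). A short internal burn-in is discarded, so the returned
#' frames are all usable (pass `discard_ns = 0` downstream).
#'
#' @param pmf A [membrane_pmf()].
#' @param n_samples Number of samples to return.
#' @param temperature Temperature in K (default 310).
#' @param seed Integer seed.
#' @param method `"metropolis"` or `"overdamped"`.
#' @param step Uniform proposal half-width in nm (Metropolis; default 0.6).
#' @param dt Reduced time step (overdamped; default 0.002).
#' @param burnin Burn-in steps discarded before recording (default 1000).
#'
#' @return A [z_trajectory()] with one particle and `time_ns = 0, 1, ...`;
#'   the Metropolis acceptance rate is stored in attribute `acceptance` and
#'   a warning is raised if it falls outside `[0.05, 0.95]`.
#' @export
sample_pmf <- function(pmf, n_samples, temperature = 310, seed = 1,
                       method = c("metropolis", "overdamped"), step = 0.6,
                       dt = 0.002, burnin = 1000L) {
  method <- match.arg(method)
  if (n_samples < 1) abort("`n_samples` must be >= 1")
  kT <- .kB * temperature
  res <- if (method == "metropolis") {
    cpp_sample_pmf_metropolis(
      as.integer(n_samples), kT, step, pmf$box_half, as.integer(burnin),
      as.numeric(seed), pmf$wall_pos, pmf$wall_amp, pmf$wall_steep,
      pmf$well_depth, pmf$well_pos, pmf$well_width, pmf$barrier_height,
      pmf$barrier_pos, pmf$barrier_width
    )
  } else {
    cpp_sample_pmf_overdamped(
      as.integer(n_samples), kT, dt, pmf$box_half, as.integer(burnin),
      as.numeric(seed), pmf$wall_pos, pmf$wall_amp, pmf$wall_steep,
      pmf$well_depth, pmf$well_pos, pmf$well_width, pmf$barrier_height,
      pmf$barrier_pos, pmf$barrier_width
    )
  }
  if (method == "metropolis" &&
      (res$acceptance < 0.05 || res$acceptance > 0.95)) {
    warn(sprintf(
      "Metropolis acceptance rate %.1f%% outside [5%%, 95%%]; adjust `step`",
      100 * res$acceptance
    ))
  }
  out <- z_trajectory(
    tibble::tibble(
      time_ns = seq_len(n_samples) - 1,
      particle_id = 1L,
      z_nm = res$z
    ),
    box_z = 2 * pmf$box_half,
    species_label = "synthetic PMF walker"
  )
  attr(out, "acceptance") <- res$acceptance
  attr(out, "pmf") <- pmf
  out
}

#' Synthetic 2-D free-energy surface with known ground truth
#'
#' Builds a square free-energy grid from a separable ground truth
#' `f(a, b) = U(a) + U(b)` (the same one-dimensional membrane PMF applied to
#' each collective variable) plus independent Gaussian noise, which breaks
#' the transpose symmetry the truth possesses. The exact noiseless truth is
#' kept in attribute `truth` for error measurements. Grid points beyond the
#' PMF's `box_half` evaluate the potential at `box_half` (bulk, effectively
#' zero).
#'
#' @param pmf A [membrane_pmf()].
#' @param noise_sd Standard deviation of the added noise (kJ/mol).
#' @param seed Integer seed.
#' @param grid Common grid for both collective variables (nm).
#' @param time_stamp Metadata time stamp (ns).
#'
#' @return A [fes2d()] with attribute `truth` (matrix).
#' @export
make_fes <- function(pmf, noise_sd = 0, seed = 1,
                     grid = seq(1, 5, by = 0.05), time_stamp = NA_real_) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  u <- pmf_value(pmf, pmin(grid, pmf$box_half))
  truth <- outer(u, u, "+")
  noise <- 0
  if (noise_sd > 0) {
    noise <- with_preserved_seed(seed, {
      matrix(stats::rnorm(length(truth), sd = noise_sd),
             nrow = nrow(truth))
    })
  }
  out <- fes2d(grid, grid, truth + noise, time_stamp = time_stamp)
  attr(out, "truth") <- truth
  out
}

# evaluate `expr` under set.seed(seed) and restore the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Toy multi-peptide contact trajectory with ground-truth labels
#'
#' Generates, per frame and peptide, a bound/unbound state (Bernoulli), a
#' peptide center-of-mass z consistent with that state relative to the
#' binding cutoff, nine guanidinium-carbon z coordinates of which a known
#' number are buried below the phosphate plane plus margin, and a phosphate
#' atom set whose mean |z| equals `plane` exactly. The generator's own
#' bookkeeping (`truth`) is the oracle for [count_bound_peptides()] and
#' [count_buried_gdm()]: both must recount it exactly.
#'
#' @param n_peptides Number of peptides (>= 1).
#' @param frames Number of frames.
#' @param seed Integer seed.
#' @param z_cut Binding cutoff used to place bound/unbound peptides (nm).
#' @param margin Burial margin matching [count_buried_gdm()] (nm).
#' @param plane Phosphate-plane distance from the membrane center (nm).
#' @param p_bound Per-frame probability that a peptide is bound.
#' @param box_half Half box height (nm).
#'
#' @return A list with tibbles `peptides` (`time_ns`, `particle_id`, `z_nm`),
#'   `gdm` (`time_ns`, `peptide_id`, `z_nm`), `phosphates`
#'   (`time_ns`, `z_nm`), `bound_flags` (`time_ns`, `peptide_id`, `bound`)
#'   and `truth` (`time_ns`, `peptide_id`, `bound`, `buried`).
#' @export
toy_contact_trajectory <- function(n_peptides, frames, seed = 1, z_cut = 3.5,
                                   margin = 0.1, plane = 2.0, p_bound = 0.6,
                                   box_half = 4.5) {
  if (n_peptides < 1) abort("`n_peptides` must be >= 1")
  if (frames < 1) abort("`frames` must be >= 1")
  with_preserved_seed(seed, {
    grid <- expand.grid(time_ns = seq_len(frames) - 1,
                        peptide_id = seq_len(n_peptides))
    n <- nrow(grid)
    bound <- stats::runif(n) < p_bound
    z_com <- ifelse(
      bound,
      stats::runif(n, plane - 0.3, z_cut - 0.1),
      stats::runif(n, z_cut + 0.2, box_half - 0.2)
    )
    buried <- ifelse(bound, sample(0:9, n, replace = TRUE), 0L)
    gdm <- purrr::map_dfr(seq_len(n), function(k) {
      nb <- buried[k]
      z <- c(
        stats::runif(nb, plane - 0.5, plane + margin - 0.02),
        stats::runif(9 - nb, plane + margin + 0.02, plane + margin + 1.2)
      )
      tibble::tibble(time_ns = grid$time_ns[k], peptide_id = grid$peptide_id[k],
                     z_nm = z)
    })
    # 8 phosphate atoms symmetric about the plane: mean |z| is exactly `plane`
    offsets <- c(-0.21, -0.15, -0.09, -0.03, 0.03, 0.09, 0.15, 0.21)
    phosphates <- tibble::tibble(
      time_ns = rep(seq_len(frames) - 1, each = length(offsets)),
      z_nm = rep(plane + offsets, times = frames)
    )
    list(
      peptides = tibble::tibble(time_ns = grid$time_ns,
                                particle_id = grid$peptide_id, z_nm = z_com),
      gdm = gdm,
      phosphates = phosphates,
      bound_flags = tibble::tibble(time_ns = grid$time_ns,
                                   peptide_id = grid$peptide_id, bound = bound),
      truth = tibble::tibble(time_ns = grid$time_ns,
                             peptide_id = grid$peptide_id, bound = bound,
                             buried = as.integer(buried))
    )
  })
}
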
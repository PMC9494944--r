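#' Parameters for the synthetic FCCS titration simulator
#'
#' Bundles the physical and instrumental parameters of the Brownian-dynamics
#' photon-trace simulator, with defaults emulating the vesicle-binding
#' titration this package analyzes: 50-nm extruded vesicles at 0.5 mM lipid
#' (about 20 nM vesicles), a tenth of the peptide carrying the blue label,
#' about six red lipid dyes per vesicle from 4000:1 lipid:dye labeling, and
#' a confocal geometry with 0.2/0.25 um focus radii and structural
#' parameter 5.
#'
#' @param kd Ground-truth dissociation constant (mol/L). Required.
#' @param n_max Maximum binding sites per vesicle (default 50).
#' @param c_vesicle Vesicle number concentration (mol/L, default 2e-8).
#' @param c_p_total Vector of total peptide concentrations for the titration
#'   (mol/L); default 12 log-spaced points from 0.1 kd to 10 kd.
#' @param d_vesicle,d_peptide Diffusion coefficients (m^2/s; defaults
#'   9.8e-12 for a 50-nm vesicle by Stokes-Einstein and 1.5e-10 for a small
#'   labeled peptide).
#' @param brightness_blue Molecular brightness of a labeled peptide
#'   (counts/s at focus center, default 3e4).
#' @param brightness_red Brightness per vesicle (all its lipid dyes
#'   combined; default 1.8e5).
#' @param omega_b,omega_r Lateral focus radii (m; defaults 2e-7, 2.5e-7).
#' @param s_param Structural parameter (default 5).
#' @param box Periodic box dimensions (m; default 1.5 x 1.5 x 4 um, the long
#'   axis along the optical axis so periodic images stay outside the
#'   detection volume).
#' @param duration Trace duration per titration point (s, default 60,
#'   the acquisition time per point of the titration protocol this emulates;
#'   scale down for quick exploratory runs).
#' @param bin_width Photon binning time (s, default 1e-4).
#' @param label_fraction Labeled fraction of the peptide (default 0.1).
#' @param n_r Red dyes per vesicle (metadata for bookkeeping, default 6).
#' @param seed Integer seed; point i of the titration uses `seed + i`.
#'
#' @return A list of class `fccs_sim_params`.
#' @export
fccs_sim_params <- function(kd, n_max = 50, c_vesicle = 2e-8,
                            c_p_total = NULL,
                            d_vesicle = 9.8e-12, d_peptide = 1.5e-10,
                            brightness_blue = 3e4, brightness_red = 1.8e5,
                            omega_b = 2e-7, omega_r = 2.5e-7, s_param = 5,
                            box = c(1.5e-6, 1.5e-6, 4e-6),
                            duration = 60, bin_width = 1e-4,
                            label_fraction = 0.1, n_r = 6, seed = 1) {
  .check_scalar_pos(kd, "kd")
  .check_scalar_pos(n_max, "n_max")
  .check_scalar_pos(c_vesicle, "c_vesicle")
  .check_scalar_pos(duration, "duration")
  .check_scalar_pos(bin_width, "bin_width")
  if (is.null(c_p_total)) {
    c_p_total <- kd * 10^seq(-1, 1, length.out = 12)
  }
  if (any(c_p_total <= 0)) abort("`c_p_total` must be positive")
  if (label_fraction <= 0 || label_fraction > 1) {
    abort("`label_fraction` must be in (0, 1]")
  }
  if (length(box) != 3L || any(box <= 0)) {
    abort("`box` must be three positive lengths (m)")
  }
  if (box[1] < 6 * omega_b || box[3] < 3 * s_param * omega_r) {
    warn("box is small relative to the detection volume; periodic images may bias amplitudes")
  }
  n_bins <- round(duration / bin_width)
  if (n_bins < 1e5) {
    warn("duration/bin_width below the recommended 1e5 bins; amplitude noise may be large")
  }
  # one-step-per-bin propagation is accurate for the species whose
  # correlations are analyzed (vesicles and bound peptides); warn if the
  # bin width exceeds the vesicle-scale stability step
  if (bin_width > omega_b^2 / (20 * d_vesicle)) {
    warn("bin_width exceeds omega_b^2/(20 D_vesicle); vesicle-scale correlations may be underresolved")
  }
  structure(
    list(kd = kd, n_max = n_max, c_vesicle = c_vesicle,
         c_p_total = c_p_total, d_vesicle = d_vesicle, d_peptide = d_peptide,
         brightness_blue = brightness_blue, brightness_red = brightness_red,
         omega_b = omega_b, omega_r = omega_r, s_param = s_param, box = box,
         duration = duration, bin_width = bin_width,
         label_fraction = label_fraction, n_r = n_r, seed = seed),
    class = "fccs_sim_params"
  )
}

#' Langmuir binding equilibrium of a titration point
#'
#' Solves the mass-action equilibrium for independent sites: given total
#' peptide `c_p_total`, vesicles at `c_vesicle` with `n_max` sites each and
#' dissociation constant `kd`, the free concentration satisfies
#' `c_free + n_max c_vesicle c_free / (kd + c_free) = c_p_total`
#' (positive root of the quadratic); the mean occupancy is
#' `n_p = n_max c_free / (kd + c_free)`.
#'
#' @param kd Dissociation constant (mol/L).
#' @param n_max Sites per vesicle.
#' @param c_vesicle Vesicle concentration (mol/L).
#' @param c_p_total Total peptide concentration (mol/L), vectorized.
#' @return A tibble with `c_p_total`, `c_p_free`, `n_p`.
#' @export
langmuir_equilibrium <- function(kd, n_max, c_vesicle, c_p_total) {
  b <- kd + n_max * c_vesicle - c_p_total
  disc <- sqrt(b^2 + 4 * kd * c_p_total)
  # numerically stable root: avoid the cancellation of (-b + disc) when
  # b > 0 (strong depletion, c_free << c_p_total)
  c_free <- ifelse(b >= 0, 2 * kd * c_p_total / (b + disc), (-b + disc) / 2)
  tibble::tibble(
    c_p_total = c_p_total,
    c_p_free = c_free,
    n_p = n_max * c_free / (kd + c_free)
  )
}

#' Simulate a dual-color FCCS titration with known ground truth
#'
#' For each titration point, labeled peptides and red-labeled vesicles are
#' placed in a periodic box; each labeled peptide is independently assigned
#' bound (co-diffusing at its vesicle's position) or free according to the
#' Langmuir equilibrium at the ground-truth `kd`/`n_max` (binding is
#' quasi-static over one trace, matching the equilibrium assumption of the
#' amplitude analysis). All particles then undergo Brownian motion, per-bin
#' expected photon counts follow the 3-D Gaussian detection profiles of the
#' two channels, and Poisson-sampled counts are emitted.
#'
#' @param params A [fccs_sim_params()].
#' @return A list of class `fccs_simulation` with `traces` (list of
#'   [intensity_trace()], one per titration point, carrying `c_p_total`) and
#'   `truth` (tibble of exact per-point equilibrium values and realized
#'   particle counts).
#' @export
simulate_fccs <- function(params) {
  stopifnot(inherits(params, "fccs_sim_params"))
  v_box_l <- prod(params$box) * 1e3 # m^3 -> L
  n_bins <- round(params$duration / params$bin_width)
  n_ves <- round(params$c_vesicle * .NA_CONST * v_box_l)
  if (n_ves < 1) abort("box contains no vesicles; enlarge box or c_vesicle")
  eq <- langmuir_equilibrium(params$kd, params$n_max, params$c_vesicle,
                             params$c_p_total)
  if (any(eq$n_p > params$n_max + 1e-9) || any(eq$c_p_free < 0)) {
    abort("occupancy demand exceeds available sites: infeasible titration point")
  }
  wz_b <- params$s_param * params$omega_b
  wz_r <- params$s_param * params$omega_r
  traces <- vector("list", length(params$c_p_total))
  truth_rows <- vector("list", length(params$c_p_total))
  for (i in seq_along(params$c_p_total)) {
    seed_i <- params$seed + i
    sim <- with_preserved_seed(seed_i, {
      n_lab <- round(params$label_fraction * params$c_p_total[i] *
                       .NA_CONST * v_box_l)
      p_bound <- eq$n_p[i] * params$c_vesicle / params$c_p_total[i]
      n_bound_lab <- stats::rbinom(1L, n_lab, p_bound)
      bound_counts <- tabulate(
        sample.int(n_ves, n_bound_lab, replace = TRUE), nbins = n_ves
      )
      expected <- cpp_fccs_expected(
        as.integer(n_bins), params$bin_width,
        as.integer(bound_counts), as.integer(n_lab - n_bound_lab),
        params$d_vesicle, params$d_peptide, params$box,
        params$omega_b, params$omega_r, wz_b, wz_r,
        params$brightness_blue, params$brightness_red,
        as.numeric(seed_i)
      )
      list(
        trace = intensity_trace(
          stats::rpois(n_bins, expected[1, ]),
          stats::rpois(n_bins, expected[2, ]),
          params$bin_width,
          c_p_total = params$c_p_total[i]
        ),
        n_lab = n_lab, n_bound_lab = n_bound_lab
      )
    })
    traces[[i]] <- sim$trace
    truth_rows[[i]] <- tibble::tibble(
      c_p_total = params$c_p_total[i],
      c_p_free = eq$c_p_free[i],
      n_p = eq$n_p[i],
      n_vesicles = n_ves,
      n_labeled = sim$n_lab,
      n_bound_labeled = sim$n_bound_lab,
      seed = seed_i
    )
  }
  structure(
    list(traces = traces, truth = dplyr::bind_rows(truth_rows),
         params = params),
    class = "fccs_simulation"
  )
}

#' @export
print.fccs_simulation <- function(x, ...) {
  cat(sprintf(
    "<fccs_simulation> %d titration points, kd = %.3g M, n_max = %g, %d vesicles/box\n",
    length(x$traces), x$params$kd, x$params$n_max, x$truth$n_vesicles[1]
  ))
  invisible(x)
}
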
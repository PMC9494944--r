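#' Effective confocal detection volumes
#'
#' Builds the detection geometry from the lateral focus radii of the two
#' lasers and the structural parameter, and fills in the effective volumes:
#' the cross-correlation volume
#' `V_eff,x = pi^{3/2} S ((omega_b^2 + omega_r^2)/2)^{3/2}` and the
#' single-color red volume `V_eff,r = pi^{3/2} S omega_r^3`, both in liters.
#' With equal radii the cross volume reduces to the single-color volume.
#'
#' @param omega_b,omega_r Lateral 1/e^2 focus radii of the blue and red
#'   lasers (m).
#' @param s_param Structural parameter S (> 1): axial-to-lateral extent
#'   ratio of the (assumed 3-D Gaussian) detection profile.
#'
#' @return A list of class `detection_geometry` with `omega_b`, `omega_r`,
#'   `s_param`, `v_eff_x`, `v_eff_r` (liters).
#' @export
#' @examples
#' geom <- effective_volume(2e-7, 2.5e-7, 5)
#' geom$v_eff_x # liters
effective_volume <- function(omega_b, omega_r, s_param) {
  .check_scalar_pos(omega_b, "omega_b")
  .check_scalar_pos(omega_r, "omega_r")
  if (!is.numeric(s_param) || s_param <= 1) abort("`s_param` must be > 1")
  v_x_m3 <- pi^1.5 * s_param * ((omega_b^2 + omega_r^2) / 2)^1.5
  v_r_m3 <- pi^1.5 * s_param * omega_r^3
  structure(
    list(omega_b = omega_b, omega_r = omega_r, s_param = s_param,
         v_eff_x = v_x_m3 * 1e3, v_eff_r = v_r_m3 * 1e3),
    class = "detection_geometry"
  )
}

#' @export
print.detection_geometry <- function(x, ...) {
  cat(sprintf(
    "<detection_geometry> omega_b = %.3g m, omega_r = %.3g m, S = %g; V_eff,x = %.3g L, V_eff,r = %.3g L\n",
    x$omega_b, x$omega_r, x$s_param, x$v_eff_x, x$v_eff_r
  ))
  invisible(x)
}

#' Focus radius from a calibration dye
#'
#' Given the tabulated diffusion coefficient of a calibration dye and its
#' fitted diffusion time, the lateral focus radius is
#' `omega = sqrt(4 D tauD)`.
#'
#' @param known_d Diffusion coefficient (m^2/s).
#' @param fitted_tau_d Fitted diffusion time (s).
#' @return Focus radius in m.
#' @export
#' @examples
#' calibrate_radius(4e-10, 25e-6) # 2e-7 m
calibrate_radius <- function(known_d, fitted_tau_d) {
  .check_scalar_pos(known_d, "known_d")
  .check_scalar_pos(fitted_tau_d, "fitted_tau_d")
  sqrt(4 * known_d * fitted_tau_d)
}

#' Mean number of bound peptides per vesicle from FCCS amplitudes
#'
#' `<NP> = Gx0 * V_eff,x * N_A * C_P^0`: the cross-correlation amplitude
#' measures the concentration of peptide-vesicle co-diffusion relative to the
#' total peptide concentration, so scaling is linear in the amplitude. A red
#' autocorrelation amplitude must be positive (vesicles present in the
#' detection volume); zero cross-correlation means no detectable binding and
#' gives `<NP> = 0`.
#'
#' @param gx0 Cross-correlation amplitude (>= 0; small negative fitted values
#'   are truncated to zero with a warning).
#' @param gr0 Red autocorrelation amplitude (> 0).
#' @param geom A [effective_volume()] geometry.
#' @param c_p_total Total peptide concentration (mol/L).
#' @return Mean bound peptides per vesicle (dimensionless count).
#' @export
bound_per_vesicle <- function(gx0, gr0, geom, c_p_total) {
  stopifnot(inherits(geom, "detection_geometry"))
  if (gr0 <= 0) abort("`gr0` must be > 0 (no vesicle signal)")
  .check_scalar_pos(c_p_total, "c_p_total")
  if (gx0 < 0) {
    warn("negative cross-correlation amplitude truncated to zero (no detectable binding)")
    gx0 <- 0
  }
  gx0 * geom$v_eff_x * .NA_CONST * c_p_total
}

#' Free peptide concentration by mass conservation
#'
#' The vesicle number concentration follows from the red autocorrelation
#' amplitude, `C_V = 1 / (Gr0 V_eff,r N_A)`, and the free peptide
#' concentration from mass conservation,
#' `C_P^free = C_P^0 - <NP> * C_V`. A substantially negative result signals
#' inconsistent amplitudes and is raised as an error; negative values within
#' numerical noise are clamped to zero.
#'
#' @param c_p_total Total peptide concentration (mol/L).
#' @param n_p Mean bound peptides per vesicle, from [bound_per_vesicle()].
#' @param gr0 Red autocorrelation amplitude (> 0).
#' @param geom A [effective_volume()] geometry.
#' @param tol Absolute noise tolerance on the free concentration (mol/L):
#'   negative results no further below zero than `tol` (e.g. the propagated
#'   amplitude uncertainty, in a strongly depleted titration point) are
#'   clamped to zero; more negative results are an error. Default 0.
#' @return A one-row tibble: `c_p_total`, `c_p_free`, `n_p`, `c_vesicle`
#'   (all concentrations mol/L).
#' @export
free_concentration <- function(c_p_total, n_p, gr0, geom, tol = 0) {
  stopifnot(inherits(geom, "detection_geometry"))
  if (gr0 <= 0) abort("`gr0` must be > 0 (no vesicle signal)")
  c_v <- 1 / (gr0 * geom$v_eff_r * .NA_CONST)
  c_free <- c_p_total - n_p * c_v
  if (c_free < -(tol + 1e-9 * c_p_total)) {
    abort("computed free concentration is negative: inconsistent amplitudes")
  }
  c_free <- max(c_free, 0)
  tibble::tibble(c_p_total = c_p_total, c_p_free = c_free, n_p = n_p,
                 c_vesicle = c_v)
}

#' Fit a Langmuir binding isotherm
#'
#' Nonlinear least squares of `<NP> = N_max C_free / (K_D + C_free)`
#' (independent, non-cooperative binding sites), returning the dissociation
#' constant and the maximum number of sites per vesicle with standard errors
#' from the fit covariance. If the sampled concentrations never reach the
#' fitted `K_D`, all points lie in the linear regime and `K_D` is flagged as
#' poorly identified.
#'
#' @param points Data frame with columns `c_p_free` (mol/L) and `n_p`
#'   (bound peptides per vesicle); at least four points spanning both sides
#'   of half-saturation are recommended, fewer than three is an error.
#' @param start Optional named list with starting values `kd`, `n_max`.
#' @return A list of class `langmuir_fit`: `kd`, `n_max`, `se_kd`,
#'   `se_n_max`, `poorly_identified`, `points` (with a `normalized` column
#'   `n_p / n_max`), and the underlying `fit`.
#' @export
fit_langmuir <- function(points, start = NULL) {
  .check_columns(points, c("c_p_free", "n_p"), "points")
  points <- tibble::as_tibble(points)
  if (nrow(points) < 3L) {
    abort("cannot fit two isotherm parameters from fewer than three points")
  }
  n_max0 <- 1.2 * max(points$n_p)
  if (n_max0 <= 0) abort("all occupancies are zero: no detectable binding")
  half <- which.min(abs(points$n_p - max(points$n_p) / 2))
  kd0 <- max(points$c_p_free[half], min(points$c_p_free[points$c_p_free > 0]))
  if (!is.null(start)) {
    if (!is.null(start$kd)) kd0 <- start$kd
    if (!is.null(start$n_max)) n_max0 <- start$n_max
  }
  fit <- try(minpack.lm::nlsLM(
    n_p ~ n_max * c_p_free / (kd + c_p_free),
    data = points,
    start = list(n_max = n_max0, kd = kd0),
    lower = c(1e-300, 1e-300),
    control = minpack.lm::nls.lm.control(maxiter = 500)
  ), silent = TRUE)
  if (inherits(fit, "try-error")) {
    abort(paste0("Langmuir fit did not converge: ", as.character(fit)))
  }
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) c(NA_real_, NA_real_))
  kd <- unname(est["kd"])
  n_max <- unname(est["n_max"])
  poorly <- max(points$c_p_free) < kd
  if (poorly) {
    warn("all points lie in the linear regime; K_D is poorly identified")
  }
  points$normalized <- points$n_p / n_max
  structure(
    list(kd = kd, n_max = n_max,
         se_kd = unname(se["kd"]), se_n_max = unname(se["n_max"]),
         poorly_identified = poorly, points = points, fit = fit,
         n_avogadro = .NA_CONST),
    class = "langmuir_fit"
  )
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf(
    "<langmuir_fit> K_D = %.4g +/- %.2g M, N_max = %.4g +/- %.2g sites/vesicle (%d points)%s\n",
    x$kd, x$se_kd, x$n_max, x$se_n_max, nrow(x$points),
    if (x$poorly_identified) " [K_D poorly identified]" else ""
  ))
  invisible(x)
}

#' @export
tidy.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    term = c("kd", "n_max"),
    estimate = c(x$kd, x$n_max),
    std.error = c(x$se_kd, x$se_n_max)
  )
}

#' @export
glance.langmuir_fit <- function(x, ...) {
  tibble::tibble(
    kd = x$kd, n_max = x$n_max, se_kd = x$se_kd, se_n_max = x$se_n_max,
    poorly_identified = x$poorly_identified, n = nrow(x$points),
    sigma = tryCatch(stats::sigma(x$fit), error = function(e) NA_real_)
  )
}

#' Free-energy shift between two dissociation constants
#'
#' `ddG = kB T ln(kd_weak / kd_tight)` in kJ/mol: the binding free-energy
#' difference implied by two dissociation constants at the same temperature
#' (default 298 K for solution experiments).
#'
#' @param kd_weak,kd_tight Dissociation constants (mol/L).
#' @param temperature Temperature in K (default 298).
#' @return Free-energy shift in kJ/mol.
#' @export
#' @examples
#' kd_free_energy_shift(4.8e-6, 129e-9) # about 9 kJ/mol
kd_free_energy_shift <- function(kd_weak, kd_tight, temperature = 298) {
  .check_scalar_pos(kd_weak, "kd_weak")
  .check_scalar_pos(kd_tight, "kd_tight")
  .kB * temperature * log(kd_weak / kd_tight)
}

#' Full FCCS binding analysis: traces to Langmuir fit
#'
#' Runs the complete analysis chain on a titration series of two-channel
#' traces: multi-tau correlation (cross and red auto), diffusion-model
#' amplitude fits, bound peptides per vesicle, free concentration by mass
#' conservation, and the Langmuir fit. Points with zero (or negative) fitted
#' cross-correlation amplitude are retained with `n_p = 0`. If no point shows
#' a cross-correlation amplitude above three standard errors, the titration
#' is flagged as showing no detectable binding and no isotherm is fitted.
#'
#' @param traces List of [intensity_trace()] objects, one per titration
#'   concentration, each carrying `c_p_total` (or supply `c_p_total`).
#' @param geom A [effective_volume()] geometry.
#' @param c_p_total Optional vector of total peptide concentrations (mol/L)
#'   overriding the per-trace metadata.
#' @param m Lags per octave for the correlator.
#' @param max_lag Maximum correlator lag (s); default `duration / 20`.
#'
#' @return A list of class `binding_pipeline`: `points` (per-concentration
#'   tibble with amplitudes and concentrations), `fit` (a
#'   [fit_langmuir()] result, or `NULL` when no binding is detectable),
#'   `no_binding` flag, and `curves` (list of cross-correlation curves).
#' @export
binding_pipeline <- function(traces, geom, c_p_total = NULL, m = 16L,
                             max_lag = NULL) {
  stopifnot(inherits(geom, "detection_geometry"))
  if (length(traces) < 1L) abort("no traces supplied")
  if (is.null(c_p_total)) {
    c_p_total <- vapply(traces, function(tr) tr$c_p_total, numeric(1))
  }
  if (any(!is.finite(c_p_total))) {
    abort("every trace needs a total peptide concentration")
  }
  if (length(traces) == 1L) {
    abort("cannot fit a two-parameter isotherm from a single titration point")
  }
  rows <- vector("list", length(traces))
  curves <- vector("list", length(traces))
  for (i in seq_along(traces)) {
    cross <- correlate(traces[[i]], "cross", m = m, max_lag = max_lag)
    red <- correlate(traces[[i]], "red_auto", m = m, max_lag = max_lag)
    fx <- fit_amplitude(cross, geom$s_param)
    fr <- fit_amplitude(red, geom$s_param)
    gx0 <- max(fx$g0, 0)
    n_p <- gx0 * geom$v_eff_x * .NA_CONST * c_p_total[i]
    # in the strongly depleted regime C_free is a small difference of two
    # noisy estimates (amplitude noise plus finite-particle realization
    # noise); negative values are an expected outcome there, clamped to
    # zero and flagged non-informative below
    pt <- free_concentration(c_p_total[i], n_p, fr$g0, geom, tol = Inf)
    pt$gx0 <- fx$g0
    pt$se_gx0 <- fx$se_g0
    pt$gr0 <- fr$g0
    pt$se_gr0 <- fr$se_g0
    pt$tau_d_red <- fr$tau_d
    rows[[i]] <- pt
    curves[[i]] <- cross
  }
  points <- dplyr::bind_rows(rows)
  # a point whose free concentration is indistinguishable from zero carries
  # no usable abscissa for the isotherm; keep it in the table, flag it out
  # of the fit
  points$informative <- points$c_p_free > 0
  # 5 SE rather than 3: the amplitude-fit standard errors are optimistic
  # because residuals across multi-tau lags are correlated
  detectable <- points$gx0 > 5 * points$se_gx0
  no_binding <- !any(detectable, na.rm = TRUE)
  fit <- NULL
  if (no_binding) {
    warn("no titration point shows a cross-correlation amplitude above noise: no detectable binding")
  } else if (sum(points$informative) < 3L) {
    warn("fewer than three informative titration points; isotherm not fitted")
  } else {
    fit <- fit_langmuir(points[points$informative, , drop = FALSE])
  }
  structure(
    list(points = points, fit = fit, no_binding = no_binding,
         curves = curves, geom = geom),
    class = "binding_pipeline"
  )
}

#' @export
print.binding_pipeline <- function(x, ...) {
  cat(sprintf("<binding_pipeline> %d titration points\n", nrow(x$points)))
  if (x$no_binding) {
    cat("  no detectable binding (all cross-correlation amplitudes within noise)\n")
  } else {
    print(x$fit)
  }
  invisible(x)
}

#' @export
tidy.binding_pipeline <- function(x, ...) {
  x$points
}

#' @export
glance.binding_pipeline <- function(x, ...) {
  if (x$no_binding || is.null(x$fit)) {
    return(tibble::tibble(kd = NA_real_, n_max = NA_real_, se_kd = NA_real_,
                          se_n_max = NA_real_, no_binding = x$no_binding,
                          n = nrow(x$points)))
  }
  out <- glance(x$fit)
  out$no_binding <- FALSE
  out
}
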
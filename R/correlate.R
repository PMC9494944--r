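#' Two-channel photon-count trace
#'
#' Container for binned photon counts from the blue (peptide label) and red
#' (vesicle label) detection channels.
#'
#' @param counts_blue,counts_red Non-negative integer photon counts per bin
#'   (equal length).
#' @param bin_width Bin width in seconds.
#' @param c_p_total Optional total peptide concentration of the titration
#'   point this trace belongs to (mol/L), carried as metadata.
#'
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(counts_blue, counts_red, bin_width,
                            c_p_total = NA_real_) {
  if (length(counts_blue) != length(counts_red)) {
    abort("channels must have equal length")
  }
  if (any(counts_blue < 0) || any(counts_red < 0)) {
    abort("photon counts must be non-negative")
  }
  .check_scalar_pos(bin_width, "bin_width")
  structure(
    list(counts_blue = as.numeric(counts_blue),
         counts_red = as.numeric(counts_red),
         bin_width = bin_width,
         duration = bin_width * length(counts_blue),
         c_p_total = c_p_total),
    class = "intensity_trace"
  )
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf(
    "<intensity_trace> %d bins x %.3g s = %.3g s; <F_blue> = %.1f kHz, <F_red> = %.1f kHz%s\n",
    length(x$counts_blue), x$bin_width, x$duration,
    mean(x$counts_blue) / x$bin_width / 1000,
    mean(x$counts_red) / x$bin_width / 1000,
    if (is.finite(x$c_p_total)) sprintf("; C_P = %.3g M", x$c_p_total) else ""
  ))
  invisible(x)
}

#' @export
as_tibble.intensity_trace <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$counts_blue) - 1) * x$bin_width,
    counts_blue = x$counts_blue,
    counts_red = x$counts_red
  )
}

# rebin a trace by factor `b` via averaging (counts averaged, not summed),
# truncating the tail that does not fill a whole group
rebin_average <- function(x, b) {
  n <- (length(x) %/% b) * b
  if (n == 0L) return(numeric(0))
  colMeans(matrix(x[seq_len(n)], nrow = b))
}

# fluctuation correlation of two (rebinned) series at an integer lag,
# normalized by the means over the overlapping segments
lag_correlation <- function(x, y, k) {
  m <- length(x)
  if (k >= m) return(NA_real_)
  xs <- x[seq_len(m - k)]
  ys <- y[seq.int(k + 1L, m)]
  mean(xs * ys) / (mean(xs) * mean(ys)) - 1
}

#' Multi-tau correlation of a photon-count trace
#'
#' Estimates the fluctuation-normalized correlation function
#' `G(tau) = <F1(t) F2(t+tau)> / (<F1><F2>) - 1`
#' on a quasi-logarithmic lag grid by the multi-tau scheme: `2 m` linearly
#' spaced lags at the native bin width, then `m` lags per octave on traces
#' progressively rebinned by factors of two (counts averaged on rebinning).
#' Segment means over the overlapping windows are used in the normalization,
#' which removes the finite-length bias of a global-mean normalization.
#'
#' With the `- 1` convention a vanishing amplitude means no co-diffusion:
#' two species that never move together give `G(tau)` statistically zero,
#' the no-binding signature of the free-dye control.
#'
#' @param trace An [intensity_trace()].
#' @param pair `"cross"` (blue x red), `"blue_auto"`, or `"red_auto"`.
#' @param m Lags per octave (default 16).
#' @param max_lag Largest lag in seconds (default `duration / 20`); must stay
#'   below half the trace duration.
#'
#' @return A tibble of class `correlation_curve` with columns `tau_s`, `g`,
#'   `pair`, and attributes `mean_f1`, `mean_f2` (counts/s), `bin_width`, `m`.
#' @export
correlate <- function(trace, pair = c("cross", "blue_auto", "red_auto"),
                      m = 16L, max_lag = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  pair <- match.arg(pair)
  f1 <- switch(pair, cross = trace$counts_blue, blue_auto = trace$counts_blue,
               red_auto = trace$counts_red)
  f2 <- switch(pair, cross = trace$counts_red, blue_auto = trace$counts_blue,
               red_auto = trace$counts_red)
  if (mean(f1) == 0 || mean(f2) == 0) {
    abort("zero mean intensity in at least one channel")
  }
  if (is.null(max_lag)) max_lag <- trace$duration / 20
  if (max_lag >= trace$duration / 2) {
    abort("`max_lag` must be below half the trace duration")
  }
  dt <- trace$bin_width
  m <- as.integer(m)
  taus <- numeric(0)
  gs <- numeric(0)
  level <- 0L
  x <- f1
  y <- f2
  repeat {
    b <- 2^level
    ks <- if (level == 0L) seq_len(2L * m) else seq.int(m + 1L, 2L * m)
    ks <- ks[ks * b * dt <= max_lag & ks < length(x)]
    if (length(ks) == 0L) break
    gs <- c(gs, vapply(ks, function(k) lag_correlation(x, y, k), numeric(1)))
    taus <- c(taus, ks * b * dt)
    if ((2L * m) * (2 * b) * dt > max_lag || length(x) < 4L * m) break
    x <- rebin_average(x, 2L)
    y <- rebin_average(y, 2L)
    level <- level + 1L
  }
  out <- tibble::tibble(tau_s = taus, g = gs, pair = pair)
  out <- out[is.finite(out$g), ]
  class(out) <- c("correlation_curve", class(out))
  attr(out, "mean_f1") <- mean(f1) / dt
  attr(out, "mean_f2") <- mean(f2) / dt
  attr(out, "bin_width") <- dt
  attr(out, "m") <- m
  out
}

#' Fit the single-species 3-D diffusion model to a correlation curve
#'
#' Weighted least-squares fit of
#' `G(tau) = G0 (1 + tau/tauD)^-1 (1 + tau/(S^2 tauD))^-1/2`,
#' the correlation function of one freely diffusing species in a 3-D Gaussian
#' detection volume with structural parameter S. The amplitude is extracted
#' from the model fit rather than by shortest-lag extrapolation, which makes
#' it robust to short-lag artifacts.
#'
#' @param curve A [correlate()] result (>= 10 lag points spanning the decay).
#' @param s_param Structural parameter S (> 1, axial-to-lateral focus ratio).
#' @param weights Optional fit weights (e.g. inverse variance from replicate
#'   spread); default unweighted.
#' @param start Optional named list overriding the self-starting values
#'   `g0`, `tau_d`.
#'
#' @return A list of class `amplitude_fit`: `g0`, `tau_d` (s), `se_g0`,
#'   `se_tau_d`, `converged`, `negative_amplitude` flag, `s_param`, and the
#'   underlying `fit` object.
#' @export
fit_amplitude <- function(curve, s_param, weights = NULL, start = NULL) {
  .check_columns(curve, c("tau_s", "g"), "curve")
  if (nrow(curve) < 10L) abort("need at least 10 lag points to fit")
  if (s_param <= 1) abort("`s_param` must be > 1")
  df <- tibble::tibble(tau = curve$tau_s, g = curve$g)
  g0_0 <- mean(head(df$g, 3L))
  if (abs(g0_0) < 1e-8) g0_0 <- 1e-4 # avoid a singular all-zero start
  half <- which(abs(df$g) <= abs(g0_0) / 2)
  td_0 <- if (length(half) > 0) df$tau[half[1]] else stats::median(df$tau)
  td_0 <- max(td_0, df$tau[1])
  if (!is.null(start)) {
    if (!is.null(start$g0)) g0_0 <- start$g0
    if (!is.null(start$tau_d)) td_0 <- start$tau_d
  }
  s2 <- s_param^2
  w <- if (is.null(weights)) rep(1, nrow(df)) else weights
  sw <- sqrt(w)
  model_f <- function(td) 1 / ((1 + df$tau / td) * sqrt(1 + df$tau / (s2 * td)))
  resid_fn <- function(p) {
    sw * (df$g - p[1] * model_f(p[2]))
  }
  jac_fn <- function(p) {
    f <- model_f(p[2])
    dlnf_dtd <- (df$tau / p[2]^2) / (1 + df$tau / p[2]) +
      0.5 * (df$tau / (s2 * p[2]^2)) / (1 + df$tau / (s2 * p[2]))
    cbind(-sw * f, -sw * p[1] * f * dlnf_dtd)
  }
  best <- NULL
  for (tds in unique(c(td_0, unname(stats::quantile(df$tau, c(0.1, 0.5, 0.9)))))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(g0_0, tds), fn = resid_fn, jac = jac_fn,
      lower = c(-Inf, 1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ), silent = TRUE)
    if (!inherits(fit, "try-error") &&
        (is.null(best) || fit$deviance < best$deviance)) {
      best <- fit
    }
  }
  if (is.null(best)) abort("amplitude fit did not converge")
  p <- best$par
  # covariance from the weighted Jacobian at the optimum
  J <- jac_fn(p)
  n <- nrow(df)
  sigma2 <- best$deviance / max(n - 2L, 1L)
  se <- tryCatch(sqrt(diag(solve(crossprod(J))) * sigma2),
                 error = function(e) c(NA_real_, NA_real_))
  neg <- p[1] < 0
  if (neg) {
    warn("fitted amplitude is negative; treating as no detectable correlation")
  }
  structure(
    list(g0 = p[1], tau_d = p[2],
         se_g0 = se[1], se_tau_d = se[2],
         converged = best$info %in% 1:4, negative_amplitude = neg,
         s_param = s_param, fit = best),
    class = "amplitude_fit"
  )
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "<amplitude_fit> G0 = %.4g +/- %.2g, tauD = %.4g +/- %.2g s (S = %g)\n",
    x$g0, x$se_g0, x$tau_d, x$se_tau_d, x$s_param
  ))
  invisible(x)
}

#' @export
tidy.amplitude_fit <- function(x, ...) {
  tibble::tibble(
    term = c("g0", "tau_d"),
    estimate = c(x$g0, x$tau_d),
    std.error = c(x$se_g0, x$se_tau_d)
  )
}

#' @export
glance.amplitude_fit <- function(x, ...) {
  tibble::tibble(
    g0 = x$g0, tau_d = x$tau_d, se_g0 = x$se_g0, se_tau_d = x$se_tau_d,
    converged = x$converged, negative_amplitude = x$negative_amplitude,
    s_param = x$s_param
  )
}

#' Closed-form single-species diffusion correlation model
#'
#' `G(tau) = g0 (1 + tau/tau_d)^-1 (1 + tau/(s^2 tau_d))^-1/2`, the model
#' fitted by [fit_amplitude()]; exported for constructing reference curves.
#'
#' @param tau Lag times (s).
#' @param g0 Zero-lag amplitude.
#' @param tau_d Diffusion time (s).
#' @param s_param Structural parameter.
#' @return Numeric vector of correlation values.
#' @export
fcs_diffusion_model <- function(tau, g0, tau_d, s_param) {
  g0 / ((1 + tau / tau_d) * sqrt(1 + tau / (s_param^2 * tau_d)))
}
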
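# small, fast simulator configurations for unit checks; the full-scale
# titrations are exercised by the acceptance suite
small_params <- function(kd = 1e-7, c_p_total = 1e-7, duration = 2, seed = 1,
                         ...) {
  suppressWarnings(fccs_sim_params(
    kd = kd, c_p_total = c_p_total, duration = duration, seed = seed, ...
  ))
}

test_that("the Langmuir equilibrium solver satisfies mass action exactly", {
  eq <- langmuir_equilibrium(1e-7, 50, 2e-8, c(1e-8, 1e-7, 1e-6))
  # mass balance: free + bound = total
  expect_equal(eq$c_p_free + eq$n_p * 2e-8, eq$c_p_total, tolerance = 1e-9)
  # isotherm identity at the solution
  expect_equal(eq$n_p, 50 * eq$c_p_free / (1e-7 + eq$c_p_free),
               tolerance = 1e-12)
  # independent root-finding oracle
  for (ct in c(1e-8, 1e-7, 1e-6)) {
    root <- uniroot(function(cf) cf + 50 * 2e-8 * cf / (1e-7 + cf) - ct,
                    c(0, ct), tol = 1e-18)$root
    expect_equal(eq$c_p_free[match(ct, eq$c_p_total)], root, tolerance = 1e-6)
  }
})

test_that("simulated traces are deterministic under a fixed seed", {
  s1 <- simulate_fccs(small_params(seed = 9))
  s2 <- simulate_fccs(small_params(seed = 9))
  s3 <- simulate_fccs(small_params(seed = 10))
  expect_identical(s1$traces[[1]]$counts_blue, s2$traces[[1]]$counts_blue)
  expect_identical(s1$traces[[1]]$counts_red, s2$traces[[1]]$counts_red)
  expect_false(identical(s1$traces[[1]]$counts_blue,
                         s3$traces[[1]]$counts_blue))
})

test_that("simulator bookkeeping conserves peptide number and follows the isotherm", {
  p <- small_params(c_p_total = c(2e-8, 2e-7), duration = 0.5)
  sim <- simulate_fccs(p)
  tru <- sim$truth
  expect_equal(tru$c_p_free + tru$n_p * p$c_vesicle, tru$c_p_total,
               tolerance = 1e-12)
  expect_equal(tru$n_p, p$n_max * tru$c_p_free / (p$kd + tru$c_p_free),
               tolerance = 1e-9)
  expect_true(all(tru$n_bound_labeled <= tru$n_labeled))
})

test_that("red-channel amplitude reflects the vesicle concentration", {
  p <- small_params(c_p_total = 1e-9, duration = 10, seed = 4)
  sim <- simulate_fccs(p)
  geom <- effective_volume(p$omega_b, p$omega_r, p$s_param)
  red <- correlate(sim$traces[[1]], "red_auto")
  fit <- fit_amplitude(red, p$s_param)
  v_box_l <- prod(p$box) * 1e3
  cv_realized <- sim$truth$n_vesicles / (6.02214076e23 * v_box_l)
  g0_expected <- 1 / (cv_realized * 6.02214076e23 * geom$v_eff_r)
  expect_equal(fit$g0, g0_expected, tolerance = 0.15)
  # and the diffusion time matches omega_r^2 / (4 D)
  expect_equal(fit$tau_d, p$omega_r^2 / (4 * p$d_vesicle), tolerance = 0.25)
})

test_that("without binding the cross-correlation is statistically zero", {
  # kd far above every concentration: all peptide stays free (the
  # free-dye control), so cross amplitude must vanish
  p <- small_params(kd = 1, c_p_total = 2e-7, duration = 5, seed = 12)
  sim <- simulate_fccs(p)
  expect_equal(sim$truth$n_bound_labeled, 0)
  curve <- correlate(sim$traces[[1]], "cross")
  fit <- suppressWarnings(fit_amplitude(curve, p$s_param))
  expect_lt(abs(fit$g0), 3 * max(fit$se_g0, 1e-4))
})

test_that("in the strong-binding limit peptides co-diffuse with vesicles", {
  # kd ~ 0 with excess sites: every labeled peptide rides a vesicle, so the
  # blue autocorrelation decays on the slow vesicle timescale
  p <- small_params(kd = 1e-15, c_p_total = 5e-8, duration = 10, seed = 13)
  sim <- simulate_fccs(p)
  expect_equal(sim$truth$n_bound_labeled, sim$truth$n_labeled)
  blue <- fit_amplitude(correlate(sim$traces[[1]], "blue_auto"), p$s_param)
  tau_ves_blue <- p$omega_b^2 / (4 * p$d_vesicle)
  expect_equal(blue$tau_d, tau_ves_blue, tolerance = 0.35)
  expect_gt(blue$tau_d, 10 * p$omega_b^2 / (4 * p$d_peptide))
})

test_that("infeasible and invalid simulator parameters are rejected", {
  expect_error(fccs_sim_params(kd = -1), "kd")
  expect_error(small_params(label_fraction = 0), "label_fraction")
  expect_error(small_params(box = c(1e-6, 1e-6)), "box")
})

test_that("the binding pipeline conserves mass and flags no-binding controls", {
  geom <- effective_volume(2e-7, 2.5e-7, 5)
  p <- small_params(kd = 1e-7, c_p_total = 1e-7 * 10^seq(-0.5, 1, length.out = 6),
                    duration = 5, seed = 2)
  sim <- simulate_fccs(p)
  res <- suppressWarnings(binding_pipeline(sim$traces, geom))
  pts <- res$points[res$points$informative, ]
  # mass conservation on every informative point, by construction of Eq-5 route
  expect_equal(pts$c_p_free + pts$n_p * pts$c_vesicle, pts$c_p_total,
               tolerance = 1e-9)
  expect_false(res$no_binding)
  expect_s3_class(res$fit, "langmuir_fit")
  expect_equal(nrow(tidy(res)), 6)

  # free-dye control: kd far above all concentrations, no co-diffusion
  p0 <- small_params(kd = 10, c_p_total = c(5e-8, 2e-7), duration = 5, seed = 3)
  sim0 <- simulate_fccs(p0)
  res0 <- suppressWarnings(binding_pipeline(sim0$traces, geom))
  expect_true(res0$no_binding)
  expect_true(all(sim0$truth$n_bound_labeled == 0))
  expect_null(res0$fit)
  expect_true(all(is.na(glance(res0)$kd)))
})
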
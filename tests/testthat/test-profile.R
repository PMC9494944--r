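make_traj <- function(z, times = seq_along(z) - 1, box_z = 9) {
  z_trajectory(
    data.frame(time_ns = times, particle_id = 1L, z_nm = z),
    box_z = box_z
  )
}

test_that("a particle pinned at one position yields a delta-like profile", {
  tr <- make_traj(rep(1.0, 200))
  prof <- density_profile(tr, bin_width = 0.1, discard_ns = 0)
  expect_true(attr(prof, "symmetrized"))
  # all mass in [1.0, 1.1)
  hot <- prof$rho_per_nm > 0
  expect_equal(sum(hot), 1L)
  expect_equal(prof$z_nm[hot], 1.05)
  widths <- diff(attr(prof, "bin_edges"))
  expect_equal(sum(prof$rho_per_nm * widths), 1, tolerance = 1e-12)
})

test_that("uniform samples fold to a flat profile at the analytic level", {
  set.seed(42)
  n <- 1e5
  tr <- make_traj(runif(n, -4, 4), box_z = 8)
  prof <- density_profile(tr, bin_width = 0.1, discard_ns = 0)
  widths <- diff(attr(prof, "bin_edges"))
  expect_equal(sum(prof$rho_per_nm * widths), 1, tolerance = 1e-9)
  # folded uniform density on (0, 4): 0.25 per nm, Poisson counting noise
  expected_counts <- n * 0.1 * 0.25
  sigma <- sqrt(expected_counts)
  counts <- prof$rho_per_nm * n * 0.1
  expect_true(all(abs(counts - expected_counts) < 3.5 * sigma))
})

test_that("equilibration frames are excluded by the discard", {
  tr <- make_traj(rep(1, 201), times = seq(0, 2000, by = 10))
  prof <- density_profile(tr, discard_ns = 500)
  expect_equal(attr(prof, "n_frames_used"), sum(seq(0, 2000, by = 10) >= 500))
  expect_error(density_profile(tr, discard_ns = 1e6), "discard")
})

test_that("find_cutoff detects the density minimum between peak and bulk", {
  z <- seq(0.05, 4.45, by = 0.1)
  rho <- 0.15 + 0.6 * exp(-((z - 2.2) / 0.3)^2) - 0.1 * exp(-((z - 3.0) / 0.25)^2)
  rho <- rho / sum(rho * 0.1)
  prof <- structure(
    tibble::tibble(z_nm = z, rho_per_nm = rho),
    class = c("density_profile", class(tibble::tibble())),
    bin_edges = seq(0, 4.5, by = 0.1), z_max = 4.5
  )
  cut <- find_cutoff(prof)
  expect_equal(cut$method, "detected_minimum")
  expect_equal(cut$z_cut, 2.95, tolerance = 0.11) # minimum near 3.0
  expect_equal(cut$rho_min, min(rho[z > 2.5 & z < 3.4]))
})

test_that("profiles without an interfacial peak fall back to 3.5 nm", {
  z <- seq(0.05, 4.45, by = 0.1)
  rho <- z / sum(z * 0.1) # monotonically rising toward bulk, no binding peak
  prof <- structure(
    tibble::tibble(z_nm = z, rho_per_nm = rho),
    class = c("density_profile", class(tibble::tibble())),
    bin_edges = seq(0, 4.5, by = 0.1), z_max = 4.5
  )
  cut <- find_cutoff(prof)
  expect_equal(cut$method, "default_fallback")
  expect_equal(cut$z_cut, 3.5)
  expect_true(is.na(cut$rho_min))

  short <- structure(
    tibble::tibble(z_nm = z[z < 3], rho_per_nm = rho[z < 3]),
    class = c("density_profile", class(tibble::tibble()))
  )
  expect_error(find_cutoff(short), "extent")
})

test_that("cutoff from a sampled Boltzmann profile matches the analytic argmin", {
  pmf <- membrane_pmf(well_depth = 15)
  tr <- sample_pmf(pmf, 4e5, seed = 3)
  prof <- density_profile(tr, discard_ns = 0)
  cut <- find_cutoff(prof)
  expect_equal(cut$method, "detected_minimum")
  expect_equal(cut$z_cut, boltzmann_argmin(pmf), tolerance = 0.05)
})

test_that("binding probabilities integrate the profile exactly", {
  tr <- make_traj(rep(1.0, 100))
  prof <- density_profile(tr, bin_width = 0.1, discard_ns = 0)
  probs <- binding_probabilities(prof, 3.5)
  expect_equal(probs$p_bound, 1)
  expect_equal(probs$p_unbound, 0)

  # uniform on (0, 7): cutoff at half the range splits mass evenly,
  # including the partial-bin interpolation (cut mid-bin on purpose)
  z <- seq(0.1, 6.9, by = 0.2)
  prof_u <- structure(
    tibble::tibble(z_nm = z, rho_per_nm = rep(1 / 7, length(z))),
    class = c("density_profile", class(tibble::tibble())),
    bin_edges = seq(0, 7, by = 0.2)
  )
  probs_u <- binding_probabilities(prof_u, 3.5)
  expect_equal(probs_u$p_bound, 0.5, tolerance = 1e-12)
  expect_equal(probs_u$p_bound + probs_u$p_unbound, 1, tolerance = 1e-12)
  expect_error(binding_probabilities(prof_u, 7.5), "inside")
})

test_that("sampled binding probabilities match direct quadrature of the PMF", {
  pmf <- membrane_pmf(well_depth = 12)
  tr <- sample_pmf(pmf, 1e6, seed = 5)
  prof <- density_profile(tr, discard_ns = 0)
  probs <- binding_probabilities(prof, 3.2)
  oracle <- quadrature_probs(pmf, 3.2)
  expect_equal(probs$p_bound, unname(oracle["p_bound"]), tolerance = 5e-3)
})

test_that("adsorption_dg implements the Boltzmann inversion with its symmetries", {
  mk <- function(pb) {
    structure(list(p_bound = pb, p_unbound = 1 - pb,
                   cutoff = list(z_cut = 3.5)),
              class = "binding_probabilities")
  }
  expect_equal(adsorption_dg(mk(0.5))$delta_g, 0)
  # closed form at 310 K
  expect_equal(adsorption_dg(mk(0.9), temperature = 310)$delta_g,
               -0.0083145 * 310 * log(9), tolerance = 1e-12)
  # antisymmetry under p_bound <-> p_unbound
  expect_equal(adsorption_dg(mk(0.1))$delta_g,
               -adsorption_dg(mk(0.9))$delta_g, tolerance = 1e-12)
  expect_error(adsorption_dg(mk(0)), "divergent")
  expect_error(adsorption_dg(mk(1)), "divergent")
})

test_that("density profiles round-trip through CSV", {
  tr <- make_traj(runif(500, 0, 4), box_z = 9)
  prof <- density_profile(tr, bin_width = 0.05, discard_ns = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$rho_per_nm, prof$rho_per_nm, tolerance = 1e-6)
  expect_equal(attr(back, "n_frames_used"), attr(prof, "n_frames_used"))
  probs_a <- binding_probabilities(prof, 2.0)
  probs_b <- binding_probabilities(back, 2.0)
  expect_equal(probs_a$p_bound, probs_b$p_bound, tolerance = 1e-6)
})
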
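grid44 <- seq(1, 5, by = 0.1)

test_that("symmetrize averages a surface with its transpose and is idempotent", {
  f <- outer(grid44, grid44, function(a, b) a) # f(a,b) = a
  fes <- fes2d(grid44, grid44, f)
  sym <- symmetrize(fes)
  expect_equal(sym$f, outer(grid44, grid44, function(a, b) (a + b) / 2))
  expect_equal(sym$f, t(sym$f))
  expect_equal(symmetrize(sym)$f, sym$f) # idempotent

  asym_grid <- fes2d(grid44, grid44 + 0.05,
                     matrix(0, length(grid44), length(grid44)))
  expect_error(symmetrize(asym_grid), "square")
})

test_that("symmetrizing a noisy surface moves it closer to the symmetric truth", {
  pmf <- membrane_pmf(well_depth = 18)
  fes <- make_fes(pmf, noise_sd = 1.5, seed = 4)
  truth <- attr(fes, "truth")
  rms <- function(m) sqrt(mean((m - truth)^2))
  expect_lt(rms(symmetrize(fes)$f), rms(fes$f))
  # averaging two independent noise draws halves the error variance
  expect_equal(rms(symmetrize(fes)$f), rms(fes$f) / sqrt(2), tolerance = 0.1)
})

test_that("shift_to_bulk zeroes the joint-bulk minimum exactly", {
  f <- matrix(7, length(grid44), length(grid44))
  fes <- shift_to_bulk(fes2d(grid44, grid44, f))
  expect_true(all(fes$f == 0))

  f2 <- outer(grid44, grid44, function(a, b) sin(a) + cos(b)) + 12.3
  s2 <- shift_to_bulk(fes2d(grid44, grid44, f2))
  mask <- outer(grid44 > 4, grid44 > 4, "&")
  expect_equal(min(s2$f[mask]), 0)
  # brute-force masked minimum equals the applied shift
  shift_applied <- f2[1, 1] - s2$f[1, 1]
  expect_equal(shift_applied, min(f2[mask]))

  narrow <- seq(1, 3, by = 0.1)
  expect_error(shift_to_bulk(fes2d(narrow, narrow,
                                   matrix(0, 21, 21))), "extend")
})

test_that("global_minimum recovers constructed wells and ties break low", {
  f <- outer(grid44, grid44, function(a, b) {
    -20 * exp(-((a - 2.2)^2 + (b - 4.5)^2) / 0.05)
  })
  m <- global_minimum(fes2d(grid44, grid44, f))
  expect_equal(m$cv1, 2.2)
  expect_equal(m$cv2, 4.5)
  expect_equal(m$depth, -20, tolerance = 1e-6)

  flat <- global_minimum(fes2d(grid44, grid44,
                               matrix(0, length(grid44), length(grid44))))
  expect_equal(flat$depth, 0)
  expect_equal(c(flat$cv1, flat$cv2), c(1, 1)) # smallest (cv1, cv2)

  set.seed(13)
  for (rep in 1:5) {
    f <- matrix(rnorm(length(grid44)^2), length(grid44))
    m <- global_minimum(fes2d(grid44, grid44, f))
    idx <- which(f == min(f), arr.ind = TRUE)
    expect_equal(m$depth, f[idx[1, 1], idx[1, 2]])
  }
})

test_that("unexplored cells are excluded, never imputed", {
  f <- matrix(5, length(grid44), length(grid44))
  f[3, 4] <- NA # would be a fake -inf well if imputed as zero
  f[40, 40] <- 2
  s <- shift_to_bulk(fes2d(grid44, grid44, f))
  expect_equal(global_minimum(s)$depth, 0)
  expect_true(is.na(s$f[3, 4]))
})

test_that("flat surfaces give the entropic area-ratio adsorption free energy", {
  # place a cell boundary exactly at c = 1 - 1/sqrt(2), where the 2-D bound
  # and bulk areas are equal, so the flat-surface free energy is exactly zero
  c0 <- 1 - 1 / sqrt(2)
  g <- sort(unique(c(seq(0, c0 - 0.01, length.out = 30), c0 - 0.01,
                     c0 + 0.01, seq(c0 + 0.01, 1, length.out = 30))))
  fes <- fes2d(g, g, matrix(0, length(g), length(g)))
  expect_lt(abs(total_adsorption_dg(fes, cutoff = c0)), 1e-10)

  # unequal split on a uniform grid, cutoff on a cell boundary
  g2 <- seq(0.5, 6.5, by = 0.1)
  fes2 <- fes2d(g2, g2, matrix(0, length(g2), length(g2)))
  kT <- 0.0083145 * 310
  p <- (2.05 - 0.5) / 6 # one-sided bound fraction
  expected <- -kT * log((1 - (1 - p)^2) / (1 - p)^2)
  expect_equal(total_adsorption_dg(fes2, cutoff = 2.05), expected,
               tolerance = 1e-9)
})

test_that("a deep bound-region well gives negative adsorption free energy", {
  pmf <- membrane_pmf(well_depth = 20)
  fes <- shift_to_bulk(symmetrize(make_fes(pmf, noise_sd = 0)))
  expect_lt(total_adsorption_dg(fes, cutoff = 3.5), 0)
})

test_that("total_adsorption_dg matches a refined-grid Boltzmann sum", {
  pmf <- membrane_pmf(well_depth = 15)
  g <- seq(1, 5, by = 0.02)
  u <- pmf_value(pmf, pmin(g, pmf$box_half))
  fes <- fes2d(g, g, outer(u, u, "+"))
  dg <- total_adsorption_dg(fes, cutoff = 3.5, temperature = 310)
  oracle <- refined_fes_dg(function(z) pmf_value(pmf, pmin(z, pmf$box_half)),
                           cutoff = 3.5, temperature = 310, lo = 1, hi = 5,
                           n = 4000)
  expect_equal(dg, oracle, tolerance = 0.05)
})

test_that("convergence series tracks snapshots and reports last-half drift", {
  pmf <- membrane_pmf(well_depth = 16)
  base <- make_fes(pmf, noise_sd = 0)
  snaps <- lapply(c(100, 200, 300, 400), function(t) {
    f <- make_fes(pmf, noise_sd = 400 / t * 0.5, seed = t)
    f$time_stamp <- t
    f
  })
  ser <- convergence_series(snaps, cutoff = 3.5)
  expect_equal(nrow(ser), 4)
  expect_equal(ser$time_ns, c(100, 200, 300, 400))

  same <- convergence_series(list(base, base), cutoff = 3.5)
  expect_equal(nrow(same), 2)
  expect_equal(attr(same, "last_half_drift"), 0)

  other <- fes2d(grid44, grid44, matrix(0, length(grid44), length(grid44)))
  expect_error(convergence_series(list(base, other)), "common grid")
})

test_that("FES files round-trip including unexplored cells", {
  pmf <- membrane_pmf(well_depth = 10)
  fes <- make_fes(pmf, noise_sd = 0.3, seed = 2, grid = seq(1, 5, 0.25))
  fes$f[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".dat")
  write_fes(fes, path)
  back <- read_fes(path)
  expect_equal(back$cv1_grid, fes$cv1_grid)
  expect_equal(back$f, fes$f, tolerance = 1e-9)
  # comment lines tolerated
  lines <- readLines(path)
  expect_true(grepl("^#", lines[1]))
})
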
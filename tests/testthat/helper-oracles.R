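# Independent oracles used across the suite. These deliberately use naive,
# from-scratch computations (Riemann sums, O(N^2) scans, direct lag products)
# so they share no code path with the package implementations they check.

kB_ORACLE <- 0.0083145

# Riemann-sum Boltzmann inversion of a PMF on a fine fixed grid
riemann_dg <- function(pmf, z_cut, temperature = 310, n = 1e5) {
  kT <- kB_ORACLE * temperature
  z <- seq(0, pmf$box_half, length.out = n)
  w <- exp(-pmf_value(pmf, z) / kT)
  dz <- z[2] - z[1]
  bound <- sum(w[z <= z_cut]) * dz
  unbound <- sum(w[z > z_cut]) * dz
  -kT * log(bound / unbound)
}

# density minimum position of exp(-U/kT) between well and bulk, on a fine grid
boltzmann_argmin <- function(pmf, temperature = 310, n = 20001) {
  z <- seq(pmf$well_pos, pmf$box_half - 1, length.out = n)
  dens <- exp(-pmf_value(pmf, z) / (kB_ORACLE * temperature))
  z[which.min(dens)]
}

# direct quadrature of bound probability for a given profile-free PMF
quadrature_probs <- function(pmf, z_cut, temperature = 310) {
  kT <- kB_ORACLE * temperature
  f <- function(z) exp(-pmf_value(pmf, z) / kT)
  ib <- stats::integrate(f, 0, z_cut, rel.tol = 1e-12)$value
  iu <- stats::integrate(f, z_cut, pmf$box_half, rel.tol = 1e-12)$value
  c(p_bound = ib / (ib + iu), p_unbound = iu / (ib + iu))
}

# brute-force correlator: rebins the ORIGINAL trace by direct grouping and
# forms the lag products one by one
naive_correlation <- function(f1, f2, lag_bins, rebin) {
  nb <- (length(f1) %/% rebin)
  x <- numeric(nb)
  y <- numeric(nb)
  for (j in seq_len(nb)) {
    idx <- ((j - 1) * rebin + 1):(j * rebin)
    x[j] <- mean(f1[idx])
    y[j] <- mean(f2[idx])
  }
  k <- lag_bins
  num <- 0
  for (t in seq_len(nb - k)) num <- num + x[t] * y[t + k]
  num <- num / (nb - k)
  num / (mean(x[1:(nb - k)]) * mean(y[(k + 1):nb])) - 1
}

# exhaustive O(N^2) periodic minimum distance for one frame
brute_min_distance <- function(a, b, box) {
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- 0
      for (k in 1:3) {
        dd <- a[i, k] - b[j, k]
        dd <- dd - box[k] * round(dd / box[k])
        d <- d + dd^2
      }
      best <- min(best, d)
    }
  }
  sqrt(best)
}

# fine-grid Boltzmann double sum for the 2-D adsorption free energy
refined_fes_dg <- function(u_fun, cutoff, temperature, lo, hi, n = 2000) {
  kT <- kB_ORACLE * temperature
  g <- seq(lo, hi, length.out = n)
  w <- exp(-u_fun(g) / kT)
  bound1 <- g <= cutoff
  # either CV bound vs both bulk, separable weights
  s_all <- sum(w)^2
  s_bulk <- sum(w[!bound1])^2
  s_bound <- s_all - s_bulk
  -kT * log(s_bound / s_bulk)
}
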
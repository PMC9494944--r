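#' Two-dimensional free-energy surface over peptide-membrane distances
#'
#' Container for a free-energy grid over the two collective variables (the
#' z-components of the center-of-mass distances between the membrane and each
#' of the two peptides). Unexplored cells are stored as `NA` and are excluded
#' from all sums and minima (never imputed as zero, which would create
#' fictitious wells).
#'
#' @param cv1_grid,cv2_grid Strictly increasing grid coordinates (nm).
#' @param f Matrix of free energies (kJ/mol), `length(cv1_grid)` rows by
#'   `length(cv2_grid)` columns; `NA` marks unexplored cells.
#' @param bias_factor Optional well-tempered bias factor (metadata).
#' @param time_stamp Simulation time of the snapshot (ns, metadata).
#'
#' @return An object of class `fes2d`.
#' @export
fes2d <- function(cv1_grid, cv2_grid, f, bias_factor = NA_real_,
                  time_stamp = NA_real_) {
  if (any(diff(cv1_grid) <= 0) || any(diff(cv2_grid) <= 0)) {
    abort("grids must be strictly increasing")
  }
  f <- as.matrix(f)
  if (nrow(f) != length(cv1_grid) || ncol(f) != length(cv2_grid)) {
    abort("dimensions of `f` must match the grids")
  }
  if (any(is.infinite(f))) {
    abort("free energy must be finite on explored cells (use NA for unexplored)")
  }
  structure(
    list(cv1_grid = cv1_grid, cv2_grid = cv2_grid, f = f,
         bias_factor = bias_factor, time_stamp = time_stamp),
    class = "fes2d"
  )
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf(
    "<fes2d> %d x %d grid, cv range [%.2f, %.2f] nm, %d unexplored cells\n",
    length(x$cv1_grid), length(x$cv2_grid),
    min(x$cv1_grid), max(x$cv1_grid), sum(is.na(x$f))
  ))
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.fes2d <- function(x, ...) {
  tibble::tibble(
    cv1 = rep(x$cv1_grid, times = length(x$cv2_grid)),
    cv2 = rep(x$cv2_grid, each = length(x$cv1_grid)),
    free_energy = as.vector(x$f)
  )
}

#' Read / write a plain-text free-energy grid
#'
#' The on-disk dialect is the common metadynamics FES dump: whitespace
#' separated `cv1 cv2 f` triples with the first column varying fastest, and
#' `#` comment lines tolerated. Non-finite `f` values (`nan`, `inf`) are
#' read as unexplored cells.
#'
#' @param path File path.
#' @return For `read_fes`, a [fes2d()]; `write_fes` returns `path`
#'   invisibly.
#' @export
read_fes <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(parts) < 3L)) abort("expected three whitespace-separated columns")
  m <- matrix(as.numeric(unlist(lapply(parts, `[`, 1:3))), ncol = 3L,
              byrow = TRUE)
  cv1 <- sort(unique(m[, 1]))
  cv2 <- sort(unique(m[, 2]))
  f <- matrix(NA_real_, length(cv1), length(cv2))
  i <- match(m[, 1], cv1)
  j <- match(m[, 2], cv2)
  f[cbind(i, j)] <- ifelse(is.finite(m[, 3]), m[, 3], NA_real_)
  fes2d(cv1, cv2, f)
}

#' @rdname read_fes
#' @param fes A [fes2d()].
#' @export
write_fes <- function(fes, path) {
  df <- as_tibble.fes2d(fes)
  df <- df[order(df$cv2, df$cv1), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cv1_nm cv2_nm free_energy_kj_mol", con)
  writeLines(sprintf("%.10g %.10g %.10g", df$cv1, df$cv2,
                     ifelse(is.na(df$free_energy), NaN, df$free_energy)), con)
  invisible(path)
}

#' Symmetrize a free-energy surface along the identity line
#'
#' The two collective variables are exchangeable (two copies of the same
#' peptide), so the surface is averaged with its transpose:
#' `f'(a,b) = (f(a,b) + f(b,a)) / 2`. Requires a square grid with
#' `cv1_grid == cv2_grid`. If exactly one of the mirror cells is unexplored,
#' the explored value is kept. The operation is idempotent.
#'
#' @param fes A [fes2d()].
#' @return A transpose-invariant [fes2d()].
#' @export
symmetrize <- function(fes) {
  stopifnot(inherits(fes, "fes2d"))
  if (length(fes$cv1_grid) != length(fes$cv2_grid) ||
      any(abs(fes$cv1_grid - fes$cv2_grid) > 1e-9)) {
    abort("symmetrization requires a square grid with cv1_grid == cv2_grid")
  }
  ft <- t(fes$f)
  f2 <- (fes$f + ft) / 2
  only_a <- is.na(ft) & !is.na(fes$f)
  only_b <- is.na(fes$f) & !is.na(ft)
  f2[only_a] <- fes$f[only_a]
  f2[only_b] <- ft[only_b]
  fes2d(fes$cv1_grid, fes$cv2_grid, f2, fes$bias_factor, fes$time_stamp)
}

#' Shift a free-energy surface to the bulk reference
#'
#' Sets the zero of free energy at the bulk: the lowest explored free energy
#' in the region where both peptides are further than `bulk_threshold` from
#' the membrane is subtracted, so that region's minimum becomes exactly 0.
#'
#' @param fes A [fes2d()].
#' @param bulk_threshold Bulk distance threshold in nm (default 4.0).
#' @return A bulk-referenced [fes2d()].
#' @export
shift_to_bulk <- function(fes, bulk_threshold = 4.0) {
  stopifnot(inherits(fes, "fes2d"))
  if (max(fes$cv1_grid) <= bulk_threshold ||
      max(fes$cv2_grid) <= bulk_threshold) {
    abort("grid does not extend beyond the bulk threshold in both CVs")
  }
  mask <- outer(fes$cv1_grid > bulk_threshold, fes$cv2_grid > bulk_threshold,
                "&")
  vals <- fes$f[mask]
  if (all(is.na(vals))) abort("bulk region is entirely unexplored")
  fes2d(fes$cv1_grid, fes$cv2_grid, fes$f - min(vals, na.rm = TRUE),
        fes$bias_factor, fes$time_stamp)
}

#' Global minimum of a bulk-referenced surface
#'
#' Location and depth of the minimum over explored cells. Ties are broken
#' toward the smallest `(cv1, cv2)` (cv1 first).
#'
#' @param fes A [fes2d()], shifted to the bulk reference.
#' @return A list of class `fes_minimum` with `cv1`, `cv2` (nm) and `depth`
#'   (kJ/mol, relative to the bulk zero).
#' @export
global_minimum <- function(fes) {
  stopifnot(inherits(fes, "fes2d"))
  if (all(is.na(fes$f))) abort("all cells are unexplored")
  fmin <- min(fes$f, na.rm = TRUE)
  hits <- which(fes$f == fmin, arr.ind = TRUE)
  ord <- order(fes$cv1_grid[hits[, 1]], fes$cv2_grid[hits[, 2]])
  i <- hits[ord[1], 1]
  j <- hits[ord[1], 2]
  structure(
    list(cv1 = fes$cv1_grid[i], cv2 = fes$cv2_grid[j], depth = fmin),
    class = "fes_minimum"
  )
}

#' @export
print.fes_minimum <- function(x, ...) {
  cat(sprintf("<fes_minimum> %.2f kJ/mol at (%.2f, %.2f) nm\n",
              x$depth, x$cv1, x$cv2))
  invisible(x)
}

# trapezoid-style cell widths for a (possibly non-uniform) grid
.cell_widths <- function(g) {
  n <- length(g)
  if (n == 1L) return(1)
  mid <- (g[-1] + g[-n]) / 2
  c(mid[1] - g[1], diff(mid), g[n] - mid[n - 1])
}

#' Total adsorption free energy from a 2-D surface
#'
#' Boltzmann-weighted partition of the surface into a bound region (either
#' peptide within `cutoff` of the membrane) and a bulk region (both beyond):
#' `dG_ads = -kB T log( sum_bound w exp(-f/kBT) / sum_bulk w exp(-f/kBT) )`,
#' with cell-area weights `w`. Unexplored cells are excluded. On a flat
#' surface this reduces to the entropic area ratio
#' `-kB T log(A_bound / A_bulk)`.
#'
#' @param fes A bulk-referenced [fes2d()].
#' @param cutoff Bound-region cutoff distance (nm).
#' @param temperature Temperature in K (default 310).
#' @return Total adsorption free energy in kJ/mol.
#' @export
total_adsorption_dg <- function(fes, cutoff = 3.5, temperature = 310) {
  stopifnot(inherits(fes, "fes2d"))
  .check_scalar_pos(temperature, "temperature")
  kT <- .kB * temperature
  w <- outer(.cell_widths(fes$cv1_grid), .cell_widths(fes$cv2_grid))
  bound <- outer(fes$cv1_grid <= cutoff, fes$cv2_grid <= cutoff, "|")
  bulk <- !bound
  boltz <- w * exp(-fes$f / kT)
  s_bound <- sum(boltz[bound], na.rm = TRUE)
  s_bulk <- sum(boltz[bulk], na.rm = TRUE)
  if (s_bound == 0 || all(is.na(fes$f[bound]))) abort("empty bound partition")
  if (s_bulk == 0 || all(is.na(fes$f[bulk]))) abort("empty bulk partition")
  -kT * log(s_bound / s_bulk)
}

#' Convergence of the total adsorption free energy over snapshots
#'
#' Applies [total_adsorption_dg()] to a time-ordered list of surfaces and
#' reports the drift over the last half of the series (max minus min), a
#' simple plateau diagnostic for metadynamics convergence.
#'
#' @param snapshots List of [fes2d()] objects at increasing `time_stamp`,
#'   on identical grids, already bulk-referenced.
#' @param cutoff,temperature Passed to [total_adsorption_dg()].
#' @return A tibble with `time_ns` and `dg_kj_mol`, with attribute
#'   `last_half_drift` (kJ/mol).
#' @export
convergence_series <- function(snapshots, cutoff = 3.5, temperature = 310) {
  if (length(snapshots) < 2L) abort("need at least two snapshots")
  g1 <- snapshots[[1]]
  for (s in snapshots[-1]) {
    if (length(s$cv1_grid) != length(g1$cv1_grid) ||
        any(abs(s$cv1_grid - g1$cv1_grid) > 1e-9) ||
        any(abs(s$cv2_grid - g1$cv2_grid) > 1e-9)) {
      abort("snapshots must share a common grid")
    }
  }
  out <- tibble::tibble(
    time_ns = vapply(snapshots, function(s) s$time_stamp, numeric(1)),
    dg_kj_mol = vapply(snapshots, total_adsorption_dg, numeric(1),
                       cutoff = cutoff, temperature = temperature)
  )
  last <- out$dg_kj_mol[seq.int(floor(nrow(out) / 2) + 1L, nrow(out))]
  attr(out, "last_half_drift") <- max(last) - min(last)
  out
}
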
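#' Count membrane-bound peptides per frame
#'
#' A peptide counts as bound in a frame when the absolute distance of its
#' center of mass from the membrane center does not exceed the cutoff — the
#' same cutoff that defines the bound region of the free-energy integrals,
#' keeping the two observables consistent.
#'
#' @param traj Data frame (or [z_trajectory()]) with one z series per peptide:
#'   columns `time_ns`, `particle_id`, `z_nm`.
#' @param cutoff A `cutoff_result` from [find_cutoff()] or a numeric cutoff
#'   in nm.
#' @param discard_ns Equilibration span to discard (ns).
#' @param blocks Number of blocks for the block-averaged SEM (default 5).
#'
#' @return A `contact_stats` object: list with `mean`, `sem`, `blocks`,
#'   `statistic`, and the per-frame series in `per_frame`.
#' @export
count_bound_peptides <- function(traj, cutoff, discard_ns = 0, blocks = 5L) {
  if (missing(cutoff) || is.null(cutoff)) abort("`cutoff` is required")
  z_cut <- if (is.numeric(cutoff)) cutoff else cutoff$z_cut
  .check_columns(traj, c("time_ns", "particle_id", "z_nm"), "trajectory")
  kept <- traj[traj$time_ns >= discard_ns, , drop = FALSE]
  if (nrow(kept) == 0L) abort("no frames survive the equilibration discard")
  per_frame <- kept |>
    dplyr::group_by(.data$time_ns) |>
    dplyr::summarise(value = sum(abs(.data$z_nm) <= z_cut), .groups = "drop")
  new_contact_stats(per_frame, "bound_peptides", blocks)
}

#' Count buried guanidinium groups per bound peptide
#'
#' An arginine side chain counts as buried in a frame when its guanidinium
#' carbon sits below the phosphate plane of the proximal leaflet plus a small
#' margin: `|z_gdm| < mean(|z_P, proximal|) + margin`. The proximal leaflet is
#' the set of phosphorus atoms on the same side of the membrane (same sign of
#' z) as the peptide. The statistic is the per-frame mean number of buried
#' side chains per *bound* peptide; frames with no bound peptide do not
#' contribute, and an input with no bound peptide in any frame is an error
#' (the quantity is undefined, not zero).
#'
#' @param gdm_traj Data frame with `time_ns`, `peptide_id`, `z_nm`: one row
#'   per guanidinium carbon (nine per peptide per frame).
#' @param phosphate_traj Data frame with `time_ns`, `z_nm`: lipid phosphorus
#'   atoms (signed z).
#' @param bound_flags Data frame with `time_ns`, `peptide_id`, `bound`
#'   (logical), e.g. derived from [count_bound_peptides()]'s criterion.
#' @param margin Burial margin above the phosphate plane, nm (default 0.1).
#' @param blocks Blocks for the block-averaged SEM.
#'
#' @return A `contact_stats` object (statistic
#'   `"buried_gdm_per_bound_peptide"`).
#' @export
count_buried_gdm <- function(gdm_traj, phosphate_traj, bound_flags,
                             margin = 0.1, blocks = 5L) {
  .check_columns(gdm_traj, c("time_ns", "peptide_id", "z_nm"), "gdm_traj")
  .check_columns(phosphate_traj, c("time_ns", "z_nm"), "phosphate_traj")
  .check_columns(bound_flags, c("time_ns", "peptide_id", "bound"),
                 "bound_flags")
  n_per <- gdm_traj |>
    dplyr::count(.data$time_ns, .data$peptide_id)
  if (any(n_per$n != 9L)) {
    abort("guanidinium carbons must come in groups of nine per peptide")
  }
  bound <- bound_flags[bound_flags$bound, c("time_ns", "peptide_id")]
  if (nrow(bound) == 0L) {
    abort("no bound peptides in any frame; buried count is undefined")
  }
  # per peptide-frame: side of the membrane the peptide sits on
  side <- gdm_traj |>
    dplyr::group_by(.data$time_ns, .data$peptide_id) |>
    dplyr::summarise(side = sign(mean(.data$z_nm)), .groups = "drop") |>
    dplyr::mutate(side = ifelse(.data$side == 0, 1, .data$side))
  planes <- side |>
    dplyr::distinct(.data$time_ns, .data$side) |>
    dplyr::left_join(phosphate_traj, by = "time_ns",
                     relationship = "many-to-many") |>
    dplyr::filter(sign(.data$z_nm) == .data$side | sign(.data$z_nm) == 0) |>
    dplyr::group_by(.data$time_ns, .data$side) |>
    dplyr::summarise(plane = mean(abs(.data$z_nm)), .groups = "drop")
  per_pep <- gdm_traj |>
    dplyr::inner_join(bound, by = c("time_ns", "peptide_id")) |>
    dplyr::left_join(side, by = c("time_ns", "peptide_id")) |>
    dplyr::left_join(planes, by = c("time_ns", "side"))
  if (any(is.na(per_pep$plane))) {
    abort("no proximal-leaflet phosphorus atoms for at least one frame")
  }
  per_frame <- per_pep |>
    dplyr::group_by(.data$time_ns, .data$peptide_id) |>
    dplyr::summarise(
      buried = sum(abs(.data$z_nm) < .data$plane + margin),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$time_ns) |>
    dplyr::summarise(value = mean(.data$buried), .groups = "drop")
  new_contact_stats(per_frame, "buried_gdm_per_bound_peptide", blocks)
}

new_contact_stats <- function(per_frame, statistic, blocks) {
  structure(
    list(
      mean = mean(per_frame$value),
      sem = block_sem(per_frame$value, blocks),
      blocks = as.integer(blocks),
      statistic = statistic,
      per_frame = per_frame
    ),
    class = "contact_stats"
  )
}

#' @export
print.contact_stats <- function(x, ...) {
  cat(sprintf(
    "<contact_stats> %s: %.3f +/- %.3f (block SEM, %d blocks, %d frames)\n",
    x$statistic, x$mean, x$sem, x$blocks, nrow(x$per_frame)
  ))
  invisible(x)
}

#' @export
tidy.contact_stats <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, mean = x$mean, block_sem = x$sem,
    blocks = x$blocks, n_frames = nrow(x$per_frame)
  )
}

#' Area per lipid time series
#'
#' Per-frame lateral box area divided by the number of lipids per leaflet,
#' with mean and block-averaged SEM after discarding equilibration.
#'
#' @param frames Data frame with `time_ns`, `lx_nm`, `ly_nm` (per-frame
#'   lateral box dimensions), or a [z_trajectory()] carrying them.
#' @param n_lipids_per_leaflet Lipids per leaflet (default 100, the bilayer
#'   size used throughout the study this package models).
#' @param discard_ns Equilibration span to discard (ns).
#' @param blocks Blocks for the SEM.
#'
#' @return A tibble of class `apl_series` with columns `time_ns`,
#'   `apl_nm2`, and attributes `mean`, `sem`, `n_lipids_per_leaflet`.
#' @export
area_per_lipid <- function(frames, n_lipids_per_leaflet = 100,
                           discard_ns = 0, blocks = 5L) {
  if (inherits(frames, "z_trajectory")) frames <- attr(frames, "frames")
  .check_columns(frames, c("time_ns", "lx_nm", "ly_nm"), "frames")
  .check_scalar_pos(n_lipids_per_leaflet, "n_lipids_per_leaflet")
  kept <- frames[frames$time_ns >= discard_ns, , drop = FALSE]
  if (nrow(kept) == 0L) abort("no frames survive the equilibration discard")
  if (any(kept$lx_nm * kept$ly_nm <= 0)) abort("zero lateral box area")
  out <- tibble::tibble(
    time_ns = kept$time_ns,
    apl_nm2 = kept$lx_nm * kept$ly_nm / n_lipids_per_leaflet
  )
  class(out) <- c("apl_series", class(out))
  attr(out, "mean") <- mean(out$apl_nm2)
  attr(out, "sem") <- block_sem(out$apl_nm2, blocks)
  attr(out, "n_lipids_per_leaflet") <- n_lipids_per_leaflet
  out
}

#' Per-frame minimum periodic distance between two atom selections
#'
#' For every frame, the minimum over all atom pairs of the minimum-image
#' distance in a rectangular periodic box. Used e.g. to follow the minimum
#' distance of each peptide from the choline nitrogens and so diagnose
#' binding/unbinding events.
#'
#' @param peptide_atoms,reference_atoms Data frames with `time_ns`, `x_nm`,
#'   `y_nm`, `z_nm`.
#' @param box Box dimensions in nm: a length-3 numeric, or a data frame with
#'   `time_ns`, `lx_nm`, `ly_nm`, `lz_nm`.
#'
#' @return A tibble with columns `time_ns`, `min_dist_nm`.
#' @export
min_distance_series <- function(peptide_atoms, reference_atoms, box) {
  cols <- c("time_ns", "x_nm", "y_nm", "z_nm")
  .check_columns(peptide_atoms, cols, "peptide_atoms")
  .check_columns(reference_atoms, cols, "reference_atoms")
  times <- sort(unique(peptide_atoms$time_ns))
  if (is.data.frame(box)) {
    .check_columns(box, c("time_ns", "lx_nm", "ly_nm", "lz_nm"), "box")
  }
  purrr::map_dfr(times, function(t) {
    a <- peptide_atoms[peptide_atoms$time_ns == t, , drop = FALSE]
    b <- reference_atoms[reference_atoms$time_ns == t, , drop = FALSE]
    if (nrow(a) == 0L || nrow(b) == 0L) abort("empty selection in a frame")
    L <- if (is.data.frame(box)) {
      r <- box[box$time_ns == t, , drop = FALSE]
      c(r$lx_nm[1], r$ly_nm[1], r$lz_nm[1])
    } else {
      box
    }
    d2 <- matrix(0, nrow(a), nrow(b))
    for (k in seq_len(3)) {
      dd <- outer(a[[cols[k + 1]]], b[[cols[k + 1]]], "-")
      dd <- dd - L[k] * round(dd / L[k])
      d2 <- d2 + dd^2
    }
    tibble::tibble(time_ns = t, min_dist_nm = sqrt(min(d2)))
  })
}
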
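#' Construct a z-coordinate trajectory
#'
#' A `z_trajectory` is a tidy table of per-frame particle z coordinates
#' measured relative to the membrane center of mass (the membrane center is
#' the origin, so signed z spans `(-box_z/2, box_z/2]`). It is the common
#' currency of the density-profile and counting operations.
#'
#' @param data Data frame with columns `time_ns`, `particle_id`, `z_nm`.
#' @param box_z Box height(s) in nm: a single value or one per frame
#'   (ordered by time).
#' @param box_xy Optional lateral box dimensions: a data frame with columns
#'   `time_ns`, `lx_nm`, `ly_nm`, or a length-2 numeric recycled to all frames.
#' @param species_label Free-text label for the tracked species
#'   (e.g. `"R9 COM"`, `"Gdm C"`).
#' @param validate If `TRUE` (default), check invariants: strictly increasing
#'   frame times, non-empty frames, and `|z| <= box_z/2`.
#'
#' @return A tibble of class `z_trajectory` with attributes `frames`
#'   (per-frame `time_ns`, `box_z`, and lateral dimensions) and
#'   `species_label`.
#' @export
z_trajectory <- function(data, box_z, box_xy = NULL, species_label = "",
                         validate = TRUE) {
  .check_columns(data, c("time_ns", "particle_id", "z_nm"), "trajectory data")
  times <- sort(unique(data$time_ns))
  if (length(times) == 0L) abort("trajectory has no frames")
  if (length(box_z) == 1L) box_z <- rep(box_z, length(times))
  if (length(box_z) != length(times)) {
    abort("`box_z` must have length 1 or one value per frame")
  }
  frames <- tibble::tibble(time_ns = times, box_z = box_z)
  if (!is.null(box_xy)) {
    if (is.data.frame(box_xy)) {
      .check_columns(box_xy, c("time_ns", "lx_nm", "ly_nm"), "box_xy")
      frames <- dplyr::left_join(frames, box_xy, by = "time_ns")
    } else {
      frames$lx_nm <- box_xy[[1]]
      frames$ly_nm <- box_xy[[2]]
    }
  }
  if (validate) {
    if (any(frames$box_z <= 0)) abort("`box_z` must be positive")
    if (length(times) > 1L && any(diff(times) <= 0)) {
      abort("frame times must be strictly increasing")
    }
    half <- frames$box_z[match(data$time_ns, frames$time_ns)] / 2
    if (any(abs(data$z_nm) > half + 1e-9)) {
      abort("all |z| must be <= box_z/2 after centering/wrapping")
    }
  }
  out <- tibble::as_tibble(data[c("time_ns", "particle_id", "z_nm")])
  class(out) <- c("z_trajectory", class(out))
  attr(out, "frames") <- frames
  attr(out, "species_label") <- species_label
  out
}

#' @export
print.z_trajectory <- function(x, ...) {
  frames <- attr(x, "frames")
  cat(sprintf(
    "<z_trajectory> %s: %d frames, %d particles, t = [%g, %g] ns\n",
    attr(x, "species_label"), nrow(frames),
    length(unique(x$particle_id)), min(frames$time_ns), max(frames$time_ns)
  ))
  NextMethod()
}

#' Re-express particle z coordinates relative to the membrane center
#'
#' Subtracts the per-frame membrane reference center of mass (unweighted mean
#' of the reference z coordinates) from each particle z and wraps the result
#' into the periodic box, so that `|z| <= box_z/2` with the membrane center
#' at the origin.
#'
#' @param particles Data frame with `time_ns`, `particle_id`, `z_nm`:
#'   raw (laboratory-frame) particle z coordinates.
#' @param reference Data frame with `time_ns`, `z_nm`: the membrane reference
#'   atoms (e.g. all lipid phosphorus atoms) used to define the center.
#' @param box_z Box height in nm (scalar or one per frame).
#' @param box_xy Optional lateral box dimensions, passed on to
#'   [z_trajectory()].
#' @param species_label Label stored on the result.
#'
#' @return A [z_trajectory()].
#' @export
#' @examples
#' p <- data.frame(time_ns = 0, particle_id = 1, z_nm = 9.5)
#' r <- data.frame(time_ns = 0, z_nm = 0.5)
#' center_and_fold(p, r, box_z = 10)$z_nm # -1 (periodic image)
center_and_fold <- function(particles, reference, box_z, box_xy = NULL,
                            species_label = "") {
  .check_columns(particles, c("time_ns", "particle_id", "z_nm"), "particles")
  .check_columns(reference, c("time_ns", "z_nm"), "reference")
  if (any(box_z <= 0)) abort("`box_z` must be positive")
  times <- sort(unique(particles$time_ns))
  com <- reference |>
    dplyr::group_by(.data$time_ns) |>
    dplyr::summarise(com = mean(.data$z_nm), .groups = "drop")
  if (!all(times %in% com$time_ns)) {
    abort("reference selection is empty for at least one frame")
  }
  bz <- if (length(box_z) == 1L) rep(box_z, length(times)) else box_z
  if (length(bz) != length(times)) {
    abort("`box_z` must have length 1 or one value per frame")
  }
  bz_of <- stats::setNames(bz, times)
  out <- particles |>
    dplyr::left_join(com, by = "time_ns") |>
    dplyr::mutate(
      box_z = unname(bz_of[as.character(.data$time_ns)]),
      z_nm = .data$z_nm - .data$com,
      z_nm = .data$z_nm - .data$box_z * round(.data$z_nm / .data$box_z)
    ) |>
    dplyr::select("time_ns", "particle_id", "z_nm")
  z_trajectory(out, box_z = bz, box_xy = box_xy, species_label = species_label)
}

#' Read a tabular z-coordinate trajectory
#'
#' Reads the engine-agnostic plain-text trajectory format: a CSV or TSV file
#' with header `time_ns,particle_id,z_nm` (separator sniffed from the header
#' line).
#'
#' @param path File path.
#' @return A tibble with columns `time_ns`, `particle_id`, `z_nm`.
#' @export
read_z_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  .check_columns(df, c("time_ns", "particle_id", "z_nm"), path)
  tibble::as_tibble(df)
}

#' Read particle z series from a trajectory file
#'
#' Dispatches on format: tabular CSV/TSV z series (see [read_z_table()]) or a
#' multi-model PDB frame stream (read through the bio3d package, coordinates
#' converted from Angstrom to nm). GRO/XTC streams are not supported; convert
#' them to one of the supported dialects upstream.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"table"`, or `"pdb"`.
#' @param select For PDB input, an optional atom-name filter (character vector
#'   matched against the `elety` field).
#' @param frame_dt_ns For PDB input, the time spacing between models in ns
#'   (models carry no timestamps); defaults to 1.
#'
#' @return A tibble with columns `time_ns`, `particle_id`, `z_nm` (and
#'   `x_nm`, `y_nm` for PDB input).
#' @export
read_trajectory <- function(path, format = c("auto", "table", "pdb"),
                            select = NULL, frame_dt_ns = 1) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "table"
  }
  if (format == "table") {
    return(read_z_table(path))
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    abort("reading PDB streams requires the bio3d package")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  keep <- seq_len(nrow(pdb$atom))
  if (!is.null(select)) {
    keep <- which(trimws(pdb$atom$elety) %in% select)
    if (length(keep) == 0L) abort("selection resolves to zero atoms")
  }
  xyz <- pdb$xyz
  n_frames <- nrow(xyz)
  purrr::map_dfr(seq_len(n_frames), function(fr) {
    m <- matrix(xyz[fr, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    tibble::tibble(
      time_ns = (fr - 1) * frame_dt_ns,
      particle_id = keep,
      x_nm = m[, 1] / 10, y_nm = m[, 2] / 10, z_nm = m[, 3] / 10
    )
  })
}
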
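#' Write / read a density profile as CSV
#'
#' Plain CSV with columns `z_nm,rho_per_nm`; bin edges and frame counts are
#' stored in `#`-prefixed header comments and recovered on read.
#'
#' @param profile A [density_profile()].
#' @param path File path.
#' @return `write_profile_csv` returns `path` invisibly; `read_profile_csv`
#'   a `density_profile` tibble.
#' @export
write_profile_csv <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# symmetrized: %s", isTRUE(attr(profile, "symmetrized"))),
    sprintf("# n_frames_used: %d", attr(profile, "n_frames_used")),
    sprintf("# equilibration_discarded_ns: %g",
            attr(profile, "equilibration_discarded")),
    sprintf("# bin_edges: %s",
            paste(format(attr(profile, "bin_edges"), digits = 12),
                  collapse = " "))
  ), con)
  utils::write.csv(as.data.frame(profile[c("z_nm", "rho_per_nm")]), con,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  .check_columns(df, c("z_nm", "rho_per_nm"), path)
  out <- tibble::as_tibble(df)
  class(out) <- c("density_profile", class(out))
  grab <- function(key) {
    hit <- meta[grepl(paste0("^# ", key, ":"), meta)]
    if (length(hit) == 0L) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  edges <- grab("bin_edges")
  if (!is.null(edges)) {
    attr(out, "bin_edges") <- as.numeric(strsplit(edges, "\\s+")[[1]])
  }
  nf <- grab("n_frames_used")
  if (!is.null(nf)) attr(out, "n_frames_used") <- as.integer(nf)
  sym <- grab("symmetrized")
  if (!is.null(sym)) attr(out, "symmetrized") <- identical(sym, "TRUE")
  disc <- grab("equilibration_discarded_ns")
  if (!is.null(disc)) attr(out, "equilibration_discarded") <- as.numeric(disc)
  attr(out, "z_max") <- max(attr(out, "bin_edges") %||% out$z_nm)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a two-channel photon-count trace
#'
#' CSV with columns `counts_blue,counts_red` and `#`-prefixed
#' `key: value` metadata lines (at minimum `bin_width_s`).
#'
#' @param trace An [intensity_trace()].
#' @param path File path.
#' @return `write_counts_trace` returns `path` invisibly;
#'   `read_counts_trace` an `intensity_trace`.
#' @export
write_counts_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# bin_width_s: %.12g", trace$bin_width),
    sprintf("# c_p_total_M: %.12g", trace$c_p_total)
  ), con)
  utils::write.csv(
    data.frame(counts_blue = trace$counts_blue,
               counts_red = trace$counts_red),
    con, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_counts_trace
#' @export
read_counts_trace <- function(path) {
  lines <- readLines(path)
  meta <- lines[grepl("^#", lines)]
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"))
  .check_columns(df, c("counts_blue", "counts_red"), path)
  grab <- function(key, default = NA_real_) {
    hit <- meta[grepl(paste0("^# ", key, ":"), meta)]
    if (length(hit) == 0L) return(default)
    v <- trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
    if (v %in% c("NA", "NaN", "")) return(default)
    as.numeric(v)
  }
  bw <- grab("bin_width_s")
  if (!is.finite(bw)) abort("trace file lacks a '# bin_width_s:' header")
  intensity_trace(df$counts_blue, df$counts_red, bw,
                  c_p_total = grab("c_p_total_M"))
}

#' Condition-grid matrix export
#'
#' Pivots a tidy result table keyed by peptide and salt concentration into a
#' matrix layout (peptide concentration rows, salt concentration columns),
#' the layout of the free-energy heat maps over the simulation condition
#' grid. Missing conditions become `NA` cells; duplicated conditions are an
#' error.
#'
#' @param results Tidy data frame with columns `peptide_conc_m`,
#'   `salt_conc_m` and the observable named in `value`.
#' @param value Name of the observable column (default `"delta_g_kj_mol"`).
#' @return A tibble with `peptide_conc_m` as first column and one column per
#'   salt concentration.
#' @export
heatmap_table <- function(results, value = "delta_g_kj_mol") {
  .check_columns(results, c("peptide_conc_m", "salt_conc_m", value),
                 "results")
  dup <- results |>
    dplyr::count(.data$peptide_conc_m, .data$salt_conc_m) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) abort("duplicate condition records in results")
  results |>
    dplyr::select("peptide_conc_m", "salt_conc_m",
                  dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "salt_conc_m",
                       values_from = dplyr::all_of(value),
                       names_sort = TRUE) |>
    dplyr::arrange(.data$peptide_conc_m)
}

#' Write a resolved run configuration for reproducibility
#'
#' Serializes the fully resolved parameter set of an analysis run, together
#' with the package version, a content hash and a timestamp, as JSON next to
#' the run outputs.
#'
#' @param params Named list of resolved parameters (seeds included).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(params, path) {
  if (is.null(names(params)) || any(names(params) == "")) {
    abort("`params` must be a fully named list")
  }
  payload <- list(
    package = "pepmem",
    version = as.character(utils::packageVersion("pepmem")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_hash = rlang::hash(params),
    params = params
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
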
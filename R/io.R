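# Plain-text interchange: two-column CSVs with JSON sidecars carrying
# parameters, seeds and ground-truth event logs.

.sidecar_path <- function(path) sub("\\.csv$", ".json", path, ignore.case = TRUE)

#' Write a trace to CSV with a JSON sidecar
#'
#' The CSV holds `time_s`, `position_bp`; the sidecar (same path with a
#' `.json` extension) holds the variant, seed, sampling metadata and the
#' ground-truth event log, so a written trace round-trips losslessly
#' through [read_trace_csv()].
#'
#' @param trace A `scanner_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "scanner_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              position_bp = trace$position_bp),
                   path, row.names = FALSE)
  meta <- list(variant = trace$variant, seed = trace$seed,
               sample_rate_hz = trace$sample_rate_hz,
               noise_sd_bp = trace$noise_sd_bp,
               filtered = isTRUE(trace$filtered),
               events = trace$events)
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace_csv()]
#'
#' @param path CSV path; the JSON sidecar is read when present.
#' @return A `scanner_trace`.
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("time_s", "position_bp") %in% names(d)))
  tr <- list(time_s = d$time_s, position_bp = d$position_bp,
             sample_rate_hz = 1 / median(diff(d$time_s)),
             variant = NA_character_, seed = NULL, events = NULL)
  sc <- .sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    tr$variant <- meta$variant
    tr$seed <- meta$seed
    if (!is.null(meta$sample_rate_hz)) tr$sample_rate_hz <- meta$sample_rate_hz
    tr$noise_sd_bp <- meta$noise_sd_bp
    tr$filtered <- isTRUE(meta$filtered)
    tr$events <- meta$events
    # an empty pause table serializes as [] and deserializes as a bare list
    if (!is.data.frame(tr$events$pauses))
      tr$events$pauses <- data.frame(start_s = numeric(0),
                                     duration_s = numeric(0),
                                     position_bp = numeric(0),
                                     committed = logical(0))
  }
  structure(tr, class = "scanner_trace")
}

#' Write a chase series or triplex curve as two-column CSV
#'
#' @param series A `chase_series` or `triplex_curve`.
#' @param path Output CSV path; a JSON sidecar records metadata.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "chase_series")) {
    utils::write.csv(data.frame(time_min = series$time_min,
                                fragment_fraction = series$fragment_fraction),
                     path, row.names = FALSE)
    meta <- list(kind = "chase", variant = series$variant,
                 seed = series$seed, n_molecules = series$n_molecules)
  } else if (inherits(series, "triplex_curve")) {
    utils::write.csv(data.frame(time_s = series$time_s,
                                signal = series$signal),
                     path, row.names = FALSE)
    meta <- list(kind = "triplex", variant = series$variant,
                 seed = series$seed, n_molecules = series$n_molecules,
                 n_chi = series$n_chi,
                 triplex_distance_bp = series$triplex_distance_bp)
  } else stop("expected a 'chase_series' or 'triplex_curve'")
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a two-column series CSV
#'
#' The sidecar (when present) restores the series class; otherwise a plain
#' two-column data frame is returned, which every fitting function accepts.
#'
#' @param path CSV path.
#' @return A `chase_series`, `triplex_curve`, or data frame.
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  sc <- .sidecar_path(path)
  if (!file.exists(sc)) return(d)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (identical(meta$kind, "chase")) {
    structure(list(time_min = d[[1]], fragment_fraction = d[[2]],
                   n_molecules = meta$n_molecules, variant = meta$variant,
                   seed = meta$seed),
              class = "chase_series")
  } else if (identical(meta$kind, "triplex")) {
    structure(list(time_s = d[[1]], signal = d[[2]],
                   n_chi = meta$n_chi,
                   triplex_distance_bp = meta$triplex_distance_bp,
                   n_molecules = meta$n_molecules, variant = meta$variant,
                   seed = meta$seed),
              class = "triplex_curve")
  } else d
}
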
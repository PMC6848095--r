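#' Read and write vertebral landmark CSV files
#'
#' The landmark dialect is a plain CSV with header `level,x,y,z`, levels
#' ordered cranial (T1) to caudal (L5), coordinates unit-height normalized.
#' The round trip is lossless to full double precision (values are written
#' with 17 significant digits).
#'
#' @param path File path.
#' @return `read_landmarks()`: a tibble with columns `level`, `x`, `y`, `z`.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("level", "x", "y", "z") %in% names(df))) {
    stop_spinerod("landmark file must have columns level, x, y, z",
                  "spinerod_input_error")
  }
  tibble::as_tibble(df)
}

#' @rdname read_landmarks
#' @param curve Centerline tibble with columns `level`, `x`, `y`, `z`.
#' @export
write_landmarks <- function(curve, path) {
  check_curve_frame(curve)
  df <- data.frame(
    level = if ("level" %in% names(curve)) curve$level else vertebral_levels(nrow(curve)),
    x = sprintf("%.17g", curve$x),
    y = sprintf("%.17g", curve$y),
    z = sprintf("%.17g", curve$z)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write run configurations as JSON
#'
#' Serializes a [default_config()]-style configuration; a run is
#' reproducible from the JSON alone.
#'
#' @param config A `rod_config` list.
#' @param path File path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @return `read_run_config()`: a `rod_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  cfg$fe <- utils::modifyList(base$fe, as.list(cfg$fe))
  cfg$metrics <- utils::modifyList(base$metrics, as.list(cfg$metrics))
  cfg$fe$n_sub <- as.integer(cfg$fe$n_sub)
  cfg$fe$n_steps <- as.integer(cfg$fe$n_steps)
  cfg$fe$max_iter <- as.integer(cfg$fe$max_iter)
  structure(utils::modifyList(unclass(base), cfg), class = "rod_config")
}

#' Export shape metrics to CSV
#'
#' One row per model run: identifier, group, global torsion, axial class,
#' twist count, displacement ratio and inflection structure.
#'
#' @param metrics Metrics tibble (from [shape_metrics()] or
#'   [run_experiment()]).
#' @param path File path.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.csv(as.data.frame(metrics), path, row.names = FALSE)
  invisible(path)
}

#' Export a centerline as a legacy VTK polyline
#'
#' Writes an ASCII VTK (legacy format) POLYDATA file with the curve as a
#' single polyline, for visualization in ParaView or similar tools.
#'
#' @param curve Centerline tibble with columns `x`, `y`, `z`.
#' @param path Output file path (conventionally `.vtk`).
#' @export
write_polyline_vtk <- function(curve, path) {
  check_curve_frame(curve)
  n <- nrow(curve)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    "spinerod centerline",
    "ASCII",
    "DATASET POLYDATA",
    sprintf("POINTS %d double", n)
  ), con)
  writeLines(sprintf("%.17g %.17g %.17g", curve$x, curve$y, curve$z), con)
  writeLines(sprintf("LINES 1 %d", n + 1L), con)
  writeLines(paste(c(n, seq_len(n) - 1L), collapse = " "), con)
  invisible(path)
}
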
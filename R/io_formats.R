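# External representations: compression CSV (+ YAML geometry sidecar),
# filament SWC, puncta CSV, wide trace CSV, results JSON, run-config YAML.
# One strict dialect (comma, dot decimal, UTF-8, mandatory header) with a
# `delimiter` escape hatch; units are normalized once at the boundary
# (mm, N, mm^2 in; Pa for stress internally).

#' Compression recording
#'
#' Container for a raw cyclic unconfined-compression recording: time (s),
#' axial displacement (mm, compression negative), axial force (N, compression
#' negative), plus the undeformed sample geometry (initial height in mm,
#' initial cross-sectional area in mm^2) and free-form metadata (condition
#' label, day, sample id, ...). Compressive displacement and force are kept
#' negative internally so that the stretch `1 + dz/h` is below 1 under
#' compression; reporting layers print magnitudes.
#'
#' @param time Seconds, strictly increasing, length >= 3.
#' @param displacement Millimetres, same length as `time`.
#' @param force Newtons, same length as `time`.
#' @param height_mm Initial sample height in mm, > 0.
#' @param area_mm2 Initial cross-sectional area in mm^2, > 0.
#' @param metadata Named list of free-form metadata.
#' @return A tibble of class `compression_recording` with columns `time`,
#'   `displacement`, `force` and attributes `height_mm`, `area_mm2`,
#'   `metadata`.
#' @export
compression_recording <- function(time, displacement, force,
                                  height_mm, area_mm2, metadata = list()) {
  n <- length(time)
  if (n < 3L) nq_abort("recording needs at least 3 samples", field = "time")
  if (length(displacement) != n) {
    nq_abort("`displacement` length differs from `time`", field = "displacement")
  }
  if (length(force) != n) nq_abort("`force` length differs from `time`", field = "force")
  bad <- which(!is.finite(time) | !is.finite(displacement) | !is.finite(force))
  if (length(bad)) nq_abort("non-finite values in recording", field = "time/displacement/force",
                            row = head(bad, 5))
  nonmono <- which(diff(time) <= 0)
  if (length(nonmono)) {
    nq_abort("`time` must be strictly increasing", field = "time", row = nonmono[1] + 1L)
  }
  check_number(height_mm, "height_mm", positive = TRUE)
  check_number(area_mm2, "area_mm2", positive = TRUE)
  out <- tibble(time = as.numeric(time),
                displacement = as.numeric(displacement),
                force = as.numeric(force))
  structure(out,
            height_mm = height_mm, area_mm2 = area_mm2, metadata = metadata,
            class = c("compression_recording", class(out)))
}

#' @export
print.compression_recording <- function(x, ...) {
  cat(sprintf("<compression_recording> %d samples, h = %g mm, A = %g mm^2\n",
              nrow(x), attr(x, "height_mm"), attr(x, "area_mm2")))
  NextMethod()
}

#' Area of a circular punch cross-section
#'
#' Helper to derive the initial cross-sectional area from a cylindrical punch
#' diameter, e.g. 9 mm biopsy punches give `pi * 4.5^2 = 63.617` mm^2.
#'
#' @param diameter_mm Punch diameter in mm (> 0).
#' @return Area in mm^2.
#' @export
punch_area_mm2 <- function(diameter_mm) {
  check_number(diameter_mm, "diameter_mm", positive = TRUE)
  pi * (diameter_mm / 2)^2
}

default_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".yaml")
}

#' Read a compression recording from CSV
#'
#' The CSV must carry a header row with columns `time`, `displacement`,
#' `force`. The sample geometry comes either from the `geometry` argument or
#' from a YAML sidecar (`<stem>.yaml`) with keys `height_mm` and `area_mm2`
#' (additional sidecar keys become metadata).
#'
#' @param path CSV file path.
#' @param geometry Optional list with `height_mm`, `area_mm2` overriding the
#'   sidecar.
#' @param sidecar Optional explicit sidecar path.
#' @param delimiter Field delimiter, default comma.
#' @return A [compression_recording()].
#' @export
read_compression_csv <- function(path, geometry = NULL, sidecar = NULL,
                                 delimiter = ",") {
  if (!file.exists(path)) nq_abort(sprintf("file not found: %s", path), field = "path")
  df <- readr::read_delim(path, delim = delimiter, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  need <- c("time", "displacement", "force")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    nq_abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
             field = paste(missing_cols, collapse = ","))
  }
  meta <- list()
  if (is.null(geometry)) {
    sc <- sidecar %||% default_sidecar_path(path)
    if (!file.exists(sc)) {
      nq_abort(sprintf("no geometry given and sidecar not found: %s", sc),
               field = "geometry")
    }
    y <- yaml::read_yaml(sc)
    geometry <- list(height_mm = y$height_mm, area_mm2 = y$area_mm2)
    meta <- y[setdiff(names(y), c("height_mm", "area_mm2"))]
  }
  if (is.null(geometry$height_mm) || is.null(geometry$area_mm2)) {
    nq_abort("geometry must provide height_mm and area_mm2", field = "geometry")
  }
  compression_recording(df$time, df$displacement, df$force,
                        height_mm = geometry$height_mm,
                        area_mm2 = geometry$area_mm2,
                        metadata = meta)
}

#' Write a compression recording to CSV plus YAML sidecar
#'
#' @param recording A [compression_recording()].
#' @param path Output CSV path; the sidecar goes to `<stem>.yaml`.
#' @param delimiter Field delimiter, default comma.
#' @return `path`, invisibly.
#' @export
write_compression_csv <- function(recording, path, delimiter = ",") {
  stopifnot(inherits(recording, "compression_recording"))
  readr::write_delim(as_tibble(recording), path, delim = delimiter)
  side <- c(list(height_mm = attr(recording, "height_mm"),
                 area_mm2 = attr(recording, "area_mm2")),
            attr(recording, "metadata"))
  yaml::write_yaml(side, default_sidecar_path(path))
  invisible(path)
}

#' Read a neuron skeleton in SWC format
#'
#' Standard SWC dialect: whitespace-delimited columns `id type x y z radius
#' parent`, `#` comments, micrometre coordinates, `parent = -1` for roots.
#' Dangling parent references and negative radii are rejected.
#'
#' @param path SWC file path.
#' @return A [filament_model()].
#' @export
read_filament_swc <- function(path) {
  if (!file.exists(path)) nq_abort(sprintf("file not found: %s", path), field = "path")
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("id", "type", "x", "y", "z", "radius", "parent"))
  filament_model(as_tibble(df))
}

#' Write a filament model to SWC
#'
#' Coordinates and radii are written with enough digits to round-trip to at
#' least 6 decimals.
#'
#' @param filament A [filament_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filament_swc <- function(filament, path) {
  stopifnot(inherits(filament, "filament_model"))
  nodes <- as_tibble(filament)
  lines <- sprintf("%d %d %.9f %.9f %.9f %.9f %d",
                   nodes$id, nodes$type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, nodes$parent)
  writeLines(c("# SWC export", lines), path)
  invisible(path)
}

#' Read 3D puncta coordinates from CSV
#'
#' Columns `x`, `y`, `z` in micrometres, optional `intensity` (arbitrary
#' units). Non-finite coordinates are rejected.
#'
#' @param path CSV path.
#' @param delimiter Field delimiter, default comma.
#' @return A [puncta_set()].
#' @export
read_puncta_csv <- function(path, delimiter = ",") {
  if (!file.exists(path)) nq_abort(sprintf("file not found: %s", path), field = "path")
  df <- readr::read_delim(path, delim = delimiter, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  need <- c("x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    nq_abort(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")),
             field = paste(missing_cols, collapse = ","))
  }
  puncta_set(df)
}

#' Fluorescence trace set
#'
#' ROI-by-frame fluorescence matrix with a sampling rate. Duration is
#' `n_frames / rate`.
#'
#' @param mat Numeric matrix, ROIs in rows, frames in columns; or a data frame
#'   with one column per ROI (frames in rows), which is transposed.
#' @param rate Sampling rate in Hz, > 0 (default 10).
#' @param roi_ids Optional ROI identifiers (default from row names or `roi_1`
#'   ...).
#' @return An object of class `trace_set`: list with `mat`, `rate`,
#'   `duration`, `roi_ids`.
#' @export
trace_set <- function(mat, rate = 10, roi_ids = NULL) {
  if (is.data.frame(mat)) mat <- t(as.matrix(mat))
  if (!is.matrix(mat) || !is.numeric(mat)) nq_abort("`mat` must be a numeric matrix", field = "mat")
  check_number(rate, "rate", positive = TRUE)
  roi_ids <- roi_ids %||% rownames(mat) %||% paste0("roi_", seq_len(nrow(mat)))
  bad <- which(apply(mat, 1, function(r) any(!is.finite(r))))
  if (length(bad)) {
    nq_abort(sprintf("non-finite values in ROI trace(s): %s",
                     paste(roi_ids[bad], collapse = ", ")),
             field = "mat")
  }
  rownames(mat) <- roi_ids
  structure(list(mat = mat, rate = rate, duration = ncol(mat) / rate,
                 roi_ids = roi_ids),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d ROI x %d frames at %g Hz (%.1f s)\n",
              nrow(x$mat), ncol(x$mat), x$rate, x$duration))
  invisible(x)
}

#' Read ROI fluorescence traces from a wide CSV
#'
#' Expected layout: a `time` column plus one column per ROI, frames in rows.
#' The sampling rate can be stored in a header comment line
#' `# rate_hz: <value>`; otherwise `rate` (default 10 Hz) applies. Any
#' non-finite value fails validation with the offending ROI named.
#'
#' @param path CSV path.
#' @param rate Sampling rate in Hz used when no header comment is present.
#' @param delimiter Field delimiter, default comma.
#' @return A [trace_set()].
#' @export
read_trace_csv <- function(path, rate = 10, delimiter = ",") {
  if (!file.exists(path)) nq_abort(sprintf("file not found: %s", path), field = "path")
  first <- readLines(path, n = 5)
  m <- regmatches(first, regexec("^#\\s*rate_hz:\\s*([0-9.eE+-]+)", first))
  hit <- which(lengths(m) == 2)
  if (length(hit)) rate <- as.numeric(m[[hit[1]]][2])
  df <- readr::read_delim(path, delim = delimiter, comment = "#",
                          show_col_types = FALSE, progress = FALSE)
  roi_cols <- setdiff(names(df), "time")
  if (!length(roi_cols)) nq_abort("no ROI columns found", field = "columns")
  trace_set(df[roi_cols], rate = rate, roi_ids = roi_cols)
}

#' Write a trace set to wide CSV
#'
#' @param traces A [trace_set()].
#' @param path Output path; the sampling rate is recorded as a `# rate_hz:`
#'   header comment.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  df <- as_tibble(t(traces$mat), .name_repair = "minimal")
  names(df) <- traces$roi_ids
  df <- dplyr::bind_cols(tibble(time = (seq_len(ncol(traces$mat)) - 1) / traces$rate), df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# rate_hz: %.10g", traces$rate), con)
  cat(readr::format_csv(df), file = con)
  invisible(path)
}

#' Run configuration
#'
#' Central bundle of tunable parameters with the protocol defaults: 15%
#' maximum strain over three loading cycles, a 100-point averaging grid,
#' multi-start bounded least squares for the Ogden calibration, and the
#' calcium event-detection settings (signal-to-noise ratio 2.2, noise window
#' 1000 frames, minimum activity count 2).
#'
#' @param grid_size Averaging grid size (>= 10).
#' @param max_strain Maximum nominal strain, in (0, 1).
#' @param cycles Expected number of loading cycles.
#' @param alpha_starts Multi-start initial values for the Ogden nonlinearity
#'   parameter.
#' @param mu_bounds,alpha_bounds Box bounds for the calibration;
#'   `alpha_bounds` gives `(|alpha|_min, |alpha|_max)` applied on both sign
#'   branches.
#' @param fit_tol Optimizer convergence tolerance (> 0).
#' @param snr Event detection threshold in units of the local noise scale.
#' @param noise_window Rolling noise-estimation window, frames.
#' @param min_counts Minimum event count for a ROI to be scored active.
#' @param min_duration_s Minimum event duration in seconds.
#' @param merge_gap_s Events closer than this gap are merged, seconds.
#' @param baseline_quantile Quantile of the raw trace used as F0.
#' @param seed Integer seed driving all randomness downstream.
#' @return A list of class `run_config`.
#' @export
run_config <- function(grid_size = 100, max_strain = 0.15, cycles = 3,
                       alpha_starts = c(-20, -5, 2, 10),
                       mu_bounds = c(1e-3, 1e7), alpha_bounds = c(0.01, 50),
                       fit_tol = 1e-12,
                       snr = 2.2, noise_window = 1000, min_counts = 2,
                       min_duration_s = 0.3, merge_gap_s = 0.5,
                       baseline_quantile = 0.1, seed = 1L) {
  if (max_strain <= 0 || max_strain >= 1) nq_abort("max_strain must be in (0,1)", field = "max_strain")
  if (grid_size < 10) nq_abort("grid_size must be >= 10", field = "grid_size")
  check_number(fit_tol, "fit_tol", positive = TRUE)
  check_number(snr, "snr", positive = TRUE)
  check_number(noise_window, "noise_window", positive = TRUE)
  cfg <- list(grid_size = as.integer(grid_size), max_strain = max_strain,
              cycles = as.integer(cycles), alpha_starts = alpha_starts,
              mu_bounds = mu_bounds, alpha_bounds = alpha_bounds,
              fit_tol = fit_tol, snr = snr,
              noise_window = as.integer(noise_window),
              min_counts = as.integer(min_counts),
              min_duration_s = min_duration_s, merge_gap_s = merge_gap_s,
              baseline_quantile = baseline_quantile, seed = as.integer(seed))
  structure(cfg, class = "run_config")
}

#' Read / write run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read / write results as JSON
#'
#' Thin wrappers around jsonlite with full numeric precision.
#'
#' @param x A list or data frame of results.
#' @param path JSON file path.
#' @return [read_results_json()] returns the parsed list.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_results_json
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
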
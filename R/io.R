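#' Read and write experiment logs
#'
#' Logs are plain ASCII CSV with header `time_s,pH,cumulative_volume_ml`,
#' one record per logging period, suitable for any downstream statistics
#' package. pH and volume are serialized with three fixed decimals (the
#' display / dosing resolution); reading a written log reproduces it
#' exactly. An empty file reads back as an empty log.
#'
#' @param records data frame with columns `time_s`, `pH`,
#'   `cumulative_volume_ml`.
#' @param path file path.
#' @return `write_log` returns `path` invisibly; `read_log` the data frame.
#' @export
write_log <- function(records, path) {
  .write_numeric_csv(records, path,
                     c("time_s", "pH", "cumulative_volume_ml"),
                     c("%.10g", "%.3f", "%.3f"))
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  .read_numeric_csv(path, c("time_s", "pH", "cumulative_volume_ml"),
                    na_ok = "pH")
}

#' Read and write titration curves
#'
#' CSV with header `cumulative_volume_ml,pH`, three fixed decimals.
#'
#' @param curve data frame with columns `cumulative_volume_ml`, `pH`.
#' @param path file path.
#' @export
write_curve <- function(curve, path) {
  .write_numeric_csv(curve, path, c("cumulative_volume_ml", "pH"),
                     c("%.3f", "%.3f"))
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  out <- .read_numeric_csv(path, c("cumulative_volume_ml", "pH"))
  class(out) <- c("titration_curve", "data.frame")
  out
}

#' Read and write pump calibration tables
#'
#' CSV with header `run_time,measured_volume` — one row per repeated dose of
#' the bench calibration procedure, ready for [fit_calibration()].
#'
#' @param measurements data frame with columns `run_time`,
#'   `measured_volume`.
#' @param path file path.
#' @export
write_calibration_csv <- function(measurements, path) {
  .write_numeric_csv(measurements, path, c("run_time", "measured_volume"),
                     c("%.10g", "%.10g"))
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(path) {
  .read_numeric_csv(path, c("run_time", "measured_volume"))
}

.write_numeric_csv <- function(df, path, cols, fmts) {
  df <- as.data.frame(df)
  stopifnot(all(cols %in% names(df)))
  lines <- paste(cols, collapse = ",")
  if (nrow(df)) {
    body <- vapply(seq_along(cols), function(j) {
      x <- df[[cols[j]]]
      out <- sprintf(fmts[j], x)
      out[is.na(x)] <- "NA"
      out
    }, character(nrow(df)))
    body <- if (nrow(df) == 1L) paste(body, collapse = ",")
    else apply(body, 1L, paste, collapse = ",")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

.read_numeric_csv <- function(path, cols, na_ok = character(0)) {
  empty <- stats::setNames(
    as.data.frame(rep(list(numeric(0)), length(cols))), cols)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(empty)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), cols))
    stop(sprintf("parse error at line 1: expected header '%s'",
                 paste(cols, collapse = ",")), call. = FALSE)
  if (length(lines) == 1L) return(empty)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  out <- matrix(NA_real_, length(rows), length(cols),
                dimnames = list(NULL, cols))
  for (i in seq_along(rows)) {
    r <- trimws(rows[[i]])
    if (length(r) != length(cols))
      stop(sprintf("parse error at line %d: expected %d fields, got %d",
                   i + 1L, length(cols), length(r)), call. = FALSE)
    vals <- suppressWarnings(as.numeric(r))
    bad <- is.na(vals) & !(r == "NA" & cols %in% na_ok)
    if (any(bad))
      stop(sprintf("parse error at line %d: non-numeric '%s' in column %s",
                   i + 1L, r[which(bad)[1]], cols[which(bad)[1]]),
           call. = FALSE)
    out[i, ] <- vals
  }
  as.data.frame(out)
}

#' Experiment configuration files
#'
#' A whole experiment — OCR calibration, pump choice, control settings,
#' plant scenario, seed — is described by one structured YAML file, so a run
#' is reproducible from its config and seed alone. Omitted keys fall back
#' to the defaults of the corresponding constructors (setpoint 10.55,
#' initial 2 ml / 5 s, and so on); exactly one pump is active per run.
#'
#' @param path file path.
#' @return `read_experiment_config`: a validated list of class
#'   `experiment_config` with components `seed`, `control`
#'   ([control_config()]), `pump` (pump spec), `ocr`
#'   (geometry/threshold/on_fraction), `plant` ([plant_state()]),
#'   `output` (paths).
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_experiment_config(raw)
}

#' @rdname read_experiment_config
#' @param raw a nested list with the same structure as the YAML file.
#' @export
build_experiment_config <- function(raw = list()) {
  stopifnot(is.list(raw))
  arg_call <- function(fun, args) do.call(fun, args %||% list())
  control <- arg_call(control_config, raw$control)

  pump_raw <- raw$pump %||% list(type = "peristaltic", coefficient = 8.167e-4)
  ptype <- pump_raw$type %||% "peristaltic"
  pump_raw$type <- NULL
  pump <- switch(ptype,
    peristaltic = arg_call(peristaltic_pump_spec, pump_raw),
    syringe = arg_call(syringe_pump_spec, pump_raw),
    stop("unknown pump type: ", ptype, call. = FALSE))

  ocr_raw <- raw$ocr %||% list()
  geometry <- arg_call(segment_geometry,
                       ocr_raw$geometry %||%
                         list(anchor_row = 2, anchor_col = 2,
                              digit_width = 6, digit_height = 9,
                              digit_pitch = 8))
  cal <- ocr_calibration(ocr_raw$threshold %||% 128, geometry,
                         ocr_raw$on_fraction %||% 0.5)

  plant <- arg_call(plant_state,
                    local({
                      p <- raw$plant %||% list()
                      if (!is.null(p$kinetics))
                        p$kinetics <- arg_call(tempo_kinetics, p$kinetics)
                      p
                    }))

  structure(list(seed = raw$seed %||% 1L,
                 control = control, pump = pump, cal = cal,
                 plant = plant,
                 output = raw$output %||% list(log = "phstat_log.csv")),
            class = "experiment_config")
}

#' @rdname read_experiment_config
#' @param config an `experiment_config`-shaped nested list to serialize.
#' @export
write_experiment_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
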
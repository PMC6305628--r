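#' @name persistence
#' @title Text-based persistence for traces, waveforms and maps
#'
#' @description All artefacts are persisted as plain text: sampled traces
#' as headerless CSV with full `%.17g` precision (so that write/read
#' round-trips are bit-exact), with a JSON sidecar carrying the metadata,
#' and gridded maps as a directory container with one matrix file per
#' dataset plus a JSON metadata record.
NULL

fmt_full <- function(x) sprintf("%.17g", x)

sidecar_path <- function(path) paste0(path, ".json")

#' Write a drive waveform to CSV with a JSON metadata sidecar
#'
#' Two headerless columns (`time_s`, `volts`); the sidecar (`<path>.json`)
#' records scheme, f0, modulation index, sample rate, rail voltages and
#' cycle count.
#'
#' @param waveform a `switched_waveform`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  stopifnot(inherits(waveform, "switched_waveform"))
  t <- waveform_time(waveform)
  v <- waveform_volts(waveform)
  writeLines(paste(fmt_full(t), fmt_full(v), sep = ","), path)
  # numeric fields are serialised as %.17g strings: R's reader is
  # correctly rounding, so the round trip is bit-exact
  meta <- list(scheme = waveform$scheme,
               centre_frequency = fmt_full(waveform$centre_frequency),
               modulation_index = fmt_full(waveform$modulation_index),
               duty_cycle = fmt_full(waveform$duty_cycle),
               sample_rate = fmt_full(waveform$sample_rate),
               rail_step = fmt_full(waveform$rail_step),
               rail_v2 = fmt_full(waveform$rail_v2),
               n_cycles = waveform$n_cycles,
               levels = fmt_full(waveform$levels))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a drive waveform written by [write_waveform_csv()]
#' @param path CSV path (the `<path>.json` sidecar must be present).
#' @return a `switched_waveform`.
#' @export
read_waveform_csv <- function(path) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  lv <- as.numeric(meta$levels)
  if (meta$scheme != "sine") lv <- as.integer(lv)
  structure(
    list(sample_rate = as.numeric(meta$sample_rate),
         centre_frequency = as.numeric(meta$centre_frequency),
         levels = lv,
         rail_step = as.numeric(meta$rail_step),
         rail_v2 = as.numeric(meta$rail_v2),
         scheme = meta$scheme,
         n_cycles = as.integer(meta$n_cycles),
         modulation_index = as.numeric(meta$modulation_index),
         duty_cycle = as.numeric(meta$duty_cycle),
         angle_solution = NULL),
    class = "switched_waveform")
}

#' Write a voltage/current trace as three-column CSV
#'
#' Headerless columns `time_s`, `volts`, `amperes` at full precision.
#'
#' @param trace a [vi_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vi_csv <- function(trace, path) {
  stopifnot(inherits(trace, "vi_trace"))
  t <- (seq_along(trace$voltage) - 1L) * trace$sample_interval
  writeLines(paste(fmt_full(t), fmt_full(trace$voltage),
                   fmt_full(trace$current), sep = ","), path)
  invisible(path)
}

#' Read a voltage/current trace written by [write_vi_csv()]
#' @param path CSV path.
#' @return a [vi_trace()].
#' @export
read_vi_csv <- function(path) {
  m <- utils::read.table(path, sep = ",", colClasses = "numeric")
  if (ncol(m) != 3L) stop("expected three columns: time_s, volts, amperes")
  dt <- m[[1]][2] - m[[1]][1]
  vi_trace(m[[2]], m[[3]], dt)
}

#' Write a PCD trace as two-column CSV
#' @param recording a [pcd_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pcd_csv <- function(recording, path) {
  stopifnot(inherits(recording, "pcd_recording"))
  t <- (seq_along(recording$trace) - 1L) / recording$sample_rate
  writeLines(paste(fmt_full(t), fmt_full(recording$trace), sep = ","), path)
  invisible(path)
}

#' Read a PCD trace written by [write_pcd_csv()]
#' @param path CSV path.
#' @param ... trigger parameters passed to [pcd_recording()].
#' @return a [pcd_recording()].
#' @export
read_pcd_csv <- function(path, ...) {
  m <- utils::read.table(path, sep = ",", colClasses = "numeric")
  if (ncol(m) != 2L) stop("expected two columns: time_s, volts")
  fs <- 1 / (m[[1]][2] - m[[1]][1])
  pcd_recording(m[[2]], fs, ...)
}

# ---- directory container for gridded maps --------------------------------

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, function(row) paste(fmt_full(row), collapse = ",")),
             con)
}

read_matrix_txt <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", colClasses = "numeric"))
}

#' Persist a field map as a directory container
#'
#' One CSV matrix per harmonic dataset (`h1.csv` .. `h6.csv`) plus a
#' `meta.json` with the grid and frequency metadata.
#'
#' @param field a [compute_field()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_field_map <- function(field, dir) {
  stopifnot(inherits(field, "field_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (h in 1:6) {
    write_matrix_txt(field$pressure[[h]], file.path(dir, sprintf("h%d.csv", h)))
  }
  jsonlite::write_json(
    list(r = field$r, z = field$z, dr = field$dr, dz = field$dz,
         frequencies = field$frequencies, scaled_down = field$scaled_down),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a field map written by [write_field_map()]
#' @param dir container directory.
#' @return a `field_map`.
#' @export
read_field_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pressure <- lapply(1:6, function(h) {
    unname(read_matrix_txt(file.path(dir, sprintf("h%d.csv", h))))
  })
  names(pressure) <- paste0("h", 1:6)
  structure(list(r = meta$r, z = meta$z, dr = meta$dr, dz = meta$dz,
                 pressure = pressure, frequencies = meta$frequencies,
                 scaled_down = meta$scaled_down),
            class = "field_map")
}

#' Persist a thermal-dose result as a directory container
#'
#' Datasets `cem43.csv`, `T_final.csv`, `T_peak.csv` and one snapshot per
#' stored time (`T_<index>.csv`), plus `meta.json`.
#'
#' @param solution a [pennes_solve()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dose_map <- function(solution, dir) {
  stopifnot(inherits(solution, "pennes_solution"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_txt(solution$cem43, file.path(dir, "cem43.csv"))
  write_matrix_txt(solution$T_final, file.path(dir, "T_final.csv"))
  write_matrix_txt(solution$T_peak, file.path(dir, "T_peak.csv"))
  for (i in seq_along(solution$snapshots)) {
    write_matrix_txt(solution$snapshots[[i]],
                     file.path(dir, sprintf("T_%04d.csv", i)))
  }
  jsonlite::write_json(
    list(times = solution$times, dt = solution$dt, dr = solution$dr,
         dz = solution$dz, t_on = solution$t_on, t_cool = solution$t_cool,
         T0 = solution$T0),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a thermal-dose container written by [write_dose_map()]
#' @param dir container directory.
#' @return a `pennes_solution`.
#' @export
read_dose_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  snaps <- list()
  i <- 1L
  repeat {
    p <- file.path(dir, sprintf("T_%04d.csv", i))
    if (!file.exists(p)) break
    snaps[[i]] <- unname(read_matrix_txt(p))
    i <- i + 1L
  }
  structure(list(times = meta$times, snapshots = snaps,
                 T_final = unname(read_matrix_txt(file.path(dir, "T_final.csv"))),
                 T_peak = unname(read_matrix_txt(file.path(dir, "T_peak.csv"))),
                 cem43 = unname(read_matrix_txt(file.path(dir, "cem43.csv"))),
                 dt = meta$dt, dr = meta$dr, dz = meta$dz,
                 t_on = meta$t_on, t_cool = meta$t_cool, T0 = meta$T0),
            class = "pennes_solution")
}
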
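#' Default run configuration
#'
#' Grouped parameters for the end-to-end lesion-comparison pipeline.  Every
#' default matches the study conditions where one is stated: 1.1 MHz
#' centre frequency, 64 mm aperture / 63 mm focus, 112 um native grid over
#' 64 x 78 mm, 26 W calibrated acoustic power, 20 s insonation + 10 s
#' cooling from 37 C, CEM43 >= 240 min lesion threshold, PCD trigger
#' 380 mV / 50 ms hold-off / 250 us segments / 256 segment budget, and the
#' 500 kHz - 10 MHz true-power band.  Where the source tissue table is not
#' available, literature chicken-muscle stand-ins are used (and marked
#' configurable).
#'
#' @return nested list of parameter groups (`transducer`, `media`,
#'   `thermal`, `pcd`, `power_band`, `solver`, `comparison`, `seed`).
#' @export
default_config <- function() {
  list(
    transducer = list(
      aperture_diameter = 64e-3,
      focal_length = 63e-3,
      centre_frequency = 1.1e6,
      fir_order = 50L,
      fir_design_rate = 20e6,
      kaiser_beta = 4.0),
    media = list(
      water = list(sound_speed = 1482, density = 1000,
                   absorption_coeff = 0, absorption_exponent = 1,
                   thickness = 43e-3),
      tissue = list(sound_speed = 1547, density = 1060,
                    absorption_coeff = 0.52, absorption_exponent = 1.1,
                    thickness = 45e-3)),
    thermal = list(
      specific_heat = 3600,
      conductivity = 0.49,
      perfusion_rate = 0,
      blood_temperature = 37,
      start_temperature = 37,
      t_on = 20,
      t_cool = 10,
      lesion_threshold_min = 240),
    pcd = list(
      trigger_threshold = 0.380,
      holdoff = 0.050,
      segment_length = 250e-6,
      max_segments = 256L,
      highpass_hz = 5e6),
    power_band = list(f_lo = 500e3, f_hi = 10e6),
    solver = list(
      grid_spacing = 0.5e-3,
      field_supersample = 2L,
      dt = 0.025,
      samples_per_cycle = 256L,
      drive_cycles = 8L),
    comparison = list(
      schemes = c("sine", "bilevel", "hrpwm"),
      modulation_index = 0.70,
      duty_cycle = 0.5,
      acoustic_power_w = 26,
      calibrate = "drive"),
    seed = 1L)
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base)) {
      stop("unknown configuration key: ", full)
    }
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]], full)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration
#'
#' Starts from [default_config()] and overlays the supplied values; unknown
#' keys are errors, guarding against silent mis-parameterisation.
#'
#' @param path optional YAML file with overriding key groups.
#' @param overrides optional nested list of overrides (applied after the
#'   file).
#' @return full configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    if (!is.null(y)) cfg <- merge_config(cfg, y)
  }
  if (!is.null(overrides)) cfg <- merge_config(cfg, overrides)
  cfg
}

config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  # small stable polynomial hash; enough to identify the parameter set
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 31 + b) %% 2^31
  sprintf("%08x", h)
}

config_media <- function(cfg) {
  medium_stack(list(
    c(list(name = "water"), cfg$media$water),
    c(list(name = "tissue"), cfg$media$tissue)))
}

config_transducer <- function(cfg) {
  transducer_model(aperture_diameter = cfg$transducer$aperture_diameter,
                   focal_length = cfg$transducer$focal_length,
                   centre_frequency = cfg$transducer$centre_frequency,
                   fir_order = cfg$transducer$fir_order,
                   fir_design_rate = cfg$transducer$fir_design_rate,
                   kaiser_beta = cfg$transducer$kaiser_beta)
}

config_thermal <- function(cfg) {
  thermal_properties(density = cfg$media$tissue$density,
                     sound_speed = cfg$media$tissue$sound_speed,
                     specific_heat = cfg$thermal$specific_heat,
                     conductivity = cfg$thermal$conductivity,
                     perfusion_rate = cfg$thermal$perfusion_rate,
                     blood_temperature = cfg$thermal$blood_temperature)
}
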
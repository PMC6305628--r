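#' Focused-bowl transducer model
#'
#' Geometry and electromechanical band-shape of a single-element concave
#' HIFU transducer.  The band-shape is a low-pass FIR transfer function of
#' order 50 whose passband covers the first three harmonics of the centre
#' frequency and whose stopband rejects harmonic four and above by at least
#' 40 dB; it is realised as a Kaiser-windowed design with cutoff midway
#' between 3 f0 and 4 f0, and only its magnitude response is used.
#'
#' @param aperture_diameter bowl aperture (rim) diameter in metres.
#' @param focal_length radius of curvature / natural focus in metres.
#' @param centre_frequency f0 in Hz.
#' @param fir_order FIR order (number of taps minus one).
#' @param fir_design_rate sample rate at which the FIR is realised, Hz.
#' @param kaiser_beta Kaiser window shape parameter.
#' @param k_cal electromechanical calibration constant, Pa of surface
#'   pressure per volt of drive at the passband reference (f0).
#' @return an object of class `transducer_model`.
#' @export
transducer_model <- function(aperture_diameter = 64e-3,
                             focal_length = 63e-3,
                             centre_frequency = 1.1e6,
                             fir_order = 50L,
                             fir_design_rate = 20e6,
                             kaiser_beta = 4.0,
                             k_cal = 1) {
  if (aperture_diameter <= 0 || focal_length <= 0 || centre_frequency <= 0) {
    stop("geometry and frequency must be positive")
  }
  if (aperture_diameter / 2 >= focal_length) {
    stop("aperture radius must be smaller than the focal length")
  }
  f0 <- centre_frequency
  cutoff <- 3.5 * f0
  taps <- signal::fir1(fir_order, cutoff / (fir_design_rate / 2),
                       type = "low",
                       window = signal::kaiser(fir_order + 1L, kaiser_beta))
  obj <- structure(
    list(aperture_diameter = aperture_diameter,
         focal_length = focal_length,
         centre_frequency = f0,
         fir_taps = as.numeric(taps),
         fir_design_rate = fir_design_rate,
         k_cal = k_cal),
    class = "transducer_model")
  # contract check: passband f0..3f0, >= 40 dB rejection at 4f0 and above
  g_pass <- transfer_gain(obj, c(1, 2, 3) * f0)
  g_stop <- transfer_gain(obj, seq(4, 6, by = 0.25) * f0)
  if (max(g_stop) > max(g_pass) * 10^(-40 / 20)) {
    stop("FIR realisation violates the band contract: stopband rejection ",
         sprintf("%.1f dB at worst", -20 * log10(max(g_stop) / max(g_pass))))
  }
  obj
}

#' Transfer-function magnitude of a transducer at given frequencies
#'
#' Evaluates the FIR magnitude response (discrete-time Fourier transform of
#' the taps at the design rate), normalised to unit gain at the centre
#' frequency.
#'
#' @param transducer a [transducer_model()].
#' @param freqs frequencies in Hz.
#' @return numeric vector of magnitude gains (1 at f0 by construction).
#' @export
transfer_gain <- function(transducer, freqs) {
  stopifnot(inherits(transducer, "transducer_model"))
  taps <- transducer$fir_taps
  fs <- transducer$fir_design_rate
  k <- seq_along(taps) - 1L
  H <- vapply(freqs, function(f) {
    Mod(sum(taps * exp(-2i * pi * f * k / fs)))
  }, numeric(1))
  H0 <- Mod(sum(taps * exp(-2i * pi * transducer$centre_frequency * k / fs)))
  H / H0
}

#' @export
print.transducer_model <- function(x, ...) {
  g <- transfer_gain(x, c(1, 2, 3, 4, 5, 6) * x$centre_frequency)
  cat("<transducer_model>\n")
  cat(sprintf("  aperture %.1f mm, focus %.1f mm, f0 %.4g MHz\n",
              x$aperture_diameter * 1e3, x$focal_length * 1e3,
              x$centre_frequency * 1e-6))
  cat("  |H| at h=1..6:", paste(sprintf("%.3g", g), collapse = ", "), "\n")
  invisible(x)
}

# spherical-cap (active) area of the bowl
bowl_cap_area <- function(transducer) {
  Fv <- transducer$focal_length
  a <- transducer$aperture_diameter / 2
  depth <- Fv - sqrt(Fv^2 - a^2)
  2 * pi * Fv * depth
}

#' Per-harmonic surface pressure amplitudes from a drive spectrum
#'
#' Converts the electrical harmonic amplitudes of the drive into acoustic
#' surface pressure amplitudes through the transducer transfer-function
#' magnitude and the electromechanical calibration constant:
#' `p_h = |A_h| * |H(h f0)| * k_cal`.
#'
#' @param spectrum a [harmonic_levels()] result covering orders 1..6.
#' @param transducer a [transducer_model()].
#' @return an object of class `harmonic_sources`: `harmonic_orders`,
#'   `frequencies` (Hz) and `amplitude_pa` (surface pressure per harmonic).
#' @export
source_amplitudes <- function(spectrum, transducer) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"),
            inherits(transducer, "transducer_model"))
  if (!all(1:6 %in% spectrum$harmonic_orders)) {
    stop("spectrum must cover harmonic orders 1..6")
  }
  idx <- match(1:6, spectrum$harmonic_orders)
  f0 <- spectrum$fundamental_frequency
  freqs <- (1:6) * f0
  gains <- transfer_gain(transducer, freqs)
  amps <- Mod(spectrum$complex_amplitudes[idx]) * gains * transducer$k_cal
  structure(list(harmonic_orders = 1:6,
                 frequencies = freqs,
                 amplitude_pa = amps),
            class = "harmonic_sources")
}

#' @export
print.harmonic_sources <- function(x, ...) {
  cat("<harmonic_sources>\n")
  print(data.frame(order = x$harmonic_orders,
                   frequency_MHz = x$frequencies * 1e-6,
                   amplitude_Pa = signif(x$amplitude_pa, 5)),
        row.names = FALSE)
  invisible(x)
}

#' Scale surface amplitudes to a target acoustic power
#'
#' Rescales all harmonic surface pressures by a common factor so that the
#' plane-wave acoustic power summed over harmonics,
#' `sum_h p_h^2 / (2 rho c) * area`, equals the target; relative harmonic
#' ratios are preserved.
#'
#' @param sources a [source_amplitudes()] result, or a bare numeric vector
#'   of surface pressure amplitudes in Pa.
#' @param target_acoustic_watts target power in W.
#' @param rho,c density (kg/m^3) and sound speed (m/s) of the coupling
#'   medium at the source surface.
#' @param area radiating (spherical-cap) area in m^2.
#' @return object (or vector) of the same shape with scaled amplitudes.
#' @export
calibrate_power <- function(sources, target_acoustic_watts,
                            rho = 1000, c = 1482,
                            area = bowl_cap_area(transducer_model())) {
  amps <- if (inherits(sources, "harmonic_sources")) {
    sources$amplitude_pa
  } else {
    as.numeric(sources)
  }
  if (all(amps == 0)) stop("all-zero amplitudes cannot be calibrated")
  if (target_acoustic_watts <= 0) stop("target power must be positive")
  current <- sum(amps^2) / (2 * rho * c) * area
  scale <- sqrt(target_acoustic_watts / current)
  if (inherits(sources, "harmonic_sources")) {
    sources$amplitude_pa <- amps * scale
    sources
  } else {
    amps * scale
  }
}
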
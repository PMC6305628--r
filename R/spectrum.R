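#' Harmonic content of a periodic waveform
#'
#' Computes the complex amplitude at each harmonic of the drive frequency
#' from a discrete Fourier transform over an exact integer number of cycles
#' (rectangular window; the synchronous record makes leakage windowing
#' unnecessary), and expresses each harmonic in dB relative to the
#' fundamental.
#'
#' @param waveform a `switched_waveform`, or a numeric vector of samples
#'   (in which case `sample_rate` and `fundamental_frequency` are required).
#' @param n_harmonics number of harmonic orders (1..n) to report; the
#'   highest harmonic must lie below Nyquist.
#' @param sample_rate,fundamental_frequency record parameters when
#'   `waveform` is a bare numeric vector.
#' @param tol_cycles tolerance on the integer-cycle check, as a fraction of
#'   one cycle.
#' @return an object of class `harmonic_spectrum`: `fundamental_frequency`,
#'   `harmonic_orders`, `complex_amplitudes` (volts, peak), `levels_db`
#'   (fundamental = 0 dB exactly), plus the record's mean-square value
#'   `mean_square` for power bookkeeping.
#' @examples
#' w <- synthesize(excitation_spec("bilevel", n_cycles = 4))
#' round(harmonic_levels(w, 5)$levels_db, 2)  # H3 -9.54 dB, H5 -13.98 dB
#' @export
harmonic_levels <- function(waveform, n_harmonics = 6L,
                            sample_rate = NULL, fundamental_frequency = NULL,
                            tol_cycles = 1e-6) {
  if (inherits(waveform, "switched_waveform")) {
    v <- waveform_volts(waveform)
    fs <- waveform$sample_rate
    f0 <- waveform$centre_frequency
  } else {
    v <- as.numeric(waveform)
    fs <- sample_rate
    f0 <- fundamental_frequency
    if (is.null(fs) || is.null(f0)) {
      stop("sample_rate and fundamental_frequency are required for bare samples")
    }
  }
  n_harmonics <- as.integer(n_harmonics)
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (n_harmonics * f0 >= fs / 2) {
    stop("highest requested harmonic is at or above Nyquist")
  }
  N <- length(v)
  cycles <- N * f0 / fs
  if (abs(cycles - round(cycles)) > tol_cycles) {
    stop(sprintf(paste0("record does not span an integer number of cycles ",
                        "(%.6g cycles); spectral leakage would corrupt the ",
                        "harmonic levels"), cycles))
  }
  if (round(cycles) < 1) stop("record must span at least one full cycle")
  cycles <- as.integer(round(cycles))
  V <- stats::fft(v) / N
  orders <- seq_len(n_harmonics)
  amps <- 2 * V[orders * cycles + 1L]   # peak complex amplitude at h*f0
  mags <- Mod(amps)
  if (mags[1] == 0) stop("fundamental amplitude is zero; dB levels undefined")
  db <- 20 * log10(mags / mags[1])
  db[1] <- 0
  structure(
    list(fundamental_frequency = f0,
         harmonic_orders = orders,
         complex_amplitudes = amps,
         levels_db = db,
         mean_square = mean(v^2),
         sample_rate = fs,
         n_samples = N),
    class = "harmonic_spectrum")
}

#' @export
print.harmonic_spectrum <- function(x, ...) {
  cat("<harmonic_spectrum>  f0 =", format(x$fundamental_frequency), "Hz\n")
  df <- data.frame(order = x$harmonic_orders,
                   frequency_Hz = x$harmonic_orders * x$fundamental_frequency,
                   amplitude_V = signif(Mod(x$complex_amplitudes), 5),
                   level_dB = round(x$levels_db, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Check harmonic suppression against a relevance floor
#'
#' Tests whether every harmonic in `band_orders` sits at least `floor_db`
#' below the fundamental, the criterion under which residual harmonic energy
#' is considered irrelevant for the transducer.
#'
#' @param spectrum a [harmonic_levels()] result.
#' @param band_orders integer set of harmonic orders to check; must be a
#'   subset of the computed orders.  An empty set passes vacuously.
#' @param floor_db required suppression in dB (positive number; default 20).
#' @return list with `pass` (logical), `worst_order` and `worst_level_db`
#'   (the least-suppressed harmonic in the band; `NA` for an empty band).
#' @export
suppression_check <- function(spectrum, band_orders, floor_db = 20) {
  stopifnot(inherits(spectrum, "harmonic_spectrum"))
  band_orders <- as.integer(band_orders)
  if (length(band_orders) == 0L) {
    return(list(pass = TRUE, worst_order = NA_integer_,
                worst_level_db = NA_real_))
  }
  if (!all(band_orders %in% spectrum$harmonic_orders)) {
    stop("band_orders must be a subset of the computed harmonic orders")
  }
  idx <- match(band_orders, spectrum$harmonic_orders)
  lv <- spectrum$levels_db[idx]
  worst <- which.max(lv)
  list(pass = all(lv <= -floor_db),
       worst_order = band_orders[worst],
       worst_level_db = lv[worst])
}
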
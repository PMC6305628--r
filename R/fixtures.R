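#' Lumped electrical load model
#'
#' A two-element series branch (resistance + inductance) with a parallel
#' shunt capacitance, standing in for a transducer plus matching network
#' whose exact impedance is unknown.  The admittance seen by the drive is
#' `Y(f) = 1 / (R + j w L) + j w C`.
#'
#' @param resistance series resistance, Ohm.
#' @param inductance series inductance, H.
#' @param capacitance shunt capacitance, F.
#' @return an object of class `load_model`.
#' @export
load_model <- function(resistance = 50, inductance = 0, capacitance = 0) {
  if (resistance < 0 || inductance < 0 || capacitance < 0) {
    stop("load elements must be non-negative")
  }
  if (resistance == 0 && inductance == 0 && capacitance == 0) {
    stop("degenerate all-zero load")
  }
  structure(list(resistance = resistance, inductance = inductance,
                 capacitance = capacitance),
            class = "load_model")
}

#' Complex admittance of a load model
#' @param load a [load_model()].
#' @param freqs frequencies, Hz.
#' @return complex admittance vector, Siemens.
#' @export
load_admittance <- function(load, freqs) {
  stopifnot(inherits(load, "load_model"))
  w <- 2 * pi * freqs
  series <- load$resistance + 1i * w * load$inductance
  y <- ifelse(Mod(series) > 0, 1 / series, 0)
  y + 1i * w * load$capacitance
}

#' Synthetic voltage/current trace through a lumped load
#'
#' Drives the load model with a waveform's voltage samples and computes the
#' exact periodic steady-state current bin-by-bin in the frequency domain
#' (the record is treated as one period), then adds seeded Gaussian
#' measurement noise to both channels.
#'
#' @param waveform a `switched_waveform`.
#' @param load a [load_model()].
#' @param noise_rms measurement noise RMS added to each channel (volts on
#'   the voltage channel; the same value scaled by the mean admittance
#'   magnitude on the current channel).
#' @param seed integer seed; the trace is bit-reproducible from
#'   `(seed, parameters)`.
#' @return a [vi_trace()].
#' @export
make_vi_trace <- function(waveform, load, noise_rms = 0, seed = 1L) {
  stopifnot(inherits(waveform, "switched_waveform"),
            inherits(load, "load_model"))
  v <- waveform_volts(waveform)
  N <- length(v)
  fs <- waveform$sample_rate
  freqs <- (seq_len(N) - 1L) * fs / N
  freqs[freqs > fs / 2] <- freqs[freqs > fs / 2] - fs    # signed bin freqs
  Y <- load_admittance(load, freqs)
  # Hermitian symmetry: admittance at negative frequency is the conjugate
  i_t <- Re(stats::fft(stats::fft(v) * Y, inverse = TRUE)) / N
  if (noise_rms > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(N, sd = noise_rms)
    i_scale <- mean(Mod(load_admittance(load, waveform$centre_frequency)))
    i_t <- i_t + stats::rnorm(N, sd = noise_rms * i_scale)
  }
  vi_trace(v, i_t, 1 / fs)
}

#' Synthetic passive-cavitation-detector trace
#'
#' Seeded Gaussian background noise with band-limited broadband bursts
#' injected at the given event times; each burst may carry coherent spectral
#' lines (e.g. ultraharmonics of the drive).  Regeneration with the same
#' seed and parameters is bit-identical.
#'
#' @param event_times sorted burst onset times, seconds.
#' @param duration total trace duration, seconds.
#' @param sample_rate Hz (default 50 MHz).
#' @param noise_rms background noise RMS, volts.
#' @param burst_amplitude peak envelope of the broadband component, volts.
#' @param burst_duration burst envelope scale, seconds.
#' @param line_freqs optional coherent line frequencies inside each burst,
#'   Hz.
#' @param line_amplitude amplitude per line, volts.
#' @param seed integer seed.
#' @param ... further arguments passed to [pcd_recording()] (trigger
#'   parameters).
#' @return a [pcd_recording()].
#' @export
make_pcd_trace <- function(event_times, duration,
                           sample_rate = 50e6,
                           noise_rms = 0.05,
                           burst_amplitude = 1.0,
                           burst_duration = 20e-6,
                           line_freqs = numeric(0),
                           line_amplitude = 0.3,
                           seed = 1L, ...) {
  if (is.unsorted(event_times)) stop("event_times must be sorted")
  n <- round(duration * sample_rate)
  set.seed(seed)
  x <- stats::rnorm(n, sd = noise_rms)
  t <- (seq_len(n) - 1L) / sample_rate
  for (t0 in event_times) {
    i0 <- round(t0 * sample_rate) + 1L
    n_b <- round(4 * burst_duration * sample_rate)
    idx <- i0:min(i0 + n_b - 1L, n)
    if (length(idx) < 2L) next
    tb <- (idx - i0) / sample_rate
    env <- exp(-((tb - burst_duration) / (burst_duration / 2))^2)
    broadband <- stats::rnorm(length(idx))
    burst <- burst_amplitude * env * broadband
    for (fl in line_freqs) {
      burst <- burst + line_amplitude * env * sin(2 * pi * fl * tb)
    }
    x[idx] <- x[idx] + burst
  }
  pcd_recording(x, sample_rate, ...)
}
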
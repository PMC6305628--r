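#' Passive cavitation detector recording
#'
#' A sampled hydrophone trace with the segmented-acquisition trigger
#' parameters: trigger threshold (set slightly above the noise floor),
#' re-arm hold-off, per-segment record length and segment budget.
#'
#' @param trace numeric vector, volts.
#' @param sample_rate Hz.
#' @param trigger_threshold volts (default 0.380).
#' @param holdoff seconds between accepted triggers (default 0.050).
#' @param segment_length seconds per recorded segment (default 250e-6).
#' @param max_segments acquisition budget (default 256).
#' @return an object of class `pcd_recording`.
#' @export
pcd_recording <- function(trace, sample_rate,
                          trigger_threshold = 0.380,
                          holdoff = 0.050,
                          segment_length = 250e-6,
                          max_segments = 256L) {
  if (trigger_threshold <= 0 || holdoff <= 0 || segment_length <= 0) {
    stop("trigger parameters must be positive")
  }
  structure(list(trace = as.numeric(trace),
                 sample_rate = sample_rate,
                 trigger_threshold = trigger_threshold,
                 holdoff = holdoff,
                 segment_length = segment_length,
                 max_segments = as.integer(max_segments)),
            class = "pcd_recording")
}

#' @export
print.pcd_recording <- function(x, ...) {
  cat(sprintf("<pcd_recording>  %.4g s at %.4g MHz, threshold %g mV, hold-off %g ms\n",
              length(x$trace) / x$sample_rate, x$sample_rate * 1e-6,
              x$trigger_threshold * 1e3, x$holdoff * 1e3))
  invisible(x)
}

#' Detect cavitation events with the segmented trigger rules
#'
#' A trigger fires at the first sample whose absolute value exceeds the
#' threshold and that is at least one hold-off after the previous trigger
#' (broadband emissions are bipolar, so the absolute value is used); at most
#' `max_segments` segments are captured, each of the configured length
#' starting at its trigger sample.
#'
#' @param recording a [pcd_recording()].
#' @return list with `count`, `trigger_times` (s), `trigger_samples`
#'   (1-based), and `segments` (list of numeric vectors).
#' @export
detect_events <- function(recording) {
  stopifnot(inherits(recording, "pcd_recording"))
  x <- recording$trace
  fs <- recording$sample_rate
  seg_n <- round(recording$segment_length * fs)
  if (length(x) <= seg_n) stop("trace must be longer than one segment")
  hold_n <- round(recording$holdoff * fs)
  hot <- which(abs(x) > recording$trigger_threshold)
  trig <- integer(0)
  last <- -Inf
  for (i in hot) {
    if (i - last >= hold_n) {
      trig <- c(trig, i)
      last <- i
      if (length(trig) >= recording$max_segments) break
    }
  }
  segments <- lapply(trig, function(i) {
    x[i:min(i + seg_n - 1L, length(x))]
  })
  list(count = length(trig),
       trigger_times = (trig - 1L) / fs,
       trigger_samples = trig,
       segments = segments)
}

#' Classify an exposure from its cavitation event count
#'
#' More than 10 recorded cavitation triggers during an exposure marks the
#' lesion as mechanically rather than thermally formed.
#'
#' @param count non-negative trigger count.
#' @return `"thermal"` or `"mechanical"`.
#' @export
classify_exposure <- function(count) {
  if (count < 0) stop("count must be >= 0")
  if (count > 10) "mechanical" else "thermal"
}

# linear-phase FIR high-pass used to emulate the PCD receive filter;
# >= 60 dB stopband below the cut frequency
pcd_highpass <- function(fs, f_stop = 5e6, n_taps = 201L) {
  f_pass <- f_stop * 1.25
  fc <- (f_stop + f_pass) / 2
  beta <- 6.0                               # Kaiser, ~65 dB sidelobes
  taps <- signal::fir1(n_taps - 1L, fc / (fs / 2), type = "high",
                       window = signal::kaiser(n_taps, beta))
  as.numeric(taps)
}

#' Emission spectrum of a PCD segment with harmonic/ultraharmonic labels
#'
#' Applies a linear-phase high-pass (stopband below 5 MHz, emulating the
#' receive filter that removes the drive's first three harmonics), computes
#' the magnitude spectrum in dB relative to the mean noise level, and labels
#' spectral peaks lying within half a bin of an integer harmonic `n f0` or
#' an ultraharmonic `(2n+1) f0/2` of the drive frequency.  Peaks must rise
#' at least 6 dB above the local noise level to be labelled.
#'
#' @param segment numeric vector (one captured segment), volts.
#' @param sample_rate Hz.
#' @param drive_frequency drive f0 in Hz.
#' @param highpass_hz stopband edge of the receive filter (default 5 MHz).
#' @param prominence_db labelling floor above local noise (default 6).
#' @return an object of class `emission_spectrum`: `frequencies`,
#'   `level_db` (dB re mean noise), `noise_level` (linear reference), and a
#'   data frame `lines` with columns `frequency`, `level_db`, `kind`
#'   (`"harmonic"`/`"ultraharmonic"`), `order` (n, or n + 0.5).
#' @export
emission_spectrum <- function(segment, sample_rate, drive_frequency,
                              highpass_hz = 5e6, prominence_db = 6) {
  if (drive_frequency <= 0) stop("drive_frequency must be positive")
  x <- as.numeric(segment)
  if (length(x) < 64L) stop("segment must hold at least 64 samples")
  fs <- sample_rate
  taps <- pcd_highpass(fs, f_stop = highpass_hz)
  nt <- length(taps)
  gd <- (nt - 1L) %/% 2L
  # full linear convolution, then drop the linear-phase group delay
  y <- stats::convolve(x, rev(taps), type = "open")
  y <- y[(gd + 1L):(gd + length(x))]

  # averaged periodogram: splitting the segment stabilises the noise floor
  # so the prominence criterion has a negligible false-alarm rate
  n_avg <- max(1L, min(16L, floor(length(y) / 256L)))
  Nseg <- floor(length(y) / n_avg)
  pow <- 0
  for (s in seq_len(n_avg)) {
    ys <- y[((s - 1L) * Nseg + 1L):(s * Nseg)]
    pow <- pow + Mod(stats::fft(ys))[seq_len(floor(Nseg / 2) + 1L)]^2
  }
  Y <- sqrt(pow / n_avg)
  freqs <- (seq_along(Y) - 1L) * fs / Nseg
  band <- freqs >= highpass_hz * 1.5
  noise_ref <- stats::median(Y[band])
  if (!is.finite(noise_ref) || noise_ref <= 0) noise_ref <- .Machine$double.eps
  level_db <- 20 * log10(pmax(Y, .Machine$double.xmin) / noise_ref)

  df <- fs / Nseg
  # candidate lines: integer and half-integer multiples of f0 in the band
  n_max <- floor(max(freqs) / (drive_frequency / 2))
  cand <- data.frame(order = (2:n_max) / 2)
  cand$frequency <- cand$order * drive_frequency
  cand <- cand[cand$frequency >= highpass_hz, , drop = FALSE]
  lines <- list()
  for (i in seq_len(nrow(cand))) {
    fl <- cand$frequency[i]
    k <- which.min(abs(freqs - fl))
    if (abs(freqs[k] - fl) > df / 2) next
    # local maximum (allowing one bin of scalloping) and prominent above
    # the local noise level
    lo <- max(2L, k - 1L); hi <- min(length(Y), k + 1L)
    pk <- lo - 1L + which.max(Y[lo:hi])
    win <- freqs > freqs[pk] - 30 * df & freqs < freqs[pk] + 30 * df
    win[pmax(1L, pk - 2L):pmin(length(Y), pk + 2L)] <- FALSE
    local_noise <- stats::median(Y[win])
    floor_lin <- max(local_noise, noise_ref) * 10^(prominence_db / 20)
    if (Y[pk] < floor_lin) next
    is_int <- abs(cand$order[i] - round(cand$order[i])) < 1e-9
    lines[[length(lines) + 1L]] <- data.frame(
      frequency = fl,
      level_db = level_db[pk],
      kind = if (is_int) "harmonic" else "ultraharmonic",
      order = cand$order[i])
  }
  lines <- if (length(lines)) do.call(rbind, lines) else
    data.frame(frequency = numeric(0), level_db = numeric(0),
               kind = character(0), order = numeric(0))
  structure(list(frequencies = freqs, level_db = level_db,
                 noise_level = noise_ref, lines = lines,
                 drive_frequency = drive_frequency),
            class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("<emission_spectrum>  f0 = %.4g MHz, %d labelled line(s)\n",
              x$drive_frequency * 1e-6, nrow(x$lines)))
  if (nrow(x$lines)) {
    df <- x$lines
    df$frequency <- df$frequency * 1e-6
    names(df)[1] <- "frequency_MHz"
    df$level_db <- round(df$level_db, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}
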
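#' Aligned voltage/current trace
#'
#' A sampled pair of drive voltage and delivered current on a common time
#' base; the caller guarantees alignment (probe de-skew is out of scope).
#'
#' @param voltage numeric vector, volts.
#' @param current numeric vector, amperes; same length as `voltage`.
#' @param sample_interval sample spacing in seconds.
#' @return an object of class `vi_trace`.
#' @export
vi_trace <- function(voltage, current, sample_interval) {
  if (length(voltage) != length(current)) {
    stop("voltage and current must have the same length")
  }
  if (length(voltage) < 2L) stop("at least 2 samples are required")
  if (!all(is.finite(voltage)) || !all(is.finite(current))) {
    stop("voltage and current must be finite")
  }
  if (!is.finite(sample_interval) || sample_interval <= 0) {
    stop("sample_interval must be a positive number")
  }
  structure(list(sample_interval = sample_interval,
                 voltage = as.numeric(voltage),
                 current = as.numeric(current)),
            class = "vi_trace")
}

#' @export
print.vi_trace <- function(x, ...) {
  cat(sprintf("<vi_trace>  %d samples at dt = %.4g s (%.4g MHz), Vrms %.4g V, Irms %.4g A\n",
              length(x$voltage), x$sample_interval,
              1e-6 / x$sample_interval,
              sqrt(mean(x$voltage^2)), sqrt(mean(x$current^2))))
  invisible(x)
}

#' True power spectral density from a voltage/current record
#'
#' Computes the signed true (real) power density
#' \deqn{P(f) = \mathrm{Re}\{V(f)\, I(f)^*\}}
#' from the discrete Fourier transforms of the two records, folded one-sided
#' and normalised as a density in W/Hz such that the trapezoidal integral
#' over the full band equals the time-domain mean of `v * i` exactly
#' (Parseval contract).  All bins, including DC and Nyquist, carry the
#' one-sided factor of two, which compensates the half-weight that the
#' trapezoidal rule assigns to the band endpoints.
#'
#' No window is applied: records spanning an integer number of drive cycles
#' place all harmonic power in single bins; for non-synchronous records
#' band-edge leakage is the caller's risk.
#'
#' @param trace a [vi_trace()].
#' @return an object of class `power_spectrum`: `frequencies` (Hz, 0 to
#'   Nyquist) and `true_power_density` (W/Hz, signed), plus the time-domain
#'   mean power `mean_power_w`.
#' @export
power_spectrum <- function(trace) {
  stopifnot(inherits(trace, "vi_trace"))
  v <- trace$voltage
  i <- trace$current
  N <- length(v)
  fs <- 1 / trace$sample_interval
  V <- stats::fft(v) / N
  I <- stats::fft(i) / N
  cross <- Re(V * Conj(I))
  n_half <- floor(N / 2)
  freqs <- (0:n_half) * fs / N
  # one-sided factor 2: interior bins fold their conjugate pair, DC (and
  # Nyquist, for even N) appear once two-sided but get half weight from the
  # trapezoid; for odd N the final bin is still a conjugate pair yet sits at
  # the band edge, so it carries an extra factor to keep the integral exact
  dens <- 2 * cross[seq_len(n_half + 1L)]
  if (N %% 2 == 1L) dens[n_half + 1L] <- 2 * dens[n_half + 1L]
  df <- fs / N
  dens <- dens / df
  structure(list(frequencies = freqs,
                 true_power_density = dens,
                 mean_power_w = mean(v * i),
                 df = df),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum>  %d bins, df = %.4g Hz, band 0-%.4g MHz, mean power %.6g W\n",
              length(x$frequencies), x$df,
              max(x$frequencies) * 1e-6, x$mean_power_w))
  invisible(x)
}

#' Total delivered true power over a frequency band
#'
#' Trapezoidal integral of the true power density over `[f_lo, f_hi]`,
#' the band-limited total
#' \deqn{P_T = \int_{f_0}^{f_1} P(f)\, df.}
#' Band edges falling between bins are handled by linear interpolation of
#' the density.
#'
#' @param spectrum a [power_spectrum()].
#' @param f_lo,f_hi integration band in Hz (defaults 500 kHz and 10 MHz);
#'   `f_hi` must not exceed Nyquist.
#' @return total true power in watts.
#' @export
total_true_power <- function(spectrum, f_lo = 500e3, f_hi = 10e6) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  f <- spectrum$frequencies
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  if (f_lo < min(f) || f_hi > max(f) + 1e-9) {
    stop(sprintf("band [%.4g, %.4g] Hz lies outside the spectrum support [0, %.4g] Hz",
                 f_lo, f_hi, max(f)))
  }
  d <- spectrum$true_power_density
  inside <- f > f_lo & f < f_hi
  fk <- c(f_lo, f[inside], min(f_hi, max(f)))
  dk <- c(stats::approx(f, d, xout = f_lo)$y, d[inside],
          stats::approx(f, d, xout = min(f_hi, max(f)))$y)
  sum(diff(fk) * (utils::head(dk, -1) + utils::tail(dk, -1)) / 2)
}
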
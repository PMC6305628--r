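#' Excitation specification for a drive waveform
#'
#' Bundles the parameters that define one transmit excitation: the scheme
#' (ideal sinusoid, two-level square wave, or five-level HRPWM), centre
#' frequency, amplitude control, record length and sampling.
#'
#' The modulation index `m` is normalised so that `m = 1` corresponds to the
#' maximum fundamental of the un-nulled full five-level staircase (both
#' switching angles at zero), i.e. a fundamental amplitude of
#' `8 * rail_step / pi` volts.  For the sine scheme the amplitude is
#' `m * 2 * rail_step` (the top rail).
#'
#' @param scheme one of `"sine"`, `"bilevel"`, `"hrpwm"`.
#' @param centre_frequency drive frequency f0 in Hz (default 1.1 MHz).
#' @param modulation_index amplitude control parameter in `[0, 1]`.
#' @param duty_cycle fraction of the cycle spent at the positive rail
#'   (bilevel scheme only), in `(0, 1)`.
#' @param n_cycles integer number of drive cycles to synthesise.
#' @param sample_rate sample rate in Hz; must be at least
#'   `32 * centre_frequency` (switching-instant quantisation floor).
#' @param rail_step per-level rail step V1 in volts; levels +/-1 map to
#'   +/-`rail_step`.
#' @param rail_v2 outer rail voltage V2 in volts; levels +/-2 map to
#'   +/-`rail_v2`.  Defaults to `2 * rail_step` (equal steps).  The
#'   harmonic-nulling angle design assumes equal steps.
#' @return an object of class `excitation_spec`.
#' @seealso [synthesize()], [design_switching_angles()]
#' @export
excitation_spec <- function(scheme = c("sine", "bilevel", "hrpwm"),
                            centre_frequency = 1.1e6,
                            modulation_index = 0.70,
                            duty_cycle = 0.5,
                            n_cycles = 10L,
                            sample_rate = 64 * centre_frequency,
                            rail_step = 30,
                            rail_v2 = 2 * rail_step) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(centre_frequency), length(centre_frequency) == 1L)
  if (centre_frequency <= 0) stop("centre_frequency must be > 0")
  if (sample_rate < 32 * centre_frequency) {
    stop("sample_rate must be >= 32 x centre_frequency (got ",
         format(sample_rate / centre_frequency, digits = 4),
         " samples/cycle; floor is 32)")
  }
  if (modulation_index < 0 || modulation_index > 1) {
    stop("modulation_index must be in [0, 1]")
  }
  if (duty_cycle <= 0 || duty_cycle >= 1) stop("duty_cycle must be in (0, 1)")
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1L) stop("n_cycles must be >= 1")
  if (rail_step <= 0 || rail_v2 <= 0) stop("rail voltages must be positive")
  if (scheme == "hrpwm" && !isTRUE(all.equal(rail_v2, 2 * rail_step))) {
    warning("harmonic nulling assumes equal rail steps (rail_v2 = 2 * rail_step); ",
            "designed nulls will not be exact for this rail ratio")
  }
  structure(
    list(scheme = scheme,
         centre_frequency = centre_frequency,
         modulation_index = modulation_index,
         duty_cycle = duty_cycle,
         n_cycles = n_cycles,
         sample_rate = sample_rate,
         rail_step = rail_step,
         rail_v2 = rail_v2),
    class = "excitation_spec")
}

#' @export
print.excitation_spec <- function(x, ...) {
  cat("<excitation_spec>\n")
  cat(sprintf("  scheme: %s   f0: %.6g Hz   fs: %.6g Hz (%.3g samples/cycle)\n",
              x$scheme, x$centre_frequency, x$sample_rate,
              x$sample_rate / x$centre_frequency))
  cat(sprintf("  m: %.4g   duty: %.3g   cycles: %d   rails: +/-%g, +/-%g V\n",
              x$modulation_index, x$duty_cycle, x$n_cycles,
              x$rail_step, x$rail_v2))
  invisible(x)
}

# Fourier sine coefficient (in rail-step units, x 4/(n*pi)) of the
# quarter-wave-symmetric switched waveform defined by angles/steps.
# b_n = (4/(n*pi)) * sum_k s_k cos(n a_k); even n vanish by symmetry.
staircase_bn <- function(angles, steps, n) {
  (4 / (n * pi)) * sum(steps * cos(n * angles))
}

#' Design switching angles for harmonic-reduced five-level PWM
#'
#' Solves the quarter-wave-symmetric switching-angle system: the angles set
#' the fundamental amplitude to the requested fraction `m` of the full
#' staircase maximum while forcing the Fourier coefficients of the selected
#' low-order odd harmonics to zero, so that switching-induced harmonics
#' destructively interfere.
#'
#' With two angles (one pulse per half cycle, levels 0 -> 1 -> 2) and the
#' third harmonic nulled, the system
#' \deqn{\cos\alpha_1 + \cos\alpha_2 = 2m, \quad
#'       \cos 3\alpha_1 + \cos 3\alpha_2 = 0}
#' has solutions for `m` in `[sqrt(3)/4, sqrt(3)/2]` (about `[0.433, 0.866]`,
#' branches `a2 = pi/3 +/- a1`).  Outside this band the solver escalates to
#' four angles (two pulses per half cycle) nulling harmonics 3, 5 and 7.
#'
#' A damped Newton iteration with eight deterministic multi-starts is used;
#' tolerance `1e-9`, 100 iteration cap.  Infeasible requests raise an error
#' naming the feasible band.
#'
#' @param modulation_index target fundamental as a fraction of the full
#'   staircase maximum (`8 V1 / pi` volts), in `(0, 1]`.
#' @param nulled_harmonics integer set of harmonic orders to null; subset of
#'   `{3, 5}`.  Requesting `5` forces the four-angle solution.
#' @param tol residual tolerance for the nonlinear solve.
#' @param max_iter Newton iteration cap per start.
#' @return an object of class `angle_solution` with elements `angles`
#'   (radians, increasing, in `[0, pi/2]`), `steps` (level increments, each
#'   +/-1), `n_pulses_per_half_cycle` (1 or 2), `modulation_index`,
#'   `nulled_harmonics`, `residual_fundamental` and `residual_harmonics`.
#' @examples
#' sol <- design_switching_angles(0.75, 3)
#' round(sol$angles * 180 / pi, 6)  # 0 and 60 degrees
#' @export
design_switching_angles <- function(modulation_index, nulled_harmonics = 3L,
                                    tol = 1e-9, max_iter = 100L) {
  m <- modulation_index
  nulled_harmonics <- sort(unique(as.integer(nulled_harmonics)))
  if (length(nulled_harmonics) == 0L) stop("nulled_harmonics must be non-empty")
  if (!all(nulled_harmonics %in% c(3L, 5L))) {
    stop("nulled_harmonics must be a subset of {3, 5}")
  }
  if (!is.finite(m) || m <= 0 || m > 1) {
    stop("modulation_index must be in (0, 1]")
  }
  two_angle_band <- c(sqrt(3) / 4, sqrt(3) / 2)

  try_solve <- function(angles0, steps, orders) {
    # F: fundamental equation then one equation per nulled order.
    K <- length(angles0)
    fun <- function(a) {
      c(sum(steps * cos(a)) - 2 * m,
        vapply(orders, function(n) sum(steps * cos(n * a)), numeric(1)))
    }
    jac <- function(a) {
      rbind(-steps * sin(a),
            t(vapply(orders, function(n) -n * steps * sin(n * a),
                     numeric(K))))
    }
    a <- angles0
    for (it in seq_len(max_iter)) {
      Fv <- fun(a)
      if (max(abs(Fv)) < tol) break
      J <- jac(a)
      step <- tryCatch(solve(J, Fv), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      # damped update, keep iterates inside [0, pi/2]
      lambda <- 1
      repeat {
        a_new <- pmin(pmax(a - lambda * step, 0), pi / 2)
        if (max(abs(fun(a_new))) < max(abs(Fv)) || lambda < 1e-3) break
        lambda <- lambda / 2
      }
      a <- a_new
    }
    Fv <- fun(a)
    if (max(abs(Fv)) >= tol) return(NULL)
    if (any(a < -1e-12) || any(a > pi / 2 + 1e-12)) return(NULL)
    if (any(diff(a) < -1e-9)) return(NULL)   # must be (weakly) increasing
    list(angles = pmin(pmax(a, 0), pi / 2), residuals = Fv)
  }

  solve_pattern <- function(K, steps, orders) {
    starts <- seq(0.02, 0.95, length.out = 8L) * (pi / 2)
    for (s0 in starts) {
      a0 <- s0 * seq(0.35, 1, length.out = K)
      res <- try_solve(a0, steps, orders)
      if (!is.null(res)) return(res)
    }
    NULL
  }

  use_two <- identical(nulled_harmonics, 3L) &&
    m >= two_angle_band[1] - 1e-12 && m <= two_angle_band[2] + 1e-12
  if (use_two) {
    steps <- c(1, 1)
    orders <- 3L
    res <- solve_pattern(2L, steps, orders)
    npulse <- 1L
  } else {
    # two pulses per half cycle: notched ladder for low m, capped ladder for
    # high m; harmonics 3, 5, 7 nulled to make the Newton system square.
    orders <- c(3L, 5L, 7L)
    if (m < two_angle_band[1]) {
      steps <- c(1, -1, 1, -1)
    } else {
      steps <- c(1, 1, -1, 1)
    }
    res <- solve_pattern(4L, steps, orders)
    npulse <- 2L
  }
  if (is.null(res)) {
    stop(sprintf(paste0(
      "no switching-angle solution for modulation_index = %.4g with harmonics {%s} nulled; ",
      "the one-pulse (two-angle) band with H3 nulled is [%.4g, %.4g] and no ",
      "two-pulse (four-angle) solution converged"),
      m, paste(nulled_harmonics, collapse = ","),
      two_angle_band[1], two_angle_band[2]))
  }
  ord <- order(res$angles)
  structure(
    list(angles = res$angles[ord],
         steps = steps[ord],
         n_pulses_per_half_cycle = npulse,
         modulation_index = m,
         nulled_harmonics = if (npulse == 2L) orders else nulled_harmonics,
         residual_fundamental = abs(res$residuals[1]),
         residual_harmonics = abs(res$residuals[-1])),
    class = "angle_solution")
}

#' @export
print.angle_solution <- function(x, ...) {
  cat("<angle_solution>\n")
  cat(sprintf("  m = %.4g, %d pulse(s)/half-cycle, nulled: {%s}\n",
              x$modulation_index, x$n_pulses_per_half_cycle,
              paste(x$nulled_harmonics, collapse = ",")))
  cat("  angles (deg):", paste(sprintf("%.4f", x$angles * 180 / pi),
                               collapse = ", "), "\n")
  cat("  steps:       ", paste(sprintf("%+d", x$steps), collapse = ", "), "\n")
  cat(sprintf("  residuals: fundamental %.2e, harmonics %s\n",
              x$residual_fundamental,
              paste(sprintf("%.2e", x$residual_harmonics), collapse = ", ")))
  invisible(x)
}

# Switching events of one full cycle, as (phase, level increment) pairs,
# from the quarter-cycle angles by quarter-wave / half-wave symmetry.
cycle_events <- function(angles, steps) {
  phase <- c(angles, pi - rev(angles), pi + angles, 2 * pi - rev(angles))
  delta <- c(steps, -rev(steps), -steps, rev(steps))
  ord <- order(phase)
  list(phase = phase[ord], delta = delta[ord])
}

# Nearest-sample quantisation with ties resolved to the earlier sample.
quantize_index <- function(x) ceiling(x - 0.5)

# Snap the designed switching angles onto the sample lattice: enumerate the
# floor/ceil candidate for every angle and keep the combination that best
# preserves the fundamental and the nulled-harmonic cancellation.  This
# bounds the quantisation error far below naive per-instant rounding and is
# deterministic (first minimum wins).
refine_angles_to_lattice <- function(sol, samples_per_cycle) {
  m <- sol$modulation_index
  n_exact <- sol$angles / (2 * pi) * samples_per_cycle
  cand <- lapply(n_exact, function(x) unique(c(floor(x), ceiling(x))))
  combos <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE)
  qmax <- samples_per_cycle / 4
  cands <- list()
  for (i in seq_len(nrow(combos))) {
    nq <- as.numeric(combos[i, ])
    if (any(nq < 0) || any(nq > qmax)) next
    if (any(diff(nq) < 0)) next                 # keep the angle ordering
    aq <- nq * 2 * pi / samples_per_cycle
    b1 <- sum(sol$steps * cos(aq))
    if (b1 <= 0) next
    supp <- vapply(sol$nulled_harmonics, function(n) {
      abs(sum(sol$steps * cos(n * aq)) / n) / b1
    }, numeric(1))
    cands[[length(cands) + 1L]] <- list(aq = aq,
                                        err1 = abs(b1 - 2 * m) / (2 * m),
                                        supp = max(supp))
  }
  if (length(cands) == 0L) return(sol$angles)
  # prefer candidates that keep the nulled harmonics below -23 dB of the
  # fundamental (3 dB under the relevance floor), and among those take the
  # best fundamental match; relax the floor only if no candidate meets it
  for (floor_lin in c(10^(-23 / 20), 10^(-20 / 20), Inf)) {
    ok <- Filter(function(cc) cc$supp <= floor_lin, cands)
    if (length(ok)) {
      errs <- vapply(ok, `[[`, numeric(1), "err1")
      return(ok[[which.min(errs)]]$aq)
    }
  }
  sol$angles
}

#' Synthesise a sampled drive waveform
#'
#' Samples the excitation defined by an [excitation_spec()].  For the
#' `hrpwm` scheme the switching angles are designed (or supplied) and every
#' switching instant is quantised to the nearest sample, ties resolving to
#' the earlier sample.  The `bilevel` scheme is a two-level square wave at
#' the requested duty cycle; the `sine` scheme is a continuous sampled
#' sinusoid of amplitude `m * 2 * rail_step` and bypasses level
#' quantisation.
#'
#' @param spec an [excitation_spec()].
#' @param angle_solution optionally a precomputed [design_switching_angles()]
#'   result (hrpwm only); designed from `spec$modulation_index` when `NULL`.
#' @return an object of class `switched_waveform`: list with `sample_rate`,
#'   `centre_frequency`, `levels` (integer levels in `{-2..2}` for switched
#'   schemes, real level values for `sine`), `rail_step`, `rail_v2`,
#'   `scheme`, `n_cycles` and, for hrpwm, the `angle_solution` used.
#' @export
synthesize <- function(spec, angle_solution = NULL) {
  stopifnot(inherits(spec, "excitation_spec"))
  f0 <- spec$centre_frequency
  fs <- spec$sample_rate
  spc <- fs / f0                      # samples per cycle (not necessarily integer)
  n <- round(spec$n_cycles * spc)
  tcyc <- seq_len(n) - 1L             # sample indices

  if (spec$scheme == "sine") {
    levels <- spec$modulation_index * 2 *
      sin(2 * pi * f0 * tcyc / fs)
  } else if (spec$scheme == "bilevel") {
    frac <- (tcyc / spc) %% 1
    levels <- ifelse(frac < spec$duty_cycle, 1L, -1L)
  } else {
    sol <- angle_solution
    if (is.null(sol)) sol <- design_switching_angles(spec$modulation_index)
    ev <- cycle_events(refine_angles_to_lattice(sol, spc), sol$steps)
    levels <- integer(n)
    deltas <- numeric(n + 1L)
    for (c_i in seq_len(spec$n_cycles) - 1L) {
      s_idx <- quantize_index((ev$phase / (2 * pi) + c_i) * spc)
      for (j in seq_along(s_idx)) {
        k <- s_idx[j] + 1L            # 1-based sample holding this event
        if (k >= 1L && k <= n) deltas[k] <- deltas[k] + ev$delta[j]
      }
    }
    levels <- as.integer(cumsum(deltas[seq_len(n)]))
    if (any(abs(levels) > 2L)) stop("internal error: level outside {-2..2}")
    angle_solution <- sol
  }
  structure(
    list(sample_rate = fs,
         centre_frequency = f0,
         levels = levels,
         rail_step = spec$rail_step,
         rail_v2 = spec$rail_v2,
         scheme = spec$scheme,
         n_cycles = spec$n_cycles,
         modulation_index = spec$modulation_index,
         duty_cycle = spec$duty_cycle,
         angle_solution = angle_solution),
    class = "switched_waveform")
}

#' Voltage samples of a waveform
#'
#' Maps levels to volts through the rail map: +/-1 -> +/-V1, +/-2 -> +/-V2
#' (for the sine scheme, level values scale `rail_step` directly).
#'
#' @param waveform a `switched_waveform`.
#' @return numeric vector of volts.
#' @export
waveform_volts <- function(waveform) {
  stopifnot(inherits(waveform, "switched_waveform"))
  lv <- waveform$levels
  if (waveform$scheme == "sine") return(lv * waveform$rail_step)
  v <- numeric(length(lv))
  v[lv == 1L] <- waveform$rail_step
  v[lv == -1L] <- -waveform$rail_step
  v[lv == 2L] <- waveform$rail_v2
  v[lv == -2L] <- -waveform$rail_v2
  v
}

#' Time base of a waveform
#' @param waveform a `switched_waveform`.
#' @return numeric vector of sample times in seconds.
#' @export
waveform_time <- function(waveform) {
  (seq_along(waveform$levels) - 1L) / waveform$sample_rate
}

#' @export
print.switched_waveform <- function(x, ...) {
  cat("<switched_waveform>\n")
  cat(sprintf("  scheme: %s   f0: %.6g Hz   fs: %.6g Hz   %d samples (%.4g cycles)\n",
              x$scheme, x$centre_frequency, x$sample_rate, length(x$levels),
              length(x$levels) * x$centre_frequency / x$sample_rate))
  cat(sprintf("  rails: +/-%g, +/-%g V   m: %.4g\n",
              x$rail_step, x$rail_v2, x$modulation_index))
  invisible(x)
}

#' @export
plot.switched_waveform <- function(x, n_cycles = 3, ...) {
  spc <- x$sample_rate / x$centre_frequency
  n <- min(length(x$levels), ceiling(n_cycles * spc))
  t_us <- waveform_time(x)[seq_len(n)] * 1e6
  v <- waveform_volts(x)[seq_len(n)]
  plot(t_us, v, type = "s", xlab = "time (µs)", ylab = "drive (V)",
       main = sprintf("%s excitation", x$scheme), ...)
  invisible(x)
}

#' Waveform family over a set of modulation indices
#'
#' Designs and synthesises one hrpwm waveform per modulation index with the
#' rail voltages held fixed, the scheme's amplitude-control (apodisation)
#' mode of operation.  Verifies that the measured fundamental amplitude is
#' strictly increasing with `m`.
#'
#' @param m_values numeric vector of modulation indices.
#' @param spec template [excitation_spec()] supplying everything except the
#'   modulation index (its `scheme` must be `"hrpwm"`).
#' @return list of `switched_waveform` objects, one per `m`.
#' @export
apodisation_set <- function(m_values, spec = excitation_spec("hrpwm")) {
  stopifnot(inherits(spec, "excitation_spec"))
  if (spec$scheme != "hrpwm") stop("apodisation_set requires an hrpwm spec")
  sols <- vector("list", length(m_values))
  bad <- character(0)
  for (i in seq_along(m_values)) {
    sols[[i]] <- tryCatch(design_switching_angles(m_values[i]),
                          error = function(e) e)
    if (inherits(sols[[i]], "error")) {
      bad <- c(bad, format(m_values[i], digits = 4))
    }
  }
  if (length(bad)) {
    stop("infeasible modulation indices: ", paste(bad, collapse = ", "))
  }
  out <- vector("list", length(m_values))
  for (i in seq_along(m_values)) {
    sp <- spec
    sp$modulation_index <- m_values[i]
    out[[i]] <- synthesize(sp, angle_solution = sols[[i]])
  }
  fund <- vapply(out, function(w) {
    Mod(harmonic_levels(w, 1L)$complex_amplitudes[1])
  }, numeric(1))
  if (length(fund) > 1L) {
    dm <- diff(m_values)
    if (any(sign(diff(fund))[dm > 0] <= 0)) {
      stop("measured fundamental amplitudes are not strictly increasing in m")
    }
  }
  out
}
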
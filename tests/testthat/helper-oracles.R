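# Independent oracles used across the suite.  Each is written directly from
# the defining mathematics, not from the package's implementation path.

# Fourier sine coefficient b_n of the continuous quarter-wave-symmetric
# staircase defined by switching angles/steps, by brute-force numerical
# integration of the waveform itself (midpoint rule over one full cycle).
oracle_staircase_bn <- function(angles, steps, n, n_grid = 2e5) {
  theta <- (seq_len(n_grid) - 0.5) * 2 * pi / n_grid
  level <- vapply(theta, function(th) {
    # build the level directly from the symmetry definition
    thq <- th %% (2 * pi)
    sgn <- 1
    if (thq >= pi) {
      thq <- thq - pi
      sgn <- -1
    }
    if (thq > pi / 2) thq <- pi - thq
    sgn * sum(steps[angles <= thq])
  }, numeric(1))
  (2 / n_grid) * sum(level * sin(n * theta))
}

# O'Neil's closed-form on-axis pressure magnitude for a focused bowl
# (uniform surface pressure p0 = rho c u0), vertex at z = 0, focus at z = F.
oracle_oneil_axis <- function(z, k, Fv, a, p0 = 1) {
  depth <- Fv - sqrt(Fv^2 - a^2)
  ze <- sqrt(a^2 + (z - depth)^2)
  2 * p0 / abs(1 - z / Fv) * abs(sin(k * (ze - z) / 2))
}

# Brute-force Rayleigh--Sommerfeld surface quadrature over the bowl cap
# for a single off-axis field point (midpoint rule in both angles).
oracle_rs_point <- function(k, Fv, a, r0, z0, p0 = 1,
                            nth = 600L, nph = 1200L) {
  thmax <- asin(a / Fv)
  th <- (seq_len(nth) - 0.5) * thmax / nth
  ph <- (seq_len(nph) - 0.5) * 2 * pi / nph
  dth <- thmax / nth
  dph <- 2 * pi / nph
  tot <- 0 + 0i
  for (t in th) {
    zs <- Fv - Fv * cos(t)
    rs <- Fv * sin(t)
    R <- sqrt((z0 - zs)^2 + r0^2 + rs^2 - 2 * r0 * rs * cos(ph))
    tot <- tot + sum(exp(-1i * k * R) / R) * Fv^2 * sin(t) * dth * dph
  }
  Mod((1i * k * p0 / (2 * pi)) * tot)
}

# per-harmonic phasor true power of a periodic drive into a lumped load
oracle_phasor_power <- function(waveform, load, orders) {
  sp <- harmonic_levels(waveform, max(orders))
  sum(vapply(orders, function(h) {
    A <- sp$complex_amplitudes[h]
    Y <- load_admittance(load, h * waveform$centre_frequency)
    0.5 * Re(A * Conj(A * Y))
  }, numeric(1)))
}

# 3-d heat-kernel temperature rise for an instantaneous energy deposit E at
# the origin in an infinite medium
oracle_heat_kernel <- function(R, t, E, rho, Cp, kt) {
  D <- kt / (rho * Cp)
  E / (rho * Cp * (4 * pi * D * t)^1.5) * exp(-R^2 / (4 * D * t))
}
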
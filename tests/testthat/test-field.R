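water_only <- function() {
  medium_stack(list(list(name = "water", sound_speed = 1482, density = 1000,
                         absorption_coeff = 0, absorption_exponent = 1,
                         thickness = 80e-3)))
}

uniform_source <- function(h_amp) {
  structure(list(harmonic_orders = 1:6, frequencies = (1:6) * 1.1e6,
                 amplitude_pa = h_amp),
            class = "harmonic_sources")
}

test_that("the transfer function meets the band contract", {
  td <- transducer_model()
  g <- transfer_gain(td, c(1, 2, 3) * 1.1e6)
  expect_equal(g[1], 1, tolerance = 1e-12)        # normalised at f0
  expect_true(all(g > 0.9))                       # passband covers f0..3f0
  g_stop <- transfer_gain(td, seq(4, 6, by = 0.5) * 1.1e6)
  expect_true(all(g_stop < 10^(-40 / 20)))        # >= 40 dB at 4f0 and above
})

test_that("source amplitudes follow |A_h| |H| k_cal", {
  td <- transducer_model()
  ws <- synthesize(excitation_spec("sine", n_cycles = 4L))
  src_s <- source_amplitudes(harmonic_levels(ws, 6), td)
  expect_gt(src_s$amplitude_pa[1], 0)
  expect_true(all(src_s$amplitude_pa[-1] < 1e-6 * src_s$amplitude_pa[1]))

  wb <- synthesize(excitation_spec("bilevel", n_cycles = 4L))
  src_b <- source_amplitudes(harmonic_levels(wb, 6), td)
  expect_equal(src_b$amplitude_pa[3] / src_b$amplitude_pa[1], 1 / 3,
               tolerance = 0.02)
  # the transducer strips the drive's fifth harmonic
  expect_lt(src_b$amplitude_pa[5] / src_b$amplitude_pa[1], 10^(-40 / 20))
})

test_that("power calibration scales amplitudes to the target with ratios kept", {
  td <- transducer_model()
  area <- hrpwm:::bowl_cap_area(td)
  # single harmonic: closed-form plane-wave amplitude
  amp <- calibrate_power(c(1, 0, 0, 0, 0, 0), 26, rho = 1000, c = 1482,
                         area = area)
  expect_equal(amp[1], sqrt(26 * 2 * 1000 * 1482 / area), tolerance = 1e-12)

  # two harmonics with a 0.9/0.1 power split apportion 23.4 and 2.6 W
  a2 <- calibrate_power(c(3, 0, 1, 0, 0, 0), 26, rho = 1000, c = 1482,
                        area = area)
  p <- a2^2 / (2 * 1000 * 1482) * area
  expect_equal(p[1], 23.4, tolerance = 1e-9)
  expect_equal(p[3], 2.6, tolerance = 1e-9)

  # doubling the target scales amplitudes by sqrt(2)
  expect_equal(calibrate_power(c(3, 0, 1, 0, 0, 0), 52, area = area),
               sqrt(2) * a2, tolerance = 1e-12)
  expect_error(calibrate_power(rep(0, 6), 26), "all-zero")
})

test_that("the computed on-axis field matches the O'Neil closed form within 1 %", {
  td <- transducer_model()
  src <- uniform_source(c(1, 0, 0, 0, 0, 0))
  grid <- list(r = 1e-9, z = seq(20e-3, 78e-3, by = 0.5e-3),
               dr = 0.5e-3, dz = 0.5e-3)
  fm <- compute_field(td, water_only(), src, grid = grid, allow_coarse = TRUE)
  k <- 2 * pi * 1.1e6 / 1482
  zref <- grid$z[abs(grid$z - 63e-3) > 0.5e-3]
  oracle <- oracle_oneil_axis(zref, k, 63e-3, 32e-3, 1)
  got <- fm$pressure$h1[1, abs(grid$z - 63e-3) > 0.5e-3]
  expect_lt(max(abs(got - oracle) / oracle), 0.01)
})

test_that("off-axis field values match brute-force Rayleigh quadrature", {
  k <- 2 * pi * 1.1e6 / 1482
  pts <- list(c(1e-3, 63e-3), c(0.4e-3, 60e-3), c(5e-3, 50e-3))
  for (pt in pts) {
    got <- Mod(hrpwm:::bowl_field_expansion(k, 63e-3, 32e-3, 1,
                                            r = pt[1], z = pt[2]))[1, 1]
    expect_equal(got, oracle_rs_point(k, 63e-3, 32e-3, pt[1], pt[2]),
                 tolerance = 2e-3)
  }
})

test_that("the focal -6 dB beamwidth matches the measured 1.85 mm within 20 %", {
  td <- transducer_model()
  src <- uniform_source(c(1, 0, 0, 0, 0, 0))
  r <- seq(0.05e-3, 3e-3, by = 0.05e-3)
  grid <- list(r = r, z = 63e-3, dr = 0.05e-3, dz = 0.05e-3)
  fm <- compute_field(td, water_only(), src, grid = grid, allow_coarse = TRUE)
  prof <- fm$pressure$h1[, 1]
  i6 <- min(which(prof < prof[1] * 0.5))
  r6 <- stats::approx(prof[(i6 - 1):i6], r[(i6 - 1):i6],
                      xout = prof[1] * 0.5)$y
  expect_equal(2 * r6, 1.85e-3, tolerance = 0.2)
})

test_that("focal gain grows with harmonic order in lossless water and the
           tissue layer reverses it for strong absorption", {
  td <- transducer_model()
  src <- uniform_source(c(1, 0, 1, 0, 0, 0))
  grid <- list(r = 1e-9, z = 63e-3, dr = 1e-3, dz = 1e-3)
  fm_w <- compute_field(td, water_only(), src, grid = grid,
                        allow_coarse = TRUE)
  expect_gt(fm_w$pressure$h3[1, 1], fm_w$pressure$h1[1, 1])

  lossy <- medium_stack(list(
    list(name = "water", sound_speed = 1482, density = 1000,
         absorption_coeff = 0, absorption_exponent = 1, thickness = 23e-3),
    list(name = "tissue", sound_speed = 1547, density = 1060,
         absorption_coeff = 2.0, absorption_exponent = 1.1,
         thickness = 45e-3)))
  fm_t <- compute_field(td, lossy, src, grid = grid, allow_coarse = TRUE)
  expect_lt(fm_t$pressure$h3[1, 1], fm_t$pressure$h1[1, 1])
})

test_that("raising the absorption exponent lowers the focal p3/p1 ratio", {
  td <- transducer_model()
  src <- uniform_source(c(1, 0, 1, 0, 0, 0))
  grid <- list(r = 1e-9, z = 63e-3, dr = 1e-3, dz = 1e-3)
  ratio_at <- function(b) {
    media <- medium_stack(list(
      list(name = "water", sound_speed = 1482, density = 1000,
           absorption_coeff = 0, absorption_exponent = 1, thickness = 43e-3),
      list(name = "tissue", sound_speed = 1547, density = 1060,
           absorption_coeff = 0.52, absorption_exponent = b,
           thickness = 45e-3)))
    fm <- compute_field(td, media, src, grid = grid, allow_coarse = TRUE)
    fm$pressure$h3[1, 1] / fm$pressure$h1[1, 1]
  }
  ratios <- vapply(c(1.0, 1.3, 1.6), ratio_at, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("degenerate inputs are rejected or give empty fields", {
  td <- transducer_model()
  src0 <- uniform_source(rep(0, 6))
  fm <- compute_field(td, water_only(), src0,
                      grid = field_grid(spacing = 2e-3), allow_coarse = TRUE)
  expect_true(all(vapply(fm$pressure, max, numeric(1)) == 0))

  src <- uniform_source(c(1, 0, 0, 0, 0, 0))
  short <- list(r = 1e-3, z = seq(1e-3, 40e-3, by = 1e-3),
                dr = 1e-3, dz = 1e-3)
  expect_error(compute_field(td, water_only(), src, grid = short),
               "focus")
  expect_error(compute_field(td, water_only(), src,
                             grid = field_grid(spacing = 2e-3)),
               "allow_coarse")
})
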
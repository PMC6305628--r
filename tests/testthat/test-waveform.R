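test_that("two-angle designs match the closed-form solutions", {
  # m = 0.75 with H3 nulled: alpha = (0, 60) degrees
  sol <- design_switching_angles(0.75, 3)
  expect_equal(sol$angles, c(0, pi / 3), tolerance = 1e-4)
  expect_identical(sol$n_pulses_per_half_cycle, 1L)
  expect_lt(sol$residual_fundamental, 1e-9)
  expect_lt(max(sol$residual_harmonics), 1e-9)

  # m = sqrt(3)/2: degenerate double step at 30 degrees
  sol2 <- design_switching_angles(sqrt(3) / 2, 3)
  expect_equal(sol2$angles, c(pi / 6, pi / 6), tolerance = 1e-4)

  # deterministic: identical inputs give identical solutions
  expect_identical(design_switching_angles(0.7, 3),
                   design_switching_angles(0.7, 3))
})

test_that("designed waveforms satisfy the Fourier design equations (oracle)", {
  # brute-force Fourier integration of the continuous staircase must
  # reproduce the requested fundamental and null the targeted harmonics
  for (m in c(0.45, 0.6, 0.7, 0.85)) {
    sol <- design_switching_angles(m, 3)
    b1 <- oracle_staircase_bn(sol$angles, sol$steps, 1)
    expect_equal(b1, m * 8 / pi, tolerance = 1e-4)
    b3 <- oracle_staircase_bn(sol$angles, sol$steps, 3)
    expect_lt(abs(b3 / b1), 1e-4)
  }
})

test_that("the solver escalates to two pulses per half cycle for low m", {
  sol <- design_switching_angles(0.3, 3)
  expect_identical(sol$n_pulses_per_half_cycle, 2L)
  expect_length(sol$angles, 4L)
  expect_true(all(diff(sol$angles) >= -1e-9))
  b1 <- oracle_staircase_bn(sol$angles, sol$steps, 1)
  expect_equal(b1, 0.3 * 8 / pi, tolerance = 1e-4)
  for (n in c(3, 5, 7)) {
    expect_lt(abs(oracle_staircase_bn(sol$angles, sol$steps, n) / b1), 1e-4)
  }
})

test_that("infeasible modulation indices raise errors naming the band", {
  expect_error(design_switching_angles(1.0, 3), "0.433.*0.866")
  expect_error(design_switching_angles(0.7, c(2, 3)), "subset")
  expect_error(design_switching_angles(-0.1, 3), "modulation_index")
})

test_that("bilevel synthesis honours the duty cycle exactly", {
  spec <- excitation_spec("bilevel", centre_frequency = 1e6, duty_cycle = 0.5,
                          n_cycles = 3L, sample_rate = 32e6)
  w <- synthesize(spec)
  one_cycle <- w$levels[1:32]
  expect_identical(sum(one_cycle == 1L), 16L)
  expect_identical(sum(one_cycle == -1L), 16L)
  # half-wave antisymmetry at 50 % duty
  expect_identical(w$levels[1:16], -w$levels[17:32])
  w2 <- synthesize(excitation_spec("bilevel", centre_frequency = 1e6,
                                   duty_cycle = 0.25, n_cycles = 1L,
                                   sample_rate = 32e6))
  expect_identical(sum(w2$levels == 1L), 8L)
})

test_that("hrpwm switching instants are quantised to the designed angles", {
  # m = 0.75 -> angles (0, 60) degrees -> steps at samples 0 and 60 of a
  # 360-sample cycle, with the mirrored transitions at 120 and 180
  spec <- excitation_spec("hrpwm", centre_frequency = 1e6,
                          modulation_index = 0.75, n_cycles = 1L,
                          sample_rate = 360e6)
  w <- synthesize(spec)
  expect_identical(w$levels[1], 1L)             # step at sample 0
  expect_identical(w$levels[60], 1L)
  expect_identical(w$levels[61], 2L)            # step at sample 60
  expect_identical(w$levels[121], 1L)           # mirrored step down
  expect_identical(w$levels[181], -1L)          # half-wave antisymmetry
  expect_identical(w$levels[1:180], -w$levels[181:360])
  # quarter-wave symmetry of the level sequence; a transition landing
  # exactly on a sample takes its new level there, so each switching angle
  # may contribute one boundary mismatch
  expect_lte(sum(w$levels[2:90] != rev(w$levels[92:180])), 2L)
})

test_that("the sine reference is a clean sampled sinusoid", {
  spec <- excitation_spec("sine", modulation_index = 0.6, n_cycles = 4L,
                          rail_step = 25)
  w <- synthesize(spec)
  v <- waveform_volts(w)
  expect_equal(max(abs(v)), 0.6 * 2 * 25, tolerance = 1e-3)
  sp <- harmonic_levels(w, 6)
  expect_true(all(sp$levels_db[-1] < -80))
})

test_that("quantised fundamental tracks the design within 2 % at >= 64 samples/cycle", {
  for (m in c(0.5, 0.7, 0.85)) {
    sol <- design_switching_angles(m, 3)
    b1_design <- oracle_staircase_bn(sol$angles, sol$steps, 1) * 30
    spec <- excitation_spec("hrpwm", modulation_index = m, n_cycles = 8L,
                            sample_rate = 64 * 1.1e6)
    meas <- Mod(harmonic_levels(synthesize(spec), 1)$complex_amplitudes[1])
    expect_equal(meas, b1_design, tolerance = 0.02)
  }
})

test_that("quantisation error of the fundamental shrinks as sampling doubles", {
  sol <- design_switching_angles(0.7, 3)
  b1_design <- oracle_staircase_bn(sol$angles, sol$steps, 1) * 30
  errs <- vapply(c(32, 64, 128, 256, 512), function(spc) {
    spec <- excitation_spec("hrpwm", modulation_index = 0.7, n_cycles = 8L,
                            sample_rate = spc * 1.1e6)
    abs(Mod(harmonic_levels(synthesize(spec), 1)$complex_amplitudes[1]) -
          b1_design) / b1_design
  }, numeric(1))
  # monotone within measurement noise: allow small non-monotonic jitter but
  # require a clear overall decrease
  expect_true(all(errs[-1] <= errs[-5] * 1.5))
  expect_lt(errs[5], errs[1] / 4)
})

test_that("sample-rate floor and invariant violations are rejected", {
  expect_error(excitation_spec("hrpwm", sample_rate = 16 * 1.1e6), "32")
  expect_error(excitation_spec("sine", modulation_index = 1.2), "\\[0, 1\\]")
  expect_error(excitation_spec("bilevel", duty_cycle = 1), "duty")
  w <- synthesize(excitation_spec("bilevel", n_cycles = 2L))
  expect_identical(length(w$levels),
                   as.integer(round(2 * w$sample_rate / w$centre_frequency)))
})

test_that("apodisation sets keep rails fixed and fundamentals ordered", {
  set <- apodisation_set(c(0.5, 0.6, 0.7))
  expect_length(set, 3L)
  expect_true(all(vapply(set, function(w) w$rail_step, numeric(1)) ==
                    set[[1]]$rail_step))
  funds <- vapply(set, function(w) {
    Mod(harmonic_levels(w, 1)$complex_amplitudes[1])
  }, numeric(1))
  expect_true(all(diff(funds) > 0))

  # duplicated m gives identical waveforms
  pair <- apodisation_set(c(0.7, 0.7))
  expect_identical(pair[[1]]$levels, pair[[2]]$levels)

  # infeasible entries are reported
  expect_error(apodisation_set(c(0.7, 1.0)), "1")
})

test_that("apodisation reproduces the square-root power-scaling operating points", {
  # electrical power scales with amplitude^2: the 16/26/35 W points scaled
  # from a 26 W reference need fundamentals in ratio sqrt(16/26), 1,
  # sqrt(35/26)
  m_ref <- 0.7
  m_set <- m_ref * sqrt(c(16, 26, 35) / 26)
  # high sampling fidelity so switching-instant quantisation does not mask
  # the amplitude-scaling law under test
  set <- apodisation_set(m_set,
                         spec = excitation_spec("hrpwm",
                                                sample_rate = 512 * 1.1e6))
  funds <- vapply(set, function(w) {
    Mod(harmonic_levels(w, 1)$complex_amplitudes[1])
  }, numeric(1))
  expect_equal(funds / funds[2], sqrt(c(16, 26, 35) / 26), tolerance = 0.02)
})
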
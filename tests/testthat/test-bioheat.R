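dummy_field <- function(p_list, dr = 5e-4, dz = 5e-4) {
  nr <- nrow(p_list[[1]]); nz <- ncol(p_list[[1]])
  pres <- lapply(1:6, function(h) {
    if (h <= length(p_list) && !is.null(p_list[[h]])) p_list[[h]]
    else matrix(0, nr, nz)
  })
  names(pres) <- paste0("h", 1:6)
  structure(list(r = (seq_len(nr) - 0.5) * dr, z = (seq_len(nz) - 0.5) * dz,
                 dr = dr, dz = dz, pressure = pres,
                 frequencies = (1:6) * 1.1e6, scaled_down = TRUE),
            class = "field_map")
}

test_that("the heating rate is alpha p^2 / (rho c), additive and quadratic", {
  props <- thermal_properties(density = 1000, sound_speed = 1500)
  p <- matrix(1e6, 4, 5)
  Q1 <- heating_rate(dummy_field(list(p)), props, c(5, 0, 0, 0, 0, 0))
  expect_equal(Q1[1, 1], 5 * 1e12 / 1.5e6, tolerance = 1e-12)

  # six equal harmonics: exactly six times the single-harmonic rate
  Q6 <- heating_rate(dummy_field(rep(list(p), 6)), props, rep(5, 6))
  expect_equal(max(abs(Q6 - 6 * Q1)), 0)

  # doubling the pressure quadruples the rate
  Q2 <- heating_rate(dummy_field(list(2 * p)), props, c(5, 0, 0, 0, 0, 0))
  expect_equal(max(abs(Q2 - 4 * Q1)), 0)

  bad <- list(matrix(1, 3, 3))
  expect_error(heating_rate(dummy_field(list(p)), props,
                            list(matrix(5, 3, 3))), "grid")
})

test_that("zero heating leaves the field in equilibrium", {
  props <- thermal_properties()
  Q <- matrix(0, 15, 20)
  sol <- pennes_solve(Q, props, t_on = 2, t_cool = 1, dt = 0.05,
                      dr = 5e-4, dz = 5e-4)
  expect_identical(max(abs(sol$T_final - 37)), 0)
  expect_equal(max(sol$cem43), cem43(matrix(37, 1, 1), 3)[1, 1])
})

test_that("conduction-free uniform heating ramps linearly then holds", {
  props <- thermal_properties(conductivity = 0)
  Q <- matrix(2e6, 8, 8)
  sol <- pennes_solve(Q, props, t_on = 2, t_cool = 1, dt = 0.01,
                      dr = 5e-4, dz = 5e-4)
  ramp <- 2e6 * 2 / (props$density * props$specific_heat)
  expect_equal(sol$T_final[4, 4], 37 + ramp, tolerance = 1e-12)
  expect_equal(max(sol$T_final) - min(sol$T_final), 0)
})

test_that("a point deposit spreads like the heat-kernel Gaussian within 2 %", {
  props <- thermal_properties(perfusion_rate = 0)
  nr <- 60L; nz <- 121L
  dr <- dz <- 2e-4
  Q <- matrix(0, nr, nz)
  dt <- 0.004
  Q[1, 61] <- 1e9                       # single axis cell, one step of heat
  sol <- pennes_solve(Q, props, t_on = dt, t_cool = 2 - dt, dt = dt,
                      dr = dr, dz = dz, store_every = 1e6)
  E <- 1e9 * dt * pi * dr^2 * dz        # energy into the axis cell volume
  z <- (seq_len(nz) - 0.5) * dz
  Rdist <- abs(z - z[61])
  t_end <- 2
  pred <- oracle_heat_kernel(Rdist, t_end, E, props$density,
                             props$specific_heat, props$conductivity)
  got <- sol$T_final[1, ] - 37
  sel <- pred > 0.05 * max(pred)
  expect_lt(max(abs(got[sel] - pred[sel]) / max(pred)), 0.02)
})

test_that("the stability bound is enforced with a helpful maximum", {
  props <- thermal_properties()
  Q <- matrix(0, 10, 10)
  expect_error(pennes_solve(Q, props, dt = 10, dr = 5e-4, dz = 5e-4),
               "maximum stable dt")
})

test_that("insulated no-perfusion runs conserve deposited energy within 1 %", {
  props <- thermal_properties(perfusion_rate = 0)
  nr <- 25L; nz <- 30L; dr <- dz <- 5e-4
  Q <- matrix(0, nr, nz)
  Q[5:10, 12:18] <- 3e7
  sol <- pennes_solve(Q, props, t_on = 6, t_cool = 4, dt = 0.05,
                      dr = dr, dz = dz)
  rc <- (seq_len(nr) - 0.5) * dr
  vol <- outer(2 * pi * rc * dr, rep(dz, nz))
  enthalpy <- sum((sol$T_final - 37) * vol) * props$density *
    props$specific_heat
  deposited <- sum(Q * vol) * 6
  expect_equal(enthalpy / deposited, 1, tolerance = 0.01)
})

test_that("perfusion pulls the temperature back towards blood", {
  props0 <- thermal_properties(perfusion_rate = 0)
  props1 <- thermal_properties(perfusion_rate = 0.01)
  Q <- matrix(1e6, 10, 10)
  s0 <- pennes_solve(Q, props0, t_on = 5, t_cool = 5, dt = 0.02,
                     dr = 5e-4, dz = 5e-4)
  s1 <- pennes_solve(Q, props1, t_on = 5, t_cool = 5, dt = 0.02,
                     dr = 5e-4, dz = 5e-4)
  expect_lt(max(s1$T_final), max(s0$T_final))
})

test_that("CEM43 reproduces the Sapareto-Dewey closed forms", {
  expect_equal(cem43(matrix(43, 1, 1), dt = 240 * 60)[1, 1], 240)
  expect_equal(cem43(matrix(47, 1, 1), dt = 15 * 60)[1, 1], 2^4 * 15)
  expect_lt(cem43(matrix(37, 1, 1), dt = 30)[1, 1], 1e-3)
  # monotone in exposure time and in temperature
  expect_gt(cem43(matrix(45, 1, 1), 60)[1, 1],
            cem43(matrix(45, 1, 1), 30)[1, 1])
  expect_gt(cem43(matrix(46, 1, 1), 60)[1, 1],
            cem43(matrix(45, 1, 1), 60)[1, 1])
  expect_error(cem43(matrix(NaN, 1, 1), 1), "finite")
})

test_that("lesion metrics recover analytic areas and handle references", {
  dr <- dz <- 2.5e-4
  r <- (seq_len(40) - 0.5) * dr
  z <- (seq_len(120) - 0.5) * dz
  dose <- outer(r, z, function(r, z) {
    ifelse((z - 15e-3)^2 / 5e-3^2 + r^2 / 1.5e-3^2 <= 1, 300, 0)
  })
  lm <- lesion_metrics(dose, dr = dr, dz = dz)
  # half-ellipse region of semi-axes 5 x 1.5 mm: full cross-section area
  # pi a b, within one cell ring
  ring <- 2 * (pi * (5 + 1.5)) * (dr * 1e3) * 1  # generous one-ring bound
  expect_lt(abs(lm$area_mm2 - pi * 5 * 1.5), ring)
  expect_equal(lm$axial_extent_mm, 10, tolerance = 0.11)

  # all-below-threshold dose: empty lesion
  lm0 <- lesion_metrics(dose * 0, dr = dr, dz = dz)
  expect_identical(lm0$area_mm2, 0)

  # identical run against itself: zero percent change
  lm_self <- lesion_metrics(dose, reference = dose, dr = dr, dz = dz)
  expect_identical(lm_self$pct_change_vs_reference, 0)
  expect_error(lesion_metrics(dose, reference = dose * 0, dr = dr, dz = dz),
               "empty")
})

test_that("lesion area is monotone non-decreasing in acoustic power", {
  # Gaussian focal heat deposit scaled to the 16/26/35 W operating points
  props <- thermal_properties()
  nr <- 30L; nz <- 60L; dr <- dz <- 5e-4
  r <- (seq_len(nr) - 0.5) * dr
  z <- (seq_len(nz) - 0.5) * dz
  base <- outer(r, z, function(r, z) {
    4e7 * exp(-(r / 1e-3)^2 - ((z - 15e-3) / 4e-3)^2)
  })
  areas <- vapply(c(16, 26, 35) / 26, function(sc) {
    sol <- pennes_solve(base * sc, props, t_on = 20, t_cool = 10, dt = 0.05,
                        dr = dr, dz = dz, store_every = 1e6)
    lesion_metrics(sol)$area_mm2
  }, numeric(1))
  expect_true(all(diff(areas) >= 0))
  expect_gt(areas[3], areas[1])
})
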
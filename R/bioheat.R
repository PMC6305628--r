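#' Thermal and acoustic absorption properties for dose modelling
#'
#' @param density tissue density rho, kg/m^3.
#' @param sound_speed c, m/s (enters the heating rate through rho*c).
#' @param specific_heat C_p, J/(kg K).
#' @param conductivity k_t, W/(m K).
#' @param perfusion_rate blood perfusion w_b, 1/s (default 0: the
#'   comparison runs emulate ex-vivo tissue; a literature in-vivo value can
#'   be supplied through the configuration).
#' @param blood_temperature arterial blood temperature, degrees C.
#' @param blood_density,blood_specific_heat blood properties for the
#'   perfusion sink term.
#' @return an object of class `thermal_properties`.
#' @export
thermal_properties <- function(density = 1060,
                               sound_speed = 1547,
                               specific_heat = 3600,
                               conductivity = 0.49,
                               perfusion_rate = 0,
                               blood_temperature = 37,
                               blood_density = 1050,
                               blood_specific_heat = 3617) {
  vals <- c(density, sound_speed, specific_heat,
            blood_density, blood_specific_heat)
  if (any(vals <= 0)) stop("thermal properties must be positive")
  if (conductivity < 0) stop("conductivity must be >= 0")
  if (perfusion_rate < 0) stop("perfusion_rate must be >= 0")
  structure(list(density = density, sound_speed = sound_speed,
                 specific_heat = specific_heat, conductivity = conductivity,
                 perfusion_rate = perfusion_rate,
                 blood_temperature = blood_temperature,
                 blood_density = blood_density,
                 blood_specific_heat = blood_specific_heat),
            class = "thermal_properties")
}

#' Volumetric heating rate from per-harmonic pressure fields
#'
#' The plane-wave absorption heating rate summed over the first six
#' harmonics,
#' \deqn{Q = \sum_{h=1}^{6} \alpha_h p_h^2 / (\rho c),}
#' with `alpha_h` the absorption coefficient (Np/m) at each harmonic.
#'
#' @param field a [compute_field()] result.
#' @param props a [thermal_properties()] object supplying `rho * c`.
#' @param alpha_np_m numeric vector of absorption coefficients (Np/m) for
#'   harmonics 1..6, or a list of matrices on the field grid for
#'   spatially varying absorption.
#' @return matrix of Q in W/m^3 on the field grid, with attributes `r`,
#'   `z`, `dr`, `dz` copied from the field.
#' @export
heating_rate <- function(field, props, alpha_np_m) {
  stopifnot(inherits(field, "field_map"),
            inherits(props, "thermal_properties"))
  rhoc <- props$density * props$sound_speed
  Q <- matrix(0, length(field$r), length(field$z))
  for (h in 1:6) {
    p <- field$pressure[[h]]
    if (max(p) == 0) next
    a_h <- if (is.list(alpha_np_m)) alpha_np_m[[h]] else alpha_np_m[h]
    if (is.matrix(a_h) && !all(dim(a_h) == dim(p))) {
      stop("absorption grid does not match the field grid")
    }
    if (is.null(a_h) || anyNA(a_h)) {
      stop("alpha_np_m must be defined for every populated harmonic")
    }
    Q <- Q + a_h * p^2 / rhoc
  }
  attr(Q, "r") <- field$r; attr(Q, "z") <- field$z
  attr(Q, "dr") <- field$dr; attr(Q, "dz") <- field$dz
  Q
}

# maximum stable explicit time step for the axisymmetric scheme
pennes_stable_dt <- function(props, dr, dz) {
  D <- props$conductivity / (props$density * props$specific_heat)
  # finite-volume radial operator has coefficient sum <= 2/dr^2 everywhere
  # (including the axis cell); safety factor 0.9
  0.9 / (2 * D * (1 / dr^2 + 1 / dz^2))
}

#' Explicit Pennes bioheat solution on the axisymmetric grid
#'
#' Solves
#' \deqn{\rho C_p \partial T/\partial t = k_t \nabla^2 T
#'       - w_b \rho_b C_b (T - T_b) + Q}
#' with an explicit finite-volume scheme in cylindrical (r, z) coordinates:
#' zero-flux (insulated) outer boundaries, natural symmetry at the axis, and
#' the source switched off after `t_on`.  The time step must satisfy the
#' explicit stability bound (checked; the error message names the maximum
#' stable step).
#'
#' @param Q heating-rate matrix from [heating_rate()] (W/m^3), carrying the
#'   grid attributes, or a bare matrix with `dr`/`dz` supplied.
#' @param props a [thermal_properties()].
#' @param t_on insonation time, s (default 20).
#' @param t_cool cooling time after switch-off, s (default 10).
#' @param T0 starting temperature, degrees C (default 37).
#' @param dt time step, s; default half the stability bound.
#' @param dr,dz grid spacings when `Q` has no attributes.
#' @param store_every store a temperature snapshot every this many steps
#'   (the full per-step history is used internally for dosimetry; snapshots
#'   bound memory).
#' @return an object of class `pennes_solution`: `times`, `snapshots`
#'   (list of matrices), `T_final`, `T_peak` (running maximum field),
#'   `cem43` (minutes, accumulated per step at full time resolution),
#'   `dt`, grid info.
#' @export
pennes_solve <- function(Q, props, t_on = 20, t_cool = 10, T0 = 37,
                         dt = NULL, dr = attr(Q, "dr"), dz = attr(Q, "dz"),
                         store_every = 50L) {
  stopifnot(inherits(props, "thermal_properties"))
  if (is.null(dr) || is.null(dz)) stop("grid spacings dr/dz are required")
  nr <- nrow(Q); nz <- ncol(Q)
  dt_max <- pennes_stable_dt(props, dr, dz)
  if (is.null(dt)) dt <- dt_max / 2
  if (dt > dt_max) {
    stop(sprintf("dt = %.4g s violates the explicit stability bound; maximum stable dt is %.4g s",
                 dt, dt_max))
  }
  rho <- props$density; Cp <- props$specific_heat; kt <- props$conductivity
  wb <- props$perfusion_rate
  perf <- wb * props$blood_density * props$blood_specific_heat
  Tb <- props$blood_temperature

  # finite-volume radial face areas (per unit cell volume)
  rc <- (seq_len(nr) - 0.5) * dr          # cell centres
  rf_in <- (seq_len(nr) - 1) * dr         # inner faces (0 at the axis)
  rf_out <- seq_len(nr) * dr              # outer faces
  w_in <- rf_in / (rc * dr^2)             # zero at the axis: natural symmetry
  w_out <- rf_out / (rc * dr^2)
  w_out[nr] <- 0                          # insulated outer radial boundary

  n_on <- round(t_on / dt)
  n_total <- round((t_on + t_cool) / dt)
  Tm <- matrix(T0, nr, nz)
  cem <- matrix(0, nr, nz)
  Tpeak <- Tm
  snapshots <- list(); times <- numeric(0)
  Qdt <- Q * dt / (rho * Cp)
  lap_fac <- kt * dt / (rho * Cp)

  for (step in seq_len(n_total)) {
    # radial conduction
    up <- rbind(Tm[-1, , drop = FALSE], Tm[nr, ])     # neighbour r+1 (reflux at edge)
    dn <- rbind(Tm[1, ], Tm[-nr, , drop = FALSE])     # neighbour r-1
    lap_r <- w_out * (up - Tm) - w_in * (Tm - dn)
    # axial conduction, zero-flux ends
    rt <- cbind(Tm[, -1, drop = FALSE], Tm[, nz])
    lt <- cbind(Tm[, 1], Tm[, -nz, drop = FALSE])
    lap_z <- (rt - 2 * Tm + lt) / dz^2
    Tm <- Tm + lap_fac * (lap_r + lap_z) -
      perf * dt / (rho * Cp) * (Tm - Tb)
    if (step <= n_on) Tm <- Tm + Qdt
    Tpeak <- pmax(Tpeak, Tm)
    # Sapareto--Dewey accumulation at full time resolution
    Rfac <- ifelse(Tm >= 43, 0.5, 0.25)
    cem <- cem + Rfac^(43 - Tm) * (dt / 60)
    if (step %% store_every == 0L || step == n_total) {
      snapshots[[length(snapshots) + 1L]] <- Tm
      times <- c(times, step * dt)
    }
  }
  structure(list(times = times, snapshots = snapshots, T_final = Tm,
                 T_peak = Tpeak, cem43 = cem, dt = dt, dr = dr, dz = dz,
                 t_on = t_on, t_cool = t_cool, T0 = T0),
            class = "pennes_solution")
}

#' @export
print.pennes_solution <- function(x, ...) {
  cat("<pennes_solution>\n")
  cat(sprintf("  %d x %d grid, dt %.4g s, %g s on + %g s cool from %g degC\n",
              nrow(x$T_final), ncol(x$T_final), x$dt, x$t_on, x$t_cool, x$T0))
  cat(sprintf("  peak temperature %.2f degC, peak CEM43 %.3g min\n",
              max(x$T_peak), max(x$cem43)))
  invisible(x)
}

#' Cumulative equivalent minutes at 43 degrees C
#'
#' Sapareto--Dewey thermal dose of a temperature history:
#' `CEM43 = sum_t R^(43 - T(t)) dt` (minutes), with `R = 0.5` at or above
#' 43 degrees C and `R = 0.25` below.
#'
#' @param T_history a matrix (single snapshot), a list of matrices, or a
#'   3-d array with time as the last dimension, in degrees C.
#' @param dt time spacing of the history, seconds.
#' @return matrix of CEM43 in minutes.
#' @export
cem43 <- function(T_history, dt) {
  if (is.matrix(T_history)) T_history <- list(T_history)
  if (is.array(T_history) && length(dim(T_history)) == 3L) {
    T_history <- lapply(seq_len(dim(T_history)[3]),
                        function(i) T_history[, , i])
  }
  if (!all(vapply(T_history, function(m) all(is.finite(m)), logical(1)))) {
    stop("temperature history must be finite")
  }
  acc <- 0
  for (Tm in T_history) {
    Rfac <- ifelse(Tm >= 43, 0.5, 0.25)
    acc <- acc + Rfac^(43 - Tm) * (dt / 60)
  }
  acc
}

#' Lesion geometry from a thermal-dose map
#'
#' Thresholds the CEM43 map (default 240 equivalent minutes, the
#' coagulative-necrosis threshold used for lesion prediction), and reports
#' the lesion cross-section through the beam axis: area, axial and radial
#' extents, and optionally the percentage change against a reference run.
#' The cross-section area counts each cell of the axisymmetric half-plane
#' twice (both sides of the axis), matching how a sliced lesion is
#' photographed and measured.
#'
#' @param dose CEM43 matrix in minutes (half-plane, r by z), with grid
#'   spacing either attached (a `pennes_solution`) or given via `dr`/`dz`.
#' @param threshold lesion threshold in equivalent minutes (default 240).
#' @param reference optional reference result of `lesion_metrics` (or a
#'   dose matrix on the same grid) for the percentage change.
#' @param dr,dz grid spacing in metres.
#' @return an object of class `lesion_metrics`: `mask`, `area_mm2`,
#'   `axial_extent_mm`, `radial_extent_mm`, `threshold`, and
#'   `pct_change_vs_reference` when a reference is supplied.
#' @export
lesion_metrics <- function(dose, threshold = 240, reference = NULL,
                           dr = NULL, dz = NULL) {
  if (inherits(dose, "pennes_solution")) {
    dr <- dose$dr; dz <- dose$dz; dose <- dose$cem43
  }
  if (is.null(dr) || is.null(dz)) stop("grid spacings dr/dz are required")
  mask <- dose >= threshold
  n_cells <- sum(mask)
  area_mm2 <- 2 * n_cells * (dr * 1e3) * (dz * 1e3)
  ax <- if (n_cells) diff(range(which(apply(mask, 2, any)))) + 1L else 0L
  rd <- if (n_cells) max(which(apply(mask, 1, any))) else 0L
  out <- list(mask = mask, area_mm2 = area_mm2,
              axial_extent_mm = ax * dz * 1e3,
              radial_extent_mm = 2 * rd * dr * 1e3,
              threshold = threshold, dr = dr, dz = dz)
  if (!is.null(reference)) {
    ref_area <- if (inherits(reference, "lesion_metrics")) {
      reference$area_mm2
    } else {
      lesion_metrics(reference, threshold = threshold, dr = dr, dz = dz)$area_mm2
    }
    if (ref_area == 0) {
      stop("reference lesion is empty; percentage change is undefined")
    }
    out$pct_change_vs_reference <- 100 * (area_mm2 - ref_area) / ref_area
  }
  structure(out, class = "lesion_metrics")
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat(sprintf("<lesion_metrics>  area %.2f mm^2 (threshold %g min), axial %.1f mm, radial %.2f mm\n",
              x$area_mm2, x$threshold, x$axial_extent_mm, x$radial_extent_mm))
  if (!is.null(x$pct_change_vs_reference)) {
    cat(sprintf("  change vs reference: %+.1f%%\n", x$pct_change_vs_reference))
  }
  invisible(x)
}
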
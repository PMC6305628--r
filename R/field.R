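#' Layered propagation medium
#'
#' An ordered stack of homogeneous layers along the beam axis, each with a
#' sound speed, density and power-law absorption
#' `alpha(f) = absorption_coeff * (f/1 MHz)^absorption_exponent` in dB/cm.
#' The default stack is a water path with a 45 mm tissue layer positioned so
#' the transducer focus sits 20 mm deep in the tissue; the stand-in tissue
#' values are literature chicken-muscle parameters and every number is
#' overridable.
#'
#' The diffraction pattern is computed at the first (coupling) layer's sound
#' speed; layer sound speeds beyond that enter only through the impedance
#' and absorption bookkeeping (refraction is neglected in this linear
#' surrogate).
#'
#' @param layers list of layers; each a list with `name`, `sound_speed`
#'   (m/s), `density` (kg/m^3), `absorption_coeff` (dB/(cm MHz^b)),
#'   `absorption_exponent` (b), `thickness` (m).
#' @return an object of class `medium_stack`.
#' @export
medium_stack <- function(layers = list(
    list(name = "water", sound_speed = 1482, density = 1000,
         absorption_coeff = 0, absorption_exponent = 1, thickness = 43e-3),
    list(name = "tissue", sound_speed = 1547, density = 1060,
         absorption_coeff = 0.52, absorption_exponent = 1.1,
         thickness = 45e-3))) {
  need <- c("name", "sound_speed", "density", "absorption_coeff",
            "absorption_exponent", "thickness")
  for (ly in layers) {
    if (!all(need %in% names(ly))) {
      stop("each layer needs fields: ", paste(need, collapse = ", "))
    }
    if (ly$thickness <= 0) stop("layer thicknesses must be positive")
    if (ly$sound_speed <= 0 || ly$density <= 0) {
      stop("layer sound speed and density must be positive")
    }
    if (ly$absorption_coeff < 0) stop("absorption must be non-negative")
  }
  structure(list(layers = layers), class = "medium_stack")
}

#' @export
print.medium_stack <- function(x, ...) {
  cat("<medium_stack>\n")
  z0 <- 0
  for (ly in x$layers) {
    cat(sprintf("  %-8s z = %5.1f..%5.1f mm  c %.0f m/s  rho %.0f  alpha %.3g dB/(cm MHz^%.2g)\n",
                ly$name, z0 * 1e3, (z0 + ly$thickness) * 1e3, ly$sound_speed,
                ly$density, ly$absorption_coeff, ly$absorption_exponent))
    z0 <- z0 + ly$thickness
  }
  invisible(x)
}

# layer boundaries (z from the transducer face) and helpers
stack_boundaries <- function(media) {
  th <- vapply(media$layers, `[[`, numeric(1), "thickness")
  c(0, cumsum(th))
}

# the layer containing depth z (last layer extended beyond the stack)
stack_layer_at <- function(media, z) {
  b <- stack_boundaries(media)
  idx <- findInterval(z, b, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > length(media$layers)] <- length(media$layers)
  idx
}

# amplitude attenuation in nepers accumulated along the axial path 0..z at
# frequency f (Hz), from the per-layer power law (dB/cm -> Np/m: x 100 ln10/20)
stack_path_nepers <- function(media, z, f) {
  b <- stack_boundaries(media)
  total <- numeric(length(z))
  for (i in seq_along(media$layers)) {
    ly <- media$layers[[i]]
    alpha_np_m <- ly$absorption_coeff * (f / 1e6)^ly$absorption_exponent *
      100 * log(10) / 20
    seg <- pmin(pmax(z - b[i], 0), ly$thickness)
    # the last layer extends to cover any grid beyond the stack
    if (i == length(media$layers)) seg <- pmax(z - b[i], 0) * (z > b[i])
    total <- total + alpha_np_m * seg
  }
  total
}

# absorption coefficient (Np/m) of the layer at each depth z, frequency f
stack_alpha_at <- function(media, z, f) {
  idx <- stack_layer_at(media, z)
  vapply(seq_along(z), function(j) {
    ly <- media$layers[[idx[j]]]
    ly$absorption_coeff * (f / 1e6)^ly$absorption_exponent * 100 * log(10) / 20
  }, numeric(1))
}

#' Axisymmetric field grid
#'
#' Cell-centred (r, z) grid covering half of the simulation plane:
#' `r` spans `[0, width/2]`, `z` spans `[0, depth]` from the transducer
#' face, with the cell centres at odd half-multiples of the spacing.
#'
#' @param spacing grid spacing in metres (default 112 um).
#' @param width full lateral extent in metres (default 64 mm).
#' @param depth axial extent in metres (default 78 mm).
#' @return list with `r`, `z` (cell-centre coordinates), `dr`, `dz`.
#' @export
field_grid <- function(spacing = 112e-6, width = 64e-3, depth = 78e-3) {
  nr <- round(width / 2 / spacing)
  nz <- round(depth / spacing)
  list(r = (seq_len(nr) - 0.5) * spacing,
       z = (seq_len(nz) - 0.5) * spacing,
       dr = spacing, dz = spacing)
}

# Pressure field of a uniformly vibrating spherical-cap (focused bowl)
# radiator in a lossless homogeneous medium, evaluated by the
# spherical-wave (Gegenbauer addition theorem) expansion of the
# Rayleigh--Sommerfeld integral about the geometric focus.  Exact on
# convergence; accuracy degrades only in a thin shell of points at
# distance ~F from the focus (i.e. near the source surface itself).
#
# k: wavenumber (rad/m); Fv: focal length; a: rim radius; p0: surface
# pressure amplitude (rho c u0); r, z: cell-centre coordinate vectors
# (z measured from the bowl vertex along the beam axis).
# Returns the complex pressure matrix (length(r) x length(z)).
bowl_field_expansion <- function(k, Fv, a, p0, r, z, chunk = 1024L) {
  mu0 <- sqrt(Fv^2 - a^2) / Fv
  xF <- k * Fv
  # field-point polar coordinates about the focus, axis towards the vertex
  pts <- expand.grid(r = r, z = z)
  rf <- sqrt(pts$r^2 + (pts$z - Fv)^2)
  mu <- ifelse(rf > 0, (Fv - pts$z) / rf, 1)
  x <- k * rf

  nmax <- ceiling(xF + 10 * xF^(1 / 3) + 60)
  # cap-integral coefficients c_n = P_{n-1}(mu0) - P_{n+1}(mu0), c_0 = 1 - mu0
  Pm <- numeric(nmax + 2L)            # P_n(mu0), n = 0..nmax+1
  Pm[1] <- 1; Pm[2] <- mu0
  for (n in 1:nmax) {
    Pm[n + 2L] <- ((2 * n + 1) * mu0 * Pm[n + 1L] - n * Pm[n]) / (n + 1)
  }
  cn <- c(1 - mu0, Pm[seq_len(nmax)] - Pm[seq_len(nmax) + 2L])

  # spherical Bessel functions at the fixed source radius kF
  nu <- (0:nmax) + 0.5
  sc <- sqrt(pi / (2 * xF))
  jF <- sc * besselJ(xF, nu)
  yF <- sc * besselY(xF, nu)

  out <- complex(length(x))
  n_pts <- length(x)
  for (lo in seq(1L, n_pts, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_pts)
    xi <- pmax(x[lo:hi], 1e-12)
    mui <- mu[lo:hi]
    nc <- length(xi)
    inner <- xi < xF                     # field point inside the source sphere

    # backward continued fraction for the minimal-solution ratios
    # s_n = j_{n+1}(x)/j_n(x); forward products then give j_n stably for
    # all orders with no overflow (values only decay past the turning point)
    S <- matrix(0, nmax + 1L, nc)
    s <- numeric(nc)                     # seed s_{N2} = 0 well above nmax
    for (n in (nmax + 30L):0L) {
      s <- xi / ((2 * n + 3) - xi * s)
      if (n <= nmax) S[n + 1L, ] <- s
    }

    # forward/upward recurrences: j via stored ratios, y and P directly
    j_cur <- sin(xi) / xi
    y_cur <- -cos(xi) / xi
    y_prev <- numeric(nc)
    P_cur <- rep(1, nc)
    P_prev <- numeric(nc)

    acc <- complex(length.out = nc)
    for (n in 0:nmax) {
      hF <- complex(real = jF[n + 1L], imaginary = -yF[n + 1L])
      term <- complex(length.out = nc)
      if (any(inner)) {
        term[inner] <- jn_part <- j_cur[inner] * hF
      }
      if (any(!inner)) {
        term[!inner] <- jF[n + 1L] *
          complex(real = j_cur[!inner], imaginary = -y_cur[!inner])
      }
      acc <- acc + cn[n + 1L] * term * P_cur
      if (n < nmax) {
        j_cur <- j_cur * S[n + 1L, ]
        if (n == 0L) {
          y_nxt <- -cos(xi) / xi^2 - sin(xi) / xi
          P_nxt <- mui
        } else {
          y_nxt <- (2 * n + 1) / xi * y_cur - y_prev
          P_nxt <- ((2 * n + 1) * mui * P_cur - n * P_prev) / (n + 1)
        }
        y_prev <- y_cur; y_cur <- y_nxt
        P_prev <- P_cur; P_cur <- P_nxt
      }
    }
    out[lo:hi] <- acc
  }
  matrix(p0 * k^2 * Fv^2 * out, nrow = length(r))
}

#' Per-harmonic focused-bowl pressure field through a layer stack
#'
#' Computes, for each populated harmonic, the axisymmetric pressure
#' magnitude field of the focused bowl: the lossless radiation pattern
#' (numerically converged spherical-wave expansion of the bowl's Rayleigh
#' integral in the coupling medium) multiplied by the power-law amplitude
#' attenuation accumulated along the axial path through the stack.
#'
#' @param transducer a [transducer_model()].
#' @param media a [medium_stack()].
#' @param sources a [source_amplitudes()] (optionally power-calibrated)
#'   result.
#' @param grid a [field_grid()]; its axial extent must contain the focus.
#' @param allow_coarse logical; by default the grid spacing must resolve a
#'   quarter wavelength of the highest populated harmonic, and coarser
#'   (scaled-down) grids must be requested explicitly.
#' @param amplitude_floor harmonics whose surface amplitude falls below
#'   this fraction of the strongest harmonic are treated as empty.
#' @return an object of class `field_map`: `r`, `z`, `dr`, `dz`,
#'   `pressure` (list of |p| matrices, named `"h1"`..`"h6"`, zero matrices
#'   for unpopulated harmonics), `frequencies`, `scaled_down` flag.
#' @export
compute_field <- function(transducer, media, sources, grid = field_grid(),
                          allow_coarse = FALSE, amplitude_floor = 1e-3) {
  stopifnot(inherits(transducer, "transducer_model"),
            inherits(media, "medium_stack"),
            inherits(sources, "harmonic_sources"))
  Fv <- transducer$focal_length
  if (Fv < min(grid$z) || Fv > max(grid$z)) {
    stop("the focus lies outside the axial extent of the grid")
  }
  amps <- sources$amplitude_pa
  if (max(amps) <= 0) {
    fields <- lapply(1:6, function(h) {
      matrix(0, length(grid$r), length(grid$z))
    })
    names(fields) <- paste0("h", 1:6)
    return(structure(list(r = grid$r, z = grid$z, dr = grid$dr, dz = grid$dz,
                          pressure = fields, frequencies = sources$frequencies,
                          scaled_down = allow_coarse),
                     class = "field_map"))
  }
  populated <- which(amps > amplitude_floor * max(amps))
  c0 <- media$layers[[1]]$sound_speed
  lam_min <- c0 / max(sources$frequencies[populated])
  if (!allow_coarse && max(grid$dr, grid$dz) > lam_min / 4) {
    stop(sprintf(paste0("grid spacing %.3g mm does not resolve a quarter ",
                        "wavelength (%.3g mm) of the highest populated ",
                        "harmonic; pass allow_coarse = TRUE for a ",
                        "scaled-down run"),
                 max(grid$dr, grid$dz) * 1e3, lam_min / 4 * 1e3))
  }
  a <- transducer$aperture_diameter / 2
  fields <- lapply(1:6, function(h) matrix(0, length(grid$r), length(grid$z)))
  names(fields) <- paste0("h", 1:6)
  for (h in populated) {
    f <- sources$frequencies[h]
    k <- 2 * pi * f / c0
    p <- bowl_field_expansion(k, Fv, a, amps[h], grid$r, grid$z)
    att <- exp(-stack_path_nepers(media, grid$z, f))
    fields[[h]] <- Mod(p) * rep(att, each = length(grid$r))
  }
  structure(list(r = grid$r, z = grid$z, dr = grid$dr, dz = grid$dz,
                 pressure = fields, frequencies = sources$frequencies,
                 scaled_down = allow_coarse),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat("<field_map>\n")
  cat(sprintf("  grid %d x %d (dr %.3g mm, dz %.3g mm), r <= %.1f mm, z <= %.1f mm%s\n",
              length(x$r), length(x$z), x$dr * 1e3, x$dz * 1e3,
              max(x$r) * 1e3, max(x$z) * 1e3,
              if (isTRUE(x$scaled_down)) " [scaled down]" else ""))
  pk <- vapply(x$pressure, max, numeric(1))
  cat("  peak |p| (MPa) h1..h6:",
      paste(sprintf("%.3g", pk * 1e-6), collapse = ", "), "\n")
  invisible(x)
}
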
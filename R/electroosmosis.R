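# Electroosmotic flow in a slit-like tight junction with overlapping
# electrical double layers.
#
# The tight junction (TJ) between brain endothelial cells is idealised as a
# channel bounded by two parallel charged walls a distance 2h apart.  Each
# wall carries a zeta potential and supports a diffuse counter-ion layer of
# Debye thickness 1/kappa.  Because 2h is comparable to the Debye length the
# two double layers overlap, and the equilibrium potential in the channel is
# approximated by superposing the Gouy-Chapman profile of each wall.  An
# axial electric field acting on the mobile counter-charge then drags fluid
# through the channel (electroosmosis).

#' Physical parameters of the tight-junction double layer
#'
#' Bundles the constants needed to evaluate the equilibrium double-layer
#' potential and the electroosmotic velocity profile in a parallel-wall slit
#' channel. Defaults describe a blood-brain-barrier tight junction in
#' physiological saline at body temperature.
#'
#' @param zeta Zeta potential of the channel walls, V (default -0.0211).
#' @param debye_length Debye screening length \eqn{\kappa^{-1}}, m
#'   (default 9.04855e-10).
#' @param half_width_h Channel half-width \eqn{h}, m; the wall-to-wall
#'   opening is \eqn{2h} (default 1e-9).
#' @param temperature Absolute temperature, K (default 310).
#' @param valence_z Counter-ion valence (positive integer, default 1).
#' @param permittivity Permittivity of the medium, F/m (default 7.08e-10).
#' @param viscosity Dynamic viscosity, Pa s (default 7.80e-4).
#' @param boltzmann_k Boltzmann constant, J/K.
#' @param electron_charge_e Elementary charge, C.
#'
#' @return An object of class `double_layer_params`.
#' @examples
#' p <- double_layer_params()
#' p$zeta
#' @export
double_layer_params <- function(zeta = -0.0211,
                                debye_length = 9.04855e-10,
                                half_width_h = 1e-9,
                                temperature = 310,
                                valence_z = 1L,
                                permittivity = 7.08e-10,
                                viscosity = 7.80e-4,
                                boltzmann_k = 1.38064852e-23,
                                electron_charge_e = 1.60217662e-19) {
  check_positive(debye_length, "debye_length")
  check_positive(half_width_h, "half_width_h")
  check_positive(temperature, "temperature")
  check_positive(viscosity, "viscosity")
  check_positive(permittivity, "permittivity")
  if (!is.numeric(zeta) || length(zeta) != 1L || !is.finite(zeta)) {
    stop_invalid("`zeta` must be a single finite number")
  }
  if (length(valence_z) != 1L || valence_z < 1 || valence_z != round(valence_z)) {
    stop_invalid("`valence_z` must be an integer >= 1")
  }
  structure(
    list(zeta = zeta, debye_length = debye_length, half_width_h = half_width_h,
         temperature = temperature, valence_z = as.integer(valence_z),
         permittivity = permittivity, viscosity = viscosity,
         boltzmann_k = boltzmann_k, electron_charge_e = electron_charge_e),
    class = "double_layer_params"
  )
}

#' @export
print.double_layer_params <- function(x, ...) {
  cat("Tight-junction double-layer parameters\n")
  cat(sprintf("  zeta potential : %g V\n", x$zeta))
  cat(sprintf("  Debye length   : %g m\n", x$debye_length))
  cat(sprintf("  half-width h   : %g m (opening 2h = %g m)\n",
              x$half_width_h, 2 * x$half_width_h))
  cat(sprintf("  T = %g K, z = %d, eps = %g F/m, mu = %g Pa s\n",
              x$temperature, x$valence_z, x$permittivity, x$viscosity))
  invisible(x)
}

# psi(y) for a vector of positions: two-wall Gouy-Chapman superposition,
# valid for weak double-layer overlap.
.psi_profile <- function(params, y) {
  kT <- params$boltzmann_k * params$temperature
  ze <- params$valence_z * params$electron_charge_e
  pref <- 4 * kT / ze
  g <- tanh(ze * params$zeta / (4 * kT))
  kap <- 1 / params$debye_length
  h2 <- 2 * params$half_width_h
  pref * (atanh(g * exp(-kap * y)) + atanh(g * exp(-kap * (h2 - y))))
}

#' Equilibrium double-layer potential across the tight junction
#'
#' Evaluates the equilibrium potential \eqn{\psi(y)} across the slit channel
#' on a uniform grid over \eqn{[0, 2h]}, as the superposition of the
#' Gouy-Chapman potentials of the two walls (weak-overlap approximation):
#' \deqn{\psi(y) = \frac{4kT}{ze}\,\mathrm{atanh}\!\left[\tanh\left(
#'   \frac{ze\zeta}{4kT}\right) e^{-\kappa y}\right] +
#'   \frac{4kT}{ze}\,\mathrm{atanh}\!\left[\tanh\left(\frac{ze\zeta}{4kT}
#'   \right) e^{-\kappa (2h-y)}\right].}
#'
#' @param params A [double_layer_params()] object.
#' @param n_points Number of uniformly spaced sample points (>= 3).
#' @return An object of class `potential_profile`: list with `positions_y`
#'   (m) and `potentials_psi` (V).
#' @examples
#' prof <- equilibrium_potential(double_layer_params(), n_points = 101)
#' prof$potentials_psi[51]  # midline potential, about -0.0138 V
#' @export
equilibrium_potential <- function(params, n_points = 1001L) {
  stopifnot(inherits(params, "double_layer_params"))
  if (n_points < 3) stop_invalid("`n_points` must be >= 3")
  y <- seq(0, 2 * params$half_width_h, length.out = n_points)
  structure(
    list(positions_y = y, potentials_psi = .psi_profile(params, y)),
    class = "potential_profile"
  )
}

#' Electroosmotic velocity profile in the tight junction
#'
#' Computes the pointwise electroosmotic velocity
#' \deqn{u(y) = -\frac{\varepsilon \zeta E}{\mu}\left(1 -
#'   \frac{\psi(y)}{\zeta}\right)}
#' from the equilibrium potential profile. With a negative zeta potential and
#' a positive applied field the flow is positive (field-aligned).
#'
#' @inheritParams equilibrium_potential
#' @param applied_field_E Axial electric field in the junction, V/m.
#' @return An object of class `velocity_profile`: list with `positions_y`
#'   (m), `velocities_u` (m/s) and `applied_field_E`.
#' @examples
#' vp <- velocity_profile(double_layer_params(), applied_field_E = 869.4)
#' max(vp$velocities_u)  # about 5.7e-6 m/s
#' @export
velocity_profile <- function(params, applied_field_E, n_points = 1001L) {
  prof <- equilibrium_potential(params, n_points)
  u <- if (params$zeta == 0) {
    rep(0, length(prof$positions_y))
  } else {
    -(params$permittivity * params$zeta * applied_field_E / params$viscosity) *
      (1 - prof$potentials_psi / params$zeta)
  }
  structure(
    list(positions_y = prof$positions_y, velocities_u = u,
         applied_field_E = applied_field_E),
    class = "velocity_profile"
  )
}

# Trapezoid mean of u over [0, 2h] at a given resolution.
.trapz_mean_velocity <- function(params, applied_field_E, n_points) {
  vp <- velocity_profile(params, applied_field_E, n_points)
  u <- vp$velocities_u
  n <- length(u)
  sum((u[-1] + u[-n]) / 2) / (n - 1)
}

#' Channel-averaged electroosmotic velocity
#'
#' Averages the velocity profile over the channel width by composite
#' trapezoid quadrature, refining the grid (doubling intervals) until two
#' successive refinements agree to better than 0.1% relative.
#'
#' @inheritParams velocity_profile
#' @return Average velocity, m/s.
#' @examples
#' average_velocity(double_layer_params(), applied_field_E = 1)
#' @export
average_velocity <- function(params, applied_field_E) {
  stopifnot(inherits(params, "double_layer_params"))
  if (applied_field_E == 0 || params$zeta == 0) return(0)
  n <- 1001L
  prev <- .trapz_mean_velocity(params, applied_field_E, n)
  repeat {
    n <- 2L * (n - 1L) + 1L
    cur <- .trapz_mean_velocity(params, applied_field_E, n)
    if (abs(cur - prev) <= 1e-3 * abs(cur) || n > 2e6) return(cur)
    prev <- cur
  }
}

#' Linear electroosmotic velocity coefficients
#'
#' The velocity field is exactly linear in the applied field, so the average
#' and midline (maximum) velocities are characterised by their coefficients
#' per unit field, evaluated at E = 1 V/m. Coefficients are reported as
#' magnitudes; flow direction is carried by the sign of the wall current
#' density at the network level.
#'
#' @inheritParams average_velocity
#' @return An object of class `eo_coefficients`: list with
#'   `avg_velocity_coeff` and `max_velocity_coeff`, both in (m/s) per (V/m).
#' @examples
#' fit_coefficients(double_layer_params())
#' @export
fit_coefficients <- function(params) {
  stopifnot(inherits(params, "double_layer_params"))
  avg <- abs(average_velocity(params, 1))
  psi_mid <- .psi_profile(params, params$half_width_h)
  mx <- if (params$zeta == 0) 0 else
    abs(-(params$permittivity * params$zeta / params$viscosity) *
          (1 - psi_mid / params$zeta))
  structure(
    list(avg_velocity_coeff = avg, max_velocity_coeff = mx),
    class = "eo_coefficients"
  )
}

#' @export
print.eo_coefficients <- function(x, ...) {
  cat("Electroosmotic velocity coefficients [(m/s) per (V/m)]\n")
  cat(sprintf("  average (v / E_TJ) : %.4g\n", x$avg_velocity_coeff))
  cat(sprintf("  midline maximum    : %.4g\n", x$max_velocity_coeff))
  invisible(x)
}

#' Volumetric flux coefficient per unit vessel area
#'
#' Converts the average-velocity coefficient into a volumetric flow rate per
#' unit vessel wall area per unit tight-junction field, by multiplying by
#' the junction opening \eqn{2h} and the junction length per unit vessel
#' area \eqn{L_{TJ}}:
#' \deqn{Q/A = v \cdot 2h \cdot L_{TJ}.}
#'
#' @param coeffs An `eo_coefficients` object from [fit_coefficients()].
#' @param tj A [tj_geometry()] object supplying `opening_2h` (m) and
#'   `junction_length_per_area` (m per m^2).
#' @return Flux coefficient, (m^3/s per m^2) per (V/m).
#' @examples
#' flux_coefficient(fit_coefficients(double_layer_params()), tj_geometry())
#' @export
flux_coefficient <- function(coeffs, tj) {
  stopifnot(inherits(coeffs, "eo_coefficients"), inherits(tj, "tj_geometry"))
  check_positive(tj$opening_2h, "opening_2h")
  check_positive(tj$junction_length_per_area, "junction_length_per_area")
  coeffs$avg_velocity_coeff * tj$opening_2h * tj$junction_length_per_area
}
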
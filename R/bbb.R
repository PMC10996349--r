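# Reduced-order model of the blood-brain-barrier ultrastructure.
#
# The quantity of interest is the coupling constant C (V m / A) that maps a
# wall-normal current density J_vi at a capillary to the electric field
# inside the tight junction, E_TJ = C * J_vi. C is available in two modes:
# a lookup of reference values for the standard TEER conditions, and a
# series-parallel conductance network that resolves the paracellular pathway
# (glycocalyx -> cleft -> tight junction -> cleft -> basement membrane ->
# astrocytic channel) against the transcellular shunt through the insulating
# endothelial membranes.

#' Reduced-order BBB ultrastructure model
#'
#' Describes the blood-brain-barrier wall as two parallel current pathways
#' per unit vessel area: a paracellular chain of channel segments containing
#' the tight junction, and a transcellular shunt through the (insulating)
#' endothelial cell membranes. Segment conductances per unit vessel area are
#' \eqn{\sigma \cdot a / \ell} with `a` the open-area fraction of the channel
#' and \eqn{\ell} the segment length.
#'
#' @param tj A [tj_geometry()] object.
#' @param wall_thickness Endothelial wall thickness, m (default 1e-6).
#' @param conductivities Named vector from [conductivity_table()]; the
#'   entries `endothelial_cleft_channel`, `astrocytic_channel`,
#'   `basement_membrane`, `glycocalyx` and `insulating_membrane` are used.
#' @param area_correction Ratio of parenchyma to astro-endothelial surface
#'   through which the applied current converges radially (default 2.04).
#' @param n_tight_junctions Number of tight junctions in series along the
#'   cleft (default 1; values > 1 are an extrapolation).
#' @param glycocalyx_thickness Luminal glycocalyx thickness, m (default
#'   100e-9).
#' @param basement_membrane_thickness m (default 50e-9).
#' @param astrocytic_channel_length Length of the channel between astrocyte
#'   endfeet, m (default 1e-6).
#' @return An `ultrastructure_model` object.
#' @examples
#' ultrastructure_model()
#' @export
ultrastructure_model <- function(tj = tj_geometry(),
                                 wall_thickness = 1e-6,
                                 conductivities = conductivity_table(),
                                 area_correction = 2.04,
                                 n_tight_junctions = 1L,
                                 glycocalyx_thickness = 100e-9,
                                 basement_membrane_thickness = 50e-9,
                                 astrocytic_channel_length = 1e-6) {
  stopifnot(inherits(tj, "tj_geometry"))
  check_positive(wall_thickness, "wall_thickness")
  if (area_correction < 1) stop_invalid("`area_correction` must be >= 1")
  if (n_tight_junctions < 1 || n_tight_junctions != round(n_tight_junctions)) {
    stop_invalid("`n_tight_junctions` must be an integer >= 1")
  }
  need <- c("endothelial_cleft_channel", "astrocytic_channel",
            "basement_membrane", "glycocalyx", "insulating_membrane")
  if (!all(need %in% names(conductivities))) {
    stop_invalid("`conductivities` must contain: ", paste(need, collapse = ", "))
  }
  structure(
    list(tj = tj, wall_thickness = wall_thickness,
         conductivities = conductivities,
         area_correction = area_correction,
         n_tight_junctions = as.integer(n_tight_junctions),
         glycocalyx_thickness = glycocalyx_thickness,
         basement_membrane_thickness = basement_membrane_thickness,
         astrocytic_channel_length = astrocytic_channel_length),
    class = "ultrastructure_model"
  )
}

# Reference coupling constants (V m / A), single tight junction.
.coupling_lookup <- c("1000" = 2.73e6, "5000" = 3.83e6)

#' Coupling constant from wall current density to tight-junction field
#'
#' Returns the proportionality constant \eqn{C} of
#' \eqn{E_{TJ} = C \cdot J_{vi}}. In `"lookup"` mode the reference values
#' for 1000 and 5000 ohm cm^2 TEER (single tight junction) are returned. In
#' `"model"` mode \eqn{C} is computed from the reduced-order conductance
#' network: the fraction \eqn{f} of the applied current taking the
#' paracellular pathway is obtained from the series chain of segment
#' conductances against the transcellular shunt, and
#' \deqn{C = f \cdot \mathrm{TEER}_{\Omega m^2} /
#'   (\ell_{TJ} \cdot \mathrm{area\ correction}).}
#'
#' @param model An [ultrastructure_model()] object.
#' @param teer TEER value; bare numbers are ohm cm^2, or use [teer()].
#'   Lookup mode supports 1000 and 5000 ohm cm^2 only.
#' @param mode `"lookup"` (default, reference values) or `"model"`.
#' @return A `coupling_constant` object: list with `C` (V m / A),
#'   `teer_ohm_cm2` and `mode`.
#' @examples
#' coupling_constant(teer = 1000)$C                  # 2.73e6
#' coupling_constant(teer = 5000, mode = "model")$C  # about 3.7e6
#' @export
coupling_constant <- function(model = ultrastructure_model(), teer = 1000,
                              mode = c("lookup", "model")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "ultrastructure_model"))
  t_cm2 <- teer_ohm_cm2(teer)
  if (mode == "lookup") {
    key <- as.character(t_cm2)
    if (!key %in% names(.coupling_lookup)) {
      stop_invalid("lookup mode supports TEER values ",
                   paste(names(.coupling_lookup), collapse = ", "),
                   " ohm cm^2; got ", t_cm2,
                   ". Use mode = \"model\" for other values.")
    }
    if (model$n_tight_junctions != 1L) {
      stop_invalid("lookup mode provides constants for 1 tight junction only")
    }
    C <- unname(.coupling_lookup[key])
  } else {
    C <- .coupling_model_C(model, teer_ohm_m2(teer))
  }
  structure(list(C = C, teer_ohm_cm2 = t_cm2, mode = mode),
            class = "coupling_constant")
}

# Series-parallel conductance evaluation of C (per unit vessel area).
.coupling_model_C <- function(model, teer_si) {
  tj <- model$tj
  sig <- model$conductivities
  # open-area fractions of the paracellular channel per unit vessel area
  a_cleft <- tj$cleft_width * tj$junction_length_per_area
  a_tj <- tj$opening_2h * tj$junction_length_per_area
  len_before <- tj$tj_position_from_glycocalyx
  len_after <- tj$cleft_length - tj$tj_position_from_glycocalyx - tj$tj_length
  if (len_after <= 0) stop_invalid("TJ does not fit inside the cleft")
  # TJ segment: sigma_TJ(TEER) * a_TJ / l_TJ reduces exactly to 1/TEER;
  # n junctions in series multiply the TJ resistance.
  g_tj <- tj_conductivity_from_teer(teer(teer_si, unit = "ohm_m2"), tj) *
    a_tj / (tj$tj_length * model$n_tight_junctions)
  g_series <- c(
    glycocalyx = sig[["glycocalyx"]] / model$glycocalyx_thickness,
    cleft_before = sig[["endothelial_cleft_channel"]] * a_cleft / len_before,
    tight_junction = g_tj,
    cleft_after = sig[["endothelial_cleft_channel"]] * a_cleft / len_after,
    basement_membrane = sig[["basement_membrane"]] / model$basement_membrane_thickness,
    astrocytic_channel = sig[["astrocytic_channel"]] * a_cleft /
      model$astrocytic_channel_length
  )
  g_para <- 1 / sum(1 / g_series)
  g_trans <- sig[["insulating_membrane"]] / model$wall_thickness
  f <- g_para / (g_para + g_trans)
  f * teer_si / (tj$tj_length * model$area_correction)
}

#' @export
print.coupling_constant <- function(x, ...) {
  cat(sprintf("BBB coupling constant C = %.4g V m/A (TEER %g ohm cm^2, %s mode)\n",
              x$C, x$teer_ohm_cm2, x$mode))
  invisible(x)
}

#' Tight-junction electric field from wall current density
#'
#' Applies \eqn{E_{TJ} = C \cdot J_{vi}}; the sign of the current density is
#' preserved, so inward and outward wall crossings map to opposite field
#' directions in the junction.
#'
#' @param J_vi Wall-normal current density, A/m^2 (signed; vectorised).
#' @param constant A `coupling_constant` object from [coupling_constant()].
#' @return Tight-junction field, V/m, same length as `J_vi`.
#' @examples
#' tj_field_from_wall_current(3.2e-4, coupling_constant(teer = 1000))
#' @export
tj_field_from_wall_current <- function(J_vi, constant) {
  stopifnot(inherits(constant, "coupling_constant"))
  if (constant$C <= 0) stop_invalid("coupling constant must be positive")
  constant$C * J_vi
}
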
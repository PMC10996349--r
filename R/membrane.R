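# TEER-based membrane electrics.
#
# Transendothelial electrical resistance (TEER) is the areal resistance of
# the capillary wall, conventionally reported in ohm cm^2. At the micrometre
# scale the wall is treated as a uniform resistive shell; at the nanoscale
# all of the wall resistance is attributed to the tight junction. Both views
# convert a TEER value into a bulk conductivity.

#' Tag a TEER value with its unit
#'
#' TEER is reported in the literature in \eqn{\Omega\,cm^2}; the model works
#' in SI \eqn{\Omega\,m^2} (1 \eqn{\Omega\,cm^2} = 1e-4 \eqn{\Omega\,m^2}).
#' All TEER-consuming functions accept either a bare number, interpreted in
#' \eqn{\Omega\,cm^2} (the customary experimental unit), or a value tagged
#' by this constructor.
#'
#' @param value Positive areal resistance.
#' @param unit `"ohm_cm2"` (default) or `"ohm_m2"`.
#' @return A `teer` object (numeric with a unit attribute).
#' @examples
#' teer(1000)                      # 1000 ohm cm^2
#' teer(0.1, unit = "ohm_m2")      # the same resistance in SI
#' @export
teer <- function(value, unit = c("ohm_cm2", "ohm_m2")) {
  unit <- match.arg(unit)
  check_positive(value, "value")
  structure(value, unit = unit, class = "teer")
}

#' Convert a TEER value to SI areal resistance
#'
#' @param x A `teer` object or bare number (interpreted as ohm cm^2).
#' @return Areal resistance in ohm m^2.
#' @examples
#' teer_ohm_m2(1000)  # 0.1
#' @export
teer_ohm_m2 <- function(x) {
  if (inherits(x, "teer")) {
    if (attr(x, "unit") == "ohm_m2") as.numeric(x) else as.numeric(x) * 1e-4
  } else {
    check_positive(x, "teer")
    x * 1e-4
  }
}

#' Convert a TEER value to ohm cm^2
#'
#' @inheritParams teer_ohm_m2
#' @return Areal resistance in ohm cm^2.
#' @export
teer_ohm_cm2 <- function(x) teer_ohm_m2(x) * 1e4

#' TEER specification for a uniform capillary wall
#'
#' @param teer TEER value; bare numbers are ohm cm^2, or use [teer()].
#' @param wall_thickness Wall thickness \eqn{\ell_{wall}}, m (default 1e-6).
#' @return A `teer_spec` object.
#' @export
teer_spec <- function(teer = 1000, wall_thickness = 1e-6) {
  check_positive(wall_thickness, "wall_thickness")
  t_si <- teer_ohm_m2(teer)
  structure(list(teer_ohm_m2 = t_si, wall_thickness = wall_thickness),
            class = "teer_spec")
}

#' Tight-junction and interendothelial cleft geometry
#'
#' Dimensions of the blood-brain-barrier paracellular pathway: a 700 nm long,
#' 20 nm wide interendothelial cleft carrying a single 11 nm x 2 nm tight
#' junction positioned 105 nm from the luminal glycocalyx surface, with
#' 150 000 m of junction per m^2 of vessel wall.
#'
#' @param tj_length TJ length along the cleft \eqn{\ell_{TJ}}, m.
#' @param opening_2h TJ opening (slit width) \eqn{2h}, m.
#' @param junction_length_per_area Junction length per unit vessel wall area
#'   \eqn{L_{TJ}}, m per m^2.
#' @param tj_position_from_glycocalyx Distance from the glycocalyx surface to
#'   the TJ, m.
#' @param cleft_length Total interendothelial cleft length, m.
#' @param cleft_width Cleft width away from the TJ constriction, m.
#' @return A `tj_geometry` object.
#' @examples
#' tj_geometry()
#' @export
tj_geometry <- function(tj_length = 11e-9,
                        opening_2h = 2e-9,
                        junction_length_per_area = 150000,
                        tj_position_from_glycocalyx = 105e-9,
                        cleft_length = 700e-9,
                        cleft_width = 20e-9) {
  for (nm in c("tj_length", "opening_2h", "junction_length_per_area",
               "tj_position_from_glycocalyx", "cleft_length", "cleft_width")) {
    check_positive(get(nm), nm)
  }
  if (tj_position_from_glycocalyx >= cleft_length) {
    stop_invalid("`tj_position_from_glycocalyx` must be < `cleft_length`")
  }
  structure(
    list(tj_length = tj_length, opening_2h = opening_2h,
         junction_length_per_area = junction_length_per_area,
         tj_position_from_glycocalyx = tj_position_from_glycocalyx,
         cleft_length = cleft_length, cleft_width = cleft_width),
    class = "tj_geometry"
  )
}

#' @export
print.tj_geometry <- function(x, ...) {
  cat("Tight-junction geometry\n")
  cat(sprintf("  TJ length x opening : %g m x %g m\n", x$tj_length, x$opening_2h))
  cat(sprintf("  L_TJ                : %g m/m^2\n", x$junction_length_per_area))
  cat(sprintf("  cleft length/width  : %g m / %g m (TJ at %g m)\n",
              x$cleft_length, x$cleft_width, x$tj_position_from_glycocalyx))
  invisible(x)
}

#' Uniform capillary-wall conductivity from TEER
#'
#' At the micrometre scale the wall is a homogeneous shell of thickness
#' \eqn{\ell_{wall}} whose areal resistance equals the TEER, so
#' \eqn{\sigma_{wall} = \ell_{wall} / \mathrm{TEER}}.
#'
#' @param spec A [teer_spec()] object.
#' @return Wall conductivity, S/m.
#' @examples
#' wall_conductivity_from_teer(teer_spec(1000))  # 1e-5 S/m
#' wall_conductivity_from_teer(teer_spec(5000))  # 2e-6 S/m
#' @export
wall_conductivity_from_teer <- function(spec) {
  stopifnot(inherits(spec, "teer_spec"))
  spec$wall_thickness / spec$teer_ohm_m2
}

#' Tight-junction conductivity from TEER
#'
#' At the nanoscale the tight junction accounts for all of the wall
#' resistance: \eqn{\mathrm{TEER} = \rho_{TJ}\,\ell_{TJ} / (2h\,L_{TJ})},
#' so the TJ conductivity is
#' \eqn{\sigma_{TJ} = \ell_{TJ} / (\mathrm{TEER}\cdot 2h\cdot L_{TJ})}.
#'
#' @param teer TEER value; bare numbers are ohm cm^2, or use [teer()].
#' @param tj A [tj_geometry()] object.
#' @return Tight-junction conductivity, S/m.
#' @examples
#' tj_conductivity_from_teer(1000, tj_geometry())  # about 3.67e-4 S/m
#' tj_conductivity_from_teer(5000, tj_geometry())  # about 7.33e-5 S/m
#' @export
tj_conductivity_from_teer <- function(teer, tj) {
  stopifnot(inherits(tj, "tj_geometry"))
  t_si <- teer_ohm_m2(teer)
  tj$tj_length / (t_si * tj$opening_2h * tj$junction_length_per_area)
}

#' Reference tissue and ultrastructure conductivity table
#'
#' Loads the per-compartment conductivity table (S/m) shipped with the
#' package, spanning the head-scale tissues (scalp, fat, skull, CSF, gray and
#' white matter, electrode), the capillary voxel compartments (parenchyma,
#' lumen) and the BBB ultrastructure channels (astrocytic and endothelial
#' cleft channels, basement membrane, glycocalyx, insulating membranes).
#' The table is data, not code: pass `file` to override any value.
#'
#' @param file Path to a YAML file mapping compartment name to conductivity
#'   in S/m; defaults to the table shipped in `inst/extdata`.
#' @return Named numeric vector of conductivities, S/m.
#' @examples
#' conductivity_table()[["gray_matter"]]  # 0.276
#' @export
conductivity_table <- function(file = system.file("extdata", "conductivities.yaml",
                                                  package = "tdcsflow")) {
  tab <- yaml::read_yaml(file)
  out <- unlist(tab$conductivities_S_per_m)
  if (any(out <= 0)) stop_invalid("all conductivities must be > 0")
  out
}
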
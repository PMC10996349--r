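# End-to-end pipeline: stimulation dose -> voxel current -> electroosmotic
# flux -> brain-wide exchange map.

#' Build a run configuration
#'
#' Assembles the full set of pipeline parameters with defaults equal to the
#' reference study conditions: 1 mA stimulation producing a peak brain
#' current density of 0.082 A/m^2, a closed capillary network at
#' 1000 ohm cm^2 TEER, and the standard tight-junction geometry and
#' double-layer constants. Any subset can be overridden via `...` (named
#' sections) or loaded from a YAML file with [read_run_config()].
#'
#' @param ... Named sections overriding the defaults. Recognised sections:
#'   `electroosmosis` (arguments of [double_layer_params()]), `membranes`
#'   (`teer_ohm_cm2`, `wall_thickness`, arguments of [tj_geometry()]),
#'   `bbb` (`mode`, `area_correction`, `n_tight_junctions`), `network`
#'   (`seed`, `target_length_density`, `diameter_range`, `voxel_dims`),
#'   `solver` (`grid_dims`, `boundary_mode`, `n_grounded_segments`),
#'   `pipeline` (`exchange_convention`, `applied_current_mA`, `montage`,
#'   `brain_shape`, `equal_area`).
#' @return A `run_config` object (named list of sections).
#' @examples
#' cfg <- run_config(solver = list(grid_dims = c(12, 12, 32)))
#' cfg$solver$grid_dims
#' @export
run_config <- function(...) {
  defaults <- list(
    electroosmosis = list(),
    membranes = list(teer_ohm_cm2 = 1000, wall_thickness = 1e-6),
    bbb = list(mode = "lookup", area_correction = 2.04, n_tight_junctions = 1L),
    network = list(seed = 1L, target_length_density = 557,
                   diameter_range = c(8e-6, 10e-6),
                   voxel_dims = c(0.15e-3, 0.16e-3, 0.43e-3)),
    solver = list(grid_dims = c(48L, 52L, 140L), boundary_mode = "closed",
                  n_grounded_segments = 4L),
    pipeline = list(exchange_convention = "both", applied_current_mA = 1,
                    montage = "bifrontal", brain_shape = c(32L, 32L, 32L),
                    equal_area = FALSE)
  )
  overrides <- list(...)
  if (anyDuplicated(names(overrides))) {
    stop_invalid("duplicated config section(s): ",
                 paste(unique(names(overrides)[duplicated(names(overrides))]),
                       collapse = ", "))
  }
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad)) stop_invalid("unknown config section(s): ", paste(bad, collapse = ", "))
  for (sec in names(overrides)) {
    defaults[[sec]] <- utils::modifyList(defaults[[sec]], overrides[[sec]])
  }
  structure(defaults, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are config sections (see
#'   [run_config()]).
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  obj <- yaml::read_yaml(path)
  do.call(run_config, obj)
}

#' Run the full multi-scale pipeline
#'
#' Executes the stage chain: (ii) peak brain current density from the dose,
#' (iii) current flow through a synthetic capillary network in the peak
#' voxel, (iv-vi) tight-junction field and electroosmotic coupling, (vii)
#' wall volumetric flux and net interstitial exchange, (viii) scaling of
#' the brain-wide current-density map to an exchange map. Each stage's peak
#' output feeds the next, matching the linearity of every stage. All
#' results are deterministic functions of the configuration (including its
#' seeds).
#'
#' @param config A [run_config()].
#' @param out_dir Optional output directory; when given, per-stage tables
#'   (TSV), the vessel graph (JSON), the exchange map (portable array +
#'   JSON sidecar) and a provenance record of every constant used are
#'   written there.
#' @return A `pipeline_result`: list with the electroosmotic coefficients,
#'   flux coefficient, coupling constant, voxel solution summary, net
#'   exchange (1/min), scaling factor k (m^2/(A min)), the brain field and
#'   exchange map, and the provenance list.
#' @examples
#' res <- run_pipeline(run_config(
#'   solver = list(grid_dims = c(10, 10, 28)),
#'   network = list(seed = 3),
#'   pipeline = list(brain_shape = c(8L, 8L, 8L))))
#' res$scaling_factor_k
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  mA <- config$pipeline$applied_current_mA
  check_nonnegative(mA, "applied_current_mA")

  # nanoscale electroosmosis: velocity and flux coefficients
  params <- do.call(double_layer_params, config$electroosmosis)
  tj_args <- config$membranes[setdiff(names(config$membranes),
                                      c("teer_ohm_cm2", "wall_thickness"))]
  tj <- do.call(tj_geometry, tj_args)
  coeffs <- fit_coefficients(params)
  fcoeff <- flux_coefficient(coeffs, tj)

  # membrane electrics
  teer_val <- config$membranes$teer_ohm_cm2
  sigma_wall <- wall_conductivity_from_teer(
    teer_spec(teer_val, config$membranes$wall_thickness))
  sigma_tj <- tj_conductivity_from_teer(teer_val, tj)

  # BBB coupling constant
  model <- ultrastructure_model(
    tj = tj, wall_thickness = config$membranes$wall_thickness,
    area_correction = config$bbb$area_correction,
    n_tight_junctions = config$bbb$n_tight_junctions)
  const <- coupling_constant(model, teer = teer_val, mode = config$bbb$mode)

  # stage ii: brain current-density field for the dose
  field <- synthetic_brain_field(
    shape = config$pipeline$brain_shape,
    applied_current_mA = max(mA, 1),
    seed = config$network$seed)
  if (mA != 1) field$values <- field$values * (mA / max(mA, 1))
  field$applied_current_mA <- mA
  peak_J_brain <- max(field$values)

  # stage iii: capillary network solve at the peak-current voxel
  graph <- generate_network(
    voxel_dims = config$network$voxel_dims,
    target_length_density = config$network$target_length_density,
    diameter_range = config$network$diameter_range,
    seed = config$network$seed)
  sol <- solve_voxel_current(
    graph, boundary_mode = config$solver$boundary_mode, teer = teer_val,
    inward_current_density = peak_J_brain,
    grid_dims = config$solver$grid_dims,
    n_grounded_segments = config$solver$n_grounded_segments)

  # stages iv-vii: flux map, net exchange, scaling factor
  fmap <- wall_flux_map(sol, fcoeff, const,
                        equal_area = isTRUE(config$pipeline$equal_area))
  exch <- net_exchange(fmap, prod(config$network$voxel_dims),
                       convention = config$pipeline$exchange_convention)
  k <- if (peak_J_brain > 0) scaling_factor(exch, peak_J_brain) else 0

  # stage viii: brain-wide exchange map
  emap <- scale_brain_map(field, k)

  provenance <- list(
    package = "tdcsflow",
    version = as.character(utils::packageVersion("tdcsflow")),
    config = unclass(config),
    constants = list(
      avg_velocity_coeff_m_per_s_per_V_per_m = coeffs$avg_velocity_coeff,
      max_velocity_coeff_m_per_s_per_V_per_m = coeffs$max_velocity_coeff,
      flux_coefficient_m3_per_s_per_m2_per_V_per_m = fcoeff,
      coupling_constant_C_Vm_per_A = const$C,
      coupling_mode = const$mode,
      sigma_wall_S_per_m = sigma_wall,
      sigma_tj_S_per_m = sigma_tj,
      teer_ohm_cm2 = teer_ohm_cm2(teer_val),
      peak_brain_current_density_A_per_m2 = peak_J_brain,
      peak_wall_current_density_A_per_m2 = sol$peak_J_norm,
      peak_tj_field_V_per_m = const$C * sol$peak_J_norm,
      net_exchange_per_min = exch,
      scaling_factor_k_m2_per_A_min = k
    ),
    seeds = list(network = config$network$seed)
  )

  res <- structure(list(
    coefficients = coeffs, flux_coefficient = fcoeff,
    coupling_constant = const, graph = graph, solution = sol,
    flux_map = fmap, net_exchange = exch, scaling_factor_k = k,
    brain_field = field, exchange_map = emap, provenance = provenance
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tsv <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
    tsv(data.frame(
      quantity = c("avg_velocity_coeff", "max_velocity_coeff", "flux_coefficient"),
      value = c(coeffs$avg_velocity_coeff, coeffs$max_velocity_coeff, fcoeff),
      units = c("(m/s)/(V/m)", "(m/s)/(V/m)", "(m3/s/m2)/(V/m)")),
      "eo_coefficients.tsv")
    tsv(data.frame(teer_ohm_cm2 = teer_ohm_cm2(teer_val),
                   sigma_wall_S_per_m = sigma_wall,
                   sigma_tj_S_per_m = sigma_tj),
        "membrane_conductivities.tsv")
    tsv(data.frame(
      quantity = c("peak_brain_current_density", "peak_wall_current_density",
                   "peak_tj_field", "net_exchange", "scaling_factor_k"),
      value = c(peak_J_brain, sol$peak_J_norm, const$C * sol$peak_J_norm,
                exch, k),
      units = c("A/m2", "A/m2", "V/m", "1/min", "m2/(A*min)")),
      "pipeline_summary.tsv")
    write_wall_elements(sol, file.path(out_dir, "wall_elements.tsv"))
    write_vessel_graph(graph, file.path(out_dir, "vessel_graph.json"))
    write_volume(emap, file.path(out_dir, "exchange_map.txt"))
    jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  p <- x$provenance$constants
  cat("tdcsflow pipeline result\n")
  cat(sprintf("  peak brain current density : %.4g A/m^2\n",
              p$peak_brain_current_density_A_per_m2))
  cat(sprintf("  peak wall current density  : %.4g A/m^2\n",
              p$peak_wall_current_density_A_per_m2))
  cat(sprintf("  peak TJ field              : %.4g V/m\n",
              p$peak_tj_field_V_per_m))
  cat(sprintf("  net exchange               : %.4g 1/min\n", x$net_exchange))
  cat(sprintf("  scaling factor k           : %.4g m^2/(A min)\n",
              x$scaling_factor_k))
  invisible(x)
}
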
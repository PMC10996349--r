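# From wall current density to interstitial water exchange.
#
# The chain of linear constants established at the nanoscale converts the
# signed wall-normal current density at each capillary wall element into an
# electroosmotic volumetric flux, which is aggregated over the network and
# normalised by the voxel volume to a net exchange rate. Because every
# stage is linear, a single scaling factor k maps brain current density
# (A/m^2) to exchange rate (1/min) in any voxel.

#' Electroosmotic volumetric flux from wall current density
#'
#' Applies the composed linear chain
#' \deqn{Q/A = J_{norm} \cdot (Q/A / E_{TJ}) \cdot (E_{TJ}/J_{vi})
#'          = J_{norm} \cdot \mathrm{flux\ coefficient} \cdot C,}
#' preserving the sign of the current density (positive flux follows
#' positive wall current).
#'
#' @param J_norm Signed wall-normal current density, A/m^2 (vectorised).
#' @param flux_coeff Volumetric flux coefficient from [flux_coefficient()],
#'   (m^3/s per m^2) per (V/m).
#' @param constant A `coupling_constant` from [coupling_constant()].
#' @return Signed volumetric flux Q/A, m^3/s per m^2.
#' @examples
#' flux_from_current(3.2e-4, 1.15e-12, coupling_constant(teer = 1000))
#' @export
flux_from_current <- function(J_norm, flux_coeff, constant) {
  check_positive(flux_coeff, "flux_coeff")
  flux_coeff * tj_field_from_wall_current(J_norm, constant)
}

#' Wall flux map from a voxel current solution
#'
#' Converts every wall element of a [solve_voxel_current()] solution into a
#' signed volumetric flux.
#'
#' @param solution A `voxel_current_solution`.
#' @param flux_coeff Flux coefficient, see [flux_from_current()].
#' @param constant A `coupling_constant`.
#' @param equal_area If `TRUE`, replace the per-element areas by their mean
#'   (the equal-node-area compatibility convention); default `FALSE` uses
#'   the true apportioned areas.
#' @return A `wall_flux_map`: data frame with element areas (m^2), `J_norm`
#'   (A/m^2) and `QA` (m^3/s per m^2, signed).
#' @export
wall_flux_map <- function(solution, flux_coeff, constant, equal_area = FALSE) {
  stopifnot(inherits(solution, "voxel_current_solution"))
  el <- solution$wall_elements
  area <- if (equal_area && nrow(el)) rep(mean(el$area_m2), nrow(el)) else el$area_m2
  out <- data.frame(segment = el$segment, area_m2 = area, J_norm = el$J_norm,
                    QA = flux_from_current(el$J_norm, flux_coeff, constant))
  class(out) <- c("wall_flux_map", class(out))
  out
}

#' Net interstitial fluid exchange per tissue volume
#'
#' Aggregates the wall flux map to a net exchange rate:
#' \deqn{\sum_i |Q/A|_i \, A_i / V_{voxel} \times 60}
#' in m^3 per minute per m^3 of tissue (i.e. 1/min). The default
#' `"both"` convention counts flow in both directions (into and out of the
#' vessels); `"half"` halves the sum, counting each exchanged volume once.
#'
#' @param flux_map A [wall_flux_map()] (or data frame with `QA` and
#'   `area_m2` columns).
#' @param voxel_volume Voxel volume, m^3.
#' @param convention `"both"` (default) or `"half"`.
#' @return Net exchange rate, 1/min (non-negative).
#' @examples
#' fm <- data.frame(area_m2 = 1e-8, QA = 1e-9)
#' net_exchange(fm, voxel_volume = 1e-11)  # 6e-4 per min
#' @export
net_exchange <- function(flux_map, voxel_volume, convention = c("both", "half")) {
  convention <- match.arg(convention)
  check_positive(voxel_volume, "voxel_volume")
  total <- sum(abs(flux_map$QA) * flux_map$area_m2)
  fac <- if (convention == "half") 0.5 else 1
  fac * total / voxel_volume * 60
}

#' Current-density-to-exchange scaling factor
#'
#' The constant k mapping applied brain current density to interstitial
#' exchange rate: \eqn{k = \mathrm{net\ exchange} / J_{applied}}, in
#' m^2 (A min)^-1.
#'
#' @param net_exchange Exchange rate, 1/min.
#' @param applied_current_density Applied current density, A/m^2 (> 0).
#' @return Scaling factor k, m^2/(A min).
#' @examples
#' scaling_factor(1.5e-4, 0.082)  # about 1.8e-3
#' @export
scaling_factor <- function(net_exchange, applied_current_density) {
  check_positive(applied_current_density, "applied_current_density")
  check_nonnegative(net_exchange, "net_exchange")
  net_exchange / applied_current_density
}

#' Brain current-density field
#'
#' A 3D array of current-density magnitudes (A/m^2) with voxel-size
#' metadata, as produced by a head-scale volume-conductor model.
#'
#' @param values 3D numeric array, A/m^2, all values >= 0.
#' @param voxel_size_mm Length-3 voxel size, mm.
#' @param applied_current_mA Applied stimulation current, mA.
#' @return A `brain_field` object.
#' @export
brain_field <- function(values, voxel_size_mm = c(1, 1, 1),
                        applied_current_mA = 1) {
  if (any(values < 0)) stop_invalid("current-density magnitudes must be >= 0")
  structure(list(values = values, voxel_size_mm = as.numeric(voxel_size_mm),
                 applied_current_mA = applied_current_mA),
            class = "brain_field")
}

#' @export
print.brain_field <- function(x, ...) {
  cat(sprintf("Brain current-density field %s voxels (%s mm), %g mA\n",
              paste(dim(x$values), collapse = "x"),
              paste(signif(x$voxel_size_mm, 3), collapse = "x"),
              x$applied_current_mA))
  cat(sprintf("  peak %.4g A/m^2\n", max(x$values)))
  invisible(x)
}

#' Synthetic brain current-density field
#'
#' Generates a smooth stand-in for a head-model current-density
#' distribution: a sum of 3D Gaussian lobes centred under the electrode
#' positions plus low-amplitude seeded noise, rescaled so the peak equals
#' 0.082 A/m^2 per mA of applied current.
#'
#' @param shape Integer length-3 array dimensions.
#' @param electrode_centers Matrix (m x 3) of lobe centres in voxel
#'   coordinates; default two frontal lobes.
#' @param applied_current_mA Applied current, mA (> 0).
#' @param seed Integer seed (deterministic output).
#' @param lobe_sd Gaussian lobe standard deviation, voxels.
#' @param noise_amplitude Relative noise amplitude (default 0.02).
#' @return A [brain_field()].
#' @examples
#' f <- synthetic_brain_field(c(16, 16, 16), applied_current_mA = 1, seed = 7)
#' max(f$values)  # exactly 0.082
#' @export
synthetic_brain_field <- function(shape = c(32L, 32L, 32L),
                                  electrode_centers = NULL,
                                  applied_current_mA = 1,
                                  seed = 1L,
                                  lobe_sd = NULL,
                                  noise_amplitude = 0.02) {
  check_positive(applied_current_mA, "applied_current_mA")
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop_invalid("`shape` must be positive")
  if (is.null(electrode_centers)) {
    electrode_centers <- rbind(c(0.35, 0.5, 0.8), c(0.65, 0.5, 0.8)) *
      matrix(shape, 2, 3, byrow = TRUE)
  }
  if (is.null(lobe_sd)) lobe_sd <- mean(shape) / 5
  ax <- lapply(1:3, function(k) seq_len(shape[k]))
  vals <- array(0, dim = shape)
  for (r in seq_len(nrow(electrode_centers))) {
    cx <- electrode_centers[r, ]
    gx <- exp(-(ax[[1]] - cx[1])^2 / (2 * lobe_sd^2))
    gy <- exp(-(ax[[2]] - cx[2])^2 / (2 * lobe_sd^2))
    gz <- exp(-(ax[[3]] - cx[3])^2 / (2 * lobe_sd^2))
    vals <- vals + outer(outer(gx, gy), gz)
  }
  noise <- with_seed(seed, array(runif(prod(shape)), dim = shape))
  vals <- vals * (1 - noise_amplitude + noise_amplitude * noise)
  vals <- vals / max(vals) * 0.082 * applied_current_mA
  brain_field(vals, voxel_size_mm = c(1, 1, 1),
              applied_current_mA = applied_current_mA)
}

#' Scale a brain current-density map to an exchange map
#'
#' Voxelwise application of the scaling factor k: each voxel's exchange
#' rate (1/min) is k times its current density. Metadata (voxel size,
#' applied current) is preserved.
#'
#' @param field A [brain_field()].
#' @param k Scaling factor, m^2/(A min) (>= 0).
#' @return An `exchange_map`: list with `values` (1/min), `voxel_size_mm`,
#'   `applied_current_mA` and `scaling_factor_k`.
#' @examples
#' f <- synthetic_brain_field(c(8, 8, 8), seed = 1)
#' m <- scale_brain_map(f, 1.83e-3)
#' max(m$values)  # about 1.5e-4 per min
#' @export
scale_brain_map <- function(field, k) {
  stopifnot(inherits(field, "brain_field"))
  check_nonnegative(k, "k")
  if (any(field$values < 0)) stop_invalid("field values must be >= 0")
  structure(list(values = field$values * k,
                 voxel_size_mm = field$voxel_size_mm,
                 applied_current_mA = field$applied_current_mA,
                 scaling_factor_k = k),
            class = "exchange_map")
}

#' @export
print.exchange_map <- function(x, ...) {
  cat(sprintf("Interstitial exchange map %s voxels, k = %.4g m^2/(A min)\n",
              paste(dim(x$values), collapse = "x"), x$scaling_factor_k))
  cat(sprintf("  peak exchange %.4g 1/min at %g mA\n",
              max(x$values), x$applied_current_mA))
  invisible(x)
}

#' Write a volumetric map (brain field or exchange map)
#'
#' Writes NIfTI when the RNifti package is available and `path` ends in
#' `.nii`/`.nii.gz`; otherwise writes a portable flat text array
#' (one value per line, Fortran order) with a JSON sidecar carrying the
#' dimensions, voxel size, units and applied current.
#'
#' @param map A `brain_field` or `exchange_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(map, path) {
  stopifnot(inherits(map, "brain_field") || inherits(map, "exchange_map"))
  units <- if (inherits(map, "brain_field")) "A/m^2" else "1/min"
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("writing NIfTI requires the RNifti package")
    }
    img <- RNifti::asNifti(map$values)
    RNifti::pixdim(img) <- map$voxel_size_mm
    RNifti::writeNifti(img, path)
  } else {
    writeLines(format(as.vector(map$values), digits = 17), path)
    sidecar <- list(dim = dim(map$values), voxel_size_mm = map$voxel_size_mm,
                    units = units, applied_current_mA = map$applied_current_mA)
    if (inherits(map, "exchange_map")) sidecar$scaling_factor_k <- map$scaling_factor_k
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a volumetric map written by [write_volume()]
#'
#' @param path Path to the flat-text array (with JSON sidecar) or NIfTI file.
#' @return A `brain_field` (fields in A/m^2) or plain array with attributes
#'   for exchange maps.
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      stop("reading NIfTI requires the RNifti package")
    }
    img <- RNifti::readNifti(path)
    return(brain_field(array(as.numeric(img), dim = dim(img)),
                       voxel_size_mm = RNifti::pixdim(img)))
  }
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- array(as.numeric(readLines(path)), dim = sidecar$dim)
  if (identical(sidecar$units, "A/m^2")) {
    brain_field(vals, sidecar$voxel_size_mm,
                applied_current_mA = sidecar$applied_current_mA %||% 1)
  } else {
    structure(list(values = vals, voxel_size_mm = sidecar$voxel_size_mm,
                   applied_current_mA = sidecar$applied_current_mA %||% 1,
                   scaling_factor_k = sidecar$scaling_factor_k %||% NA_real_),
              class = "exchange_map")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
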
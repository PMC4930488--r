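#' Reference parameter set for the explosive-dispersal pipeline
#'
#' A single named parameter set drives every module: valve geometry and layer
#' materials for the energy landscape and rod dynamics, cell geometry and wall
#' materials for the pressurized-cell model, seed and air properties for
#' ballistics, and tether properties for seed release.  Each field carries a
#' provenance tag:
#'
#' * `PAPER` -- printed in the study this pipeline models (e.g. the 20 %
#'   exocarp rest contraction, 0.7 MPa turgor, the cell dimensions),
#' * `DERIVED` -- produced by the package's own calibration operations
#'   (layer moduli reproducing the measured energy landscape, wall moduli
#'   reproducing the osmotic deformations, tether constants reproducing the
#'   measured mean launch speed),
#' * `ASSUMED` -- set once to a realistic value where no measurement exists
#'   (layer thicknesses, seed mass, release height, ...).
#'
#' Values are stored in the natural units of each quantity (documented per
#' field in [param_units()]); modules convert to SI internally via [to_si()].
#'
#' @param ... named overrides of individual fields, e.g.
#'   `reference_params(turgor_pressure = 0.65)`.  Unknown names are an error.
#' @return an object of class `pod_params`: a named list of values with
#'   attributes `provenance` (named character) and `units`.
#' @examples
#' p <- reference_params()
#' p$exocarp_rest_contraction  # 0.2
#' p$turgor_pressure           # 0.7 MPa
#' @export
reference_params <- function(...) {
  defaults <- list(
    # --- valve / trilayer geometry ---
    valve_length = 16,            # mm, from a 17 mm fruit minus attachment
    valve_width = 2,              # mm
    exocarp_thickness = 20,       # um
    middle_thickness = 100,       # um (mesocarp + non-lignified endocarp b)
    endocarpb_rod_thickness = 5,  # um, lignified rod band on the inner face
    exocarp_rest_contraction = 0.20,  # dimensionless fraction ("gamma")
    E_exocarp = 55,               # MPa
    E_middle = 10,                # MPa
    E_lignin = 5000,              # MPa
    tissue_density = 1000,        # kg/m^3, sets mass per area of the layers
    lignified_area_fraction = 0.5,  # phi, rods as fraction of width (hinged)
    transverse_curvature = 2,     # 1/mm, initial cross-section bowing kappa_t
    hinge_stiffness = 1e-6,       # N*mm per rad^2 per mm, thin lignin hinges
    boxed_depth = 60,             # um, lignified sandwich depth (boxed walls)
    # --- cell scale ---
    turgor_pressure = 0.7,        # MPa
    cell_dims_mature = c(50, 50, 20),     # um, length x width x depth
    cell_dims_immature = c(30, 20, 14),   # um
    cell_dims_athaliana = c(100, 20, 20), # um
    wall_thickness = 1,           # um
    E_wall_width = 40,            # MPa (transverse wall modulus; calibrated)
    E_wall_length = 120,          # MPa (longitudinal wall modulus; calibrated)
    wall_poisson = 0.3,           # dimensionless
    outer_wall_factor = 4,        # outer/inner periclinal wall thickness / t_w
    # --- seeds, tethers, flight ---
    seed_mass = 1,                # mg
    seed_radius = 0.8,            # mm, drag-equivalent radius of the discoid seed
    n_seeds = 10,                 # seeds per valve
    tether_k = 350,               # N/m, pectic adhesion spring
    tether_c = 2e-4,              # N*s/m, pectic adhesion damper
    tether_delta_c = 175,         # um, critical extension at rupture
    release_height = 0.2,         # m
    air_density = 1.204,          # kg/m^3
    gravity = 9.81,               # m/s^2
    drag_model = "constant_cd",   # or "sphere_correlation"
    drag_cd = 0.7                 # dimensionless; tumbling-disc equivalent
  )
  prov <- c(
    valve_length = "DERIVED", valve_width = "ASSUMED",
    exocarp_thickness = "ASSUMED", middle_thickness = "ASSUMED",
    endocarpb_rod_thickness = "ASSUMED",
    exocarp_rest_contraction = "PAPER",
    E_exocarp = "DERIVED", E_middle = "DERIVED", E_lignin = "ASSUMED",
    tissue_density = "ASSUMED", lignified_area_fraction = "ASSUMED",
    transverse_curvature = "ASSUMED", hinge_stiffness = "ASSUMED",
    boxed_depth = "ASSUMED",
    turgor_pressure = "PAPER",
    cell_dims_mature = "PAPER", cell_dims_immature = "PAPER",
    cell_dims_athaliana = "PAPER",
    wall_thickness = "ASSUMED",
    E_wall_width = "DERIVED", E_wall_length = "DERIVED",
    wall_poisson = "ASSUMED", outer_wall_factor = "DERIVED",
    seed_mass = "ASSUMED", seed_radius = "ASSUMED", n_seeds = "ASSUMED",
    tether_k = "DERIVED", tether_c = "DERIVED", tether_delta_c = "ASSUMED",
    release_height = "ASSUMED", air_density = "ASSUMED", gravity = "ASSUMED",
    drag_model = "ASSUMED", drag_cd = "ASSUMED"
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  p <- structure(defaults, class = "pod_params",
                 provenance = prov, units = param_units())
  validate_params(p)
  p
}

#' Units of each reference parameter field
#'
#' @return named character vector mapping field names to their fixed unit.
#' @export
param_units <- function() {
  c(valve_length = "mm", valve_width = "mm", exocarp_thickness = "um",
    middle_thickness = "um", endocarpb_rod_thickness = "um",
    exocarp_rest_contraction = "1", E_exocarp = "MPa", E_middle = "MPa",
    E_lignin = "MPa", tissue_density = "kg/m^3",
    lignified_area_fraction = "1", transverse_curvature = "1/mm",
    hinge_stiffness = "N*mm/rad^2/mm", boxed_depth = "um",
    turgor_pressure = "MPa", cell_dims_mature = "um",
    cell_dims_immature = "um", cell_dims_athaliana = "um",
    wall_thickness = "um", E_wall_width = "MPa", E_wall_length = "MPa",
    wall_poisson = "1", outer_wall_factor = "1",
    seed_mass = "mg", seed_radius = "mm", n_seeds = "1",
    tether_k = "N/m", tether_c = "N*s/m", tether_delta_c = "um",
    release_height = "m", air_density = "kg/m^3", gravity = "m/s^2",
    drag_model = "id", drag_cd = "1")
}

#' Validate a reference parameter set
#'
#' Checks strict positivity of lengths, moduli, masses and pressures, that the
#' rest contraction lies in (0, 1), the lignified area fraction in (0, 1], and
#' that every field carries a provenance tag.
#'
#' @param p a `pod_params` object.
#' @return `p`, invisibly; errors name the offending field.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "pod_params"))
  positive <- c("valve_length", "valve_width", "exocarp_thickness",
                "middle_thickness", "endocarpb_rod_thickness", "E_exocarp",
                "E_middle", "E_lignin", "tissue_density", "turgor_pressure",
                "wall_thickness", "E_wall_width", "E_wall_length",
                "seed_mass", "seed_radius", "tether_k", "tether_delta_c",
                "air_density", "gravity", "drag_cd", "boxed_depth",
                "cell_dims_mature", "cell_dims_immature", "cell_dims_athaliana")
  for (f in positive) {
    if (any(!is.finite(p[[f]])) || any(p[[f]] <= 0)) {
      stop("parameter '", f, "' must be strictly positive", call. = FALSE)
    }
  }
  g <- p$exocarp_rest_contraction
  if (!is.finite(g) || g <= 0 || g >= 1) {
    stop("parameter 'exocarp_rest_contraction' must lie in (0, 1)",
         call. = FALSE)
  }
  phi <- p$lignified_area_fraction
  if (!is.finite(phi) || phi <= 0 || phi > 1) {
    stop("parameter 'lignified_area_fraction' must lie in (0, 1]",
         call. = FALSE)
  }
  if (p$wall_poisson < 0 || p$wall_poisson >= 0.5) {
    stop("parameter 'wall_poisson' must lie in [0, 0.5)", call. = FALSE)
  }
  if (!p$drag_model %in% c("constant_cd", "sphere_correlation")) {
    stop("parameter 'drag_model' must be 'constant_cd' or 'sphere_correlation'",
         call. = FALSE)
  }
  prov <- attr(p, "provenance")
  missing_tag <- setdiff(names(unclass(p)), names(prov))
  if (length(missing_tag)) {
    stop("missing provenance tag for: ", paste(missing_tag, collapse = ", "),
         call. = FALSE)
  }
  invisible(p)
}

#' Load the reference parameters, optionally overridden by a config file
#'
#' The config is a flat YAML key-value file whose keys match the field names
#' of [reference_params()].  Unknown keys are rejected; every override is
#' reported via `message()`; the merged set must pass [validate_params()].
#'
#' @param config_path path to a YAML file, or `NULL` for pure defaults.
#' @return a validated `pod_params` object.
#' @export
load_reference <- function(config_path = NULL) {
  if (is.null(config_path)) {
    return(reference_params())
  }
  if (!file.exists(config_path)) {
    stop("config file not found: ", config_path, call. = FALSE)
  }
  cfg <- tryCatch(
    yaml::read_yaml(config_path),
    error = function(e) {
      stop("malformed config file '", config_path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.list(cfg)) stop("config must be a key-value mapping", call. = FALSE)
  defaults <- reference_params()
  bad <- setdiff(names(cfg), names(unclass(defaults)))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (k in names(cfg)) {
    message("override: ", k, " = ", paste(cfg[[k]], collapse = " x "),
            " (default ", paste(defaults[[k]], collapse = " x "), ")")
  }
  do.call(reference_params, cfg)
}

#' @export
print.pod_params <- function(x, ...) {
  prov <- attr(x, "provenance")
  units <- attr(x, "units")
  cat("Reference parameter set (", length(unclass(x)), " fields)\n", sep = "")
  for (f in names(unclass(x))) {
    cat(sprintf("  %-26s %-14s [%s] %s\n", f,
                paste(format(x[[f]], digits = 4), collapse = "x"),
                units[[f]], prov[[f]]))
  }
  invisible(x)
}
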
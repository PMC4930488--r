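#' Layer specification for the valve trilayer
#'
#' A through-thickness layer of the fruit-valve wall, described by its band
#' `[z_lo, z_hi]` (um, measured from the inner face of the lignified
#' endocarp-b layer), Young's modulus, rest axial strain and load-bearing
#' area fraction.  The exocarp is the only active layer: its rest strain is
#' `-gamma`, the turgor-driven rest contraction, so that holding the valve
#' flat keeps it under tension.
#'
#' @param name label.
#' @param z_lo,z_hi band limits in um, `z_hi > z_lo`.
#' @param E Young's modulus in MPa.
#' @param g rest axial strain (dimensionless, `|g| < 1`); 0 for passive
#'   layers, `-gamma` for the exocarp.
#' @param area_fraction fraction of the width that is load-bearing (lignified
#'   rods cover only part of the width), in (0, 1].
#' @param density tissue density in kg/m^3 (sets the lumped mass).
#' @return a `layer_spec` object.
#' @export
layer_spec <- function(name, z_lo, z_hi, E, g = 0, area_fraction = 1,
                       density = 1000) {
  stopifnot(z_hi > z_lo, E > 0, area_fraction > 0, area_fraction <= 1,
            abs(g) < 1, density > 0)
  structure(list(name = name, z_lo = z_lo, z_hi = z_hi, E = E, g = g,
                 area_fraction = area_fraction, density = density),
            class = "layer_spec")
}

#' Cross-section specification: hinged versus boxed endocarp-b walls
#'
#' The lignified secondary walls of the endocarp-b layer either form three
#' stiff longitudinal rods joined by very thin hinges (the explosive,
#' "hinged" geometry) or a stiff closed box around each cell (the
#' non-explosive "boxed" geometry).  The hinges let the cross-section flatten
#' at negligible energetic cost; the box resists flattening through the
#' transverse bending stiffness of its lignified plates.
#'
#' @param kind `"hinged"` or `"boxed"`.
#' @param kappa_t initial transverse (cross-sectional) curvature, 1/mm.
#' @param hinge_stiffness effective rotational hinge stiffness, N*mm per
#'   rad^2 per mm of valve length (smeared over all hinge lines).
#' @param plate_thickness,plate_separation transverse lignified plate band
#'   thickness and mid-plane separation (um), used for the boxed
#'   plate-bending flattening cost.  The plates are per-cell in the
#'   transverse direction, so the separation is the endocarp-b cell depth,
#'   not the full lignified sandwich.
#' @param plate_area_fraction load-bearing fraction of the transverse plates.
#' @return a `cross_section_spec` object.
#' @export
cross_section_spec <- function(kind = c("hinged", "boxed"), kappa_t = 2,
                               hinge_stiffness = 1e-6, plate_thickness = 5,
                               plate_separation = 20,
                               plate_area_fraction = 0.9) {
  kind <- match.arg(kind)
  stopifnot(kappa_t >= 0, hinge_stiffness >= 0, plate_thickness > 0,
            plate_separation > plate_thickness)
  structure(list(kind = kind, kappa_t = kappa_t,
                 hinge_stiffness = hinge_stiffness,
                 plate_thickness = plate_thickness,
                 plate_separation = plate_separation,
                 plate_area_fraction = plate_area_fraction),
            class = "cross_section_spec")
}

#' Build the reference valve model
#'
#' Assembles the layered valve from a parameter set.  The hinged geometry
#' carries one band of lignified rods on the inner endocarp-b face; the boxed
#' geometry (as produced by ectopic secondary-wall patterning) carries a deep
#' lignified sandwich -- inner plate, side-wall web, outer plate -- spanning
#' the endocarp-b layer plus the two adjacent (also lignified) tissue layers,
#' with the passive middle layer thinned so that total valve thickness is
#' unchanged.
#'
#' @param params a `pod_params` set, see [reference_params()].
#' @param geometry `"hinged"` or `"boxed"`.
#' @return a `valve_model`: list with `L`, `w` (mm), `layers` (list of
#'   [layer_spec()]), `cross_section`, `mass_per_area` (mg/mm^2 per layer).
#' @export
valve_model <- function(params = reference_params(),
                        geometry = c("hinged", "boxed")) {
  geometry <- match.arg(geometry)
  g <- -params$exocarp_rest_contraction
  t_rod <- params$endocarpb_rod_thickness
  t_mid <- params$middle_thickness
  t_exo <- params$exocarp_thickness
  rho <- params$tissue_density
  if (geometry == "hinged") {
    layers <- list(
      layer_spec("endocarp_b_rods", 0, t_rod, params$E_lignin,
                 area_fraction = params$lignified_area_fraction,
                 density = rho),
      layer_spec("middle", t_rod, t_rod + t_mid, params$E_middle,
                 density = rho),
      layer_spec("exocarp", t_rod + t_mid, t_rod + t_mid + t_exo,
                 params$E_exocarp, g = g, density = rho)
    )
    cs <- cross_section_spec("hinged", kappa_t = params$transverse_curvature,
                             hinge_stiffness = params$hinge_stiffness,
                             plate_thickness = t_rod)
  } else {
    D <- params$boxed_depth
    t_mid_b <- t_rod + t_mid - D  # keep total thickness equal to hinged
    if (t_mid_b <= 0) stop("boxed_depth exceeds available middle thickness")
    layers <- list(
      layer_spec("box_inner_plate", 0, t_rod, params$E_lignin,
                 area_fraction = 0.9, density = rho),
      layer_spec("box_side_walls", t_rod, D - t_rod, params$E_lignin,
                 area_fraction = 0.2, density = rho),
      layer_spec("box_outer_plate", D - t_rod, D, params$E_lignin,
                 area_fraction = 0.9, density = rho),
      layer_spec("middle", D, D + t_mid_b, params$E_middle, density = rho),
      layer_spec("exocarp", D + t_mid_b, D + t_mid_b + t_exo,
                 params$E_exocarp, g = g, density = rho)
    )
    cs <- cross_section_spec("boxed", kappa_t = params$transverse_curvature,
                             hinge_stiffness = params$hinge_stiffness,
                             plate_thickness = t_rod, plate_separation = 20)
  }
  E_lab <- c("exocarp", "middle")
  if (!all(E_lab %in% vapply(layers, `[[`, "", "name"))) {
    stop("valve model must contain exocarp and middle layers")
  }
  mass_per_area <- vapply(layers, function(l) {
    # rho [kg/m^3] * t [m] = kg/m^2, numerically equal to mg/mm^2
    l$density * (l$z_hi - l$z_lo) * 1e-6
  }, 0)
  structure(list(L = params$valve_length, w = params$valve_width,
                 layers = layers, cross_section = cs,
                 mass_per_area = mass_per_area, E_lignin = params$E_lignin),
            class = "valve_model")
}

#' Stack resultants of the layered valve
#'
#' Closed-form integrals of the quadratic strain energy density over the
#' layer stack.  With axial strain `eps(z) = eps0 + kappa * z` and per-layer
#' rest strain `g_i`, the energy per unit length is
#' `U = 1/2 * sum_i E_i w a_i int (eps0 + kappa z - g_i)^2 dz`, which expands
#' into the resultants returned here (all SI):
#' `EA` (N), `ES` (N m), `EI` (N m^2), rest force `N0` (N), rest moment
#' `M0` (N m) and constant `C0` (J/m).
#'
#' @param valve a [valve_model()].
#' @return named list of resultants in SI units.
#' @export
stack_resultants <- function(valve) {
  if (!length(valve$layers)) stop("valve has no layers")
  w <- to_si(valve$w, "mm")
  EA <- ES <- EI <- N0 <- M0 <- C0 <- 0
  for (l in valve$layers) {
    E <- to_si(l$E, "MPa")
    z0 <- to_si(l$z_lo, "um")
    z1 <- to_si(l$z_hi, "um")
    k <- E * l$area_fraction * w
    EA <- EA + k * (z1 - z0)
    ES <- ES + k * (z1^2 - z0^2) / 2
    EI <- EI + k * (z1^3 - z0^3) / 3
    N0 <- N0 + k * l$g * (z1 - z0)
    M0 <- M0 + k * l$g * (z1^2 - z0^2) / 2
    C0 <- C0 + 0.5 * k * l$g^2 * (z1 - z0)
  }
  list(EA = EA, ES = ES, EI = EI, N0 = N0, M0 = M0, C0 = C0)
}

#' Elastic energy per unit length at a given longitudinal curvature
#'
#' Minimizes the membrane strain `eps0` out analytically (the net axial
#' stress resultant vanishes at the optimum), leaving an upward parabola in
#' the curvature.
#'
#' @param valve a [valve_model()].
#' @param kappa longitudinal curvature(s), 1/mm.  Positive values curve the
#'   valve towards its exocarp side (the coiling direction).
#' @return energy per unit length in mJ/mm (numerically equal to J/m).
#' @export
energy_at_curvature <- function(valve, kappa) {
  r <- stack_resultants(valve)
  k_si <- -kappa * 1e3  # coiling direction: exocarp on the concave side
  EIr <- r$EI - r$ES^2 / r$EA
  Mr <- r$M0 - r$ES * r$N0 / r$EA
  0.5 * EIr * k_si^2 - Mr * k_si + (r$C0 - r$N0^2 / (2 * r$EA))
}

#' Membrane strain minimizing the energy at a curvature
#'
#' @param valve a [valve_model()].
#' @param kappa curvature, 1/mm (coiling direction positive).
#' @return optimal `eps0` (dimensionless); at this strain the net axial
#'   force resultant is zero.
#' @keywords internal
optimal_eps0 <- function(valve, kappa) {
  r <- stack_resultants(valve)
  (r$N0 - r$ES * (-kappa * 1e3)) / r$EA
}

#' Energy cost of flattening the valve cross-section
#'
#' To coil lengthwise the bowed valve must first flatten transversely (the
#' slap-bracelet constraint).  With hinged endocarp-b walls the rods rotate
#' about thin lignin hinges: the cost is quadratic in the total hinge opening
#' `theta = kappa_t * w` with a very small smeared stiffness.  With boxed
#' walls the lignified plates must bend transversely: the cost is the plate
#' bending energy `1/2 * D_t * kappa_t^2 * (w * L)` with `D_t` the sandwich
#' bending stiffness of the per-cell plate pair.
#'
#' @param cross_section a [cross_section_spec()].
#' @param valve a [valve_model()].
#' @return energy in mJ (always >= 0).
#' @export
flatten_cost <- function(cross_section = valve$cross_section, valve) {
  cs <- cross_section
  kt <- cs$kappa_t * 1e3           # 1/m
  L <- to_si(valve$L, "mm")
  w <- to_si(valve$w, "mm")
  if (kt == 0) return(0)
  if (cs$kind == "hinged") {
    theta <- kt * w                 # total opening angle across the width
    k_h <- cs$hinge_stiffness * 1e-3 / 1e-3  # N*mm/mm -> N (per unit length)
    cost <- 0.5 * k_h * theta^2 * L
  } else {
    E <- to_si(valve$E_lignin, "MPa")
    tp <- to_si(cs$plate_thickness, "um")
    sep <- to_si(cs$plate_separation, "um")
    af <- cs$plate_area_fraction
    d <- (sep - tp) / 2             # plate centroid offset from mid-plane
    D_t <- 2 * E * af * (tp^3 / 12 + tp * d^2)  # N*m, per unit width
    cost <- 0.5 * D_t * kt^2 * (w * L)
  }
  from_si(cost, "mJ")
}

#' Energy landscape of the detached valve
#'
#' Computes the stored elastic energy as a function of longitudinal curvature
#' once the cross-section is flat, locates the coiled equilibrium in closed
#' form (the vertex of the parabola), and reports the energy released between
#' the initial flat, attached configuration and the coiled state.  For the
#' boxed geometry the flattening cost is subtracted from the release.
#'
#' @param valve a [valve_model()].
#' @param kappa_max upper end of the curvature grid (1/mm); defaults to twice
#'   the equilibrium curvature.
#' @param n_grid number of grid points (>= 3).
#' @return a `pod_landscape`: list with `kappa_grid` (1/mm), `U_flat` (mJ,
#'   total valve energy at each curvature), `U_initial` (mJ), `kappa_star`
#'   (1/mm), `delta_E` (mJ), `coils`, `coils_half` (rounded to nearest half
#'   coil), `flatten_cost` (mJ).
#' @export
landscape <- function(valve, kappa_max = NULL, n_grid = 201) {
  if (n_grid < 3) stop("n_grid must be >= 3")
  r <- stack_resultants(valve)
  EIr <- r$EI - r$ES^2 / r$EA
  Mr <- r$M0 - r$ES * r$N0 / r$EA
  kappa_star_si <- -Mr / EIr       # internal sign; coiling direction is -z
  kappa_star <- abs(kappa_star_si) / 1e3  # 1/mm, coiling direction positive
  if (is.null(kappa_max)) kappa_max <- max(2 * kappa_star, 1e-9)
  if (kappa_max <= 0) stop("kappa_max must be positive")
  kappa_grid <- seq(0, kappa_max, length.out = n_grid)
  L <- to_si(valve$L, "mm")
  # energy_at_curvature returns J/m; times L (m) gives J; report mJ
  U_flat <- energy_at_curvature(valve, kappa_grid) * L * 1e3
  fc <- flatten_cost(valve$cross_section, valve)
  U0 <- energy_at_curvature(valve, 0) * L * 1e3
  Ustar <- energy_at_curvature(valve, kappa_star) * L * 1e3
  delta_E <- (U0 - Ustar) - fc
  coils <- to_si(valve$L, "mm") * (kappa_star * 1e3) / (2 * pi)
  structure(list(kappa_grid = kappa_grid, U_flat = U_flat, U_initial = U0,
                 kappa_star = kappa_star, delta_E = delta_E,
                 coils = coils, coils_half = round(coils * 2) / 2,
                 flatten_cost = fc, EI_reduced = EIr, resultants = r),
            class = "pod_landscape")
}

#' @export
print.pod_landscape <- function(x, ...) {
  cat("Valve energy landscape\n")
  cat(sprintf("  equilibrium curvature : %.3f 1/mm\n", x$kappa_star))
  cat(sprintf("  coils                 : %.2f (%.1f to nearest half)\n",
              x$coils, x$coils_half))
  cat(sprintf("  energy released       : %.3f mJ\n", x$delta_E))
  cat(sprintf("  flattening cost       : %.4f mJ\n", x$flatten_cost))
  invisible(x)
}
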
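# Shared fixtures, built once per test session.

ref_p <- reference_params()
ref_valve <- valve_model(ref_p, "hinged")
ref_land <- landscape(ref_valve)
box_valve <- valve_model(ref_p, "boxed")
box_land <- landscape(box_valve)

# small bilayer valve assembled by hand (for closed-form oracles)
make_bilayer <- function(E1, E2, t1, t2, dg, L = 10, w = 1) {
  layers <- list(
    layer_spec("bottom", 0, t1, E1, g = 0),
    layer_spec("top", t1, t1 + t2, E2, g = -dg)
  )
  structure(list(L = L, w = w, layers = layers,
                 cross_section = cross_section_spec("hinged", kappa_t = 0),
                 mass_per_area = c(t1, t2) * 1e-3, E_lignin = 1),
            class = "valve_model")
}

# classical bimetal-strip curvature (Freund form), per unit misfit strain
timoshenko_kappa <- function(E1, E2, t1, t2, dg) {
  num <- 6 * E1 * E2 * t1 * t2 * (t1 + t2) * dg
  den <- E1^2 * t1^4 + 4 * E1 * E2 * t1^3 * t2 + 6 * E1 * E2 * t1^2 * t2^2 +
    4 * E1 * E2 * t1 * t2^3 + E2^2 * t2^4
  num / den
}

run_reference_release <- function(n_segments = 80, T_end = 4, seeds = NULL,
                                  dt = 1e-4, stride = 200, ...) {
  rod <- build_rod(ref_valve, ref_land, n_segments)
  if (is.null(seeds)) seeds <- seed_tethers(ref_p)
  simulate_release(rod, seeds, dt = dt, T_end = T_end, stride = stride, ...)
}

small_cell <- cell_geom(50, 50, 20, 1)
ref_wall <- wall_material(E_length = ref_p$E_wall_length,
                          E_width = ref_p$E_wall_width,
                          poisson = ref_p$wall_poisson)

# unwrap a tangent-angle sequence so finite differences measure curvature
unwrap_angles <- function(th) {
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(th[1], d))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ratio-calibrated mature-cell material at refinement 2 (computed once)
calibrated_mature <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate_anisotropy(small_cell, E_width = ref_p$E_wall_width,
                                     P = 0.7, target_volume_pct = 53,
                                     refinement = 2, outer_wall_factor = 4)
    }
    cache
  }
})
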
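#' Synthetic data bundles
#'
#' Every generator returns a `synthetic_bundle`: the payload tables in the
#' exact formats the consumer modules read, together with the ground-truth
#' parameters, the RNG seed and the noise specification.  Regenerating with
#' the same seed reproduces the payload exactly; the ground truth suffices
#' to recompute the noise-free payload.
#'
#' @param payload the generated data.
#' @param ground_truth named list of generating parameters.
#' @param rng_seed integer seed.
#' @param noise list describing the noise distribution and scale.
#' @return a `synthetic_bundle`.
#' @keywords internal
synthetic_bundle <- function(payload, ground_truth, rng_seed, noise) {
  structure(list(payload = payload, ground_truth = ground_truth,
                 rng_seed = rng_seed, noise = noise),
            class = "synthetic_bundle")
}

#' Synthetic tracked-point explosion movie
#'
#' Runs the coiling dynamics and samples material-point trajectories at the
#' high-speed frame rate, adding Gaussian position noise -- emulating
#' manually tracked points on explosion movies.
#'
#' @param params a `pod_params` set.
#' @param n_points number of tracked points (>= 1).
#' @param noise_sd Gaussian position noise (um).
#' @param seed RNG seed.
#' @param fps frame rate (Hz).
#' @param n_segments,dt,T_end simulation controls passed to the dynamics.
#' @return a `synthetic_bundle` whose payload is the tracks table
#'   (`point`, `frame`, `x`, `y` in mm).
#' @export
gen_tracked_explosion <- function(params = reference_params(), n_points = 9,
                                  noise_sd = 10, seed = 1, fps = 15000,
                                  n_segments = 60, dt = 2e-4, T_end = 3) {
  stopifnot(n_points >= 1)
  v <- valve_model(params, "hinged")
  land <- landscape(v)
  rod <- build_rod(v, land, n_segments)
  series <- simulate_release(rod, seeds = NULL, dt = dt, T_end = T_end,
                             stride = 25)
  arcs <- seq(0, params$valve_length, length.out = n_points + 2)[2:(n_points + 1)]
  tr <- point_trajectories(series, arcs)
  # resample at the camera frame rate
  frame_t <- seq(0, max(tr$t_ms), by = 1000 / fps)
  tracks <- do.call(rbind, lapply(split(tr, tr$point), function(p) {
    data.frame(point = p$point[1], frame = seq_along(frame_t),
               x = stats::approx(p$t_ms, p$x_mm, frame_t)$y,
               y = stats::approx(p$t_ms, p$y_mm, frame_t)$y)
  }))
  rownames(tracks) <- NULL
  clean <- tracks
  noisy <- with_seed(seed, {
    out <- clean
    out$x <- out$x + stats::rnorm(nrow(out), 0, noise_sd * 1e-3)
    out$y <- out$y + stats::rnorm(nrow(out), 0, noise_sd * 1e-3)
    out
  })
  synthetic_bundle(noisy,
                   ground_truth = list(params = params, arclengths = arcs,
                                       fps = fps, clean = clean),
                   rng_seed = seed,
                   noise = list(dist = "gaussian", sd_um = noise_sd))
}

#' Synthetic extensometer curve
#'
#' Elastica forces on a 50-um displacement grid, passed through the setup
#' compliance, with a rupture event appended and multiplicative Gaussian
#' force noise.
#'
#' @param B_true bending stiffness (N mm^2).
#' @param kappa_hat intrinsic curvature (1/mm).
#' @param L contour length (mm).
#' @param k_setup setup stiffness (mN/um); `Inf` for a rigid setup.
#' @param noise_frac multiplicative noise SD as a fraction of each force.
#' @param seed RNG seed.
#' @param increment_um displacement increment (um).
#' @param max_fraction fraction of the coiled-branch extension range covered
#'   by the elastica phase.
#' @param taut_points number of setup-only increments after the valve is
#'   taut (these define the pre-rupture linear region).
#' @return a `synthetic_bundle` whose payload is an [extensometer_curve()]
#'   including the rupture tail.
#' @export
gen_extensometer <- function(B_true, kappa_hat, L, k_setup = 0.5,
                             noise_frac = 0, seed = 1, increment_um = 50,
                             max_fraction = 0.9, taut_points = 8) {
  stopifnot(k_setup > 0)
  d0 <- elastica_natural_distance(kappa_hat, L)
  d_max <- elastica_extension_limit(kappa_hat, L)
  d_end <- d0 + max_fraction * (d_max - d0)
  true_disp <- seq(0, (d_end - d0) * 1e3, by = increment_um)  # um
  forces <- elastica_force_displacement(B_true, kappa_hat, L,
                                        d0 + true_disp * 1e-3)
  # taut phase: the fully uncoiled valve is inextensible, so each further
  # increment loads the setup spring alone (slope = k_setup on raw axes)
  if (taut_points > 0 && is.finite(k_setup)) {
    f_taut <- utils::tail(forces, 1) + k_setup * increment_um *
      seq_len(taut_points)
    true_disp <- c(true_disp, rep(utils::tail(true_disp, 1), taut_points))
    forces <- c(forces, f_taut)
  }
  forces_noisy <- with_seed(seed, {
    forces * (1 + stats::rnorm(length(forces), 0, noise_frac))
  })
  raw_disp <- if (is.finite(k_setup)) {
    cumsum(c(true_disp[1], pmax(diff(true_disp), 0))) + forces_noisy / k_setup
  } else true_disp
  # rupture: force collapses within one increment
  raw_disp <- c(raw_disp, max(raw_disp) + increment_um)
  forces_noisy <- c(forces_noisy, 0.02 * max(forces_noisy))
  ord <- order(raw_disp)
  payload <- extensometer_curve(raw_disp[ord], forces_noisy[ord])
  synthetic_bundle(payload,
                   ground_truth = list(B_true = B_true, kappa_hat = kappa_hat,
                                       L = L, k_setup = k_setup,
                                       natural_distance = d0,
                                       true_displacement_um = true_disp,
                                       true_forces_mN = forces),
                   rng_seed = seed,
                   noise = list(dist = "gaussian_multiplicative",
                                frac = noise_frac))
}

#' Synthetic osmotic + microindentation measurements
#'
#' Runs the pressurized-cell model at the true parameters and perturbs the
#' dimension changes (and optionally the CFM stiffness) with multiplicative
#' Gaussian noise.
#'
#' @param geom a [cell_geom()].
#' @param material_true a [wall_material()].
#' @param P_true turgor pressure (MPa).
#' @param noise_frac multiplicative noise SD.
#' @param seed RNG seed.
#' @param refinement,outer_wall_factor model controls.
#' @param with_stiffness also simulate the indentation stiffness.
#' @return a `synthetic_bundle` with payload `list(targets, stiffness)`.
#' @export
gen_osmotic_cfm <- function(geom, material_true, P_true = 0.7,
                            noise_frac = 0, seed = 1, refinement = 2,
                            outer_wall_factor = 1, with_stiffness = FALSE) {
  osm <- osmotic_response(geom, material_true, geom$t_w, 0, P_true,
                          refinement, outer_wall_factor = outer_wall_factor)
  targets <- c(d_length_pct = osm$d_length_pct,
               d_width_pct = osm$d_width_pct,
               d_depth_pct = osm$d_depth_pct,
               d_volume_pct = osm$d_volume_pct)
  stiff <- if (with_stiffness)
    indentation_stiffness(osm$state_high)$stiffness_Npm else NA_real_
  noisy <- with_seed(seed, {
    t2 <- targets * (1 + stats::rnorm(length(targets), 0, noise_frac))
    s2 <- if (with_stiffness)
      stiff * (1 + stats::rnorm(1, 0, noise_frac)) else NA_real_
    list(targets = t2, stiffness = s2)
  })
  synthetic_bundle(noisy,
                   ground_truth = list(geom = geom, material = material_true,
                                       P = P_true, clean_targets = targets,
                                       clean_stiffness = stiff),
                   rng_seed = seed,
                   noise = list(dist = "gaussian_multiplicative",
                                frac = noise_frac))
}

#' Synthetic matched cell-outline pairs
#'
#' Random simple (star-shaped) polygons deformed by a per-cell affine
#' contraction field with optional direction switch across the series, plus
#' vertex position noise -- emulating pre/post excision outlines.
#'
#' @param n_cells number of cells (>= 1).
#' @param magnitude_pct contraction magnitude(s) in percent.
#' @param direction_deg contraction direction(s) (deg from fruit axis).
#' @param switch_index if given, cells at or beyond this index use
#'   `direction2_deg`.
#' @param direction2_deg second direction after the switch.
#' @param vertex_noise Gaussian vertex noise (um).
#' @param n_vertices vertices per polygon.
#' @param seed RNG seed.
#' @return a `synthetic_bundle`; payload is a list of outline pairs
#'   (elements `cell`, `pre`, `post`) as consumed by [tension_map()].
#' @export
gen_outline_pairs <- function(n_cells, magnitude_pct = 20,
                              direction_deg = 0, switch_index = NULL,
                              direction2_deg = 90, vertex_noise = 0,
                              n_vertices = 12, seed = 1) {
  stopifnot(n_cells >= 1)
  magnitude_pct <- rep_len(magnitude_pct, n_cells)
  dirs <- rep_len(direction_deg, n_cells)
  if (!is.null(switch_index)) {
    dirs[seq_len(n_cells) >= switch_index] <- direction2_deg
  }
  pairs <- with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      ang <- sort(stats::runif(n_vertices, 0, 2 * pi))
      rad <- stats::runif(n_vertices, 15, 30)
      pre <- cbind(rad * cos(ang), rad * sin(ang))
      th <- dirs[i] * pi / 180
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      S <- R %*% diag(c(1 - magnitude_pct[i] / 100, 1)) %*% t(R)
      post <- pre %*% t(S)
      if (vertex_noise > 0) {
        post <- post + matrix(stats::rnorm(2 * n_vertices, 0, vertex_noise),
                              ncol = 2)
      }
      list(cell = i, pre = pre, post = post)
    })
  })
  synthetic_bundle(pairs,
                   ground_truth = list(magnitude_pct = magnitude_pct,
                                       direction_deg = dirs,
                                       switch_index = switch_index),
                   rng_seed = seed,
                   noise = list(dist = "gaussian", sd_um = vertex_noise))
}

#' Synthetic landing-distance field
#'
#' Samples landing distances and azimuths from a specified distribution
#' (uniform annulus by default, mimicking the plateau-shaped measured
#' distribution).
#'
#' @param n number of seeds (>= 1).
#' @param r_range annulus radii (m) for the uniform spec.
#' @param distribution `"uniform_annulus"` or `"fixed_radius"`.
#' @param seed RNG seed.
#' @return a `synthetic_bundle`; payload is a data.frame `distance`,
#'   `azimuth_deg`, plus a `degenerate` flag in the ground truth for the
#'   fixed-radius case.
#' @export
gen_landing_field <- function(n, r_range = c(0.2, 1.8),
                              distribution = c("uniform_annulus",
                                               "fixed_radius"), seed = 1) {
  stopifnot(n >= 1)
  distribution <- match.arg(distribution)
  payload <- with_seed(seed, {
    d <- if (distribution == "uniform_annulus")
      stats::runif(n, r_range[1], r_range[2]) else rep(r_range[1], n)
    data.frame(distance = d, azimuth_deg = stats::runif(n, 0, 360))
  })
  synthetic_bundle(payload,
                   ground_truth = list(distribution = distribution,
                                       r_range = r_range,
                                       degenerate =
                                         distribution == "fixed_radius"),
                   rng_seed = seed,
                   noise = list(dist = "none"))
}
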
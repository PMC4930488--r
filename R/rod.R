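#' Discretize the valve as a planar elastic rod
#'
#' Builds the initial state for the coiling simulation: a straight rod (the
#' flat, just-detached valve) with uniform intrinsic curvature equal to the
#' equilibrium curvature of the energy landscape, bending stiffness equal to
#' the reduced bending resultant of the layer stack, and mass lumped from the
#' layer mass per area.
#'
#' @param valve a [valve_model()].
#' @param land a `pod_landscape` from [landscape()].
#' @param n_segments number of segments (>= 3; >= 20 recommended).
#' @return a `rod_state` list: `X`, `V` (m, m/s; (n+1) x 2), `mass` (kg per
#'   node), `h` (m), `EA` (N), `B` (N m^2 per interior node), `kap0` (1/m),
#'   `offset` (J; axial mismatch energy of the coiled state, added to the
#'   rod's elastic energy so that the straight-rod total matches the
#'   landscape's initial energy), `L` (m).
#' @export
build_rod <- function(valve, land, n_segments = 80) {
  if (n_segments < 3) stop("n_segments must be >= 3")
  L <- to_si(valve$L, "mm")
  w <- to_si(valve$w, "mm")
  h <- L / n_segments
  n <- n_segments + 1
  X <- cbind(seq(0, L, length.out = n), rep(0, n))
  V <- matrix(0, n, 2)
  mpa <- sum(valve$mass_per_area)  # mg/mm^2, numerically kg/m^2
  mass <- rep(mpa * w * h, n)
  mass[c(1, n)] <- mass[c(1, n)] / 2
  r <- land$resultants
  structure(list(
    X = X, V = V, mass = mass, h = h,
    EA = r$EA,
    B = rep(land$EI_reduced, n - 2),
    kap0 = rep(land$kappa_star * 1e3, n - 2),
    offset = (land$U_initial - land$delta_E - land$flatten_cost) * 1e-3,  # J
    L = L), class = "rod_state")
}

#' Default seed tethers along the valve
#'
#' Seeds adhere to the inner valve surface through a pectic contact modeled
#' as a breakable Kelvin-Voigt element: tension `k * delta + c * ddelta/dt`
#' (never negative) up to a critical extension `delta_c`, after which the
#' seed is irreversibly released.
#'
#' @param params a `pod_params` set.
#' @param n number of seeds (default `params$n_seeds`).
#' @param arclengths attachment arclengths in mm; default uniform spacing
#'   `(i - 1/2) / n * L`.
#' @return data.frame with columns `seed`, `s_mm`, `k`, `c`, `delta_c_um`,
#'   `mass_mg`.
#' @export
seed_tethers <- function(params = reference_params(), n = params$n_seeds,
                         arclengths = NULL) {
  if (is.null(arclengths)) {
    arclengths <- (seq_len(n) - 0.5) / n * params$valve_length
  }
  if (any(arclengths < 0 | arclengths > params$valve_length)) {
    stop("tether arclengths must lie within [0, valve_length]")
  }
  data.frame(seed = seq_along(arclengths), s_mm = arclengths,
             k = params$tether_k, c = params$tether_c,
             delta_c_um = params$tether_delta_c,
             mass_mg = params$seed_mass)
}

#' Simulate the explosive coiling of a released valve
#'
#' Explicit velocity-Verlet integration of the planar rod with bending,
#' near-inextensible axial forces and seed tethers.  One end is clamped (the
#' attachment at the fruit base), the other free: the curl propagates from
#' the free end.  With zero damping the total energy (elastic + kinetic +
#' tether) is conserved to within 1 %; detected instability (energy growth
#' beyond 5 %) aborts with advice to reduce the time step.
#'
#' A conservative stability bound for the time step is
#' `dt < sqrt(m_node / (EA / h))`, the axial oscillation period of one node;
#' the default 0.1 us is well inside it for the reference valve.
#'
#' @param rod a `rod_state` from [build_rod()].
#' @param seeds seed tether table from [seed_tethers()], or `NULL` for none.
#' @param dt time step in ms.
#' @param T_end simulation horizon in ms.
#' @param damping mass-proportional damping coefficient (1/s); 0 keeps the
#'   run conservative.
#' @param stride record every `stride`-th step.
#' @param clamp_release_ms release the clamped end at this time (ms), or
#'   `Inf` to keep it clamped (the default; reproduces the tip-first curl).
#' @return a `rod_series`: `times` (ms), `X`, `Y` (frames x nodes, mm),
#'   `seedX`, `seedY` (mm), `energies` (data.frame, mJ), `events`
#'   (data.frame of release records), `rod`, `seeds`.
#' @export
simulate_release <- function(rod, seeds = NULL, dt = 1e-4, T_end = 5,
                             damping = 0, stride = 50,
                             clamp_release_ms = Inf) {
  if (T_end <= 0) stop("T_end must be positive")
  dt_s <- to_si(dt, "ms")
  m_min <- min(rod$mass)
  dt_bound <- sqrt(m_min / (rod$EA / rod$h))
  if (dt_s > dt_bound) {
    stop(sprintf(paste0("dt = %.3g ms exceeds the axial stability bound ",
                        "%.3g ms; reduce dt"), dt, dt_bound * 1e3))
  }
  nsteps <- ceiling(to_si(T_end, "ms") / dt_s)
  seed_mat <- matrix(numeric(0), 0, 6)
  if (is.data.frame(seeds) && nrow(seeds) > 0) {
    s_si <- to_si(seeds$s_mm, "mm")
    seg <- pmin(pmax(floor(s_si / rod$h) + 1, 1), nrow(rod$X) - 1)
    wloc <- s_si / rod$h - (seg - 1)
    seed_mat <- cbind(seg, wloc, to_si(seeds$mass_mg, "mg"),
                      seeds$k, seeds$c, to_si(seeds$delta_c_um, "um"))
  }
  crs <- if (is.finite(clamp_release_ms))
    to_si(clamp_release_ms, "ms") / dt_s else -1
  res <- rod_simulate(rod$X, rod$V, rod$mass, rod$h, rod$EA, rod$B, rod$kap0,
                      seed_mat, dt_s, as.integer(nsteps), damping, 2L,
                      as.integer(stride), crs)
  if (isTRUE(res$unstable)) {
    stop("integration unstable (energy growth > 5%): reduce dt")
  }
  nf <- res$nframes
  en <- res$energies[seq_len(nf), , drop = FALSE]
  events <- as.data.frame(res$events)
  names(events) <- c("seed", "t_release", "x", "y", "vx", "vy", "released")
  events$t_release <- from_si(events$t_release, "ms")
  events$x <- from_si(events$x, "mm")
  events$y <- from_si(events$y, "mm")
  events$released <- events$released > 0
  structure(list(
    times = from_si(res$times[seq_len(nf)], "ms"),
    X = from_si(res$X[seq_len(nf), , drop = FALSE], "mm"),
    Y = from_si(res$Y[seq_len(nf), , drop = FALSE], "mm"),
    seedX = from_si(res$seedX[seq_len(nf), , drop = FALSE], "mm"),
    seedY = from_si(res$seedY[seq_len(nf), , drop = FALSE], "mm"),
    energies = data.frame(t_ms = from_si(en[, 1], "ms"),
                          elastic_mJ = from_si(en[, 2] + rod$offset, "mJ"),
                          kinetic_mJ = from_si(en[, 3], "mJ"),
                          tether_mJ = from_si(en[, 4], "mJ")),
    events = events, rod = rod, seeds = seeds,
    n_seeds = nrow(seed_mat)), class = "rod_series")
}

#' Launch conditions of released seeds
#'
#' One record per seed: release time, position and velocity at tether
#' rupture.  Seeds that never released within the horizon are flagged with a
#' warning.
#'
#' @param series a `rod_series` from [simulate_release()].
#' @return data.frame with `seed`, `t_release` (ms), `x`, `y` (mm), `vx`,
#'   `vy`, `speed` (m/s), `angle_deg` (from the rod axis), `released`.
#' @export
launch_conditions <- function(series) {
  ev <- series$events
  if (!nrow(ev)) return(cbind(ev, speed = numeric(0), angle_deg = numeric(0)))
  ev$speed <- sqrt(ev$vx^2 + ev$vy^2)
  ev$angle_deg <- atan2(ev$vy, ev$vx) * 180 / pi
  if (any(!ev$released)) {
    warning(sum(!ev$released), " seed(s) not released within the horizon")
  }
  ev
}

#' Material-point trajectories along the valve
#'
#' Interpolates the recorded frames at fixed material arclengths, emulating
#' points tracked on high-speed movies.  Output matches the tracked-point
#' format consumed by [track_speeds()].
#'
#' @param series a `rod_series`.
#' @param arclengths material arclengths in mm, within `[0, L]`.
#' @return data.frame `point`, `frame`, `t_ms`, `x_mm`, `y_mm`.
#' @export
point_trajectories <- function(series, arclengths) {
  L_mm <- from_si(series$rod$L, "mm")
  if (any(arclengths < 0 | arclengths > L_mm + 1e-9)) {
    stop("arclengths must lie within [0, L]")
  }
  h_mm <- from_si(series$rod$h, "mm")
  pos <- arclengths / h_mm
  seg <- pmin(floor(pos), ncol(series$X) - 2)
  wloc <- pos - seg
  out <- do.call(rbind, lapply(seq_along(arclengths), function(i) {
    x <- (1 - wloc[i]) * series$X[, seg[i] + 1] + wloc[i] * series$X[, seg[i] + 2]
    y <- (1 - wloc[i]) * series$Y[, seg[i] + 1] + wloc[i] * series$Y[, seg[i] + 2]
    data.frame(point = i, frame = seq_along(series$times),
               t_ms = series$times, x_mm = x, y_mm = y)
  }))
  rownames(out) <- NULL
  out
}

#' Time to convert a given fraction of the stored energy
#'
#' @param series a `rod_series`.
#' @param frac fraction of the initial convertible elastic energy (default
#'   0.95).
#' @param require_release also require all seeds to have released.
#' @return time in ms (NA if never reached).
#' @export
coiling_time <- function(series, frac = 0.95, require_release = TRUE) {
  en <- series$energies
  E_conv0 <- en$elastic_mJ[1] - min(en$elastic_mJ)
  if (E_conv0 <= 0) return(NA_real_)
  converted <- (en$elastic_mJ[1] - en$elastic_mJ) / E_conv0
  ok <- converted >= frac
  if (require_release && series$n_seeds > 0) {
    if (any(!series$events$released)) return(NA_real_)
    t_all <- max(series$events$t_release)
    ok <- ok & en$t_ms >= t_all
  }
  if (!any(ok)) return(NA_real_)
  en$t_ms[which(ok)[1]]
}
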
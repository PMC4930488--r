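#' Sphere drag coefficient from Reynolds number
#'
#' Standard smooth-sphere correlation (Clift-Gauvin form): approaches the
#' Stokes value `24/Re` at small `Re`, levels near 0.4-0.5 in the Newton
#' regime.
#'
#' @param Re Reynolds number(s), > 0.
#' @return drag coefficient(s).
#' @export
drag_coefficient <- function(Re) {
  stopifnot(all(Re > 0))
  24 / Re * (1 + 0.15 * Re^0.687) + 0.42 / (1 + 42500 * Re^(-1.16))
}

#' Flight parameters for seed ballistics
#'
#' @param params a `pod_params` set; fields `seed_mass`, `seed_radius`,
#'   `air_density`, `gravity`, `release_height`, `drag_model`, `drag_cd`.
#' @param wind 3D wind vector (m/s).
#' @return a `flight_params` list in SI units.
#' @export
flight_params <- function(params = reference_params(), wind = c(0, 0, 0)) {
  structure(list(
    mass = to_si(params$seed_mass, "mg"),
    radius = to_si(params$seed_radius, "mm"),
    air_density = params$air_density,
    gravity = params$gravity,
    release_height = params$release_height,
    drag_model = params$drag_model,
    cd = params$drag_cd,
    air_viscosity = 1.81e-5,
    wind = wind), class = "flight_params")
}

.drag_accel <- function(v, fp) {
  vrel <- v - fp$wind
  s <- sqrt(sum(vrel^2))
  if (s == 0) return(c(0, 0, 0))
  cd <- if (fp$drag_model == "sphere_correlation") {
    Re <- fp$air_density * s * 2 * fp$radius / fp$air_viscosity
    drag_coefficient(max(Re, 1e-12))
  } else fp$cd
  -0.5 * fp$air_density * cd * pi * fp$radius^2 * s * vrel / fp$mass
}

#' Ballistic seed flight under gravity and aerodynamic drag
#'
#' Integrates `m dv/dt = m g - 1/2 rho Cd pi r^2 |v - w| (v - w)` with a
#' fixed-step 4th-order Runge-Kutta scheme, refining the final step to
#' locate the ground crossing.
#'
#' @param speed launch speed (m/s).
#' @param elevation_deg launch elevation from horizontal (deg).
#' @param azimuth_deg launch azimuth (deg, 0 = +x).
#' @param fp a [flight_params()] object.
#' @param height release height (m); default `fp$release_height`.
#' @param dt integration step (s).
#' @param t_max cap on flight time; exceeded (e.g. upward wind above the
#'   terminal velocity) is an error.
#' @return a `landing_sample` list: `distance` (m, from the plant axis),
#'   `azimuth_deg`, `flight_time` (s), `launch_speed`, `launch_elevation`,
#'   and the trajectory (matrix `t, x, y, z`).
#' @export
fly <- function(speed, elevation_deg, azimuth_deg = 0, fp = flight_params(),
                height = fp$release_height, dt = 2e-4, t_max = 60) {
  stopifnot(height >= 0, speed >= 0)
  el <- elevation_deg * pi / 180
  az <- azimuth_deg * pi / 180
  v <- speed * c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  x <- c(0, 0, height)
  deriv <- function(s) {
    # state s = (x, y, z, vx, vy, vz)
    a <- .drag_accel(s[4:6], fp) + c(0, 0, -fp$gravity)
    c(s[4:6], a)
  }
  rk4_step <- function(s, h) {
    k1 <- deriv(s)
    k2 <- deriv(s + h / 2 * k1)
    k3 <- deriv(s + h / 2 * k2)
    k4 <- deriv(s + h * k3)
    s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s <- c(x, v)
  t <- 0
  traj <- list(c(t, s[1:3]))
  # ensure we leave the ground before testing for the crossing
  repeat {
    s_new <- rk4_step(s, dt)
    t_new <- t + dt
    if (s_new[3] <= 0 && s_new[6] < 0 && (t > 0 || s[6] <= 0)) {
      # refine crossing within [t, t_new]
      ss <- s
      sub <- 100L
      hh <- dt / sub
      for (i in seq_len(sub)) {
        s2 <- rk4_step(ss, hh)
        if (s2[3] <= 0) {
          f <- if (ss[3] != s2[3]) ss[3] / (ss[3] - s2[3]) else 1
          sf <- ss + f * (s2 - ss)
          t <- t + (i - 1 + f) * hh
          s <- sf
          break
        }
        ss <- s2
        if (i == sub) { s <- s2; t <- t + dt }
      }
      traj[[length(traj) + 1]] <- c(t, s[1:3])
      break
    }
    s <- s_new
    t <- t_new
    traj[[length(traj) + 1]] <- c(t, s[1:3])
    if (t > t_max) stop("non-terminating flight (t > t_max)")
  }
  tr <- do.call(rbind, traj)
  colnames(tr) <- c("t", "x", "y", "z")
  structure(list(distance = sqrt(s[1]^2 + s[2]^2),
                 azimuth_deg = atan2(s[2], s[1]) * 180 / pi,
                 flight_time = t, launch_speed = speed,
                 launch_elevation = elevation_deg,
                 trajectory = tr), class = "landing_sample")
}

#' Evaluate an expression with a temporary RNG seed
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Monte Carlo seed dispersal
#'
#' Resamples model launch records with replacement, draws a uniform valve
#' azimuth on [0, 360) and a valve tilt from a configurable distribution
#' (default uniform on [0, 60] degrees from horizontal), flies each seed and
#' collects landing samples.  Reproducible given the RNG seed.
#'
#' @param launches data.frame of launch records (needs `speed` and
#'   `angle_deg`; see [launch_conditions()]).
#' @param fp a [flight_params()].
#' @param n number of dispersal samples (>= 1).
#' @param seed RNG seed.
#' @param tilt_range valve tilt range in degrees, default `c(0, 60)`.
#' @param dt integration step passed to [fly()].
#' @return data.frame with `distance`, `azimuth_deg`, `flight_time`,
#'   `launch_speed`, `launch_elevation`.
#' @export
monte_carlo_dispersal <- function(launches, fp = flight_params(), n = 1000,
                                  seed = 1, tilt_range = c(0, 60),
                                  dt = 2e-4) {
  if (!nrow(launches)) stop("empty launch list")
  stopifnot(n >= 1)
  with_seed(seed, {
    idx <- sample.int(nrow(launches), n, replace = TRUE)
    az <- stats::runif(n, 0, 360)
    tilt <- stats::runif(n, tilt_range[1], tilt_range[2])
    # rod axis is the (vertical) fruit axis: in-plane launch angle measured
    # from the axis maps to elevation angle (angle - 90) from horizontal,
    # shifted by the sampled valve tilt and folded into [-90, 90]
    elev <- (abs(launches$angle_deg[idx]) - 90) + tilt
    elev <- ifelse(elev > 90, 180 - elev, elev)
    elev <- pmax(pmin(elev, 90), -90)
    out <- lapply(seq_len(n), function(i) {
      ls <- fly(launches$speed[idx[i]], elev[i], az[i], fp, dt = dt)
      data.frame(distance = ls$distance, azimuth_deg = ls$azimuth_deg,
                 flight_time = ls$flight_time, launch_speed = ls$launch_speed,
                 launch_elevation = ls$launch_elevation)
    })
    do.call(rbind, out)
  })
}

#' Radial histogram and plateau statistic of landing distances
#'
#' The plateau statistic is the coefficient of variation of histogram counts
#' over the central 50 % mass interval (between the 25th and 75th distance
#' percentiles): a flat-topped ("plateau") distribution scores low, a peaked
#' one high.
#'
#' @param distances numeric vector of landing distances (m), or a data.frame
#'   with a `distance` column.
#' @param bins number of histogram bins.
#' @return list with `histogram` (data.frame `mid`, `count`, `density`),
#'   `plateau` (NA if fewer than 50 samples or degenerate), `n`.
#' @export
distance_summary <- function(distances, bins = 30) {
  if (is.data.frame(distances)) distances <- distances$distance
  n <- length(distances)
  br <- seq(min(distances), max(distances), length.out = bins + 1)
  if (diff(range(distances)) == 0) {
    return(list(histogram = data.frame(mid = distances[1], count = n,
                                       density = NA_real_),
                plateau = NA_real_, n = n, degenerate = TRUE))
  }
  h <- graphics::hist(distances, breaks = br, plot = FALSE)
  plateau <- NA_real_
  if (n >= 50) {
    q <- stats::quantile(distances, c(0.25, 0.75))
    sel <- h$mids >= q[1] & h$mids <= q[2]
    if (sum(sel) >= 2) {
      cnt <- h$counts[sel]
      plateau <- stats::sd(cnt) / mean(cnt)
    }
  }
  list(histogram = data.frame(mid = h$mids, count = h$counts,
                              density = h$density),
       plateau = plateau, n = n, degenerate = FALSE)
}
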
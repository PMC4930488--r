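#' Force-displacement of an intrinsically curved elastica
#'
#' Solves the planar inextensible elastica with uniform intrinsic curvature
#' held between two clamps aligned with the pulling axis, at a set of
#' end-to-end distances, and returns the axial force at each.  The rod is
#' discretized in tangent angles and equilibria are found by energy
#' minimization with force continuation from the taut state; the transverse
#' closure constraint is enforced by a stiff quadratic penalty.
#'
#' Distances at or below the natural (zero-force) end-to-end distance lie on
#' the slack branch and return zero force; distances must be strictly below
#' the contour length.
#'
#' @param B bending stiffness in N mm^2.
#' @param kappa_hat intrinsic curvature in 1/mm.
#' @param L contour length in mm.
#' @param distances end-to-end distances in mm (each < L).
#' @param n number of segments in the discretization.
#' @param ends `"clamped"` (tangents fixed along the axis) or `"pinned"`
#'   (moment-free).
#' @return forces in mN (same length as `distances`).
#' @export
elastica_force_displacement <- function(B, kappa_hat, L, distances,
                                        n = 160, ends = c("clamped", "pinned")) {
  ends <- match.arg(ends)
  stopifnot(B > 0, kappa_hat >= 0, L > 0)
  if (any(distances >= L)) {
    stop("end-to-end distance must be below the contour length")
  }
  if (kappa_hat == 0) return(rep(0, length(distances)))
  tab <- .elastica_table(kappa_hat * L, n, ends)
  delta <- distances / L
  if (any(delta > max(tab$delta))) {
    stop("end-to-end distance beyond the coiled-branch extension limit (",
         format(max(tab$delta) * L, digits = 4), " mm); the planar coil ",
         "cannot be pulled further without unwinding out of plane")
  }
  phi <- .elastica_phi(tab, delta)
  phi * B / L^2 * 1e3  # N mm^2 / mm^2 = N -> mN
}

#' Largest end-to-end distance reachable on the coiled branch
#'
#' With both tangents clamped the planar coil cannot change its winding
#' number, so tension tightens the residual loops instead of removing them:
#' the end-to-end distance saturates below the contour length.  This limit
#' bounds the displacement range of simulated extension experiments.
#'
#' @inheritParams elastica_force_displacement
#' @return distance in mm.
#' @export
elastica_extension_limit <- function(kappa_hat, L, n = 160,
                                     ends = "clamped") {
  if (kappa_hat == 0) return(L)
  tab <- .elastica_table(kappa_hat * L, n, ends)
  max(tab$delta) * L
}

# Dimensionless force-extension table by continuation, cached per
# (k, n, ends).  k = L * kappa_hat (total turning angle); phi = F L^2 / B.
.elastica_cache <- new.env(parent = emptyenv())

.elastica_table <- function(k, n = 160, ends = "clamped", n_phi = 60) {
  key <- paste(signif(k, 12), n, ends, n_phi)
  hit <- .elastica_cache[[key]]
  if (!is.null(hit)) return(hit)
  h <- 1 / n
  mu <- 1e4 * max(1, k^2)          # transverse closure penalty
  free_ends <- ends == "pinned"
  # unknowns: interior angles (and end angles if pinned)
  idx <- if (free_ends) seq_len(n) else 2:(n - 1)
  energy <- function(th_full, phi) {
    dth <- diff(th_full)
    x <- h * sum(cos(th_full)); y <- h * sum(sin(th_full))
    sum((dth - k * h)^2) / (2 * h) + 0.5 * mu * y^2 - phi * x
  }
  grad <- function(th_full, phi) {
    dth <- diff(th_full)
    m <- (dth - k * h) / h
    g <- numeric(n)
    g[1:(n - 1)] <- g[1:(n - 1)] - m
    g[2:n] <- g[2:n] + m
    y <- h * sum(sin(th_full))
    g <- g + mu * y * h * cos(th_full) + phi * h * sin(th_full)
    g
  }
  # continue from the natural coil at low tension up to the taut state;
  # the straight configuration is a competing local equilibrium at every
  # tension, so the coiled branch must be tracked from below
  phi_grid <- exp(seq(log(0.05), log(max(40 * k^2, 400)),
                      length.out = n_phi))
  s_mid <- (seq_len(n) - 0.5) / n
  th <- k * (s_mid - 0.5)
  delta <- ubend <- numeric(length(phi_grid))
  for (i in seq_along(phi_grid)) {
    phi <- phi_grid[i]
    opt <- stats::optim(th[idx], fn = function(z) {
      tf <- th; tf[idx] <- z; energy(tf, phi)
    }, gr = function(z) {
      tf <- th; tf[idx] <- z; grad(tf, phi)[idx]
    }, method = "L-BFGS-B",
    control = list(maxit = 2000, factr = 1e3))
    th[idx] <- opt$par
    delta[i] <- h * sum(cos(th))
    ubend[i] <- sum((diff(th) - k * h)^2) / (2 * h)  # dimensionless U L / B
  }
  ok <- is.finite(delta)
  tab <- list(delta = delta[ok], phi = phi_grid[ok], ubend = ubend[ok],
              k = k, n = n)
  # keep the strictly increasing envelope for interpolation
  keep <- !duplicated(delta[ok]) & delta[ok] == cummax(delta[ok])
  tab$delta <- tab$delta[keep]; tab$phi <- tab$phi[keep]
  tab$ubend <- tab$ubend[keep]
  .elastica_cache[[key]] <- tab
  tab
}

.elastica_phi <- function(tab, delta) {
  d0 <- min(tab$delta)  # at the smallest probed force; slack below this
  out <- numeric(length(delta))
  inside <- delta > d0
  if (any(inside)) {
    # interpolate log(phi) against delta for smoothness
    f <- stats::approxfun(tab$delta, log(tab$phi), rule = 2)
    out[inside] <- exp(f(delta[inside]))
  }
  out
}

#' Natural end-to-end distance of the curved elastica
#'
#' @inheritParams elastica_force_displacement
#' @return distance in mm at (numerically) zero force.
#' @export
elastica_natural_distance <- function(kappa_hat, L, n = 160,
                                      ends = "clamped") {
  if (kappa_hat == 0) return(L)
  tab <- .elastica_table(kappa_hat * L, n, ends)
  min(tab$delta) * L
}

#' An extensometer force-displacement curve
#'
#' @param displacement_um displacement samples (um), strictly increasing.
#' @param force_mN force samples (mN).
#' @param k_setup setup stiffness (mN/um) if known.
#' @return an `extensometer_curve` data.frame.
#' @export
extensometer_curve <- function(displacement_um, force_mN, k_setup = NA) {
  stopifnot(length(displacement_um) == length(force_mN),
            all(diff(displacement_um) > 0))
  structure(data.frame(displacement_um = displacement_um,
                       force_mN = force_mN),
            k_setup = k_setup, class = c("extensometer_curve", "data.frame"))
}

#' Correct an extensometer curve for setup compliance
#'
#' The taut valve is inextensible, so the slope of the terminal linear
#' region before rupture measures the stiffness of the setup itself.  The
#' rupture point (force drop of more than 50 % within one increment) is
#' detected and the data truncated there; the best straight-line window is
#' fit to the pre-rupture tail; and the displacement is corrected by
#' `d - F / k_setup`.
#'
#' @param raw an [extensometer_curve()].
#' @param min_window minimum number of points in a candidate linear window.
#' @param r2_min minimum R-squared to accept a linear region.
#' @return corrected `extensometer_curve` with attributes `k_setup`
#'   (mN/um) and `rupture_index` (or NA).
#' @export
correct_setup_compliance <- function(raw, min_window = 5, r2_min = 0.98) {
  d <- raw$displacement_um; f <- raw$force_mN
  # rupture: >50% force drop over one increment, from a substantial force
  rupture <- NA_integer_
  fmax <- max(f)
  for (i in seq_len(length(f) - 1)) {
    if (f[i] > 0.3 * fmax && f[i + 1] < 0.5 * f[i]) { rupture <- i; break }
  }
  keep <- if (is.na(rupture)) seq_along(f) else seq_len(rupture)
  d <- d[keep]; f <- f[keep]
  n <- length(d)
  if (n < min_window) stop("too few points before rupture")
  # anchor a base line on the last points, then grow the window backwards
  # while earlier points stay on it (the curve is stiffest, hence most
  # setup-dominated, just before rupture)
  ii <- (n - min_window + 1):n
  base <- stats::lm(f[ii] ~ d[ii])
  sigma <- stats::sd(stats::resid(base))
  tol <- max(3 * sigma, 0.005 * max(f))
  pred <- function(x) stats::coef(base)[1] + stats::coef(base)[2] * x
  lo <- n - min_window + 1
  while (lo > 1 && abs(f[lo - 1] - pred(d[lo - 1])) <= tol) lo <- lo - 1
  ii <- lo:n
  fit <- stats::lm(f[ii] ~ d[ii])
  r2 <- summary(fit)$r.squared
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(r2) || r2 < r2_min || slope <= 0) {
    stop("no linear region detected (R^2 < ", r2_min, " on all windows)")
  }
  k_setup <- slope
  # heteroscedasticity-robust (HC1) standard error: the pre-rupture forces
  # are large, so multiplicative noise makes the classical SE optimistic
  xw <- d[ii] - mean(d[ii])
  ee <- stats::resid(fit)
  nw <- length(ii)
  k_se <- sqrt(sum(xw^2 * ee^2) / sum(xw^2)^2 * nw / max(nw - 2, 1))
  if (!is.finite(k_se)) k_se <- 0
  # corrected displacements need not stay strictly monotone under noise,
  # so bypass the constructor's monotonicity check
  structure(data.frame(displacement_um = d - f / k_setup, force_mN = f),
            k_setup = k_setup, k_setup_se = k_se, rupture_index = rupture,
            class = c("extensometer_curve", "data.frame"))
}

#' Fit the whole-valve bending stiffness to a corrected curve
#'
#' Least-squares fit of the bending stiffness B: with fixed intrinsic
#' curvature the elastica force is proportional to B, so the fit is linear.
#' Displacements are measured from the natural (zero-force) end-to-end
#' distance of the coiled valve.  Confidence intervals come from a seeded
#' residual bootstrap.
#'
#' @param curve a corrected [extensometer_curve()].
#' @param kappa_hat intrinsic curvature (1/mm), typically from the observed
#'   coil diameter of the excised valve.
#' @param L contour length (mm).
#' @param fit_kappa also optimize `kappa_hat` (1D search with inner linear
#'   fit); off by default to avoid the B / kappa degeneracy on shallow
#'   curves.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param n elastica discretization.
#' @return an `elastica_fit`: `B_Nmm2`, `kappa_hat`, `L`, `residual_norm`,
#'   `ci` (2.5/97.5 % bootstrap), `forces_fit`.
#' @export
fit_bending_stiffness <- function(curve, kappa_hat, L, fit_kappa = FALSE,
                                  n_boot = 200, seed = 1, n = 160) {
  if (nrow(curve) < 5) stop("fewer than 5 usable points")
  disp <- curve$displacement_um
  Fobs <- curve$force_mN
  # after compliance correction the taut (setup-only) phase collapses onto
  # a repeated displacement; keep only the first point of any such pile-up
  med_step <- stats::median(abs(diff(disp)))
  keep <- c(TRUE, diff(disp) > 0.05 * med_step)
  disp <- disp[keep]; Fobs <- Fobs[keep]
  if (length(disp) < 5) stop("fewer than 5 usable points")
  fit_once <- function(kh, Fvec, disp_use = disp) {
    d0 <- elastica_natural_distance(kh, L, n)
    dmax <- elastica_extension_limit(kh, L, n)
    d <- d0 + disp_use * 1e-3  # um -> mm
    # the taut, setup-dominated tail carries no bending information
    use <- d <= d0 + 0.97 * (dmax - d0)
    if (sum(use) < 5) stop("fewer than 5 usable points in the bending regime")
    fB <- rep(0, length(d))
    fB[use] <- elastica_force_displacement(1, kh, L, d[use], n)
    B <- sum(fB[use] * Fvec[use]) / sum(fB[use]^2)
    # leverage of each point in the one-parameter fit; used to unshrink
    # residuals for the wild bootstrap (HC2)
    lev <- fB[use]^2 / sum(fB[use]^2)
    list(B = B, f = fB[use], resid = Fvec[use] - B * fB[use],
         lev = lev, use = use)
  }
  if (fit_kappa) {
    objk <- function(kh) sum(fit_once(kh, Fobs)$resid^2)
    kappa_hat <- stats::optimize(objk, kappa_hat * c(0.5, 2))$minimum
  }
  base <- fit_once(kappa_hat, Fobs)
  ci <- c(NA_real_, NA_real_)
  boots <- NULL
  if (n_boot > 0) {
    # residual bootstrap, plus propagation of the setup-stiffness estimate:
    # a perturbed k_setup shifts every corrected displacement by
    # F * (1/k - 1/k*), which dominates the stiffness uncertainty
    k0 <- attr(curve, "k_setup")
    k_se <- attr(curve, "k_setup_se")
    boots <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        # wild bootstrap: keeps each residual at its own point, which
        # preserves the multiplicative (heteroscedastic) error structure
        eps <- sample(c(-1, 1), length(base$resid), replace = TRUE)
        Fb <- base$B * base$f +
          base$resid / sqrt(pmax(1 - base$lev, 0.05)) * eps
        if (!is.null(k0) && !is.null(k_se) && is.finite(k0) && k_se > 0) {
          ks <- stats::rnorm(1, k0, k_se)
          fb <- fit_once(kappa_hat, Fobs,
                         disp_use = disp + Fobs * (1 / k0 - 1 / ks))$f
          sum(fb * Fb) / sum(fb^2)
        } else {
          sum(base$f * Fb) / sum(base$f^2)
        }
      }, 0)
    })
    # t-interval on the bootstrap spread: the fit is dominated by a few
    # high-force points, so use the effective degrees of freedom
    nu <- max(1 / sum(base$lev^2) - 1, 2)
    hw <- stats::qt(0.975, nu) * stats::sd(boots)
    ci <- c(base$B - hw, base$B + hw)
  }
  structure(list(B_Nmm2 = base$B, kappa_hat = kappa_hat, L = L,
                 residual_norm = sqrt(sum(base$resid^2)),
                 forces_fit = base$B * base$f, ci = ci, boot = boots),
            class = "elastica_fit")
}

#' Exocarp modulus and pre-explosion tension from the valve stiffness
#'
#' Inverts the layer-stack bending resultant for the exocarp modulus:
#' solves `B_fit = EI_reduced(E_exocarp)` with the other layer modules
#' known, then reports the exocarp tension
#' `F = E_exocarp * (w * t_exo) * gamma * hydration` released over the rest
#' contraction.
#'
#' @param B_fit fitted whole-valve bending stiffness, N mm^2.
#' @param params a `pod_params` set supplying the remaining layer moduli
#'   and geometry.
#' @param geometry `"hinged"` or `"boxed"`.
#' @param hydration factor scaling the rest contraction for the (drier)
#'   in-air experiment relative to the fully hydrated cell model.
#' @return list `E_exocarp` (MPa), `force_mN`.
#' @export
exocarp_from_valve <- function(B_fit, params = reference_params(),
                               geometry = "hinged", hydration = 1) {
  ei_of <- function(Ee) {
    v <- valve_model(do.call(reference_params,
                             utils::modifyList(as.list(unclass(params)),
                                               list(E_exocarp = Ee))),
                     geometry)
    r <- stack_resultants(v)
    (r$EI - r$ES^2 / r$EA) * 1e6  # N m^2 -> N mm^2
  }
  lo <- 1e-3
  if (B_fit <= ei_of(lo)) {
    stop("B_fit does not exceed the known-layer contributions ",
         "(would give a negative exocarp modulus)")
  }
  root <- stats::uniroot(function(Ee) ei_of(Ee) - B_fit, c(lo, 1e5),
                         tol = 1e-10)
  Ee <- root$root
  A_mm2 <- params$valve_width * params$exocarp_thickness * 1e-3  # mm^2
  force_N <- Ee * A_mm2 * params$exocarp_rest_contraction * hydration
  list(E_exocarp = Ee, force_mN = force_N * 1e3)
}
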
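#' Cell geometry
#'
#' Rectangular-box reference geometry of an exocarp cell, axes aligned to
#' the fruit: x = length (longitudinal), y = width (transverse), z = depth
#' (out of the valve plane).
#'
#' @param length,width,depth cell dimensions in um.
#' @param wall_thickness wall thickness t_w in um.
#' @return a `cell_geom` object.
#' @export
cell_geom <- function(length, width, depth, wall_thickness = 1) {
  stopifnot(length > 0, width > 0, depth > 0, wall_thickness > 0)
  structure(list(dims = c(length = length, width = width, depth = depth),
                 t_w = wall_thickness), class = "cell_geom")
}

#' Orthotropic cell-wall material
#'
#' Plane-stress wall moduli along the fruit's principal axes.  Each wall
#' face uses the two global axes it spans; `E_depth` applies to the vertical
#' direction of anticlinal (side) walls and defaults to `E_width`.
#'
#' @param E_length,E_width,E_depth Young's moduli in MPa.
#' @param poisson in-plane Poisson ratio, in [0, 0.5).
#' @return a `wall_material` with a `model` field (`"isotropic"` when all
#'   moduli are equal, `"orthotropic"` otherwise).
#' @export
wall_material <- function(E_length, E_width = E_length, E_depth = E_width,
                          poisson = 0.3) {
  stopifnot(E_length > 0, E_width > 0, E_depth > 0,
            poisson >= 0, poisson < 0.5)
  model <- if (E_length == E_width && E_width == E_depth)
    "isotropic" else "orthotropic"
  structure(list(E_length = E_length, E_width = E_width, E_depth = E_depth,
                 poisson = poisson, model = model), class = "wall_material")
}

# Face ids: 1 bottom (z=0), 2 top (z=D), 3 y=0, 4 y=W, 5 x=0, 6 x=end,
# 7 internal shared transverse walls (cell files only).
.face_span <- list(c(1L, 2L), c(1L, 2L), c(1L, 3L), c(1L, 3L),
                   c(2L, 3L), c(2L, 3L), c(2L, 3L))

#' Build the triangulated surface mesh of a cell or cell file
#'
#' The box surface is subdivided per face; element count scales with the
#' square of `refinement`.  For `n_cells > 1` a file of identical cells
#' sharing transverse walls is built: internal walls carry membrane
#' stiffness but no net pressure load.
#'
#' @param geom a [cell_geom()].
#' @param refinement mesh refinement level (>= 1); divisions per edge are
#'   `refinement * max(1, round(dim / 10))`.
#' @param n_cells number of cells in a longitudinal file.
#' @return a `cell_mesh`: `X` (nodes, um), `tri` (1-based), `face`,
#'   `pw` (pressure weight per element), `dims`, `n_cells`.
#' @export
build_cell <- function(geom, refinement = 2, n_cells = 1) {
  stopifnot(inherits(geom, "cell_geom"), refinement >= 1, n_cells >= 1)
  d <- geom$dims
  if (any(d <= 0)) stop("degenerate cell dimensions")
  base <- pmax(1, round(d / 10))
  nd <- as.integer(refinement * base)   # divisions per cell in x, and in y, z
  nx1 <- nd[1]; ny <- nd[2]; nz <- nd[3]
  nx <- nx1 * n_cells
  Lx <- d[1] * n_cells
  # node index grid over the full box lattice; only surface+internal used
  key <- function(i, j, k) (i * (ny + 1L) + j) * (nz + 1L) + k + 1L
  idx <- integer((nx + 1L) * (ny + 1L) * (nz + 1L))
  Xl <- list(); cnt <- 0L
  getn <- function(i, j, k) {
    kk <- key(i, j, k)
    if (idx[kk] == 0L) {
      cnt <<- cnt + 1L
      idx[kk] <<- cnt
      Xl[[cnt]] <<- c(i / nx * Lx, j / ny * d[2], k / nz * d[3])
    }
    idx[kk]
  }
  tris <- vector("list", 0); face <- integer(0); pwv <- numeric(0)
  addquad <- function(a, b, cc, dd, f, pw = 1) {
    tris[[length(tris) + 1L]] <<- c(a, b, cc)
    tris[[length(tris) + 1L]] <<- c(a, cc, dd)
    face <<- c(face, f, f); pwv <<- c(pwv, pw, pw)
  }
  for (i in 1:nx) for (j in 1:ny) {
    a <- getn(i - 1, j - 1, 0); b <- getn(i, j - 1, 0)
    cc <- getn(i, j, 0); dd <- getn(i - 1, j, 0)
    addquad(a, dd, cc, b, 1L)                  # bottom, outward -z
    a <- getn(i - 1, j - 1, nz); b <- getn(i, j - 1, nz)
    cc <- getn(i, j, nz); dd <- getn(i - 1, j, nz)
    addquad(a, b, cc, dd, 2L)                  # top, outward +z
  }
  for (i in 1:nx) for (k in 1:nz) {
    a <- getn(i - 1, 0, k - 1); b <- getn(i, 0, k - 1)
    cc <- getn(i, 0, k); dd <- getn(i - 1, 0, k)
    addquad(a, b, cc, dd, 3L)                  # y = 0, outward -y
    a <- getn(i - 1, ny, k - 1); b <- getn(i, ny, k - 1)
    cc <- getn(i, ny, k); dd <- getn(i - 1, ny, k)
    addquad(a, dd, cc, b, 4L)                  # y = W, outward +y
  }
  for (j in 1:ny) for (k in 1:nz) {
    a <- getn(0, j - 1, k - 1); b <- getn(0, j, k - 1)
    cc <- getn(0, j, k); dd <- getn(0, j - 1, k)
    addquad(a, dd, cc, b, 5L)                  # x = 0, outward -x
    a <- getn(nx, j - 1, k - 1); b <- getn(nx, j, k - 1)
    cc <- getn(nx, j, k); dd <- getn(nx, j - 1, k)
    addquad(a, b, cc, dd, 6L)                  # x = L, outward +x
  }
  if (n_cells > 1) {
    for (ci in seq_len(n_cells - 1)) {
      i <- ci * nx1
      for (j in 1:ny) for (k in 1:nz) {
        a <- getn(i, j - 1, k - 1); b <- getn(i, j, k - 1)
        cc <- getn(i, j, k); dd <- getn(i, j - 1, k)
        addquad(a, b, cc, dd, 7L, pw = 0)      # internal shared wall
      }
    }
  }
  structure(list(X = do.call(rbind, Xl), tri = do.call(rbind, tris),
                 face = face, pw = pwv, dims = d, Lx = Lx,
                 n_cells = n_cells, geom = geom, refinement = refinement),
            class = "cell_mesh")
}

#' Enclosed volume of a (deformed) cell mesh
#'
#' Signed volume of the outer surface (internal shared walls are skipped).
#'
#' @param mesh a `cell_mesh`.
#' @param X node positions; defaults to the rest mesh.
#' @return volume in um^3.
#' @export
mesh_volume <- function(mesh, X = mesh$X) {
  sel <- mesh$pw > 0
  t1 <- mesh$tri[sel, 1]; t2 <- mesh$tri[sel, 2]; t3 <- mesh$tri[sel, 3]
  x1 <- X[t1, , drop = FALSE]; x2 <- X[t2, , drop = FALSE]
  x3 <- X[t3, , drop = FALSE]
  cr <- cbind(x2[, 2] * x3[, 3] - x2[, 3] * x3[, 2],
              x2[, 3] * x3[, 1] - x2[, 1] * x3[, 3],
              x2[, 1] * x3[, 2] - x2[, 2] * x3[, 1])
  sum(rowSums(x1 * cr)) / 6
}

#' Surface area of a cell mesh
#' @param mesh a `cell_mesh`.
#' @param X node positions; defaults to the rest mesh.
#' @param outer_only skip internal walls (default TRUE).
#' @return area in um^2.
#' @export
mesh_area <- function(mesh, X = mesh$X, outer_only = TRUE) {
  sel <- if (outer_only) mesh$pw > 0 else rep(TRUE, nrow(mesh$tri))
  t1 <- mesh$tri[sel, 1]; t2 <- mesh$tri[sel, 2]; t3 <- mesh$tri[sel, 3]
  e1 <- X[t2, , drop = FALSE] - X[t1, , drop = FALSE]
  e2 <- X[t3, , drop = FALSE] - X[t1, , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

# per-element precomputation: inverse rest-edge matrices, areas, thickness,
# plane-stress stiffness rows
.prep_elements <- function(mesh, material, t_w, outer_wall_factor = 1) {
  nel <- nrow(mesh$tri)
  Bm <- matrix(0, nel, 4); A0 <- numeric(nel); tw <- numeric(nel)
  Q <- matrix(0, nel, 4)
  Evec <- c(material$E_length, material$E_width, material$E_depth)
  nu <- material$poisson
  tw_face <- c(t_w * outer_wall_factor, t_w * outer_wall_factor,
               2 * t_w, 2 * t_w, 2 * t_w, 2 * t_w, 2 * t_w)
  for (e in seq_len(nel)) {
    f <- mesh$face[e]
    sp <- .face_span[[f]]
    P3 <- mesh$X[mesh$tri[e, ], sp]
    D <- cbind(P3[2, ] - P3[1, ], P3[3, ] - P3[1, ])
    A0[e] <- abs(det(D)) / 2
    Bm[e, ] <- as.vector(solve(D))
    tw[e] <- tw_face[f]
    E1 <- Evec[sp[1]]; E2 <- Evec[sp[2]]
    n21 <- nu * E2 / E1
    den <- 1 - nu * n21
    Q[e, ] <- c(E1 / den, E2 / den, n21 * E1 / den,
                sqrt(E1 * E2) / (2 * (1 + nu)))
  }
  list(Bm = Bm, A0 = A0, tw = tw, Q = Q)
}

# Reduced degree-of-freedom map implementing planar-wall and prescribed
# constraints.  Returns an n x 3 integer matrix: >0 reduced index (planar
# groups share one), 0 = coordinate fixed at `fixed` value.
.dof_map <- function(mesh, constraints = c("tissue", "free"),
                     prescribe_ends = NULL) {
  constraints <- match.arg(constraints)
  X <- mesh$X; n <- nrow(X)
  group <- matrix(0L, n, 3)
  fixedv <- matrix(NA_real_, n, 3)
  g <- 0L
  xmax <- max(X[, 1])
  on_lo <- abs(X[, 1]) < 1e-9
  on_hi <- abs(X[, 1] - xmax) < 1e-9
  if (!is.null(prescribe_ends)) {
    fixedv[on_lo, 1] <- prescribe_ends[1]
    fixedv[on_hi, 1] <- prescribe_ends[2]
    group[on_lo, 1] <- -1L  # marker: fixed
    group[on_hi, 1] <- -1L
  } else if (constraints == "tissue") {
    g <- g + 1L; group[on_lo, 1] <- g
    g <- g + 1L; group[on_hi, 1] <- g
  }
  map <- matrix(0L, n, 3)
  k <- g
  for (i in seq_len(n)) for (c in 1:3) {
    if (group[i, c] > 0L) map[i, c] <- group[i, c]
    else if (group[i, c] == -1L) map[i, c] <- 0L
    else { k <- k + 1L; map[i, c] <- k }
  }
  list(map = map, nred = k, fixed = fixedv)
}

.expand_x <- function(xr, dm, X0) {
  X <- matrix(0, nrow(X0), 3)
  sel <- dm$map > 0L
  X[sel] <- xr[dm$map[sel]]
  X[!sel] <- dm$fixed[!sel]
  X
}

.reduce_g <- function(G, dm) {
  sel <- dm$map > 0L
  as.vector(rowsum(G[sel], dm$map[sel]))
}

.init_xr <- function(X, dm) {
  xr <- numeric(dm$nred)
  sel <- dm$map > 0L
  # planar groups get the (shared) coordinate; assignment order irrelevant
  xr[dm$map[sel]] <- X[sel]
  xr
}

#' Inflate a pressurized cell to quasi-static equilibrium
#'
#' Minimizes total potential energy (orthotropic membrane strain energy
#' minus pressure times enclosed volume) with an incremental pressure ramp.
#' By default the transverse end walls are constrained to remain planar
#' ("tissue" constraints): they are shared with file neighbours in the
#' intact exocarp, which is also how the osmotic imaging was done.  Use
#' `constraints = "free"` for an isolated cell.
#'
#' @param mesh a [build_cell()] mesh.
#' @param material a [wall_material()].
#' @param t_w wall thickness in um.
#' @param P turgor pressure in MPa (>= 0).
#' @param constraints `"tissue"` (planar shared end walls) or `"free"`.
#' @param outer_wall_factor thickness multiplier for the outer and inner
#'   periclinal walls (top/bottom faces).
#' @param ramp_steps pressure increments (>= 1; >= 10 recommended for large
#'   deformations).
#' @param X0 warm-start node positions.
#' @param maxit,factr L-BFGS-B controls per ramp step.
#' @param contact optional contact sphere list (`center`, `radius`, `k`,
#'   `nodes`).
#' @param prescribe_ends optional length-2 vector: prescribed x-coordinates
#'   of the two end walls (overrides planar constraints on x).
#' @return a `cell_state`: `X` (deformed nodes), `mesh`, `material`, `P`,
#'   `V` (um^3), `gnorm` (residual gradient inf-norm, uN), `reaction_x`
#'   (uN, total axial reaction at the high-x end when ends are prescribed).
#' @export
inflate <- function(mesh, material, t_w = 1, P = 0.7,
                    constraints = c("tissue", "free"),
                    outer_wall_factor = 1, ramp_steps = 10, X0 = NULL,
                    maxit = 4000, factr = 10, contact = NULL,
                    prescribe_ends = NULL) {
  constraints <- match.arg(constraints)
  stopifnot(P >= 0)
  pp <- .prep_elements(mesh, material, t_w, outer_wall_factor)
  dm <- .dof_map(mesh, constraints, prescribe_ends)
  Xs <- if (is.null(X0)) mesh$X else X0
  if (!is.null(prescribe_ends)) {
    # affine warm start onto the prescribed end positions
    xmax <- max(mesh$X[, 1])
    cur_lo <- mean(Xs[abs(mesh$X[, 1]) < 1e-9, 1])
    cur_hi <- mean(Xs[abs(mesh$X[, 1] - xmax) < 1e-9, 1])
    sc <- (prescribe_ends[2] - prescribe_ends[1]) / (cur_hi - cur_lo)
    Xs[, 1] <- prescribe_ends[1] + (Xs[, 1] - cur_lo) * sc
  }
  xr <- .init_xr(Xs, dm)
  n <- nrow(mesh$X)
  eg <- function(z, Ps) {
    membrane_eg(as.vector(.expand_x(z, dm, mesh$X)), mesh$tri, pp$Bm, pp$A0,
                pp$tw, pp$Q, Ps, mesh$pw, contact)
  }
  res <- NULL
  for (s in seq_len(max(ramp_steps, 1))) {
    Ps <- P * s / max(ramp_steps, 1)
    opt <- stats::optim(xr, fn = function(z) eg(z, Ps)$W,
                        gr = function(z) .reduce_g(matrix(eg(z, Ps)$G, n, 3), dm),
                        method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = factr))
    xr <- opt$par
  }
  fin <- eg(xr, P)
  Gm <- matrix(fin$G, n, 3)
  gnorm <- if (dm$nred) max(abs(.reduce_g(Gm, dm))) else 0
  gtol <- max(1e-6, 1e-6 * abs(fin$W))
  if (gnorm > 1e3 * gtol) {
    stop(sprintf("inflation failed to converge: |grad| = %.3g uN", gnorm))
  }
  X1 <- .expand_x(xr, dm, mesh$X)
  reaction_x <- NA_real_
  if (!is.null(prescribe_ends)) {
    xmax <- max(mesh$X[, 1])
    hi <- abs(mesh$X[, 1] - xmax) < 1e-9
    reaction_x <- sum(Gm[hi, 1])
  }
  structure(list(X = X1, mesh = mesh, material = material, t_w = t_w, P = P,
                 constraints = constraints,
                 outer_wall_factor = outer_wall_factor,
                 V = fin$V, W = fin$W, gnorm = gnorm,
                 reaction_x = reaction_x,
                 fcontact = fin$fcontact, ncontact = fin$ncontact),
            class = "cell_state")
}

#' Axis-aligned dimensions of a (deformed) cell state
#'
#' @param state a `cell_state` (or a `cell_mesh` for the rest shape).
#' @return list with `extent` (bounding box spans, um) and `span`
#'   (distances between opposite face centroids, um).
#' @export
cell_dims <- function(state) {
  X <- if (inherits(state, "cell_state")) state$X else state$X
  mesh <- if (inherits(state, "cell_state")) state$mesh else state
  extent <- apply(X, 2, function(cc) diff(range(cc)))
  span <- numeric(3)
  pairs <- list(c(5L, 6L), c(3L, 4L), c(1L, 2L))
  for (a in 1:3) {
    f <- pairs[[a]]
    n1 <- unique(as.vector(mesh$tri[mesh$face == f[1], ]))
    n2 <- unique(as.vector(mesh$tri[mesh$face == f[2], ]))
    span[a] <- abs(mean(X[n2, a]) - mean(X[n1, a]))
  }
  names(extent) <- names(span) <- c("length", "width", "depth")
  list(extent = extent, span = span)
}

#' Osmotic response: shape change between two turgor pressures
#'
#' Inflates the same cell at a low and a high pressure (plasmolysed versus
#' fully turgid) and reports percent changes of the bounding dimensions and
#' of the enclosed volume (high relative to low).
#'
#' @inheritParams inflate
#' @param geom a [cell_geom()].
#' @param P_low,P_high pressures in MPa, `P_high > P_low >= 0`.
#' @param refinement mesh refinement.
#' @return an `osmotic_response`: `dims_low`, `dims_high` (um),
#'   `d_length_pct`, `d_width_pct`, `d_depth_pct`, `d_volume_pct`, states.
#' @export
osmotic_response <- function(geom, material, t_w = geom$t_w, P_low = 0,
                             P_high = 0.7, refinement = 2,
                             constraints = "tissue", outer_wall_factor = 1,
                             ramp_steps = 10) {
  if (P_high < P_low || P_low < 0) stop("need P_high >= P_low >= 0")
  mesh <- build_cell(geom, refinement)
  st_lo <- inflate(mesh, material, t_w, P_low, constraints,
                   outer_wall_factor, ramp_steps = ramp_steps)
  st_hi <- inflate(mesh, material, t_w, P_high, constraints,
                   outer_wall_factor, ramp_steps = ramp_steps, X0 = st_lo$X)
  d_lo <- cell_dims(st_lo)$extent
  d_hi <- cell_dims(st_hi)$extent
  V_lo <- mesh_volume(mesh, st_lo$X)
  V_hi <- mesh_volume(mesh, st_hi$X)
  pct <- 100 * (d_hi / d_lo - 1)
  structure(list(dims_low = d_lo, dims_high = d_hi,
                 d_length_pct = pct[["length"]],
                 d_width_pct = pct[["width"]],
                 d_depth_pct = pct[["depth"]],
                 d_volume_pct = 100 * (V_hi / V_lo - 1),
                 state_low = st_lo, state_high = st_hi),
            class = "osmotic_response")
}

#' @export
print.osmotic_response <- function(x, ...) {
  cat(sprintf(paste0("Osmotic response: length %+.1f%%, width %+.1f%%, ",
                     "depth %+.1f%%, volume %+.1f%%\n"),
              x$d_length_pct, x$d_width_pct, x$d_depth_pct, x$d_volume_pct))
  invisible(x)
}

#' Apparent stiffness under microindentation
#'
#' Emulates cellular force microscopy on a turgid cell with the
#' pressure-shell contact model: the force required to press a rigid probe
#' a depth `delta` into the bulged outer wall equals the turgor pressure
#' times the area of wall flattened against the probe,
#' `F(delta) = P * A_cap(delta)`, the dominant term for pressurized cells
#' whose contact patch is wide compared to the wall thickness.  Wall
#' bending contributions are neglected (the walls are membranes).  The
#' apparent stiffness is the slope of a linear fit to the force-depth curve
#' over the central window (20-80 % of the maximum depth); uN/um equals
#' N/m.
#'
#' @param state an inflated `cell_state`.
#' @param tip_radius probe radius in um; caps the contact area.
#' @param max_depth maximum indentation depth in um.
#' @param n_steps number of depth steps.
#' @return an `indentation_result`: `depth_um`, `force_uN`, `stiffness_Npm`.
#' @export
indentation_stiffness <- function(state, tip_radius = 20, max_depth = 1,
                                  n_steps = 8) {
  mesh <- state$mesh
  sel <- mesh$face == 2L
  tri <- mesh$tri[sel, , drop = FALSE]
  X <- state$X
  z0 <- max(X[unique(as.vector(tri)), 3])
  if (max_depth <= 0) stop("max_depth must be positive")
  # projected area of the top face lying above z0 - depth (the part that a
  # descending plate has flattened), per linear interpolation on triangles
  cap_area <- function(zc) {
    a <- 0
    for (e in seq_len(nrow(tri))) {
      zv <- X[tri[e, ], 3]
      xy <- X[tri[e, ], 1:2]
      above <- zv > zc
      na <- sum(above)
      tri_area <- abs((xy[2, 1] - xy[1, 1]) * (xy[3, 2] - xy[1, 2]) -
                      (xy[3, 1] - xy[1, 1]) * (xy[2, 2] - xy[1, 2])) / 2
      if (na == 3L) {
        a <- a + tri_area
      } else if (na > 0L) {
        # fraction of the triangle above the cut, from the linear field
        if (na == 1L) {
          i <- which(above)
          f <- prod((zv[i] - zc) / (zv[i] - zv[-i]))
          a <- a + tri_area * f
        } else {
          i <- which(!above)
          f <- prod((zc - zv[i]) / (zv[-i] - zv[i]))
          a <- a + tri_area * (1 - f)
        }
      }
    }
    a
  }
  depths <- seq(0, max_depth, length.out = n_steps + 1)[-1]
  A_tip <- pi * tip_radius^2
  forces <- state$P * pmin(vapply(depths, function(d) cap_area(z0 - d), 0),
                           A_tip)
  if (all(forces <= 0)) stop("contact never established")
  win <- depths >= 0.2 * max_depth & depths <= 0.8 * max_depth
  fit <- stats::lm(forces[win] ~ depths[win])
  structure(list(depth_um = depths, force_uN = forces,
                 stiffness_Npm = unname(stats::coef(fit)[2])),
            class = "indentation_result")
}

#' Calibrate the wall anisotropy against the measured volume change
#'
#' Adjusts the longitudinal-to-transverse modulus ratio until the simulated
#' volume increase from 0 to `P` matches the target (the measured osmotic
#' volume change), keeping `E_width` fixed.  The ratio is found by 1D root
#' bracketing on the log scale.
#'
#' @param geom a [cell_geom()].
#' @param E_width transverse wall modulus, MPa.
#' @param P turgor pressure, MPa.
#' @param target_volume_pct target percent volume increase.
#' @param t_w,refinement,outer_wall_factor,poisson passed through.
#' @param ratio_range search interval for `E_length / E_width`.
#' @return list with the calibrated `material` and the achieved
#'   `osmotic_response`.
#' @export
calibrate_anisotropy <- function(geom, E_width, P = 0.7,
                                 target_volume_pct = 53, t_w = geom$t_w,
                                 refinement = 2, outer_wall_factor = 1,
                                 poisson = 0.3, ratio_range = c(1, 400)) {
  f <- function(log_ratio) {
    mat <- wall_material(E_length = E_width * exp(log_ratio),
                         E_width = E_width, poisson = poisson)
    osm <- osmotic_response(geom, mat, t_w, 0, P, refinement,
                            outer_wall_factor = outer_wall_factor)
    osm$d_volume_pct - target_volume_pct
  }
  root <- stats::uniroot(f, log(ratio_range), tol = 1e-3)
  ratio <- exp(root$root)
  mat <- wall_material(E_length = E_width * ratio, E_width = E_width,
                       poisson = poisson)
  osm <- osmotic_response(geom, mat, t_w, 0, P, refinement,
                          outer_wall_factor = outer_wall_factor)
  list(material = mat, ratio = ratio, response = osm)
}

#' Least-squares calibration of wall parameters
#'
#' Fits a subset of `{E_length, E_width, P}` to observed osmotic percent
#' changes (and optionally a CFM stiffness) by weighted least squares on the
#' simulation outputs, and reports a local sensitivity table (outputs under
#' each parameter perturbed by +/- `sens_delta`).
#'
#' @param targets named numeric; recognized names `d_length_pct`,
#'   `d_width_pct`, `d_depth_pct`, `d_volume_pct`, `stiffness_Npm`.
#' @param free character vector of free parameters among `"E_length"`,
#'   `"E_width"`, `"P"`.
#' @param start named numeric starting values for the free parameters.
#' @param geom a [cell_geom()].
#' @param fixed named list of fixed parameter values (defaults
#'   `E_width = 40`, `E_length = 320`, `P = 0.7`).
#' @param weights named weights; default `1 / pmax(|target|, 1)`.
#' @param refinement,outer_wall_factor,poisson,t_w passed to the model.
#' @param sens_delta relative perturbation for the sensitivity table.
#' @param maxit optimizer iterations.
#' @return a `cell_calibration`: `par` (fitted values), `residuals`,
#'   `fitted`, `sensitivity` (data.frame), `convergence`.
#' @export
calibrate_cell <- function(targets, free = c("E_width", "E_length", "P"),
                           start = NULL, geom = cell_geom(50, 50, 20),
                           fixed = list(E_width = 40, E_length = 320, P = 0.7),
                           weights = NULL, refinement = 2,
                           outer_wall_factor = 1, poisson = 0.3,
                           t_w = geom$t_w, sens_delta = 0.15, maxit = 60) {
  known <- c("d_length_pct", "d_width_pct", "d_depth_pct", "d_volume_pct",
             "stiffness_Npm")
  stopifnot(all(names(targets) %in% known), length(targets) >= 1)
  free <- match.arg(free, c("E_length", "E_width", "P"), several.ok = TRUE)
  if (length(targets) < length(free)) {
    stop("under-determined: ", length(free), " free parameters but only ",
         length(targets), " target(s)")
  }
  if (identical(names(targets), "d_volume_pct") && length(free) >= 2) {
    stop("non-identifiable: a volume target alone cannot constrain ",
         "two wall moduli")
  }
  if (is.null(weights)) weights <- 1 / pmax(abs(targets), 1)
  simulate <- function(pars) {
    pl <- utils::modifyList(fixed, as.list(pars))
    mat <- wall_material(E_length = pl$E_length, E_width = pl$E_width,
                         poisson = poisson)
    osm <- osmotic_response(geom, mat, t_w, 0, pl$P, refinement,
                            outer_wall_factor = outer_wall_factor)
    out <- c(d_length_pct = osm$d_length_pct, d_width_pct = osm$d_width_pct,
             d_depth_pct = osm$d_depth_pct, d_volume_pct = osm$d_volume_pct)
    if ("stiffness_Npm" %in% names(targets)) {
      ind <- indentation_stiffness(osm$state_high)
      out <- c(out, stiffness_Npm = ind$stiffness_Npm)
    }
    out[names(targets)]
  }
  if (is.null(start)) start <- unlist(fixed)[free]
  obj <- function(logp) {
    pars <- exp(logp); names(pars) <- free
    sum((weights * (simulate(pars) - targets))^2)
  }
  opt <- stats::optim(log(start), obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-4))
  par <- exp(opt$par); names(par) <- free
  fitted <- simulate(par)
  # sensitivity of outputs to +/- sens_delta in each fitted parameter
  sens <- do.call(rbind, lapply(free, function(pn) {
    lo <- par; lo[pn] <- par[pn] * (1 - sens_delta)
    hi <- par; hi[pn] <- par[pn] * (1 + sens_delta)
    out_lo <- simulate(lo); out_hi <- simulate(hi)
    data.frame(param = pn, output = names(targets),
               low = out_lo, high = out_hi,
               range = abs(out_hi - out_lo), row.names = NULL)
  }))
  structure(list(par = par, fitted = fitted, targets = targets,
                 residuals = fitted - targets, sensitivity = sens,
                 convergence = opt$convergence, value = opt$value),
            class = "cell_calibration")
}

#' Tension carried by a stretched file of turgid exocarp cells
#'
#' Simulates a file of cells sharing transverse walls, inflated at turgor
#' and held at the in-planta (flat-valve) length, and reports the end
#' reaction force scaled to the number of cell files across the valve
#' width.  This is the cell-level route to the pre-explosion exocarp
#' tension.
#'
#' @param geom a [cell_geom()].
#' @param material a [wall_material()].
#' @param P turgor pressure, MPa.
#' @param stretch in-planta length / free turgid length (default
#'   `1 / (1 - gamma)` with `gamma` = 0.2, the measured exocarp rest
#'   contraction).
#' @param n_cells cells per simulated file (shared walls modeled
#'   explicitly).
#' @param n_files number of files across the valve width (default valve
#'   width / cell width from the reference parameters).
#' @param t_w,refinement,outer_wall_factor,ramp_steps passed through.
#' @return a `file_tension`: `force_mN` (total across the valve),
#'   `force_per_file_uN`, `free_length_um`, `constrained_length_um`, states.
#' @export
file_tension_force <- function(geom, material, P = 0.7, stretch = 1 / 0.8,
                               n_cells = 2, n_files = NULL, t_w = geom$t_w,
                               refinement = 2, outer_wall_factor = 1,
                               ramp_steps = 10) {
  if (is.null(n_files)) {
    pr <- reference_params()
    n_files <- to_si(pr$valve_width, "mm") / to_si(geom$dims[["width"]], "um")
  }
  mesh <- build_cell(geom, refinement, n_cells = n_cells)
  free_st <- inflate(mesh, material, t_w, P, "tissue", outer_wall_factor,
                     ramp_steps = ramp_steps)
  xmax <- max(mesh$X[, 1])
  lo <- abs(mesh$X[, 1]) < 1e-9
  hi <- abs(mesh$X[, 1] - xmax) < 1e-9
  L_free <- mean(free_st$X[hi, 1]) - mean(free_st$X[lo, 1])
  L_c <- stretch * L_free
  if (L_c < L_free - 1e-9) stop("constrained length below free length")
  mid <- (mean(free_st$X[hi, 1]) + mean(free_st$X[lo, 1])) / 2
  st <- inflate(mesh, material, t_w, P, "tissue", outer_wall_factor,
                ramp_steps = 1, X0 = free_st$X,
                prescribe_ends = c(mid - L_c / 2, mid + L_c / 2))
  f_uN <- st$reaction_x
  structure(list(force_per_file_uN = f_uN, n_files = n_files,
                 force_mN = f_uN * n_files * 1e-3,
                 free_length_um = L_free, constrained_length_um = L_c,
                 state_free = free_st, state_constrained = st),
            class = "file_tension")
}
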
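#' Per-cell principal deformation from matched outlines
#'
#' Fits a single affine deformation gradient to index-matched vertex lists
#' of a cell outline before and after a treatment (e.g. excision), by least
#' squares on centered vertices, and extracts principal stretches and
#' directions from the polar decomposition -- the standard principal
#' directions-of-growth computation applied to shrinkage.
#'
#' @param pre,post matrices (>= 3 x 2) of matched vertices (um).
#' @return a `deformation_summary`: `lambda1 >= lambda2` (principal
#'   stretches), `dir1_deg`, `dir2_deg` (deg from the fruit axis, in
#'   [0, 180)), `shrinkage_pct` (per principal direction, `(1 - lambda)*100`),
#'   `Fgrad` (2 x 2).
#' @export
cell_deformation <- function(pre, post) {
  pre <- as.matrix(pre); post <- as.matrix(post)
  stopifnot(ncol(pre) == 2, ncol(post) == 2, nrow(pre) == nrow(post),
            nrow(pre) >= 3)
  X <- sweep(pre, 2, colMeans(pre))
  Y <- sweep(post, 2, colMeans(post))
  XtX <- crossprod(X)
  if (abs(det(XtX)) < 1e-12 * sum(diag(XtX))^2) {
    stop("degenerate (collinear) vertices")
  }
  # least squares Y ~ X %*% t(F):  F = (Y'X)(X'X)^-1
  Fg <- crossprod(Y, X) %*% solve(XtX)
  # polar decomposition F = R U; U from svd
  sv <- svd(Fg)
  U <- sv$v %*% diag(sv$d) %*% t(sv$v)
  eu <- eigen(U, symmetric = TRUE)
  lambda <- eu$values            # decreasing
  dirs <- eu$vectors
  ang <- atan2(dirs[2, ], dirs[1, ]) * 180 / pi
  ang <- ang %% 180
  structure(list(lambda1 = lambda[1], lambda2 = lambda[2],
                 dir1_deg = ang[1], dir2_deg = ang[2],
                 shrinkage_pct = (1 - lambda) * 100, Fgrad = Fg),
            class = "deformation_summary")
}

#' Per-cell tension map and dominant shrinkage class
#'
#' Applies [cell_deformation()] to a list of outline pairs and reports, per
#' cell, the maximal shrinkage and its direction, plus the dominant class:
#' `"longitudinal"` when the median maximal-shrinkage direction (folded to
#' [0, 90] degrees from the fruit axis) is below 45 degrees, else
#' `"lateral"`.
#'
#' @param pairs list of lists with elements `cell` (id), `pre`, `post`.
#' @return list with `table` (data.frame `cell`, `shrinkage_pct`,
#'   `direction_deg`) and `class`.
#' @export
tension_map <- function(pairs) {
  if (!length(pairs)) stop("need at least one outline pair")
  rows <- lapply(pairs, function(p) {
    ds <- cell_deformation(p$pre, p$post)
    # maximal shrinkage direction: the smaller principal stretch
    dir <- ds$dir2_deg
    dir <- if (dir > 90) 180 - dir else dir
    data.frame(cell = p$cell, shrinkage_pct = (1 - ds$lambda2) * 100,
               direction_deg = dir)
  })
  tab <- do.call(rbind, rows)
  cls <- if (stats::median(tab$direction_deg) < 45) "longitudinal" else
    "lateral"
  list(table = tab, class = cls)
}

#' Orientation statistics of microtubule / fibril segments
#'
#' Folds segment angles relative to the fruit axis into [0, 90] degrees,
#' bins them into the longitudinal ([0, 30)), intermediate ([30, 45)) and
#' transverse ([45, 90]) classes, and computes the principal orientation
#' from the weighted structure-tensor mean of doubled angles.  When the
#' doubled-angle vector cancels (isotropy) the principal orientation is
#' flagged undefined.
#'
#' @param angles_deg segment orientations in degrees (any range; folded
#'   modulo 180).
#' @param weights non-negative weights (e.g. segment lengths).
#' @param fruit_axis_deg orientation of the fruit axis (deg).
#' @return an `orientation_stats` list: `histogram` (named fractions),
#'   `principal_deg` (in [0, 90], or NA), `isotropic`, `class`.
#' @export
orientation_stats <- function(angles_deg, weights = NULL,
                              fruit_axis_deg = 0) {
  stopifnot(length(angles_deg) >= 1)
  if (is.null(weights)) weights <- rep(1, length(angles_deg))
  stopifnot(all(weights >= 0), length(weights) == length(angles_deg))
  rel <- (angles_deg - fruit_axis_deg) %% 180
  fold <- ifelse(rel > 90, 180 - rel, rel)
  w <- weights / sum(weights)
  bins <- c(longitudinal = sum(w[fold < 30]),
            intermediate = sum(w[fold >= 30 & fold < 45]),
            transverse = sum(w[fold >= 45]))
  # structure tensor: mean of doubled angles
  a2 <- 2 * rel * pi / 180
  cx <- sum(w * cos(a2)); sx <- sum(w * sin(a2))
  r <- sqrt(cx^2 + sx^2)
  isotropic <- r < 1e-8
  principal <- if (isotropic) NA_real_ else {
    p <- (atan2(sx, cx) / 2 * 180 / pi) %% 180
    if (p > 90) 180 - p else p
  }
  cls <- names(bins)[which.max(bins)]
  structure(list(histogram = bins, principal_deg = principal,
                 isotropic = isotropic, class = cls),
            class = "orientation_stats")
}

#' Speeds from tracked points
#'
#' Central-difference velocities of tracked points from high-speed frames;
#' per-point launch speed (speed at the first frame after an optional
#' release flag) and summary statistics.
#'
#' @param tracks data.frame with columns `point`, `frame`, `x`, `y`
#'   (coordinates in mm).
#' @param fps frame rate in Hz.
#' @param release optional named vector: first released frame per point.
#' @return list with `speeds` (data.frame `point`, `frame`, `t_s`,
#'   `speed_mps`), `launch` (per-point launch speed, m/s) and `summary`
#'   (mean, sd, max).
#' @export
track_speeds <- function(tracks, fps, release = NULL) {
  stopifnot(fps > 0)
  if (anyDuplicated(tracks[, c("point", "frame")])) {
    stop("duplicate (point, frame) rows")
  }
  dt <- 1 / fps
  out <- lapply(split(tracks, tracks$point), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < 2) stop("each point needs at least 2 frames")
    n <- nrow(tr)
    # central differences; one-sided at the ends (mm -> m)
    vx <- numeric(n); vy <- numeric(n)
    fdt <- c(diff(tr$frame)[1], diff(tr$frame, lag = 2) / 2,
             diff(tr$frame)[n - 1]) * dt
    vx <- c(diff(tr$x)[1], diff(tr$x, lag = 2) / 2, diff(tr$x)[n - 1]) *
      1e-3 / fdt
    vy <- c(diff(tr$y)[1], diff(tr$y, lag = 2) / 2, diff(tr$y)[n - 1]) *
      1e-3 / fdt
    data.frame(point = tr$point, frame = tr$frame, t_s = tr$frame * dt,
               speed_mps = sqrt(vx^2 + vy^2))
  })
  speeds <- do.call(rbind, out)
  rownames(speeds) <- NULL
  launch <- vapply(split(speeds, speeds$point), function(sp) {
    fr <- if (!is.null(release) && as.character(sp$point[1]) %in%
              names(release)) {
      rel <- release[[as.character(sp$point[1])]]
      sel <- sp$frame >= rel
      if (!any(sel)) return(NA_real_)
      sp$speed_mps[which(sel)[1]]
    } else sp$speed_mps[1]
  }, 0)
  list(speeds = speeds, launch = launch,
       summary = c(mean = mean(launch, na.rm = TRUE),
                   sd = stats::sd(launch),
                   max = max(launch, na.rm = TRUE)))
}
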
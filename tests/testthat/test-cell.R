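test_that("the box mesh closes with exact volume, area and element scaling", {
  m1 <- build_cell(small_cell, 1)
  d <- small_cell$dims
  expect_equal(mesh_volume(m1), unname(prod(d)), tolerance = 1e-6)
  expect_equal(mesh_area(m1),
               unname(2 * (d[1] * d[2] + d[1] * d[3] + d[2] * d[3])),
               tolerance = 1e-6)
  m2 <- build_cell(small_cell, 2)
  expect_equal(nrow(m2$tri), 4 * nrow(m1$tri))
  expect_error(build_cell(cell_geom(1, 1, 1), 0), "refinement")
})

test_that("the membrane gradient matches finite differences", {
  mesh <- build_cell(cell_geom(20, 20, 20, 1), 1)
  pp <- podburst:::.prep_elements(mesh, wall_material(50, 30, 20, 0.3), 1, 2)
  set.seed(4)
  x0 <- as.vector(mesh$X) + stats::rnorm(3 * nrow(mesh$X), 0, 0.02)
  eg <- podburst:::membrane_eg(x0, mesh$tri, pp$Bm, pp$A0, pp$tw, pp$Q,
                               0.4, mesh$pw, NULL)
  ii <- sample(length(x0), 10)
  h <- 1e-5
  num <- vapply(ii, function(i) {
    xp <- x0; xp[i] <- xp[i] + h
    xm <- x0; xm[i] <- xm[i] - h
    (podburst:::membrane_eg(xp, mesh$tri, pp$Bm, pp$A0, pp$tw, pp$Q, 0.4,
                            mesh$pw, NULL)$W -
       podburst:::membrane_eg(xm, mesh$tri, pp$Bm, pp$A0, pp$tw, pp$Q, 0.4,
                              mesh$pw, NULL)$W) / (2 * h)
  }, 0)
  expect_equal(num, eg$G[ii], tolerance = 1e-5)
})

test_that("one element under uniaxial stretch reproduces the plane-stress closed form", {
  # single triangle, unit rest legs, material frame = global (x, y)
  tri <- matrix(c(1L, 2L, 3L), 1)
  Bm <- matrix(c(1, 0, 0, 1), 1)  # rest edges = identity
  A0 <- 0.5; tw <- 1
  E1 <- 80; E2 <- 20; nu <- 0.3
  n21 <- nu * E2 / E1; den <- 1 - nu * n21
  Q <- matrix(c(E1 / den, E2 / den, n21 * E1 / den,
                sqrt(E1 * E2) / (2 * (1 + nu))), 1)
  lam <- 1.07
  x <- c(0, lam, 0,  0, 0, 1,  0, 0, 0)  # nodes (0,0,0), (lam,0,0), (0,1,0)
  eg <- podburst:::membrane_eg(x, tri, Bm, A0, tw, Q, 0, 1, NULL)
  # energy density 1/2 * E : C : E with only E11 nonzero (laterally
  # constrained stretch): W = 1/2 * Q11 * E11^2 per unit volume
  E11 <- (lam^2 - 1) / 2
  expect_equal(eg$W, A0 * tw * 0.5 * (E1 / den) * E11^2, tolerance = 1e-12)
})

test_that("zero pressure leaves the mesh untouched", {
  mesh <- build_cell(small_cell, 1)
  st <- inflate(mesh, ref_wall, 1, 0, outer_wall_factor = 4, ramp_steps = 1)
  expect_lt(max(abs(st$X - mesh$X)), 1e-9)
})

test_that("an isotropic cube inflates isotropically", {
  mesh <- build_cell(cell_geom(20, 20, 20, 1), 2)
  st <- inflate(mesh, wall_material(40), 1, 0.5, constraints = "free",
                outer_wall_factor = 2)  # equal thickness on all faces
  ch <- cell_dims(st)$extent / 20 - 1
  expect_lt(diff(range(ch)), 0.005)
})

test_that("mesh refinement has converged at the default level", {
  o1 <- osmotic_response(small_cell, ref_wall, refinement = 1,
                         outer_wall_factor = 4)
  o2 <- osmotic_response(small_cell, ref_wall, refinement = 2,
                         outer_wall_factor = 4)
  expect_lt(abs(o1$d_volume_pct - o2$d_volume_pct), 6)
  expect_lt(abs(o1$d_length_pct - o2$d_length_pct), 2)
})

test_that("turgor lengthens slender cells and slightly shortens squat ones", {
  iso <- wall_material(40)
  thal <- osmotic_response(cell_geom(100, 20, 20, 1), iso, refinement = 1,
                           outer_wall_factor = 4)
  expect_gt(thal$d_length_pct, 0)
  hirs <- osmotic_response(cell_geom(50, 50, 20, 1), iso, refinement = 1,
                           outer_wall_factor = 4)
  expect_lt(hirs$d_length_pct, 0)
  expect_gt(hirs$d_length_pct, -8)   # "slightly"
  expect_gt(hirs$d_depth_pct, 0)     # surface and bottom walls bulge out
})

test_that("equal pressures produce a null osmotic response", {
  o <- osmotic_response(small_cell, ref_wall, P_low = 0.4, P_high = 0.4,
                        refinement = 1, outer_wall_factor = 4)
  expect_equal(o$d_volume_pct, 0, tolerance = 1e-4)
  expect_equal(o$d_length_pct, 0, tolerance = 1e-4)
  expect_error(osmotic_response(small_cell, ref_wall, P_low = 0.7,
                                P_high = 0.2), "P_high")
})

test_that("apparent stiffness rises with turgor, cell size and wall stiffness", {
  stiff <- function(P = 0.7, geom = small_cell, fac = 1) {
    m <- wall_material(ref_p$E_wall_length * fac, ref_p$E_wall_width * fac,
                       poisson = 0.3)
    st <- inflate(build_cell(geom, 2), m, 1, P, outer_wall_factor = 4)
    indentation_stiffness(st)$stiffness_Npm
  }
  ks <- vapply(c(0.35, 0.7, 1.05), stiff, 0)
  expect_true(all(diff(ks) > 0))
  expect_gt(stiff(geom = small_cell), stiff(geom = cell_geom(30, 20, 14, 1)))
  expect_gt(stiff(fac = 2), stiff(fac = 1))
  ind <- indentation_stiffness(inflate(build_cell(small_cell, 2), ref_wall,
                                       1, 0.7, outer_wall_factor = 4))
  expect_true(all(diff(ind$force_uN) >= 0))
})

test_that("calibration recovers the generating wall parameters exactly", {
  truth <- wall_material(E_length = 100, E_width = 35, poisson = 0.3)
  osmT <- osmotic_response(small_cell, truth, refinement = 1,
                           outer_wall_factor = 4)
  targets <- c(d_length_pct = osmT$d_length_pct,
               d_width_pct = osmT$d_width_pct,
               d_depth_pct = osmT$d_depth_pct,
               d_volume_pct = osmT$d_volume_pct)
  cal <- calibrate_cell(targets, free = c("E_width", "E_length"),
                        geom = small_cell,
                        fixed = list(E_width = 40, E_length = 120, P = 0.7),
                        refinement = 1, outer_wall_factor = 4, maxit = 40)
  expect_equal(unname(cal$par[["E_width"]]), 35, tolerance = 0.02)
  expect_equal(unname(cal$par[["E_length"]]), 100, tolerance = 0.02)
})

test_that("ill-posed calibration requests are refused with a reason", {
  expect_error(calibrate_cell(c(d_volume_pct = 53),
                              free = c("E_width", "E_length")),
               "under-determined")
  expect_error(calibrate_cell(c(d_volume_pct = 53),
                              free = c("E_width", "E_length", "P")),
               "under-determined|non-identifiable")
})

test_that("a file held at its free length exerts no tension", {
  ft <- file_tension_force(small_cell, ref_wall, stretch = 1,
                           refinement = 1, outer_wall_factor = 4)
  scale_uN <- 0.7 * prod(small_cell$dims[2:3])  # pressure x cross-section
  expect_lt(abs(ft$force_per_file_uN) / scale_uN, 0.05)
})

test_that("file tension grows monotonically with the imposed stretch", {
  f <- vapply(c(1.05, 1.15, 1.25), function(s) {
    file_tension_force(small_cell, ref_wall, stretch = s, refinement = 1,
                       outer_wall_factor = 4)$force_per_file_uN
  }, 0)
  expect_true(all(diff(f) > 0))
  expect_error(file_tension_force(small_cell, ref_wall, stretch = 0.9,
                                  refinement = 1), "below free length")
})
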
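test_that("lumped rod mass equals the layer mass of the valve", {
  rod <- build_rod(ref_valve, ref_land, 80)
  total <- sum(ref_valve$mass_per_area) * ref_p$valve_width *
    ref_p$valve_length  # mg
  expect_equal(sum(rod$mass), to_si(total, "mg"), tolerance = 1e-10)
  expect_error(build_rod(ref_valve, ref_land, 2), "n_segments")
})

test_that("a rod without intrinsic curvature stays straight", {
  p0 <- reference_params(exocarp_rest_contraction = 1e-12)
  v0 <- valve_model(p0, "hinged")
  rod <- build_rod(v0, landscape(v0), 30)
  ser <- simulate_release(rod, NULL, dt = 1e-4, T_end = 0.5, stride = 100)
  expect_lt(max(abs(ser$Y)), 1e-9)
})

test_that("initial rod energy matches the landscape's initial energy", {
  rod <- build_rod(ref_valve, ref_land, 80)
  ser <- simulate_release(rod, NULL, dt = 1e-4, T_end = 0.02, stride = 10)
  expect_equal(ser$energies$elastic_mJ[1], ref_land$U_initial,
               tolerance = 0.02)
})

test_that("undamped coiling conserves total energy to within 1 %", {
  # no tethers: a rupture discards the stored adhesion energy by design,
  # so conservation is a property of the rod integrator alone
  ser <- run_reference_release(n_segments = 60, T_end = 2.5, seeds = list())
  tot <- ser$energies$elastic_mJ + ser$energies$kinetic_mJ +
    ser$energies$tether_mJ
  expect_lt(max(abs(tot - tot[1])) / tot[1], 0.01)
})

test_that("an unclamped, untethered rod conserves linear momentum", {
  rod <- build_rod(ref_valve, ref_land, 40)
  ser <- simulate_release(rod, NULL, dt = 1e-4, T_end = 1, stride = 100,
                          clamp_release_ms = 0)
  # zero initial momentum and no external force: the mass centroid stays put
  m <- rod$mass
  comx <- as.vector(ser$X %*% m) / sum(m)
  comy <- as.vector(ser$Y %*% m) / sum(m)
  L_mm <- ref_p$valve_length
  expect_lt(max(abs(comx - comx[1])) / L_mm, 1e-6)
  expect_lt(max(abs(comy - comy[1])) / L_mm, 1e-6)
})

test_that("with damping the rod settles onto the equilibrium curvature", {
  rod <- build_rod(ref_valve, ref_land, 40)
  ser <- simulate_release(rod, NULL, dt = 1e-4, T_end = 12, stride = 500,
                          damping = 3000)
  nf <- nrow(ser$X)
  x <- ser$X[nf, ] ; y <- ser$Y[nf, ]
  h <- from_si(rod$h, "mm")
  th <- atan2(diff(y), diff(x))
  kap <- abs(diff(unwrap_angles(th))) / h      # 1/mm at interior nodes
  interior <- 5:(length(kap) - 4)              # away from clamp and tip
  expect_lt(max(abs(kap[interior] - ref_land$kappa_star)) /
              ref_land$kappa_star, 0.05)
})

test_that("refining the discretization leaves the settled curvature unchanged", {
  kap_mean <- function(n) {
    rod <- build_rod(ref_valve, ref_land, n)
    ser <- simulate_release(rod, NULL, dt = 1e-4, T_end = 12, stride = 1000,
                            damping = 3000)
    nf <- nrow(ser$X)
    th <- atan2(diff(ser$Y[nf, ]), diff(ser$X[nf, ]))
    mean(abs(diff(unwrap_angles(th))) / from_si(rod$h, "mm"))
  }
  expect_lt(abs(kap_mean(20) - kap_mean(40)) / kap_mean(40), 0.02)
})

test_that("seeds with a vanishing critical extension release immediately and slowly", {
  p <- reference_params(tether_delta_c = 0.005)  # 5 nm
  ser <- run_reference_release(n_segments = 40, T_end = 0.5,
                               seeds = seed_tethers(p), stride = 50)
  lc <- launch_conditions(ser)
  expect_true(all(lc$released))
  expect_lt(max(lc$t_release), 0.1)
  # released essentially from rest: speed is that of the barely-moving valve
  expect_lt(mean(lc$speed), 0.5)
})

test_that("doubling seed mass strictly slows the mean launch", {
  mean_speed <- function(mass) {
    p <- reference_params(seed_mass = mass)
    ser <- run_reference_release(n_segments = 60, T_end = 4,
                                 seeds = seed_tethers(p))
    lc <- suppressWarnings(launch_conditions(ser))
    mean(lc$speed[lc$released])
  }
  expect_gt(mean_speed(1), mean_speed(2))
})

test_that("material-point trajectories behave like tracked points", {
  ser <- run_reference_release(n_segments = 40, T_end = 3)
  tr <- point_trajectories(ser, c(seq(1, 15, length.out = 8), 16))
  expect_equal(length(unique(tr$point)), 9)
  first <- tr[tr$frame == 1, ]
  expect_lt(max(abs(first$y_mm)), 1e-9)     # all start on the straight valve
  clamped <- point_trajectories(ser, 0)
  expect_lt(max(abs(clamped$x_mm - clamped$x_mm[1])), 1e-9)
  tip <- tr[tr$point == 9, ]              # the free tip, arclength L
  path <- sum(sqrt(diff(tip$x_mm)^2 + diff(tip$y_mm)^2))
  expect_gt(path, ref_p$valve_length)       # the tip whips farther than L
  expect_error(point_trajectories(ser, 99), "arclength")
})

test_that("integration aborts cleanly when the step exceeds the stability bound", {
  rod <- build_rod(ref_valve, ref_land, 40)
  expect_error(simulate_release(rod, NULL, dt = 0.05, T_end = 1),
               "stability bound")
})
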
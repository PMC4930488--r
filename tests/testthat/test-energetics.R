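test_that("stack resultants reproduce the single-layer closed form", {
  v <- structure(list(
    L = 10, w = 1,
    layers = list(layer_spec("only", -500, 500, 1)),  # +-0.5 mm band, 1 MPa
    cross_section = cross_section_spec("hinged", kappa_t = 0),
    mass_per_area = 1, E_lignin = 1), class = "valve_model")
  r <- stack_resultants(v)
  expect_equal(r$EA, 1, tolerance = 1e-12)                 # N
  expect_equal(r$EI * 1e6, 1 / 12, tolerance = 1e-12)      # N mm^2
  expect_equal(r$ES, 0, tolerance = 1e-15)
  expect_equal(r$N0, 0)
})

test_that("a zero area-fraction layer contributes nothing", {
  v1 <- make_bilayer(10, 20, 50, 50, 0.1)
  v2 <- v1
  v2$layers <- c(v1$layers, list(layer_spec("ghost", 100, 150, 1000,
                                            area_fraction = 1)))
  v2$layers[[3]]$area_fraction <- 1e-12
  r1 <- stack_resultants(v1)
  r2 <- stack_resultants(v2)
  expect_equal(r2$EA, r1$EA, tolerance = 1e-9)
  expect_equal(r2$EI, r1$EI, tolerance = 1e-9)
})

test_that("reference resultants match brute-force quadrature", {
  # midpoint quadrature of the energy integrand at 1e4 points per layer
  r <- stack_resultants(ref_valve)
  w <- to_si(ref_valve$w, "mm")
  num <- list(EA = 0, ES = 0, EI = 0, N0 = 0, M0 = 0)
  for (l in ref_valve$layers) {
    E <- to_si(l$E, "MPa")
    z <- seq(to_si(l$z_lo, "um"), to_si(l$z_hi, "um"), length.out = 1e4 + 1)
    zm <- (z[-1] + z[-length(z)]) / 2
    h <- diff(z)[1]
    k <- E * l$area_fraction * w
    num$EA <- num$EA + k * sum(h * rep(1, length(zm)))
    num$ES <- num$ES + k * sum(h * zm)
    num$EI <- num$EI + k * sum(h * zm^2)
    num$N0 <- num$N0 + k * l$g * sum(h * rep(1, length(zm)))
    num$M0 <- num$M0 + k * l$g * sum(h * zm)
  }
  for (f in names(num)) {
    expect_equal(r[[f]], num[[f]], tolerance = 1e-8, label = f)
  }
})

test_that("zero rest contraction gives a stress-free flat minimum", {
  p0 <- reference_params(exocarp_rest_contraction = 1e-12)
  v0 <- valve_model(p0, "hinged")
  expect_equal(energy_at_curvature(v0, 0), 0, tolerance = 1e-15)
  l0 <- landscape(v0)
  expect_equal(l0$kappa_star, 0, tolerance = 1e-9)
  expect_equal(l0$coils, 0, tolerance = 1e-9)
  # no bending energy to release (the residual is the small hinge cost that
  # flattening the bowed cross-section always consumes)
  expect_lt(abs(l0$delta_E + l0$flatten_cost), 1e-9)
})

test_that("bilayer equilibrium curvature matches the bimetal closed form", {
  cases <- list(c(E1 = 10, E2 = 10, t1 = 40, t2 = 40, dg = 0.05),
                c(E1 = 100, E2 = 5, t1 = 10, t2 = 60, dg = 0.2),
                c(E1 = 3, E2 = 80, t1 = 25, t2 = 75, dg = 0.1))
  for (cs in cases) {
    v <- make_bilayer(cs["E1"], cs["E2"], cs["t1"], cs["t2"], cs["dg"])
    l <- landscape(v)
    k_ref <- timoshenko_kappa(cs["E1"], cs["E2"], to_si(cs["t1"], "um"),
                              to_si(cs["t2"], "um"), cs["dg"]) / 1e3  # 1/mm
    expect_equal(unname(l$kappa_star), abs(unname(k_ref)), tolerance = 1e-8)
  }
})

test_that("the flat-section energy is an upward parabola with zero net axial force", {
  kg <- seq(0, 3, length.out = 31)
  U <- energy_at_curvature(ref_valve, kg)
  d2 <- diff(diff(U))
  expect_true(all(d2 > 0))
  # force balance at the optimal membrane strain, a few curvatures
  r <- stack_resultants(ref_valve)
  for (k in c(0, 0.7, 1.43, 2.5)) {
    e0 <- podburst:::optimal_eps0(ref_valve, k)
    net <- r$EA * e0 + r$ES * (-k * 1e3) - r$N0
    expect_lt(abs(net), 1e-10)
  }
})

test_that("curvature and release grow with contraction, shrink with stiffer rods", {
  gam <- seq(0.1, 0.3, length.out = 5)
  ks <- de <- numeric(5)
  for (i in seq_along(gam)) {
    l <- landscape(valve_model(reference_params(exocarp_rest_contraction =
                                                  gam[i]), "hinged"))
    ks[i] <- l$kappa_star; de[i] <- l$delta_E
  }
  expect_true(all(diff(ks) > 0))
  expect_true(all(diff(de) > 0))

  rods <- seq(3, 12, length.out = 5)
  ks2 <- vapply(rods, function(t) {
    landscape(valve_model(reference_params(endocarpb_rod_thickness = t),
                          "hinged"))$kappa_star
  }, 0)
  expect_true(all(diff(ks2) < 0))
})

test_that("flattening is free without transverse curvature or hinge stiffness", {
  cs0 <- cross_section_spec("hinged", kappa_t = 0)
  expect_equal(flatten_cost(cs0, ref_valve), 0)
  csb0 <- cross_section_spec("boxed", kappa_t = 0)
  expect_equal(flatten_cost(csb0, ref_valve), 0)
  csh <- cross_section_spec("hinged", kappa_t = 2, hinge_stiffness = 0)
  expect_equal(flatten_cost(csh, ref_valve), 0)
})

test_that("boxed flattening cost equals the quadrature of plate bending energy", {
  cs <- box_valve$cross_section
  got <- flatten_cost(cs, box_valve)
  # independent quadrature: 1/2 E kappa_t^2 z^2 over the two plate bands,
  # z measured from the plate-pair mid-plane
  E <- to_si(box_valve$E_lignin, "MPa")
  kt <- cs$kappa_t * 1e3
  tp <- to_si(cs$plate_thickness, "um")
  sep <- to_si(cs$plate_separation, "um")
  zl <- seq(-sep / 2, -sep / 2 + tp, length.out = 2e4)
  h <- diff(zl)[1]
  I_plate <- sum(h * ((zl[-1] + zl[-length(zl)]) / 2)^2)
  D_t <- 2 * E * cs$plate_area_fraction * I_plate
  exp_cost <- from_si(0.5 * D_t * kt^2 * to_si(box_valve$w, "mm") *
                        to_si(box_valve$L, "mm"), "mJ")
  expect_equal(got, exp_cost, tolerance = 1e-7)
})

test_that("hinged geometry out-coils and out-releases the boxed geometry", {
  expect_gt(ref_land$coils, box_land$coils)
  expect_gt(ref_land$delta_E, box_land$delta_E)
  expect_lte(ref_land$flatten_cost, 0.01 * ref_land$delta_E)
  expect_true(all(ref_land$U_flat >= min(ref_land$U_flat)))
  # the closed-form vertex beats every grid point
  expect_lte(min(energy_at_curvature(ref_valve, ref_land$kappa_star)),
             min(ref_land$U_flat) / (to_si(ref_valve$L, "mm") * 1e3) + 1e-12)
})

test_that("landscape argument validation", {
  expect_error(landscape(ref_valve, n_grid = 2), "n_grid")
  expect_error(landscape(ref_valve, kappa_max = -1), "kappa_max")
  v_empty <- ref_valve
  v_empty$layers <- list()
  expect_error(stack_resultants(v_empty), "no layers")
})
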
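test_that("a straight rod pulled below its length is slack", {
  expect_equal(elastica_force_displacement(1, 0, 16, c(5, 10, 15)),
               c(0, 0, 0))
  expect_error(elastica_force_displacement(1, 0.5, 16, 16), "contour length")
})

test_that("tension rises monotonically as the coil is pulled out", {
  dmax <- elastica_extension_limit(1.4, 16)
  d0 <- elastica_natural_distance(1.4, 16)
  dd <- seq(d0 + 0.2, 0.97 * dmax, length.out = 8)
  f <- elastica_force_displacement(0.02, 1.4, 16, dd)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0))
})

test_that("the axial force equals the energy gradient (virtual work)", {
  # the continuation table stores the minimized bending energy, so the
  # multiplier (force) must equal dU/d(end-to-end distance)
  kh <- 1; L <- 16
  tab <- podburst:::.elastica_table(kh * L, 160, n_phi = 240)
  i <- seq(40, length(tab$delta) - 10)
  dudd <- (tab$ubend[i + 1] - tab$ubend[i - 1]) /
    (tab$delta[i + 1] - tab$delta[i - 1])
  expect_lt(stats::median(abs(dudd - tab$phi[i]) / tab$phi[i]), 0.005)
  expect_lt(max(abs(dudd - tab$phi[i]) / tab$phi[i]), 0.05)
  # refinement stability of the forces themselves
  d0 <- elastica_natural_distance(kh, L)
  dmax <- elastica_extension_limit(kh, L)
  dd <- seq(d0 + 0.25 * (dmax - d0), d0 + 0.9 * (dmax - d0),
            length.out = 8)
  f1 <- elastica_force_displacement(1, kh, L, dd, n = 160)
  f2 <- elastica_force_displacement(1, kh, L, dd, n = 320)
  expect_lt(max(abs(f2 - f1) / f1), 0.06)
})

test_that("setup compliance is recovered exactly from a clean curve", {
  gb <- gen_extensometer(B_true = 0.02, kappa_hat = 1.2, L = 16,
                         k_setup = 0.5, noise_frac = 0, seed = 1)
  cor <- suppressWarnings(correct_setup_compliance(gb$payload))
  expect_equal(attr(cor, "k_setup"), 0.5, tolerance = 1e-6)
  expect_false(is.na(attr(cor, "rupture_index")))
})

test_that("a pure spring input corrects to zero net displacement", {
  k <- 0.8
  f <- seq(0.5, 12, by = 0.5)
  raw <- extensometer_curve(f / k, f)
  cor <- suppressWarnings(correct_setup_compliance(raw))
  expect_lt(max(abs(cor$displacement_um)), 1e-8)
})

test_that("noisy curves still yield the setup stiffness within 5 %", {
  errs <- vapply(1:5, function(s) {
    gb <- gen_extensometer(B_true = 0.02, kappa_hat = 1.2, L = 16,
                           k_setup = 0.5, noise_frac = 0.02, seed = s)
    cor <- suppressWarnings(correct_setup_compliance(gb$payload))
    abs(attr(cor, "k_setup") - 0.5) / 0.5
  }, 0)
  expect_lt(stats::median(errs), 0.05)
  expect_lt(max(errs), 0.10)
})

test_that("bending stiffness round-trips through generator and fit", {
  gb <- gen_extensometer(B_true = 0.015, kappa_hat = 1.4, L = 16,
                         k_setup = 0.5, noise_frac = 0, seed = 2)
  cor <- suppressWarnings(correct_setup_compliance(gb$payload))
  fit <- fit_bending_stiffness(cor, 1.4, 16, n_boot = 0)
  expect_equal(fit$B_Nmm2, 0.015, tolerance = 1e-3)
})

test_that("doubling all forces doubles the fitted stiffness", {
  gb <- gen_extensometer(B_true = 0.015, kappa_hat = 1.4, L = 16,
                         k_setup = 1e9, noise_frac = 0, seed = 2)
  cur <- gb$payload
  cur2 <- extensometer_curve(cur$displacement_um, 2 * cur$force_mN)
  f1 <- fit_bending_stiffness(cur, 1.4, 16, n_boot = 0)
  f2 <- fit_bending_stiffness(cur2, 1.4, 16, n_boot = 0)
  expect_equal(f2$B_Nmm2 / f1$B_Nmm2, 2, tolerance = 1e-10)
})

test_that("the fit is stable under curve subsampling", {
  gb <- gen_extensometer(B_true = 0.03, kappa_hat = 1.4, L = 16,
                         k_setup = 0.5, noise_frac = 0.02, seed = 5)
  cor <- suppressWarnings(correct_setup_compliance(gb$payload))
  full <- fit_bending_stiffness(cor, 1.4, 16, n_boot = 0)
  half <- cor[seq(1, nrow(cor), by = 2), ]
  class(half) <- class(cor)
  sub <- fit_bending_stiffness(half, 1.4, 16, n_boot = 0)
  expect_equal(sub$B_Nmm2, full$B_Nmm2, tolerance = 0.02)
})

test_that("bootstrap intervals cover the generating stiffness", {
  hits <- 0; trials <- 50
  for (s in seq_len(trials)) {
    gb <- gen_extensometer(B_true = 0.02, kappa_hat = 1.4, L = 16,
                           k_setup = 0.5, noise_frac = 0.04, seed = 100 + s)
    cor <- suppressWarnings(correct_setup_compliance(gb$payload))
    fit <- fit_bending_stiffness(cor, 1.4, 16, n_boot = 150, seed = s)
    if (fit$ci[1] <= 0.02 && 0.02 <= fit$ci[2]) hits <- hits + 1
  }
  expect_gte(hits / trials, 0.9)
})

test_that("replicate noisy fits stay within the observed experimental spread", {
  Bs <- vapply(1:5, function(s) {
    gb <- gen_extensometer(B_true = 0.02, kappa_hat = 1.4, L = 16,
                           k_setup = 0.5, noise_frac = 0.05, seed = 200 + s)
    cor <- suppressWarnings(correct_setup_compliance(gb$payload))
    fit_bending_stiffness(cor, 1.4, 16, n_boot = 0)$B_Nmm2
  }, 0)
  expect_lt(stats::sd(Bs) / mean(Bs), 0.5)
})

test_that("the exocarp modulus inverts the layer stack exactly", {
  r <- stack_resultants(ref_valve)
  B_true <- (r$EI - r$ES^2 / r$EA) * 1e6
  ex <- exocarp_from_valve(B_true, ref_p)
  expect_equal(ex$E_exocarp, ref_p$E_exocarp, tolerance = 1e-8)
  expect_equal(ex$force_mN,
               ref_p$E_exocarp * ref_p$valve_width *
                 ref_p$exocarp_thickness * 1e-3 *
                 ref_p$exocarp_rest_contraction * 1e3,
               tolerance = 1e-8)
  expect_error(exocarp_from_valve(1e-9, ref_p), "negative exocarp modulus")
})
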
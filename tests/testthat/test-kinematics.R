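square <- cbind(c(-1, 1, 1, -1, 0.2), c(-1, -1, 1, 1, 1.4)) * 10

test_that("identity and uniaxial contraction are measured exactly", {
  ds <- cell_deformation(square, square)
  expect_equal(ds$lambda1, 1, tolerance = 1e-12)
  expect_equal(ds$lambda2, 1, tolerance = 1e-12)

  post <- square %*% diag(c(0.8, 1))
  ds <- cell_deformation(square, post)
  expect_equal(ds$lambda2, 0.8, tolerance = 1e-12)
  expect_equal(ds$shrinkage_pct[2], 20, tolerance = 1e-10)
  expect_equal(ds$dir2_deg %% 180, 0, tolerance = 1e-8)
})

test_that("a random affine map is recovered to machine precision", {
  set.seed(42)
  for (i in 1:5) {
    ang <- sort(stats::runif(8, 0, 2 * pi))
    poly <- cbind(cos(ang), sin(ang)) * stats::runif(8, 5, 12)
    Fg <- matrix(stats::rnorm(4, sd = 0.2), 2) + diag(2)
    ds <- cell_deformation(poly, poly %*% t(Fg))
    expect_equal(ds$Fgrad, Fg, tolerance = 1e-10)
  }
})

test_that("degenerate collinear outlines are rejected", {
  line <- cbind(1:5, 2 * (1:5))
  expect_error(cell_deformation(line, line), "collinear")
})

test_that("principal directions rotate with the data, stretches do not", {
  post <- square %*% diag(c(0.7, 1.1))
  base <- cell_deformation(square, post)
  for (th in c(30, 77) * pi / 180) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    rot <- cell_deformation(square %*% t(R), post %*% t(R))
    expect_equal(sort(c(rot$lambda1, rot$lambda2)),
                 sort(c(base$lambda1, base$lambda2)), tolerance = 1e-10)
    dd <- (rot$dir2_deg - base$dir2_deg - th * 180 / pi) %% 180
    expect_lt(min(dd, 180 - dd), 1e-6)
  }
})

test_that("tension maps classify the contraction axis and detect switches", {
  gx <- gen_outline_pairs(8, magnitude_pct = 20, direction_deg = 0, seed = 1)
  tm <- tension_map(gx$payload)
  expect_equal(tm$class, "longitudinal")
  expect_equal(tm$table$shrinkage_pct, rep(20, 8), tolerance = 1e-8)

  gy <- gen_outline_pairs(8, magnitude_pct = 20, direction_deg = 90, seed = 1)
  expect_equal(tension_map(gy$payload)$class, "lateral")

  gs <- gen_outline_pairs(12, magnitude_pct = 15, direction_deg = 80,
                          switch_index = 7, direction2_deg = 10, seed = 3)
  tm <- tension_map(gs$payload)
  folded <- tm$table$direction_deg
  detected <- which(folded < 45)[1]
  expect_equal(detected, 7)

  g0 <- gen_outline_pairs(5, magnitude_pct = 0, seed = 2)
  expect_lt(max(abs(tension_map(g0$payload)$table$shrinkage_pct)), 1e-8)
  expect_error(tension_map(list()), "at least one")
})

test_that("orientation statistics bin and classify segment angles", {
  s0 <- orientation_stats(rep(0, 10))
  expect_equal(unname(s0$histogram["longitudinal"]), 1)
  expect_equal(s0$class, "longitudinal")
  expect_equal(s0$principal_deg, 0, tolerance = 1e-8)

  s90 <- orientation_stats(rep(90, 10))
  expect_equal(unname(s90$histogram["transverse"]), 1)
  expect_equal(s90$principal_deg, 90, tolerance = 1e-8)

  iso <- orientation_stats(c(0, 90), weights = c(1, 1))
  expect_true(iso$isotropic)
  expect_true(is.na(iso$principal_deg))
  expect_equal(unname(iso$histogram[c("longitudinal", "transverse")]),
               c(0.5, 0.5))
})

test_that("orientation statistics are invariant to order and angle folding", {
  set.seed(9)
  ang <- stats::runif(40, 0, 180)
  w <- stats::runif(40)
  a <- orientation_stats(ang, w)
  pr <- sample(40)
  b <- orientation_stats(ang[pr], w[pr])
  expect_equal(a$histogram, b$histogram, tolerance = 1e-12)
  expect_equal(a$principal_deg, b$principal_deg, tolerance = 1e-10)
  cc <- orientation_stats(ang + 180, w)
  expect_equal(a$principal_deg, cc$principal_deg, tolerance = 1e-10)
})

test_that("track speeds recover constant velocities and flag bad input", {
  fps <- 15000
  tr <- data.frame(point = 1, frame = 1:20,
                   x = 3 * (1:20) / fps * 1e3, y = 0)  # 3 m/s in mm
  ts <- track_speeds(tr, fps)
  expect_equal(ts$speeds$speed_mps, rep(3, 20), tolerance = 1e-10)
  expect_equal(unname(ts$summary["mean"]), 3, tolerance = 1e-10)

  shifted <- tr; shifted$frame <- shifted$frame + 500
  ts2 <- track_speeds(shifted, fps)
  expect_equal(ts2$speeds$speed_mps, ts$speeds$speed_mps, tolerance = 1e-12)

  expect_error(track_speeds(rbind(tr, tr[1, ]), fps), "duplicate")
  expect_error(track_speeds(data.frame(point = 1, frame = 1, x = 0, y = 0),
                            fps), "2 frames")
})

test_that("synthetic launch speeds are recovered within sampling error", {
  set.seed(21)
  n <- 40
  true_speed <- pmax(stats::rnorm(n, 5.0, 2.1), 0.3)
  fps <- 15000
  tracks <- do.call(rbind, lapply(seq_len(n), function(i) {
    ang <- stats::runif(1, 0, 2 * pi)
    data.frame(point = i, frame = 1:8,
               x = cos(ang) * true_speed[i] * (1:8) / fps * 1e3,
               y = sin(ang) * true_speed[i] * (1:8) / fps * 1e3)
  }))
  ts <- track_speeds(tracks, fps)
  se <- stats::sd(true_speed) / sqrt(n)
  expect_lt(abs(unname(ts$summary["mean"]) - mean(true_speed)), 2 * se + 1e-9)
})
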
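test_that("time of flight matches closed forms and frozen high-precision values", {
  expect_equal(tof(c(0, 0), c(0, 0), c(0, 30)), 2 * 30 / 1540e3)
  expect_equal(tof(c(-1, 0), c(1, 0), c(0, 1)), 2 * sqrt(2) / 1540e3)
  # frozen 25-digit symbolic evaluations
  expect_equal(tof(c(-3, 0.5), c(7, -0.2), c(2.3, 41)),
               5.344969736070727829056481e-5, tolerance = 1e-14)
  expect_equal(tof(c(0, 0), c(0, 0), c(12.3, 45.6)),
               6.133734749184327419767323e-5, tolerance = 1e-14)
  expect_equal(tof(c(-12, 3), c(15, 2), c(-4, 60)),
               7.700743104110464440923542e-5, tolerance = 1e-14)
})

test_that("time of flight agrees with an independent formulation on random triples", {
  set.seed(1)
  for (i in 1:1000) {
    tx <- runif(2, -50, 50); rx <- runif(2, -50, 50); f <- runif(2, -50, 80)
    # hypot-based independent evaluation
    ref <- (sqrt(sum((f - tx)^2)) + sqrt(sum((f - rx)^2))) / 1.54e6
    expect_equal(tof(tx, rx, f), ref, tolerance = 1e-12)
  }
})

test_that("imaging grid geometry follows the element normals", {
  sp <- probe_spec(K = 16)
  flat <- polyline_shape(rep(0, 15), sp)
  g <- build_grid(flat, c(5, 20), 0.5)
  expect_true(all(g$directions[, 1] == 0) && all(g$directions[, 2] == 1))
  expect_equal(unique(round(diff(g$origins[, 1]), 12)), sp$pitch)

  R <- 70
  arc <- arc_shape(R, sp)
  ga <- build_grid(arc, c(5, 20), 0.5)
  expect_equal(diff(-ga$angles), rep(sp$pitch / R, 15), tolerance = 1e-12)
  # the concave array wraps a convex body: its normals converge toward the
  # arc center, so endpoints at depth u lie on the concentric circle of
  # radius R - u
  ends <- ga$focal[seq(ga$D, ga$L * ga$D, by = ga$D), ]
  d_end <- sqrt(ends[, 1]^2 + (ends[, 2] - R)^2)
  expect_equal(d_end, rep(R - 20, 16), tolerance = 1e-9)
})

test_that("DAS reproduces the delta construction and is linear", {
  sp <- tiny_probe(4L)
  sh <- arc_shape(80, sp)
  g <- build_grid(sh, c(10, 12), 0.5)
  focal <- g$focal[7, ]
  pos <- cbind(sh$x, sh$z)
  N <- 600L
  rf_cube <- array(0, c(4, 4, N))
  for (t in 1:4) for (r in 1:4) {
    tau <- tof(pos[t, ], pos[r, ], focal, sp$c)
    n <- floor(tau * sp$fs + 0.5) + 1    # nearest receive sample, 1-based
    rf_cube[t, r, n] <- 1
  }
  rf <- structure(list(rf = rf_cube, fs = sp$fs, t0 = 0, f0 = sp$f0,
                       transmit = tibble::tibble(event = 1:4, element = 1:4),
                       spec = sp, seed = 0L), class = "rf_data")
  img <- das(rf, sh, g)
  expect_equal(as.numeric(t(img$values))[7], 16)

  zero <- rf; zero$rf[] <- 0
  expect_true(all(das(zero, sh, g)$values == 0))

  rf2 <- rf; rf2$rf <- 2.5 * rf$rf
  expect_equal(das(rf2, sh, g)$values, 2.5 * img$values)
})

test_that("DAS equals a brute-force triple loop with the same tie rule", {
  sp <- tiny_probe(6L)
  sh <- arc_shape(90, sp)
  set.seed(11)
  N <- 256L
  rf_cube <- array(rnorm(6 * 6 * N), c(6, 6, N))
  rf <- structure(list(rf = rf_cube, fs = sp$fs, t0 = 0, f0 = sp$f0,
                       transmit = tibble::tibble(event = 1:6, element = 1:6),
                       spec = sp, seed = 0L), class = "rf_data")
  g <- build_grid(sh, c(3, 9), 1)
  img <- das(rf, sh, g)
  pos <- cbind(sh$x, sh$z)
  brute <- matrix(0, g$L, g$D)
  for (l in 1:g$L) for (d in 1:g$D) {
    fp <- g$focal[(l - 1) * g$D + d, ]
    acc <- 0
    for (t in 1:6) for (r in 1:6) for (n in 1:N) {
      tau <- (sqrt(sum((fp - pos[t, ])^2)) + sqrt(sum((fp - pos[r, ])^2))) /
        (sp$c * 1e3)
      # extraction rule: |n - tau fs| <= 1/2, half-sample tie to the larger n
      if (abs((n - 1) - tau * sp$fs) < 0.5 ||
          ((n - 1) - tau * sp$fs) == 0.5) acc <- acc + rf_cube[t, r, n]
    }
    brute[l, d] <- acc
  }
  expect_identical(img$values, brute)
})

test_that("point-target peak lands within one grid cell across radii and depths", {
  # depths chosen at f-numbers >= ~1.3, where the main lobe dominates the
  # (element-width-attenuated) grating lobes of the 3.2-wavelength pitch
  for (R in c(60, 70, 80, 90, 100)) for (z_t in c(20, 30, 40)) {
    sp <- probe_spec(K = 16)
    sh <- arc_shape(R, sp)
    rf <- simulate_rf(sh, phantom_spec(
      point_targets = data.frame(x = 0, z = z_t, amplitude = 1)), sp,
      seed = 5)
    g <- build_grid(sh, c(z_t - 6, z_t + 6), 0.3)
    img <- das(rf, sh, g)
    pk <- which(img$envelope == max(img$envelope), arr.ind = TRUE)[1, ]
    fp <- g$focal[(pk[1] - 1) * g$D + pk[2], ]
    # within a cell: lateral spacing is the (converged) line pitch at
    # depth, axial one depth step
    expect_lt(abs(fp[2] - z_t), 0.3 + 1e-9)
    expect_lt(abs(fp[1] - 0), sp$pitch * (R - z_t) / R + 1e-9)
  }
})

test_that("half-wavelength shape errors cause signal loss at the point target", {
  ref <- point_rf(K = 16, R = 70, z_t = 25)
  g <- build_grid(ref$shape, c(20, 30), 0.2)
  peak_true <- max(das(ref$rf, ref$shape, g)$envelope)
  p0 <- params_from_shape(ref$shape)
  lambda_half <- half_wavelength(ref$spec)
  set.seed(21)
  for (i in 1:5) {
    repeat {   # draw until the perturbed shape errs by at least lambda/2
      par <- p0 + runif(15, -0.05, 0.05)
      cand <- polyline_shape(par, ref$spec)
      if (shape_mae(ref$shape, cand) >= lambda_half) break
    }
    img_p <- das(ref$rf, cand, build_grid(cand, c(20, 30), 0.2))
    expect_lt(max(img_p$envelope), peak_true)
  }
})

test_that("envelope and display behave like an analytic-signal B-mode chain", {
  # pure sinusoid: interior envelope equals the amplitude
  x <- sin(2 * pi * 0.1 * (0:199))
  env <- Mod(flexbeam:::analytic_signal(x))
  expect_equal(unname(env[30:170]), rep(1, 141), tolerance = 1e-2)

  g <- build_grid(polyline_shape(rep(0, 3), tiny_probe(4L)), c(5, 10), 1)
  img <- structure(list(values = matrix(1, 4, 6),
                        envelope = matrix(1, 4, 6), grid = g),
                   class = "bf_image")
  expect_true(all(envelope_display(img, 60)$display == 0))
  img$envelope <- matrix(c(1, 0.5), 4, 6)
  d <- envelope_display(img, 60)$display
  expect_equal(sort(unique(as.numeric(round(d, 2)))), c(-6.02, 0))

  img$envelope[] <- 0
  expect_true(all(envelope_display(img, 60)$display == -60))
  expect_error(envelope_display(img, -3), class = "flexbeam_input_error")
})

test_that("DAS validates channel-count agreement", {
  ref <- point_rf(K = 8, R = 80)
  sh_bad <- arc_shape(80, probe_spec(K = 6))
  expect_error(das(ref$rf, sh_bad, build_grid(sh_bad, c(10, 20), 1)),
               class = "flexbeam_dim_error")
})
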
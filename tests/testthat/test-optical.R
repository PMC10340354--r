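test_that("in-plane marker projection is an isometry", {
  th <- seq(0.3, 1.1, length.out = 6)
  P <- cbind(80 * cos(th), rep(0, 6), 80 * sin(th))
  mk <- marker_set(P, r_sphere = 6)
  pr <- project_markers(mk)
  d3 <- dist(P); d2 <- dist(cbind(pr$x, pr$z))
  expect_equal(as.numeric(d2), as.numeric(d3), tolerance = 1e-9)
})

test_that("out-of-plane jitter only perturbs the projection by its own scale", {
  th <- seq(-0.3, 0.3, length.out = 7)
  base <- cbind(90 * sin(th), rep(0, 7), 90 * (1 - cos(th)))
  pr0 <- project_markers(marker_set(base, 6))
  set.seed(3)
  eps <- 0.05
  jit <- base; jit[, 2] <- jit[, 2] + runif(7, -eps, eps)
  pr1 <- project_markers(marker_set(jit, 6))
  expect_lt(max(abs(pr1$x - pr0$x)), eps)
  expect_lt(max(abs(pr1$z - pr0$z)), eps)
})

test_that("orientation normalization makes mirrored inputs project identically", {
  th <- c(-0.4, -0.15, 0.05, 0.2, 0.45)   # deliberately asymmetric
  P <- cbind(85 * sin(th), rep(0, 5), 85 * (1 - cos(th)))
  Pm <- P; Pm[, 1] <- -Pm[, 1]            # mirror across the y-z plane
  pr <- project_markers(marker_set(P, 6))
  prm <- project_markers(marker_set(Pm, 6))
  expect_equal(pr$x, prm$x, tolerance = 1e-9)
  expect_equal(pr$z, prm$z, tolerance = 1e-9)
})

test_that("collinear markers raise a degenerate-configuration error", {
  P <- cbind(1:5, rep(0, 5), rep(0, 5))
  expect_error(project_markers(marker_set(P, 6)),
               class = "flexbeam_degenerate_configuration")
  expect_error(fit_circle_pratt(data.frame(x = 1:5, z = 2 * (1:5))),
               class = "flexbeam_degenerate_configuration")
})

test_that("Pratt fit is exact on noiseless circles", {
  th <- seq(0.1, 1.4, length.out = 5)
  f <- fit_circle_pratt(data.frame(x = 2 + 50 * cos(th), z = 3 + 50 * sin(th)))
  expect_equal(f$center, c(2, 3), tolerance = 1e-8)
  expect_equal(f$r_fit, 50, tolerance = 1e-8)
  expect_lt(f$rms_residual, 1e-8)

  # right triangle inscribed in the unit circle
  f2 <- fit_circle_pratt(data.frame(x = c(1, -1, 0), z = c(0, 0, 1)))
  expect_equal(f2$r_fit, 1, tolerance = 1e-10)
  expect_equal(f2$center, c(0, 0), tolerance = 1e-10)

  expect_error(fit_circle_pratt(data.frame(x = 1:2, z = 2:3)),
               class = "flexbeam_input_error")
})

test_that("Pratt fit stays exact across radii and shallow arcs", {
  for (R in c(10, 100, 1e3, 1e4)) {
    th <- seq(-0.15, 0.15, length.out = 9)  # shallow arc (< 5 degrees half)
    pts <- data.frame(x = R * sin(th), z = R * (1 - cos(th)))
    f <- fit_circle_pratt(pts)
    expect_equal(f$r_fit, R, tolerance = 1e-6 * R)
    expect_lt(f$rms_residual, 1e-8 * max(1, R))
  }
})

test_that("Pratt fit on noisy circles agrees with an independent geometric fit", {
  set.seed(9)
  th <- runif(20, 0, 1.6)
  r_noisy <- 70 + rnorm(20, 0, 0.25)
  x <- 5 + r_noisy * cos(th); z <- -3 + r_noisy * sin(th)
  f <- fit_circle_pratt(data.frame(x = x, z = z))
  g <- geo_circle_fit(x, z)
  expect_equal(f$r_fit, g$r, tolerance = 0.02)
  expect_equal(f$center, g$center, tolerance = 0.05)
  # the Pratt objective at the algebraic solution is no worse than at the
  # oracle's geometric solution
  pratt_obj <- function(A, B, R)
    sum(((x - A)^2 + (z - B)^2 - R^2)^2) / R^2
  expect_lte(pratt_obj(f$center[1], f$center[2], f$r_fit),
             pratt_obj(g$center[1], g$center[2], g$r) * (1 + 1e-6))
})

test_that("radius correction subtracts sphere radius and thickness", {
  mk <- marker_set(matrix(rnorm(9), 3), r_sphere = 6)
  fit <- structure(list(r_fit = 100), class = "circle_fit")
  expect_equal(correct_radius(fit, mk, probe_spec()), 92.5)
  mk0 <- marker_set(matrix(rnorm(9), 3), r_sphere = 0)
  expect_equal(correct_radius(fit, mk0, probe_spec(thickness = 0)), 100)
  fit_small <- structure(list(r_fit = 5), class = "circle_fit")
  expect_error(correct_radius(fit_small, mk, probe_spec()),
               class = "flexbeam_invalid_geometry")
})

test_that("noiseless optical pipeline recovers the arc exactly", {
  sp <- probe_spec()
  for (R in c(65, 72.5, 110)) {
    mk <- simulate_markers(R, sp, r_sphere = 6, m = 5, noise_mm = 0, seed = 1)
    sh <- estimate_arc_shape(mk, sp)
    expect_lt(abs(circle_fit(sh)$r_corrected - R), 1e-6)
    expect_lt(shape_mae(sh, arc_shape(R, sp)), 1e-6)
  }
  # minimum-information case: 3 markers
  mk3 <- simulate_markers(72.5, sp, r_sphere = 6, m = 3, noise_mm = 0, seed = 1)
  expect_lt(abs(circle_fit(estimate_arc_shape(mk3, sp))$r_corrected - 72.5),
            1e-6)
})

test_that("optical estimate is invariant to rigid motion of the marker set", {
  sp <- probe_spec()
  mk <- simulate_markers(80, sp, r_sphere = 6, m = 5, noise_mm = 0.2, seed = 4)
  sh0 <- estimate_arc_shape(mk, sp)
  # arbitrary 3D rotation + translation of the tracker frame
  ax <- c(1, 2, 3) / sqrt(14); ang <- 0.7
  Kx <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  Rm <- diag(3) + sin(ang) * Kx + (1 - cos(ang)) * (Kx %*% Kx)
  P <- cbind(mk$x, mk$y, mk$z) %*% t(Rm)
  P <- sweep(P, 2, c(12, -30, 7), "+")
  sh1 <- estimate_arc_shape(marker_set(P, 6), sp)
  expect_lt(shape_mae(sh0, sh1), 1e-6)
})

test_that("radius error degrades monotonically with marker noise", {
  sp <- probe_spec()
  med_err <- sapply(c(0, 0.1, 0.25, 0.5), function(s) {
    errs <- sapply(1:100, function(i) {
      mk <- simulate_markers(72.5, sp, r_sphere = 6, m = 5, noise_mm = s,
                             seed = 1000 + i)
      abs(circle_fit(estimate_arc_shape(mk, sp))$r_corrected - 72.5)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) >= 0))
})

test_that("marker CSV round trip preserves coordinates", {
  mk <- simulate_markers(70, probe_spec(), r_sphere = 6, m = 4,
                         noise_mm = 0.1, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_markers_csv(mk, f)
  mk2 <- read_markers_csv(f, r_sphere = 6)
  expect_equal(mk2$x, mk$x)
  expect_equal(mk2$z, mk$z)
  expect_equal(attr(mk2, "r_sphere"), 6)
})
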
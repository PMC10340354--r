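circle_mask <- function(r_mm, spacing = 0.1, pad = 2, center = c(0, 0),
                        semi = c(r_mm, r_mm)) {
  xs <- seq(-semi[1] - pad, semi[1] + pad, by = spacing) + center[1]
  zs <- seq(-semi[2] - pad, semi[2] + pad, by = spacing) + center[2]
  m <- outer(xs, zs, function(x, z)
    ((x - center[1]) / semi[1])^2 + ((z - center[2]) / semi[2])^2 <= 1)
  seg_mask(m, spacing = spacing)
}

test_that("lateral FWHM matches the Gaussian closed form and is scale-free", {
  spacing <- 0.05
  xs <- seq(-10, 10, by = spacing); zs <- seq(-2, 2, by = spacing)
  sigma <- 1.3
  img <- list(pixels = outer(xs, zs, function(x, z)
                exp(-x^2 / (2 * sigma^2)) * exp(-z^2 / 8)),
              mask = matrix(TRUE, length(xs), length(zs)),
              xs = xs, zs = zs, spacing = spacing)
  class(img) <- "raster_image"
  expect_equal(lateral_fwhm(img), 2 * sqrt(2 * log(2)) * sigma,
               tolerance = 0.01)
  img2 <- img; img2$pixels <- 7 * img2$pixels
  expect_equal(lateral_fwhm(img2), lateral_fwhm(img))

  img3 <- img; img3$pixels <- img3$pixels + 10   # never below half max
  expect_error(lateral_fwhm(img3), class = "flexbeam_undefined_width")
})

test_that("aspect ratio identifies circles and follows axis swaps", {
  expect_equal(aspect_ratio(circle_mask(5)), 1, tolerance = 0.02)
  ell <- circle_mask(6, semi = c(6, 4))
  expect_equal(aspect_ratio(ell), 1.5, tolerance = 0.02)
  rot <- seg_mask(t(ell$mask), spacing = ell$spacing)
  expect_equal(aspect_ratio(rot), 1 / aspect_ratio(ell), tolerance = 1e-9)
  expect_error(aspect_ratio(seg_mask(matrix(FALSE, 3, 3))),
               class = "flexbeam_input_error")
})

test_that("Dice and Jaccard match closed forms and their mutual identity", {
  a <- seg_mask(matrix(rep(c(TRUE, FALSE), each = 100), 10), spacing = 1)
  expect_equal(as.numeric(dice_jaccard(a, a)), c(1, 1))
  b <- seg_mask(matrix(rep(c(FALSE, TRUE), each = 100), 10), spacing = 1)
  expect_equal(as.numeric(dice_jaccard(a, b)), c(0, 0))

  # |X| = |Y| = 100, overlap 50
  m1 <- matrix(FALSE, 20, 20); m1[1:10, 1:10] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[6:15, 1:10] <- TRUE
  dj <- dice_jaccard(seg_mask(m1, 1), seg_mask(m2, 1))
  expect_equal(dj$dice, 0.5)
  expect_equal(dj$jaccard, 1 / 3)

  set.seed(5)
  for (i in 1:20) {
    ra <- seg_mask(matrix(runif(400) < 0.3, 20), 1)
    rb <- seg_mask(matrix(runif(400) < 0.3, 20), 1)
    if (sum(ra$mask) + sum(rb$mask) == 0) next
    dj <- dice_jaccard(ra, rb)
    expect_equal(dj$jaccard, dj$dice / (2 - dj$dice), tolerance = 1e-12)
  }
  expect_error(dice_jaccard(seg_mask(matrix(FALSE, 2, 2), 1),
                            seg_mask(matrix(FALSE, 2, 2), 1)),
               class = "flexbeam_input_error")
})

test_that("Hausdorff distance matches an all-pairs brute force", {
  p1 <- matrix(FALSE, 15, 15); p1[3, 4] <- TRUE
  p2 <- matrix(FALSE, 15, 15); p2[3, 12] <- TRUE
  expect_equal(hausdorff(seg_mask(p1, 0.5), seg_mask(p2, 0.5)), 4)  # 8 px * 0.5
  a <- circle_mask(3, spacing = 0.5)
  expect_equal(hausdorff(a, a), 0)

  set.seed(6)
  for (i in 1:10) {
    ma <- seg_mask(matrix(runif(225) < 0.2, 15), spacing = 0.7)
    mb <- seg_mask(matrix(runif(225) < 0.2, 15), spacing = 0.7)
    if (!any(ma$mask) || !any(mb$mask)) next
    # oracle over *all* foreground pixels (boundary subset gives the same
    # max-min for finite unions of pixels)
    wa <- which(ma$mask, arr.ind = TRUE); wb <- which(mb$mask, arr.ind = TRUE)
    d2 <- outer(wa[, 1], wb[, 1], "-")^2 + outer(wa[, 2], wb[, 2], "-")^2
    h_ab <- sqrt(max(apply(d2, 1, min))) * 0.7
    h_ba <- sqrt(max(apply(d2, 2, min))) * 0.7
    expect_equal(hausdorff(ma, mb, directed = TRUE), h_ab)
    expect_equal(hausdorff(ma, mb), max(h_ab, h_ba))
    expect_gte(hausdorff(ma, mb), hausdorff(ma, mb, directed = TRUE))
  }
})

test_that("CNR matches direct evaluation and flags degenerate inputs", {
  inner <- matrix(FALSE, 20, 20); inner[5:8, 5:8] <- TRUE
  outer_m <- matrix(FALSE, 20, 20); outer_m[12:18, 12:18] <- TRUE
  rp <- region_pair(seg_mask(inner, 1), seg_mask(outer_m, 1))
  img <- matrix(0, 20, 20)
  set.seed(2)
  img[inner] <- rnorm(sum(inner), 1, 0.5)
  img[outer_m] <- rnorm(sum(outer_m), 2, 0.5)
  v_in <- img[inner]; v_out <- img[outer_m]
  expect_equal(cnr(rp, img),
               20 * log10(abs(mean(v_out) - mean(v_in)) /
                          sqrt(sd(v_out)^2 + sd(v_in)^2)))
  # swap symmetry
  rp_sw <- region_pair(seg_mask(outer_m, 1), seg_mask(inner, 1))
  expect_equal(cnr(rp_sw, img), cnr(rp, img))
  # sentinels
  img2 <- matrix(1, 20, 20)
  expect_identical(cnr(rp, img2), -Inf)
  img3 <- img2; img3[inner] <- 0
  expect_identical(cnr(rp, img3), Inf)
  expect_error(region_pair(seg_mask(inner, 1), seg_mask(inner, 1)),
               class = "flexbeam_input_error")
})

test_that("GCNR spans identical (0) to disjoint (1) distributions", {
  n <- 120   # large regions keep the 256-bin histogram estimate dense
  inner <- matrix(FALSE, n, n); inner[1:40, ] <- TRUE
  outer_m <- matrix(FALSE, n, n); outer_m[81:n, ] <- TRUE
  rp <- region_pair(seg_mask(inner, 1), seg_mask(outer_m, 1))
  npx <- sum(inner)
  # identical value populations in both regions
  img_same <- matrix(0, n, n)
  img_same[inner] <- rep(1:10, npx / 10); img_same[outer_m] <- rep(1:10, npx / 10)
  expect_equal(gcnr(rp, img_same), 0)
  img_sep <- matrix(0, n, n)
  set.seed(3)
  img_sep[inner] <- runif(npx, 0, 1); img_sep[outer_m] <- runif(npx, 2, 3)
  expect_equal(gcnr(rp, img_sep), 1)
  # half-overlapping uniforms -> 0.5
  img_half <- matrix(0, n, n)
  img_half[inner] <- seq(0, 1, length.out = npx)
  img_half[outer_m] <- seq(0.5, 1.5, length.out = npx)
  expect_equal(gcnr(rp, img_half), 0.5, tolerance = 0.02)
})

test_that("GCNR is invariant under monotone intensity maps", {
  n <- 120
  inner <- matrix(FALSE, n, n); inner[1:40, ] <- TRUE
  outer_m <- matrix(FALSE, n, n); outer_m[81:n, ] <- TRUE
  rp <- region_pair(seg_mask(inner, 1), seg_mask(outer_m, 1))
  set.seed(4)
  # partially overlapping uniforms: true GCNR well away from 0
  img <- matrix(0, n, n)
  img[rp$inner$mask] <- runif(sum(rp$inner$mask), 0.1, 1.1)
  img[rp$outer$mask] <- runif(sum(rp$outer$mask), 0.8, 2.0)
  # equal-width binning makes the rank invariance exact only in the
  # continuum; 64 bins over ~4800 samples keeps the estimate dense
  g0 <- gcnr(rp, img, n_bins = 64L)
  expect_gt(g0, 0.5)
  for (gam in c(0.5, 2, 3)) {
    expect_equal(gcnr(rp, img^gam, n_bins = 64L), g0, tolerance = 0.03)
  }
})

test_that("rigid registration recovers translations and never hurts Dice", {
  base <- matrix(FALSE, 40, 40); base[10:20, 8:26] <- TRUE   # anisotropic
  fixed <- seg_mask(base, spacing = 0.5)
  moved <- matrix(FALSE, 40, 40); moved[18:28, 4:22] <- TRUE  # shift (8, -4)
  reg <- rigid_register(seg_mask(moved, 0.5), fixed)
  expect_equal(reg$shift_mm, c(-8, 4) * 0.5, tolerance = 1e-9)
  expect_gte(reg$dice_after, 0.99)

  # identity case
  reg_id <- rigid_register(fixed, fixed)
  expect_equal(reg_id$theta_rad, 0)
  expect_equal(reg_id$dice_after, 1)

  # rotation case: Dice can only improve
  w <- which(base, arr.ind = TRUE)
  th <- 15 * pi / 180
  ctr <- colMeans(w)
  rot <- unique(round(cbind(
    cos(th) * (w[, 1] - ctr[1]) - sin(th) * (w[, 2] - ctr[2]) + ctr[1],
    sin(th) * (w[, 1] - ctr[1]) + cos(th) * (w[, 2] - ctr[2]) + ctr[2])))
  rot <- rot[rot[, 1] >= 1 & rot[, 1] <= 40 & rot[, 2] >= 1 & rot[, 2] <= 40, ]
  mrot <- matrix(FALSE, 40, 40); mrot[rot] <- TRUE
  reg_rot <- rigid_register(seg_mask(mrot, 0.5), fixed)
  expect_gte(reg_rot$dice_after, reg_rot$dice_before)
})

test_that("evaluation report bundles the segmentation metrics", {
  a <- circle_mask(4, spacing = 0.2)
  rep <- evaluate_segmentation(a, a)
  expect_equal(rep$value[rep$metric == "dice"], 1)
  expect_equal(rep$value[rep$metric == "hausdorff"], 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_report_csv(rep, f)
  expect_equal(read.csv(f)$metric, rep$metric)
})
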
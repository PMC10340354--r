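#' Binary segmentation mask on a raster grid
#'
#' @param mask Logical (or 0/1) matrix, `mask[i, j]` at
#'   `origin + (i - 1, j - 1) * spacing` (x lateral, z axial).
#' @param spacing Pixel size, mm.
#' @param origin World coordinate of pixel (1, 1), mm.
#' @return Object of class `seg_mask`.
#' @export
seg_mask <- function(mask, spacing = 1, origin = c(0, 0)) {
  mask <- mask != 0
  if (spacing <= 0) stop_flexbeam("spacing must be positive", "input_error")
  structure(list(mask = mask, spacing = spacing, origin = origin),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %d x %d px at %.3g mm, %d foreground px\n",
              nrow(x$mask), ncol(x$mask), x$spacing, sum(x$mask)))
  invisible(x)
}

check_same_grid <- function(x, y) {
  if (!all(dim(x$mask) == dim(y$mask)) || x$spacing != y$spacing)
    stop_flexbeam("masks are not on the same grid", "dim_error")
}

#' Disjoint inner/outer region pair for contrast metrics
#'
#' @param inner,outer [seg_mask()] objects on the same grid; must be
#'   disjoint and non-empty.
#' @return Object of class `region_pair`.
#' @export
region_pair <- function(inner, outer) {
  check_same_grid(inner, outer)
  if (!any(inner$mask) || !any(outer$mask))
    stop_flexbeam("both regions must be non-empty", "input_error")
  if (any(inner$mask & outer$mask))
    stop_flexbeam("inner and outer regions overlap", "input_error")
  structure(list(inner = inner, outer = outer), class = "region_pair")
}

region_values <- function(regions, image) {
  px <- if (inherits(image, "raster_image")) image$pixels else image
  if (!all(dim(px) == dim(regions$inner$mask)))
    stop_flexbeam("image and region grids differ", "dim_error")
  list(inner = px[regions$inner$mask], outer = px[regions$outer$mask])
}

#' Lateral full width at half maximum of a point target
#'
#' Extracts the lateral (constant-depth) profile of the linear envelope
#' through the peak, finds the two half-maximum crossings on either side by
#' linear interpolation, and returns their separation. Scale-invariant (the
#' half level is relative to the peak).
#'
#' @param image A [scan_convert()] raster of the envelope.
#' @param peak Optional (x, z) peak position, mm; default the brightest
#'   in-region pixel.
#' @return FWHM, mm.
#' @export
lateral_fwhm <- function(image, peak = NULL) {
  px <- image$pixels
  if (is.null(peak)) {
    idx <- which(px == max(px, na.rm = TRUE), arr.ind = TRUE)[1, ]
  } else {
    idx <- c(which.min(abs(image$xs - peak[1])),
             which.min(abs(image$zs - peak[2])))
  }
  prof <- px[, idx[2]]
  pk <- idx[1]
  if (is.na(prof[pk])) stop_flexbeam("peak is outside the mask", "input_error")
  half <- prof[pk] / 2
  xs <- image$xs
  cross_at <- function(ii) {  # ii: indices walking away from the peak
    for (j in seq_along(ii)[-1]) {
      a <- ii[j - 1]; b <- ii[j]
      if (is.na(prof[b])) break
      if (prof[b] < half) {
        w <- (prof[a] - half) / (prof[a] - prof[b])
        return(xs[a] + w * (xs[b] - xs[a]))
      }
    }
    NA_real_
  }
  xr <- cross_at(pk:length(prof))
  xl <- cross_at(pk:1)
  if (is.na(xl) || is.na(xr))
    stop_flexbeam("profile never falls below half maximum", "undefined_width")
  abs(xr - xl)
}

#' Aspect ratio of a segmented inclusion
#'
#' Lateral extent divided by axial extent, both measured as the full widths
#' of the mask's bounding intervals. An undistorted circle has aspect ratio
#' 1.
#'
#' @param mask A non-empty [seg_mask()].
#' @return Dimensionless ratio.
#' @export
aspect_ratio <- function(mask) {
  w <- which(mask$mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop_flexbeam("mask is empty", "input_error")
  lat <- (diff(range(w[, 1])) + 1) * mask$spacing
  axi <- (diff(range(w[, 2])) + 1) * mask$spacing
  lat / axi
}

#' Dice and Jaccard overlap coefficients
#'
#' `DSC = 2|X n Y| / (|X| + |Y|)`, `J = |X n Y| / |X u Y|`; both in
#' `[0, 1]` with the identity `J = DSC / (2 - DSC)`.
#'
#' @param x,y [seg_mask()] objects on the same grid, not both empty.
#' @return Tibble with columns `dice`, `jaccard`.
#' @export
dice_jaccard <- function(x, y) {
  check_same_grid(x, y)
  nx <- sum(x$mask); ny <- sum(y$mask)
  if (nx + ny == 0)
    stop_flexbeam("Dice/Jaccard undefined for two empty masks", "input_error")
  inter <- sum(x$mask & y$mask)
  tibble::tibble(dice = 2 * inter / (nx + ny),
                 jaccard = inter / (nx + ny - inter))
}

mask_boundary <- function(m) {
  # foreground pixels with any 8-neighbor outside the mask (image border
  # counts as outside)
  nr <- nrow(m$mask); nc <- ncol(m$mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m$mask
  interior <- matrix(TRUE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    interior <- interior & pad[(2:(nr + 1)) + di, (2:(nc + 1)) + dj]
  }
  which(m$mask & !interior, arr.ind = TRUE)
}

#' Hausdorff distance between segmentations
#'
#' Maximal boundary mismatch: the directed form is
#' `h(X, Y) = max_x min_y d(x, y)` over boundary pixels; the default
#' symmetric form is `max(h(X, Y), h(Y, X))`. Distances are Euclidean in mm
#' (grid spacing applied).
#'
#' @param x,y Non-empty [seg_mask()] objects on the same grid.
#' @param directed If `TRUE`, return the directed distance from `x` to `y`.
#' @return Distance, mm.
#' @export
hausdorff <- function(x, y, directed = FALSE) {
  check_same_grid(x, y)
  bx <- mask_boundary(x); by <- mask_boundary(y)
  if (nrow(bx) == 0 || nrow(by) == 0)
    stop_flexbeam("Hausdorff distance needs non-empty masks", "input_error")
  d2 <- outer(bx[, 1], by[, 1], "-")^2 + outer(bx[, 2], by[, 2], "-")^2
  h_xy <- sqrt(max(apply(d2, 1, min)))
  if (directed) return(h_xy * x$spacing)
  h_yx <- sqrt(max(apply(d2, 2, min)))
  max(h_xy, h_yx) * x$spacing
}

#' Contrast-to-noise ratio
#'
#' `CNR = 20 log10(|mu_out - mu_in| / sqrt(sigma_out^2 + sigma_in^2))` in
#' dB, computed on the supplied pixel values (by convention the linear
#' envelope). Equal means yield `-Inf`; zero pooled deviation with distinct
#' means yields `+Inf` (documented sentinels).
#'
#' @param regions A [region_pair()].
#' @param image A `raster_image` or matrix on the same grid.
#' @return CNR, dB.
#' @export
cnr <- function(regions, image) {
  v <- region_values(regions, image)
  if (length(v$inner) < 2 || length(v$outer) < 2)
    stop_flexbeam("both regions need >= 2 pixels", "input_error")
  num <- abs(mean(v$outer) - mean(v$inner))
  den <- sqrt(sd(v$outer)^2 + sd(v$inner)^2)
  if (num == 0) return(-Inf)
  if (den == 0) return(Inf)
  20 * log10(num / den)
}

#' Generalized contrast-to-noise ratio
#'
#' `GCNR = 1 - integral of min(p_in, p_out)`: one minus the overlap of the
#' two regions' pixel-intensity distributions, estimated with shared
#' equal-width histogram bins spanning the pooled value range. 0 means the
#' distributions coincide; 1 means they are fully separable. Invariant
#' under strictly monotone intensity maps (up to binning).
#'
#' @param regions A [region_pair()].
#' @param image A `raster_image` or matrix on the same grid.
#' @param n_bins Shared histogram bins (default 256).
#' @return GCNR in `[0, 1]`.
#' @export
gcnr <- function(regions, image, n_bins = 256L) {
  v <- region_values(regions, image)
  rng <- range(c(v$inner, v$outer))
  if (diff(rng) == 0) return(0)
  brk <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  pin <- tabulate(findInterval(v$inner, brk, rightmost.closed = TRUE),
                  n_bins) / length(v$inner)
  pout <- tabulate(findInterval(v$outer, brk, rightmost.closed = TRUE),
                   n_bins) / length(v$outer)
  1 - sum(pmin(pin, pout))
}

mask_centroid <- function(m) {
  w <- which(m$mask, arr.ind = TRUE)
  colMeans(w)
}

principal_angle <- function(m) {
  w <- which(m$mask, arr.ind = TRUE)
  wc <- sweep(w, 2, colMeans(w))
  ev <- eigen(crossprod(wc) / nrow(wc), symmetric = TRUE)
  if (ev$values[1] - ev$values[2] < 1e-9 * max(ev$values[1], 1))
    return(NULL)  # isotropic: orientation undefined
  atan2(ev$vectors[2, 1], ev$vectors[1, 1])
}

transform_mask <- function(moving, fixed, theta, shift) {
  # nearest-neighbor resample of `moving` onto the fixed grid under
  # rotation `theta` about the moving centroid followed by `shift` (pixels)
  cm <- mask_centroid(moving)
  nr <- nrow(fixed$mask); nc <- ncol(fixed$mask)
  g <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  # inverse map: fixed pixel -> moving frame
  di <- g$i - (cm[1] + shift[1]); dj <- g$j - (cm[2] + shift[2])
  si <- cos(-theta) * di - sin(-theta) * dj + cm[1]
  sj <- sin(-theta) * di + cos(-theta) * dj + cm[2]
  ri <- round(si); rj <- round(sj)
  ok <- ri >= 1 & ri <= nrow(moving$mask) & rj >= 1 & rj <= ncol(moving$mask)
  out <- rep(FALSE, nrow(g))
  out[ok] <- moving$mask[cbind(ri[ok], rj[ok])]
  seg_mask(matrix(out, nr, nc), spacing = fixed$spacing,
           origin = fixed$origin)
}

#' Rigid pre-registration of segmentations
#'
#' Removes the translational and rotational difference between two
#' segmentations before overlap metrics are computed: centroids are
#' aligned, and the principal second-moment axes define the rotation (the
#' 180-degree ambiguity, and a translation-only fallback for isotropic
#' masks, are resolved by maximizing the Dice overlap; the identity is also
#' a candidate, so registration never reduces Dice).
#'
#' @param moving,fixed Non-empty [seg_mask()] objects on the same grid.
#' @return List with `mask` (the registered moving mask), `theta_rad`,
#'   `shift_mm` (applied translation), `dice_before`, `dice_after`.
#' @export
rigid_register <- function(moving, fixed) {
  check_same_grid(moving, fixed)
  if (!any(moving$mask) || !any(fixed$mask))
    stop_flexbeam("both masks must be non-empty", "input_error")
  shift <- mask_centroid(fixed) - mask_centroid(moving)
  a_f <- principal_angle(fixed); a_m <- principal_angle(moving)
  thetas <- 0
  if (!is.null(a_f) && !is.null(a_m))
    thetas <- c(0, a_f - a_m, a_f - a_m + pi)
  cands <- c(list(list(theta = 0, shift = c(0, 0))),
             lapply(thetas, function(th) list(theta = th, shift = shift)))
  scored <- lapply(cands, function(cd) {
    m2 <- transform_mask(moving, fixed, cd$theta, cd$shift)
    list(cd = cd, mask = m2, dice = dice_jaccard(m2, fixed)$dice)
  })
  best <- scored[[which.max(vapply(scored, `[[`, numeric(1), "dice"))]]
  list(mask = best$mask,
       theta_rad = best$cd$theta,
       shift_mm = unname(best$cd$shift * fixed$spacing),
       dice_before = dice_jaccard(moving, fixed)$dice,
       dice_after = best$dice)
}

#' Segmentation and contrast evaluation report
#'
#' Convenience wrapper producing the full metric table for one
#' reconstructed image against ground truth: Dice, Jaccard and Hausdorff
#' after rigid registration, plus CNR and GCNR from a region pair.
#'
#' @param result,truth [seg_mask()] objects (result is registered to
#'   truth).
#' @param regions Optional [region_pair()] for CNR/GCNR.
#' @param image Image for the contrast metrics (required with `regions`).
#' @return Tibble with columns `metric`, `value`, `units`.
#' @export
evaluate_segmentation <- function(result, truth, regions = NULL,
                                  image = NULL) {
  reg <- rigid_register(result, truth)
  dj <- dice_jaccard(reg$mask, truth)
  out <- tibble::tibble(
    metric = c("dice", "jaccard", "hausdorff", "aspect_ratio"),
    value = c(dj$dice, dj$jaccard, hausdorff(reg$mask, truth),
              aspect_ratio(result)),
    units = c("", "", "mm", ""))
  if (!is.null(regions)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      metric = c("cnr", "gcnr"),
      value = c(cnr(regions, image), gcnr(regions, image)),
      units = c("dB", "")))
  }
  out
}

#' @rdname evaluate_segmentation
#' @param report A metric tibble.
#' @param path File path.
#' @export
write_report_csv <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
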
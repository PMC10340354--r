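#' Synthetic phantom specification
#'
#' Describes the scattering medium for the RF simulator: isolated point
#' targets, a diffuse speckle background of randomly placed scatterers, and
#' elliptical inclusions that rescale the speckle amplitude inside them
#' (multiplier 0 = anechoic cyst, > 1 = hyperechoic).
#'
#' @param point_targets Data frame with columns `x`, `z` (mm) and
#'   `amplitude`, or `NULL`.
#' @param speckle `NULL`, or a list with `xlim`, `zlim` (mm, length-2 each),
#'   `density` (scatterers per mm^2) and optionally `amplitude` (sd of the
#'   Gaussian scatterer strength, default 1).
#' @param inclusions Data frame with columns `x`, `z` (center, mm),
#'   `semi_lateral`, `semi_axial` (semi-axes, mm), `multiplier`, or `NULL`.
#' @return Object of class `phantom_spec`.
#' @examples
#' phantom_spec(point_targets = data.frame(x = 0, z = 30, amplitude = 1))
#' @export
phantom_spec <- function(point_targets = NULL, speckle = NULL,
                         inclusions = NULL) {
  if (!is.null(point_targets)) {
    point_targets <- tibble::as_tibble(point_targets)
    if (!all(c("x", "z", "amplitude") %in% names(point_targets)))
      stop_flexbeam("point_targets needs columns x, z, amplitude", "input_error")
  }
  if (!is.null(speckle)) {
    if (!all(c("xlim", "zlim", "density") %in% names(speckle)))
      stop_flexbeam("speckle needs xlim, zlim, density", "input_error")
    if (speckle$density < 0)
      stop_flexbeam("speckle density must be >= 0", "input_error")
    if (is.null(speckle$amplitude)) speckle$amplitude <- 1
  }
  if (!is.null(inclusions)) {
    inclusions <- tibble::as_tibble(inclusions)
    need <- c("x", "z", "semi_lateral", "semi_axial", "multiplier")
    if (!all(need %in% names(inclusions)))
      stop_flexbeam(paste("inclusions needs columns",
                          paste(need, collapse = ", ")), "input_error")
    if (any(inclusions$semi_lateral <= 0 | inclusions$semi_axial <= 0))
      stop_flexbeam("inclusion semi-axes must be positive", "input_error")
    if (any(inclusions$multiplier < 0))
      stop_flexbeam("inclusion multipliers must be >= 0", "input_error")
  }
  if (is.null(point_targets) && is.null(speckle))
    stop_flexbeam("phantom is empty: give point targets and/or speckle",
                  "input_error")
  structure(list(point_targets = point_targets, speckle = speckle,
                 inclusions = inclusions), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  np <- if (is.null(x$point_targets)) 0L else nrow(x$point_targets)
  ni <- if (is.null(x$inclusions)) 0L else nrow(x$inclusions)
  cat(sprintf("<phantom_spec> %d point target(s), %s speckle, %d inclusion(s)\n",
              np, if (is.null(x$speckle)) "no" else
                sprintf("%.3g/mm^2", x$speckle$density), ni))
  invisible(x)
}

# Draw the concrete scatterer population (positions + amplitudes) for a
# phantom. Deterministic under the supplied seed.
phantom_scatterers <- function(phantom, seed) {
  set.seed(seed)
  sc <- NULL
  sp <- phantom$speckle
  if (!is.null(sp) && sp$density > 0) {
    area <- diff(sp$xlim) * diff(sp$zlim)
    n <- max(0L, round(sp$density * area))
    if (n > 0) {
      sc <- cbind(runif(n, sp$xlim[1], sp$xlim[2]),
                  runif(n, sp$zlim[1], sp$zlim[2]),
                  rnorm(n, 0, sp$amplitude))
      if (!is.null(phantom$inclusions)) {
        for (i in seq_len(nrow(phantom$inclusions))) {
          inc <- phantom$inclusions[i, ]
          inside <- ((sc[, 1] - inc$x) / inc$semi_lateral)^2 +
                    ((sc[, 2] - inc$z) / inc$semi_axial)^2 <= 1
          sc[inside, 3] <- sc[inside, 3] * inc$multiplier
        }
      }
    }
  }
  if (!is.null(phantom$point_targets)) {
    pt <- phantom$point_targets
    sc <- rbind(sc, cbind(pt$x, pt$z, pt$amplitude))
  }
  sc
}

#' Rasterize phantom inclusions to binary ground-truth masks
#'
#' Supplies the ground-truth segmentations for the image-quality metrics: a
#' pixel belongs to a mask iff its center satisfies the inclusion's ellipse
#' inequality.
#'
#' @param phantom A [phantom_spec()] with at least one inclusion.
#' @param xlim,zlim Raster extents, mm.
#' @param spacing Pixel size, mm.
#' @return List of [seg_mask()] objects, one per inclusion.
#' @export
ground_truth_masks <- function(phantom, xlim, zlim, spacing) {
  if (is.null(phantom$inclusions) || nrow(phantom$inclusions) == 0)
    stop_flexbeam("phantom has no inclusions", "input_error")
  xs <- seq(xlim[1], xlim[2], by = spacing)
  zs <- seq(zlim[1], zlim[2], by = spacing)
  lapply(seq_len(nrow(phantom$inclusions)), function(i) {
    inc <- phantom$inclusions[i, ]
    m <- outer(xs, zs, function(px, pz)
      ((px - inc$x) / inc$semi_lateral)^2 +
      ((pz - inc$z) / inc$semi_axial)^2 <= 1)
    seg_mask(m, spacing = spacing, origin = c(xlim[1], zlim[1]))
  })
}
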
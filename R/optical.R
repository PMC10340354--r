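#' Optical marker set
#'
#' Passive marker spheres are mounted on the back of the flexible probe and
#' localized in 3D by an infrared optical tracker. The tracker reports the
#' sphere *centers*; the sphere radius is needed later to correct the fitted
#' circle radius down to the array surface.
#'
#' @param coords Numeric M x 3 matrix or data frame of marker center
#'   coordinates (mm) in the tracker frame, M >= 3.
#' @param r_sphere Marker sphere radius, mm.
#' @return A tibble of class `marker_set` with columns `marker`, `x`, `y`,
#'   `z` and an `r_sphere` attribute.
#' @export
marker_set <- function(coords, r_sphere) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop_flexbeam("marker coordinates must be M x 3", "input_error")
  if (nrow(coords) < 3L)
    stop_flexbeam("at least 3 markers are required", "input_error")
  if (any(!is.finite(coords)))
    stop_flexbeam("marker coordinates must be finite", "input_error")
  if (!is.finite(r_sphere) || r_sphere < 0)
    stop_flexbeam("r_sphere must be a non-negative number", "input_error")
  out <- tibble::tibble(marker = seq_len(nrow(coords)),
                        x = coords[, 1], y = coords[, 2], z = coords[, 3])
  attr(out, "r_sphere") <- r_sphere
  class(out) <- c("marker_set", class(out))
  out
}

marker_r_sphere <- function(markers) {
  r <- attr(markers, "r_sphere")
  if (is.null(r)) stop_flexbeam("marker set has no r_sphere", "input_error")
  r
}

#' Project 3D marker coordinates onto the array plane
#'
#' The markers are nominally coplanar with the array (y = 0) but manual
#' mounting introduces out-of-plane error, so the in-plane coordinates are
#' recovered by principal component analysis: the first two principal
#' components of the centered coordinates become the (x, z) axes. The sign
#' ambiguity of the components is resolved deterministically: x runs from
#' the first to the last marker, and z is flipped if needed so the circle
#' fitted through the projected points has its center at positive z (array
#' concave toward the imaging region).
#'
#' @param markers A [marker_set()].
#' @return Tibble with columns `x`, `z` (mm), one row per marker, in input
#'   order.
#' @export
project_markers <- function(markers) {
  P <- cbind(markers$x, markers$y, markers$z)
  pc <- prcomp(P, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 1e-9 * max(pc$sdev[1], 1e-12))
    stop_flexbeam("markers are collinear; circle fit is impossible",
                  "degenerate_configuration")
  S <- pc$x[, 1:2, drop = FALSE]
  if (S[1, 1] > S[nrow(S), 1]) S[, 1] <- -S[, 1]
  fit <- fit_circle_pratt(tibble::tibble(x = S[, 1], z = S[, 2]))
  if (fit$center[2] < 0) S[, 2] <- -S[, 2]
  tibble::tibble(x = S[, 1], z = S[, 2])
}

#' Pratt least-squares circle fit
#'
#' Algebraic circle fit minimizing the Pratt-normalized objective
#' `sum(((X - A)^2 + (Z - B)^2 - R^2)^2) / R^2`: the circle is represented
#' as `a(x^2 + z^2) + b x + c z + d = 0` with the normalization
#' `b^2 + c^2 - 4 a d = 1`, and the coefficient vector is the generalized
#' eigenvector of the design moment matrix with the smallest non-negative
#' eigenvalue. Exact on noiseless circular data; no iterative refinement.
#' Data are centroid-centered and scaled internally for conditioning, which
#' also keeps the solution stable for shallow arcs.
#'
#' @param points Data frame or matrix with columns `x`, `z` (mm), >= 3
#'   non-collinear points.
#' @return Object of class `circle_fit`: list with `center` (A, B in mm),
#'   `r_fit` (mm), `rms_residual` (mm), `n` (point count) and `r_corrected`
#'   (`NA` until [correct_radius()] fills it).
#' @examples
#' th <- seq(0.2, 1.2, length.out = 8)
#' fit_circle_pratt(data.frame(x = 2 + 50 * cos(th), z = 3 + 50 * sin(th)))
#' @export
fit_circle_pratt <- function(points) {
  pts <- as.matrix(as.data.frame(points)[, c("x", "z")])
  if (nrow(pts) < 3L)
    stop_flexbeam("circle fit needs at least 3 points", "input_error")
  ctr <- colMeans(pts)
  Q <- sweep(pts, 2, ctr)
  scl <- sqrt(mean(rowSums(Q^2)))
  if (scl < 1e-12)
    stop_flexbeam("markers are coincident", "degenerate_configuration")
  Q <- Q / scl
  # collinearity check on the centered, scaled data
  sv <- svd(Q, nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * sv[1])
    stop_flexbeam("points are collinear; circle fit is impossible",
                  "degenerate_configuration")
  zsq <- rowSums(Q^2)
  Zm <- cbind(zsq, Q[, 1], Q[, 2], 1)
  M <- crossprod(Zm) / nrow(Q)
  B <- matrix(c(0, 0, 0, -2,
                0, 1, 0, 0,
                0, 0, 1, 0,
                -2, 0, 0, 0), 4, 4, byrow = TRUE)
  eg <- eigen(solve(B, M))
  ev <- Re(eg$values)
  # eigenvalues are real for this pencil; smallest non-negative one is Pratt's
  ok <- which(ev > -1e-9)
  i <- ok[which.min(ev[ok])]
  v <- Re(eg$vectors[, i])
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  if (abs(a) < 1e-14)
    stop_flexbeam("degenerate (near-line) circle fit", "degenerate_configuration")
  cx <- -b / (2 * a); cz <- -cc / (2 * a)
  r <- sqrt(max(b^2 + cc^2 - 4 * a * d, 0)) / (2 * abs(a))
  center <- c(cx, cz) * scl + ctr
  r <- r * scl
  resid <- sqrt(rowSums(sweep(pts, 2, center)^2)) - r
  structure(list(center = unname(center), r_fit = r,
                 r_corrected = NA_real_,
                 rms_residual = sqrt(mean(resid^2)), n = nrow(pts)),
            class = "circle_fit")
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("<circle_fit> center (%.3f, %.3f) mm, r_fit %.4f mm",
              x$center[1], x$center[2], x$r_fit))
  if (!is.na(x$r_corrected)) cat(sprintf(", r_corrected %.4f mm", x$r_corrected))
  cat(sprintf(", rms residual %.3g mm, n = %d\n", x$rms_residual, x$n))
  invisible(x)
}

#' @export
tidy.circle_fit <- function(x, ...) {
  tibble::tibble(center_x = x$center[1], center_z = x$center[2],
                 r_fit = x$r_fit, r_corrected = x$r_corrected,
                 rms_residual = x$rms_residual, n_points = x$n)
}

#' Correct the fitted circle radius down to the array surface
#'
#' The optical tracker reports sphere centers, which sit one sphere radius
#' plus one transducer thickness outside the element surface, so the array
#' radius is `r_fit - r_sphere - thickness`.
#'
#' @param fit A [fit_circle_pratt()] result.
#' @param markers The [marker_set()] (supplies `r_sphere`).
#' @param spec A [probe_spec()] (supplies `thickness`).
#' @return The corrected array radius, mm.
#' @examples
#' f <- fit_circle_pratt(data.frame(x = 100 * cos(1:5 / 5), z = 100 * sin(1:5 / 5)))
#' m <- marker_set(matrix(rnorm(9), 3), r_sphere = 6)
#' correct_radius(f, m, probe_spec())  # 100 - 6 - 1.5 = 92.5
#' @export
correct_radius <- function(fit, markers, spec = probe_spec()) {
  r_s <- marker_r_sphere(markers)
  r <- fit$r_fit - r_s - spec$thickness
  if (!is.finite(r) || r <= 0)
    stop_flexbeam(sprintf(
      "corrected radius %.3g mm is not positive (r_fit = %.3g, r_sphere = %.3g, thickness = %.3g)",
      r, fit$r_fit, r_s, spec$thickness), "invalid_geometry")
  r
}

#' Optical-marker array shape estimate (full pipeline)
#'
#' Projects the 3D marker coordinates onto the array plane by PCA, fits a
#' circle through them with the Pratt least-squares fit, corrects the radius
#' from sphere centers down to the element surface, and returns the
#' circular-arc shape of that radius. The fit diagnostics (including the
#' corrected radius) are attached as the `circle_fit` attribute, retrievable
#' with [circle_fit()].
#'
#' @param markers A [marker_set()].
#' @param spec A [probe_spec()].
#' @return A `flex_shape` tibble (arc model) with a `circle_fit` attribute.
#' @examples
#' m <- simulate_markers(R = 72.5, probe_spec(), r_sphere = 6, m = 5,
#'                       noise_mm = 0, seed = 1)
#' sh <- estimate_arc_shape(m, probe_spec())
#' circle_fit(sh)$r_corrected
#' @export
estimate_arc_shape <- function(markers, spec = probe_spec()) {
  pts <- project_markers(markers)
  fit <- fit_circle_pratt(pts)
  fit$r_corrected <- correct_radius(fit, markers, spec)
  shape <- arc_shape(fit$r_corrected, spec)
  attr(shape, "circle_fit") <- fit
  shape
}

#' @rdname estimate_arc_shape
#' @param shape A shape returned by [estimate_arc_shape()].
#' @export
circle_fit <- function(shape) attr(shape, "circle_fit")

#' Read / write marker sets as CSV
#'
#' Header `marker,x_mm,y_mm,z_mm`, one row per sphere. The sphere radius is
#' not part of the file (it is an acquisition constant) and must be supplied
#' when reading.
#'
#' @param markers A [marker_set()].
#' @param path File path.
#' @param r_sphere Sphere radius, mm.
#' @return `write_markers_csv()` returns `path` invisibly;
#'   `read_markers_csv()` a [marker_set()].
#' @export
write_markers_csv <- function(markers, path) {
  write.csv(data.frame(marker = markers$marker, x_mm = markers$x,
                       y_mm = markers$y, z_mm = markers$z),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path, r_sphere) {
  df <- read.csv(path)
  need <- c("marker", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop_flexbeam("marker CSV must have columns marker,x_mm,y_mm,z_mm",
                  "io_error")
  df <- df[order(df$marker), ]
  marker_set(cbind(df$x_mm, df$y_mm, df$z_mm), r_sphere = r_sphere)
}
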
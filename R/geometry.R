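#' @title Array shape containers
#'
#' @description An array shape is a tibble with one row per element and
#' columns `element`, `x`, `z` (element center, mm) and `alpha` (azimuth
#' angle, rad). The azimuth is the signed angle from the element normal to
#' the +z axis, oriented so that the scan-line direction of element k is
#' `(sin(alpha_k), cos(alpha_k))`; z increases into the imaging region and
#' physically realizable shapes are concave toward +z.
#'
#' @param x,z,alpha Numeric vectors of equal length K.
#' @param pitch Element pitch, mm (stored as an attribute).
#' @param model Which model produced the shape (`"arc"`, `"polyline"`, ...).
#' @return A tibble of class `flex_shape`.
#' @keywords internal
new_array_shape <- function(x, z, alpha, pitch, model = "custom") {
  if (length(x) != length(z) || length(x) != length(alpha))
    stop_flexbeam("x, z, alpha must have equal length", "dim_error")
  out <- tibble::tibble(element = seq_along(x), x = x, z = z, alpha = alpha)
  attr(out, "pitch") <- pitch
  attr(out, "model") <- model
  class(out) <- c("flex_shape", class(out))
  out
}

shape_centers <- function(shape) cbind(shape$x, shape$z)

#' Circular-arc array shape
#'
#' Places K elements on a concave circular arc of radius `R`, equally spaced
#' by the pitch measured along the arc, with the array center at the origin
#' and the shape symmetric about the z axis. Element k sits at
#' `x_k = R sin(((2k - K - 1)/2) p/R)`, `z_k = R - R cos(...)`, with azimuth
#' `alpha_k = ((K + 1 - 2k)/2) p/R`.
#'
#' @param R Arc radius, mm. Must satisfy `R > (K - 1) * pitch / pi` (the
#'   array spans less than a half circle).
#' @param spec A [probe_spec()].
#' @return A `flex_shape` tibble (see [new_array_shape()]).
#' @examples
#' arc_shape(65, probe_spec())
#' @export
arc_shape <- function(R, spec = probe_spec()) {
  K <- spec$K; p <- spec$pitch
  if (!is.finite(R) || R <= 0)
    stop_flexbeam("arc radius must be positive and finite", "invalid_geometry")
  if (R <= (K - 1) * p / pi)
    stop_flexbeam(
      sprintf("R = %g mm makes the array span >= half a circle (need R > %g mm)",
              R, (K - 1) * p / pi), "invalid_geometry")
  k <- seq_len(K)
  theta <- ((2 * k - K - 1) / 2) * (p / R)
  new_array_shape(x = R * sin(theta), z = R - R * cos(theta),
                  alpha = -theta, pitch = p, model = "arc")
}

#' External-angle polyline array shape
#'
#' Builds the shape from the K - 1 external angles between successive
#' elements. Element 1 is at the origin with tangent along +x; the k-th
#' tangent angle is the cumulative sum of the external angles, and element
#' centers follow `x_k = p * sum(cos(t_i))`, `z_k = p * sum(sin(t_i))`
#' (i < k), so consecutive centers are exactly one pitch apart. Positive
#' external angles bend the array concave toward +z. The stored azimuth is
#' the negative cumulative tangent angle, keeping the scan-line convention
#' `(sin(alpha), cos(alpha))` shared with [arc_shape()].
#'
#' @param params Numeric vector of K - 1 external angles, rad.
#' @param spec A [probe_spec()].
#' @return A `flex_shape` tibble.
#' @examples
#' polyline_shape(rep(0.01, 127), probe_spec())  # approximates a 100 mm arc
#' @export
polyline_shape <- function(params, spec = probe_spec()) {
  K <- spec$K; p <- spec$pitch
  if (length(params) != K - 1L)
    stop_flexbeam(sprintf("expected %d external angles, got %d",
                          K - 1L, length(params)), "dim_error")
  if (any(!is.finite(params)) || any(abs(params) >= pi / 2))
    stop_flexbeam("external angles must be finite and |delta alpha| < pi/2",
                  "invalid_geometry")
  tang <- c(0, cumsum(params))           # tangent angle at each element
  x <- p * c(0, cumsum(cos(tang[-K])))
  z <- p * c(0, cumsum(sin(tang[-K])))
  new_array_shape(x = x, z = z, alpha = -tang, pitch = p, model = "polyline")
}

#' External angles equivalent to a circular arc
#'
#' The constant per-element azimuth increment of an arc of radius `R` is
#' `pitch / R`; feeding the result to [polyline_shape()] reproduces
#' [arc_shape()] up to a rigid transform and an O(pitch^3 / R^2) arc-vs-chord
#' discrepancy.
#'
#' @inheritParams arc_shape
#' @return Numeric vector of K - 1 equal external angles, rad.
#' @export
params_from_arc <- function(R, spec = probe_spec()) {
  if (!is.finite(R) || R <= 0)
    stop_flexbeam("arc radius must be positive and finite", "invalid_geometry")
  if (R <= (spec$K - 1) * spec$pitch / pi)
    stop_flexbeam("radius too small for a sub-half-circle array",
                  "invalid_geometry")
  rep(spec$pitch / R, spec$K - 1L)
}

#' Rigid (Procrustes) alignment of one shape onto another
#'
#' Closed-form least-squares rotation + translation (no scaling, no
#' reflection) of the element centers of `moving` onto `fixed`.
#'
#' @param moving,fixed `flex_shape` tibbles with equal element counts.
#' @return List with `centers` (aligned K x 2 matrix), `rotation` (2 x 2),
#'   `translation` (length 2).
#' @keywords internal
align_centers <- function(moving, fixed) {
  A <- shape_centers(fixed); B <- shape_centers(moving)
  if (nrow(A) != nrow(B))
    stop_flexbeam("shapes have different element counts", "dim_error")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  s <- svd(crossprod(Bc, Ac))
  d <- sign(det(s$v %*% t(s$u)))
  Rm <- s$v %*% diag(c(1, d)) %*% t(s$u)
  aligned <- Bc %*% t(Rm)
  aligned <- sweep(aligned, 2, ca, FUN = "+")
  list(centers = aligned, rotation = Rm, translation = ca - cb %*% t(Rm))
}

#' Mean absolute element-position error between two shapes
#'
#' Rigidly aligns `b` onto `a` (least-squares rotation + translation over
#' element centers, no scaling) and returns the mean Euclidean distance
#' between corresponding centers. The two shape parameterizations used in
#' this package live in different frames (arc: array-center origin;
#' polyline: element-1 origin), a difference that carries no physical
#' meaning, hence the rigid pre-alignment. Symmetric in its arguments; zero
#' iff the shapes are congruent.
#'
#' @param a,b `flex_shape` tibbles with equal element counts.
#' @param align If `FALSE`, skip the rigid alignment and compare coordinates
#'   as given.
#' @return Mean absolute position error, mm.
#' @examples
#' shape_mae(arc_shape(70), polyline_shape(params_from_arc(70)))
#' @export
shape_mae <- function(a, b, align = TRUE) {
  A <- shape_centers(a)
  B <- if (align) align_centers(b, a)$centers else shape_centers(b)
  if (nrow(A) != nrow(B))
    stop_flexbeam("shapes have different element counts", "dim_error")
  mean(sqrt(rowSums((A - B)^2)))
}

#' Read / write array shapes and external-angle parameters as CSV
#'
#' Shapes use the header `element,x_mm,z_mm,alpha_rad` (one row per element);
#' parameter vectors use `k,delta_alpha_rad` (K - 1 rows).
#'
#' @param shape A `flex_shape` tibble.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_shape_csv()` returns a
#'   `flex_shape`; `read_params_csv()` a numeric vector.
#' @export
write_shape_csv <- function(shape, path) {
  df <- data.frame(element = shape$element, x_mm = shape$x, z_mm = shape$z,
                   alpha_rad = shape$alpha)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @export
read_shape_csv <- function(path) {
  df <- read.csv(path)
  need <- c("element", "x_mm", "z_mm", "alpha_rad")
  if (!all(need %in% names(df)))
    stop_flexbeam("shape CSV must have columns element,x_mm,z_mm,alpha_rad",
                  "io_error")
  p <- if (nrow(df) > 1)
    mean(sqrt(diff(df$x_mm)^2 + diff(df$z_mm)^2)) else NA_real_
  new_array_shape(df$x_mm, df$z_mm, df$alpha_rad, pitch = p)
}

#' @rdname write_shape_csv
#' @param params Numeric vector of external angles, rad.
#' @export
write_params_csv <- function(params, path) {
  write.csv(data.frame(k = seq_along(params), delta_alpha_rad = params),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_shape_csv
#' @export
read_params_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("k", "delta_alpha_rad") %in% names(df)))
    stop_flexbeam("params CSV must have columns k,delta_alpha_rad", "io_error")
  df$delta_alpha_rad[order(df$k)]
}

#' @export
autoplot.flex_shape <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$z)) +
    ggplot2::geom_path(colour = "grey60") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "lateral x (mm)", y = "axial z (mm)",
                  title = sprintf("Array shape (%s model, K = %d)",
                                  attr(object, "model"), nrow(object)))
}
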
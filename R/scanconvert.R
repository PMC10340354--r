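#' Bilinear interpolation on a rectilinear node grid
#'
#' Standard bilinear form: the value at a query point is interpolated first
#' along x between the two bracketing node columns, then along z between the
#' two bracketing rows. Exact at nodes, linear along cell edges, and always
#' a convex combination of the four surrounding node values. Queries outside
#' the node footprint return `NA` (masked).
#'
#' @param values Matrix of node values, `values[i, j]` at
#'   `(x_nodes[i], z_nodes[j])`.
#' @param x_nodes,z_nodes Strictly increasing node coordinates.
#' @param queries Q x 2 matrix of query points (x, z).
#' @return Numeric vector of length Q.
#' @export
bilinear_sample <- function(values, x_nodes, z_nodes, queries) {
  queries <- matrix(as.numeric(queries), ncol = 2)
  qx <- queries[, 1]; qz <- queries[, 2]
  nx <- length(x_nodes); nz <- length(z_nodes)
  ix <- findInterval(qx, x_nodes, rightmost.closed = TRUE)
  iz <- findInterval(qz, z_nodes, rightmost.closed = TRUE)
  ok <- !is.na(qx) & !is.na(qz) &
    ix >= 1 & ix <= nx - 1 & iz >= 1 & iz <= nz - 1 &
    qx >= x_nodes[1] & qx <= x_nodes[nx] &
    qz >= z_nodes[1] & qz <= z_nodes[nz]
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, length(qx))
  if (!any(ok)) return(out)
  i <- ix[ok]; j <- iz[ok]
  wx <- (qx[ok] - x_nodes[i]) / (x_nodes[i + 1] - x_nodes[i])
  wz <- (qz[ok] - z_nodes[j]) / (z_nodes[j + 1] - z_nodes[j])
  v00 <- values[cbind(i, j)];     v10 <- values[cbind(i + 1, j)]
  v01 <- values[cbind(i, j + 1)]; v11 <- values[cbind(i + 1, j + 1)]
  t1 <- (1 - wx) * v00 + wx * v10
  t2 <- (1 - wx) * v01 + wx * v11
  out[ok] <- (1 - wz) * t1 + wz * t2
  out
}

# Inverse scan geometry: map world points to fractional (line, depth)
# coordinates. A point's signed lateral offset v_i from each scan line i
# (cross product of the line direction with the point offset) increases
# with i for a fan of lines ordered left to right; the point lies between
# the bracketing pair where v changes sign. Within that pair the fraction f
# solves the exact inverse of position-bilinear interpolation,
#   P = (1 - f) (o_i + u d_i) + f (o_{i+1} + u d_{i+1}),
# i.e. the quadratic (1-f)^2 c11 + f (1-f) (c12 + c21) + f^2 c22 = 0 with
# c_ab = cross(d_a, P - o_b); the along-line depth u follows by projection.
# This makes scan conversion reproduce any affine test pattern exactly, for
# arc and polyline geometries alike.
inverse_scan_map <- function(grid, px, pz) {
  L <- grid$L
  npix <- length(px)
  Vm <- matrix(NA_real_, npix, L)
  for (i in seq_len(L)) {
    wx <- px - grid$origins[i, 1]; wz <- pz - grid$origins[i, 2]
    Vm[, i] <- grid$directions[i, 1] * wz - grid$directions[i, 2] * wx
  }
  # small tolerance keeps pixels lying exactly on a boundary line inside
  # the closed region despite rounding in the cross products
  nleft <- rowSums(Vm <= 1e-9)
  line <- rep(NA_real_, npix); depth <- rep(NA_real_, npix)
  on_last <- nleft == L & abs(Vm[, L]) <= 1e-9
  ok <- which(nleft >= 1 & nleft <= L - 1)
  if (length(ok)) {
    i <- nleft[ok]
    o0 <- grid$origins[i, , drop = FALSE]
    o1 <- grid$origins[i + 1, , drop = FALSE]
    d0 <- grid$directions[i, , drop = FALSE]
    d1 <- grid$directions[i + 1, , drop = FALSE]
    Px <- px[ok]; Pz <- pz[ok]
    c11 <- Vm[cbind(ok, i)]
    c22 <- Vm[cbind(ok, i + 1)]
    c12 <- d0[, 1] * (Pz - o1[, 2]) - d0[, 2] * (Px - o1[, 1])
    c21 <- d1[, 1] * (Pz - o0[, 2]) - d1[, 2] * (Px - o0[, 1])
    a <- c11 - c12 - c21 + c22
    b <- -2 * c11 + c12 + c21
    cc <- c11
    f <- ifelse(b != 0, -cc / b, 0)          # linear (parallel-line) case
    flin <- ifelse(c11 - c22 != 0, c11 / (c11 - c22), 0)
    quad <- abs(a) > 1e-14 * pmax(abs(b), 1e-30)
    if (any(quad)) {
      disc <- pmax(b[quad]^2 - 4 * a[quad] * cc[quad], 0)
      q <- -(b[quad] + sign(b[quad] + (b[quad] == 0)) * sqrt(disc)) / 2
      r1 <- q / a[quad]
      r2 <- ifelse(q != 0, cc[quad] / q, Inf)
      # of the two roots, keep the one nearest the linear bracket fraction
      f[quad] <- ifelse(abs(r1 - flin[quad]) <= abs(r2 - flin[quad]), r1, r2)
    }
    f <- pmin(pmax(f, 0), 1)
    Ofx <- (1 - f) * o0[, 1] + f * o1[, 1]
    Ofz <- (1 - f) * o0[, 2] + f * o1[, 2]
    Dx <- (1 - f) * d0[, 1] + f * d1[, 1]
    Dz <- (1 - f) * d0[, 2] + f * d1[, 2]
    u <- ((Px - Ofx) * Dx + (Pz - Ofz) * Dz) / (Dx^2 + Dz^2)
    line[ok] <- i + f
    depth[ok] <- u
  }
  line[on_last] <- L
  if (any(on_last)) {
    wL <- cbind(px[on_last] - grid$origins[L, 1],
                pz[on_last] - grid$origins[L, 2])
    depth[on_last] <- wL[, 1] * grid$directions[L, 1] +
                      wL[, 2] * grid$directions[L, 2]
  }
  list(line = line, depth = depth)
}

#' Scan-region binary mask
#'
#' A raster pixel is in-region iff it lies inside the closed area swept by
#' the scan lines: between the first and last lines (boundary included) and
#' between the shallow- and far-depth arcs through the line endpoints.
#'
#' @param grid An [build_grid()] imaging grid.
#' @param xs,zs Raster pixel center coordinates, mm.
#' @return Logical matrix `[length(xs), length(zs)]`.
#' @export
region_mask <- function(grid, xs, zs) {
  P <- expand.grid(x = xs, z = zs)
  m <- inverse_scan_map(grid, P$x, P$z)
  dmin <- min(grid$depths); dmax <- max(grid$depths)
  ok <- !is.na(m$line) & m$depth >= dmin - 1e-9 & m$depth <= dmax + 1e-9
  matrix(ok, length(xs), length(zs))
}

#' Scan conversion to a Cartesian raster
#'
#' Inverts the scan-line geometry per pixel to fractional (line, depth)
#' coordinates and bilinearly interpolates the beamformed image there;
#' pixels outside the scanned region are masked.
#'
#' @param img A `bf_image` from [das()].
#' @param spacing Raster pixel size, mm (default half a wavelength at
#'   5 MHz / 1540 m/s).
#' @param what `"envelope"` (default) or `"values"` (signed RF sum).
#' @param xlim,zlim Raster extents, mm; default the focal-point bounding
#'   box.
#' @return Object of class `raster_image`: list with `pixels`
#'   (`[nx, nz]`, `NA` outside the mask), `mask`, `xs`, `zs`, `origin`,
#'   `spacing`.
#' @export
scan_convert <- function(img, spacing = 0.154,
                         what = c("envelope", "values"),
                         xlim = NULL, zlim = NULL) {
  what <- match.arg(what)
  grid <- img$grid
  if (grid$L < 2)
    stop_flexbeam("scan conversion needs at least 2 scan lines", "input_error")
  if (spacing <= 0) stop_flexbeam("spacing must be positive", "input_error")
  if (is.null(xlim)) xlim <- range(grid$focal[, 1])
  if (is.null(zlim)) zlim <- range(grid$focal[, 2])
  xs <- seq(xlim[1], xlim[2], by = spacing)
  zs <- seq(zlim[1], zlim[2], by = spacing)
  P <- expand.grid(x = xs, z = zs)
  m <- inverse_scan_map(grid, P$x, P$z)
  dstep <- grid$depths[2] - grid$depths[1]
  di <- (m$depth - grid$depths[1]) / dstep + 1
  vals <- if (what == "envelope") img$envelope else img$values
  px <- bilinear_sample(vals, seq_len(grid$L), seq_len(grid$D),
                        cbind(m$line, di))
  # boundary pixels: clamp exact-edge coordinates into the closed region
  edge <- !is.na(m$line) & is.na(px) &
    m$line >= 1 - 1e-9 & m$line <= grid$L + 1e-9 &
    di >= 1 - 1e-9 & di <= grid$D + 1e-9
  if (any(edge)) {
    le <- pmin(pmax(m$line[edge], 1), grid$L)
    de <- pmin(pmax(di[edge], 1), grid$D)
    px[edge] <- bilinear_sample(vals, seq_len(grid$L), seq_len(grid$D),
                                cbind(pmin(le, grid$L - 1e-9),
                                      pmin(de, grid$D - 1e-9)))
  }
  pixels <- matrix(px, length(xs), length(zs))
  mask <- !is.na(pixels)
  structure(list(pixels = pixels, mask = mask, xs = xs, zs = zs,
                 origin = c(xs[1], zs[1]), spacing = spacing, what = what),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("<raster_image> %d x %d px at %.3g mm, %d in-region px\n",
              length(x$xs), length(x$zs), x$spacing, sum(x$mask)))
  invisible(x)
}

#' @export
autoplot.raster_image <- function(object, dynamic_range_db = 60, ...) {
  obj <- envelope_display(object, dynamic_range_db)
  df <- expand.grid(x = object$xs, z = object$zs)
  df$db <- as.numeric(obj$display)
  df$db[!as.logical(object$mask)] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$z,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 na.value = "grey20") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "z (mm)", fill = "dB")
}
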
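#' Two-way time of flight
#'
#' Transmit element -> focal point -> receive element path length divided by
#' the speed of sound. Coordinates in mm, `c` in m/s; the result is in
#' seconds.
#'
#' @param tx,rx Length-2 element center coordinates, mm.
#' @param focal Length-2 focal point, mm (or an F x 2 matrix).
#' @param c Speed of sound, m/s.
#' @return Time of flight, s (vector of length F).
#' @examples
#' tof(c(0, 0), c(0, 0), c(0, 30))  # pulse-echo: 2 * 30 mm / 1540 m/s
#' @export
tof <- function(tx, rx, focal, c = 1540) {
  if (c <= 0) stop_flexbeam("c must be positive", "input_error")
  focal <- matrix(as.numeric(focal), ncol = 2)
  d_tx <- sqrt((focal[, 1] - tx[1])^2 + (focal[, 2] - tx[2])^2)
  d_rx <- sqrt((focal[, 1] - rx[1])^2 + (focal[, 2] - rx[2])^2)
  (d_tx + d_rx) / (c * 1e3)
}

#' Imaging grid of focal points along per-element scan lines
#'
#' One scan line per element: origin at the element center, direction along
#' the element normal (`(sin(alpha), cos(alpha))`), focal points at depths
#' `seq(depth_range[1], depth_range[2], by = depth_step)`.
#'
#' @param shape A `flex_shape`.
#' @param depth_range Length-2 depth limits along each line, mm (a scalar is
#'   taken as the maximum depth with the minimum equal to `depth_step`).
#' @param depth_step Depth sample spacing, mm.
#' @return Object of class `imaging_grid`: list with `origins` (L x 2),
#'   `directions` (L x 2), `angles` (rad), `depths` (length D) and `focal`
#'   (an (L*D) x 2 matrix, depth-major within each line).
#' @export
build_grid <- function(shape, depth_range = c(5, 60), depth_step = 0.154) {
  if (length(depth_range) == 1L) depth_range <- c(depth_step, depth_range)
  if (depth_step <= 0 || depth_range[2] <= depth_range[1])
    stop_flexbeam("need 0 < depth_step and increasing depth_range", "input_error")
  origins <- shape_centers(shape)
  dirs <- cbind(sin(shape$alpha), cos(shape$alpha))
  depths <- seq(depth_range[1], depth_range[2], by = depth_step)
  L <- nrow(origins); D <- length(depths)
  fx <- origins[, 1] %o% rep(1, D) + dirs[, 1] %o% depths
  fz <- origins[, 2] %o% rep(1, D) + dirs[, 2] %o% depths
  structure(list(origins = origins, directions = dirs,
                 angles = shape$alpha, depths = depths,
                 focal = cbind(as.numeric(t(fx)), as.numeric(t(fz))),
                 L = L, D = D),
            class = "imaging_grid")
}

#' @export
print.imaging_grid <- function(x, ...) {
  cat(sprintf("<imaging_grid> %d scan lines x %d depths (%.3g..%.3g mm, step %.3g mm)\n",
              x$L, x$D, min(x$depths), max(x$depths),
              x$depths[2] - x$depths[1]))
  invisible(x)
}

#' Delay-and-sum beamforming with nearest-sample extraction
#'
#' Reconstructs `I(x_f, z_f) = sum_t sum_r RF(t, r, n*)` where `n*` is the
#' unique sample whose receive time is nearest the two-way time of flight
#' from the transmitting element through the focal point to the receiving
#' element (half-sample ties round away from zero; delays outside the
#' record contribute zero). Transmit and receive element positions are both
#' taken from `shape` — the *assumed* shape, which is what the shape
#' estimation problem is about; it need not equal the shape that produced
#' the data. All K receive channels are summed with unit apodization.
#'
#' @param rf An [simulate_rf()] result (or compatible `rf_data`).
#' @param shape Assumed array shape (`flex_shape`, K elements).
#' @param grid An [build_grid()] grid (defaults to a grid built on `shape`).
#' @param interp `"nearest"` (canonical) or `"linear"` (linear-in-time
#'   interpolation between the two bracketing samples).
#' @return Object of class `bf_image`: list with `values` (L x D matrix,
#'   lines in rows), `envelope` (L x D, analytic-signal magnitude along
#'   depth), and `grid`.
#' @examples
#' sp <- probe_spec(K = 16)
#' sh <- arc_shape(70, sp)
#' rf <- simulate_rf(sh, phantom_spec(
#'   point_targets = data.frame(x = 0, z = 25, amplitude = 1)), sp, seed = 1)
#' img <- das(rf, sh, build_grid(sh, c(15, 35), 0.2))
#' @export
das <- function(rf, shape, grid = build_grid(shape),
                interp = c("nearest", "linear")) {
  interp <- match.arg(interp)
  d <- dim(rf$rf)
  if (nrow(shape) != d[2])
    stop_flexbeam("shape element count does not match RF receive channels",
                  "dim_error")
  if (any(rf$transmit$element > nrow(shape)))
    stop_flexbeam("transmit event element index outside shape", "dim_error")
  pos <- shape_centers(shape)
  tx <- pos[rf$transmit$element, , drop = FALSE]
  c_mm <- rf$spec$c * 1e3
  if (interp == "nearest") {
    v <- das_kernel(as.numeric(rf$rf), d[1], d[2], d[3], tx, pos,
                    grid$focal, rf$fs, rf$t0, c_mm)
  } else {
    v <- das_linear(rf, tx, pos, grid, c_mm)
  }
  values <- matrix(v, nrow = grid$L, ncol = grid$D, byrow = TRUE)
  structure(list(values = values,
                 envelope = envelope_matrix(values), grid = grid),
            class = "bf_image")
}

# Linear-in-time delay interpolation (optional alternative to the canonical
# nearest-sample extraction); plain R, intended for small cases.
das_linear <- function(rf, tx, rx, grid, c_mm) {
  d <- dim(rf$rf)
  F <- nrow(grid$focal)
  out <- numeric(F)
  for (t in seq_len(d[1])) {
    dtx <- sqrt((grid$focal[, 1] - tx[t, 1])^2 + (grid$focal[, 2] - tx[t, 2])^2)
    for (r in seq_len(d[2])) {
      drx <- sqrt((grid$focal[, 1] - rx[r, 1])^2 +
                  (grid$focal[, 2] - rx[r, 2])^2)
      nn <- ((dtx + drx) / c_mm - rf$t0) * rf$fs + 1
      n0 <- floor(nn); w <- nn - n0
      ok0 <- n0 >= 1 & n0 <= d[3]
      ok1 <- n0 + 1 >= 1 & n0 + 1 <= d[3]
      tr <- rf$rf[t, r, ]
      out <- out +
        ifelse(ok0, (1 - w) * tr[pmax(pmin(n0, d[3]), 1)], 0) +
        ifelse(ok1, w * tr[pmax(pmin(n0 + 1, d[3]), 1)], 0)
    }
  }
  out
}

# Analytic-signal magnitude along each scan line (rows of the L x D image).
envelope_matrix <- function(values) {
  t(apply(values, 1, function(x) Mod(analytic_signal(x))))
}

# Discrete analytic signal via the FFT half-spectrum construction.
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2) return(complex(real = x, imaginary = 0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Log-compressed B-mode display image
#'
#' Normalizes the envelope to its maximum and log-compresses to
#' `[-dynamic_range_db, 0]` dB. An all-zero image maps to the display floor.
#'
#' @param img A `bf_image` (or a raster from [scan_convert()], whose
#'   unmasked pixels are compressed).
#' @param dynamic_range_db Display dynamic range, dB (> 0).
#' @return Same structure with a `display` matrix in dB.
#' @export
envelope_display <- function(img, dynamic_range_db = 60) {
  if (dynamic_range_db <= 0)
    stop_flexbeam("dynamic_range_db must be positive", "input_error")
  env <- if (inherits(img, "bf_image")) img$envelope else img$pixels
  m <- max(env, na.rm = TRUE)
  db <- if (m <= 0) matrix(-dynamic_range_db, nrow(env), ncol(env))
        else pmax(20 * log10(pmax(env / m, 10^(-dynamic_range_db / 20 - 1))),
                  -dynamic_range_db)
  img$display <- db
  img$dynamic_range_db <- dynamic_range_db
  img
}

#' @export
print.bf_image <- function(x, ...) {
  cat(sprintf("<bf_image> %d scan lines x %d depths, peak envelope %.4g\n",
              nrow(x$values), ncol(x$values), max(x$envelope)))
  invisible(x)
}

#' @export
autoplot.bf_image <- function(object, dynamic_range_db = 60, ...) {
  obj <- envelope_display(object, dynamic_range_db)
  df <- tidyr::expand_grid(line = seq_len(nrow(obj$display)),
                           depth_i = seq_len(ncol(obj$display)))
  df$db <- as.numeric(t(obj$display))[
    (df$line - 1) * ncol(obj$display) + df$depth_i]
  df$depth <- obj$grid$depths[df$depth_i]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$line, y = .data$depth,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-dynamic_range_db, 0)) +
    ggplot2::labs(x = "scan line", y = "depth (mm)", fill = "dB")
}
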
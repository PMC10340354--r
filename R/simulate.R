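#' Simulate RF channel data for a known array shape and phantom
#'
#' Forward model used to exercise the whole pipeline without hardware: each
#' scatterer contributes, for every transmit event and receive element, a
#' Gaussian-windowed sinusoid at the probe center frequency delayed by the
#' two-way time of flight, weighted per element by a hard-baffle directivity
#' `cos(theta) * sinc(w sin(theta) / lambda)` (clipped at zero; `w` is the
#' element width, whose sinc factor keeps the 3.2-wavelength element pitch
#' from producing grating lobes as strong as the main lobe) and a
#' `1 / max(d_tx * d_rx, eps)` geometric spreading factor. This is a
#' point-scatterer superposition model for testing focusing logic, not a
#' diffraction solver.
#'
#' @param shape True array shape (`flex_shape`) used for the acoustics.
#' @param phantom A [phantom_spec()].
#' @param spec A [probe_spec()].
#' @param noise_snr_db If non-`NULL`, additive white Gaussian noise at this
#'   SNR (dB, relative to the RMS of the clean RF).
#' @param seed Integer seed; fixes the scatterer draw and the noise.
#' @param tx_mode `"saft"` (default): full synthetic aperture, each element
#'   fires alone and all receive. `"walking"`: per scan line, a contiguous
#'   `n_active`-element sub-aperture fires with delays focused at
#'   `tx_focus_mm` along the center element's normal (virtual-source model
#'   of a focused walking aperture).
#' @param n_active Active transmit elements per line in `"walking"` mode.
#' @param tx_focus_mm Transmit focal depth, mm (`"walking"` mode).
#' @param fractional_bandwidth Pulse -6 dB fractional bandwidth (default 0.6).
#' @param t0 Receive time of sample 1 relative to transmit, s.
#' @param n_samples Record length; default covers the deepest scatterer's
#'   two-way time of flight plus the pulse tail.
#' @param spreading_eps Floor (mm^2) of the spreading denominator.
#' @return Object of class `rf_data`: list with `rf` (array
#'   `[T, K, N]`), `fs`, `t0`, `f0`, `transmit` (tibble `event`, `element`),
#'   `spec`, `true_shape`, `seed`.
#' @examples
#' sp <- probe_spec(K = 8)
#' ph <- phantom_spec(point_targets = data.frame(x = 0, z = 20, amplitude = 1))
#' rf <- simulate_rf(arc_shape(70, sp), ph, sp, seed = 1)
#' dim(rf$rf)
#' @export
simulate_rf <- function(shape, phantom, spec = probe_spec(),
                        noise_snr_db = NULL, seed = 1L,
                        tx_mode = c("saft", "walking"), n_active = 64L,
                        tx_focus_mm = 30, fractional_bandwidth = 0.6,
                        t0 = 0, n_samples = NULL, spreading_eps = 1) {
  tx_mode <- match.arg(tx_mode)
  K <- spec$K
  if (nrow(shape) != K)
    stop_flexbeam("shape element count does not match probe spec", "dim_error")
  sc <- phantom_scatterers(phantom, seed)
  if (is.null(sc) || nrow(sc) == 0)
    stop_flexbeam("phantom produced no scatterers", "input_error")

  dirs <- cbind(sin(shape$alpha), cos(shape$alpha))
  pos <- shape_centers(shape)

  # reject scatterers behind the array face (negative range along the
  # normal of the nearest element)
  d2 <- outer(sc[, 1], pos[, 1], "-")^2 + outer(sc[, 2], pos[, 2], "-")^2
  nearest <- max.col(-d2)
  proj <- (sc[, 1] - pos[nearest, 1]) * dirs[nearest, 1] +
          (sc[, 2] - pos[nearest, 2]) * dirs[nearest, 2]
  if (any(proj < 0))
    stop_flexbeam("scatterer(s) behind the array face", "invalid_geometry")

  c_mm <- spec$c * 1e3                       # mm/s
  sigma_t <- sqrt(2 * log(2)) / (pi * fractional_bandwidth * spec$f0)

  if (tx_mode == "saft") {
    txrows <- cbind(seq_len(K) - 1, pos, dirs, 0, 1)
    transmit <- tibble::tibble(event = seq_len(K), element = seq_len(K))
  } else {
    rows <- vector("list", K)
    half <- (n_active - 1) / 2
    for (k in seq_len(K)) {
      lo <- max(1L, k - floor(half)); hi <- min(K, k + ceiling(half))
      mem <- lo:hi
      focus <- pos[k, ] + tx_focus_mm * dirs[k, ]
      dmem <- sqrt(rowSums(sweep(pos[mem, , drop = FALSE], 2, focus)^2))
      dctr <- sqrt(sum((pos[k, ] - focus)^2))
      rows[[k]] <- cbind(k - 1, pos[mem, , drop = FALSE],
                         dirs[mem, , drop = FALSE],
                         (dctr - dmem) / c_mm, 1 / length(mem))
    }
    txrows <- do.call(rbind, rows)
    transmit <- tibble::tibble(event = seq_len(K), element = seq_len(K))
  }
  T_ev <- K

  if (is.null(n_samples)) {
    dmax <- sqrt(max(d2))
    tau_max <- max(txrows[, 6]) + 2 * dmax / c_mm + 5 * sigma_t
    n_samples <- ceiling((tau_max - t0) * spec$fs) + 2L
  }

  w_ol <- if (is.null(spec$element_width)) 0 else spec$element_width / spec$lambda
  rf <- simrf_kernel(T_ev, K, as.integer(n_samples), txrows,
                     cbind(pos, dirs), sc, spec$fs, t0, spec$f0,
                     sigma_t, c_mm, spreading_eps, w_ol)
  dim(rf) <- c(T_ev, K, n_samples)
  if (!is.null(noise_snr_db)) {
    s_rms <- sqrt(mean(rf^2))
    rf <- rf + rnorm(length(rf), 0, s_rms * 10^(-noise_snr_db / 20))
  }
  structure(list(rf = rf, fs = spec$fs, t0 = t0, f0 = spec$f0,
                 transmit = transmit, spec = spec, true_shape = shape,
                 seed = seed),
            class = "rf_data")
}

#' @export
print.rf_data <- function(x, ...) {
  d <- dim(x$rf)
  cat(sprintf("<rf_data> %d transmit events x %d channels x %d samples, fs = %g MHz\n",
              d[1], d[2], d[3], x$fs / 1e6))
  invisible(x)
}

#' Simulate optical marker positions on an arc-shaped probe
#'
#' Places `m` marker sphere centers over the back surface of an arc-shaped
#' array: each sits one transducer thickness plus one sphere radius outward
#' (away from the imaging region) along the local normal, with the first and
#' last markers at the two array ends and the rest equally spaced along the
#' arc. Isotropic 3D Gaussian jitter of sd `noise_mm` emulates tracker and
#' mounting error.
#'
#' @param R True array radius, mm.
#' @param spec A [probe_spec()].
#' @param r_sphere Marker sphere radius, mm.
#' @param m Number of markers (>= 3).
#' @param noise_mm Jitter sd, mm (0 = exact).
#' @param seed Integer seed.
#' @return A [marker_set()].
#' @examples
#' m <- simulate_markers(72.5, probe_spec(), r_sphere = 6, m = 5,
#'                       noise_mm = 0.25, seed = 7)
#' @export
simulate_markers <- function(R, spec = probe_spec(), r_sphere = 6,
                             m = 5L, noise_mm = 0, seed = 1L) {
  if (m < 3L) stop_flexbeam("at least 3 markers are required", "input_error")
  if (!is.finite(R) || R <= 0)
    stop_flexbeam("R must be positive", "invalid_geometry")
  theta_end <- (spec$K - 1) * spec$pitch / (2 * R)
  phi <- seq(-theta_end, theta_end, length.out = m)
  Rm <- R + spec$thickness + r_sphere
  x <- Rm * sin(phi)
  z <- R - Rm * cos(phi)
  set.seed(seed)
  coords <- cbind(x, 0, z) + matrix(rnorm(3 * m, 0, noise_mm), m, 3)
  marker_set(coords, r_sphere = r_sphere)
}
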
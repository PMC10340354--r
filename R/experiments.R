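#' Reference phantom and probe for the desk-scale experiments
#'
#' The packaged experiments run on a scaled-down 32-element probe (all other
#' probe constants as in [probe_spec()]) bent to a 70 mm arc — the curvature
#' scale of an adult abdominal surface — over phantoms that emulate the two
#' classic test objects: a wire phantom (point targets at several depths on
#' the axis) for resolution work, and a speckle phantom (diffuse scatterers
#' with one anechoic and one hyperechoic elliptical inclusion) for
#' contrast/autofocus work.
#'
#' @param kind `"speckle"` or `"wires"`.
#' @return A [phantom_spec()].
#' @export
reference_phantom <- function(kind = c("speckle", "wires")) {
  kind <- match.arg(kind)
  if (kind == "wires") {
    phantom_spec(point_targets = data.frame(x = 0, z = c(10, 20, 30, 40),
                                            amplitude = 1))
  } else {
    phantom_spec(
      speckle = list(xlim = c(-18, 18), zlim = c(8, 42), density = 3),
      inclusions = data.frame(x = c(0, -8), z = c(25, 18),
                              semi_lateral = c(4, 3), semi_axial = c(4, 3),
                              multiplier = c(0, 2)))
  }
}

#' @rdname reference_phantom
#' @export
reference_probe <- function() probe_spec(K = 32L)

#' Printed radius calibration of the optical shape estimation
#'
#' Ground-truth radii of the three cylinder calibration objects and the
#' radii recovered for them by the optical-marker pipeline in the original
#' bench measurement, mm.
#'
#' @return Tibble with columns `object`, `r_object_mm`, `r_array_mm`,
#'   `abs_error_mm`.
#' @export
cylinder_radius_table <- function() {
  tibble::tibble(
    object = 1:3,
    r_object_mm = c(110.00, 72.50, 65.00),
    r_array_mm = c(110.20, 71.77, 63.45),
    abs_error_mm = abs(r_array_mm - r_object_mm))
}

#' Optical-pipeline radius recovery experiment
#'
#' For each radius, simulates markers on the arc and runs the full optical
#' pipeline ([estimate_arc_shape()]). Noiseless markers must return the
#' radius to numerical precision; with tracker-scale jitter (0.25 mm, the
#' nominal accuracy of a clinical infrared tracker) the median error over
#' replicates characterizes robustness.
#'
#' @param radii True arc radii, mm.
#' @param noise_mm Marker jitter sd, mm.
#' @param n_seeds Replicates per radius.
#' @param seed Base seed.
#' @param spec Probe; the bench device is the 128-element probe.
#' @param r_sphere Marker sphere radius, mm.
#' @param m Markers per set.
#' @return Tibble with columns `r_true_mm`, `seed`, `r_est_mm`,
#'   `abs_error_mm`.
#' @export
optical_recovery_experiment <- function(radii = c(65, 72.5, 110),
                                        noise_mm = 0.25, n_seeds = 100L,
                                        seed = 1L, spec = probe_spec(),
                                        r_sphere = 6, m = 5L) {
  tidyr::expand_grid(r_true_mm = radii, rep = seq_len(n_seeds)) |>
    purrr::pmap_dfr(function(r_true_mm, rep) {
      s <- seed * 20011L + rep * 211L + round(r_true_mm * 10)
      mk <- simulate_markers(r_true_mm, spec, r_sphere = r_sphere, m = m,
                             noise_mm = noise_mm, seed = s)
      fit <- circle_fit(estimate_arc_shape(mk, spec))
      tibble::tibble(r_true_mm = r_true_mm, seed = s,
                     r_est_mm = fit$r_corrected,
                     abs_error_mm = abs(fit$r_corrected - r_true_mm))
    })
}

# Shared RF simulation for the autofocus experiments: speckle phantom on
# the reference 32-element probe bent to a 70 mm arc.
reference_rf <- function(seed) {
  sp <- reference_probe()
  true_shape <- arc_shape(70, sp)
  rf <- simulate_rf(true_shape, reference_phantom("speckle"), sp,
                    seed = seed * 1000L + 11L)
  list(rf = rf, true_shape = true_shape, spec = sp)
}

#' Error-entropy direction experiment
#'
#' Simulates the reference speckle phantom, draws random shape assumptions
#' around the truth at the optimizer's bound scale, and returns the scan
#' plus the Spearman rank correlation between position error and image
#' entropy — negative when the autofocus principle (maximize entropy) holds.
#'
#' @param n_assumptions Random assumptions.
#' @param seed Integer seed.
#' @param perturb_scale Per-angle perturbation half-width, rad.
#' @return List with `scan` (tibble) and `spearman`.
#' @export
entropy_direction_experiment <- function(n_assumptions = 100L, seed = 1L,
                                         perturb_scale = pi / 720) {
  ref <- reference_rf(seed)
  scan <- entropy_error_scan(ref$rf, ref$true_shape,
                             n_assumptions = n_assumptions,
                             perturb_scale = perturb_scale,
                             seed = seed * 77L + 5L,
                             depth_range = c(8, 42), depth_step = 0.154)
  list(scan = scan,
       spearman = cor(scan$mae_mm, scan$entropy_bits, method = "spearman"))
}

#' Entropy-optimization shape recovery experiment
#'
#' The scaled-down counterpart of the bench shape-optimization protocol:
#' the initial shape is the truth perturbed per-angle within the
#' optimization bounds (as an optical estimate would be), and the optimizer
#' runs its 200-evaluation budget. Per replicate the initial and final
#' element-position MAEs are recorded, optionally together with an
#' entropy-*minimizing* control run (which should end farther from the
#' truth than the maximizing run).
#'
#' @param n_seeds Replicates.
#' @param seed Base seed.
#' @param max_evals Objective evaluation budget per run.
#' @param bound_halfwidth Optimization box half-width, rad.
#' @param control If `TRUE`, also run the minimizing control per replicate.
#' @return Tibble with one row per replicate: `rep`, `initial_mae_mm`,
#'   `final_mae_mm`, `final_entropy_bits`, and with `control`
#'   `control_mae_mm`.
#' @export
optimization_recovery_experiment <- function(n_seeds = 10L, seed = 1L,
                                             max_evals = 200L,
                                             bound_halfwidth = pi / 720,
                                             control = TRUE) {
  ref <- reference_rf(seed)
  p_true <- params_from_shape(ref$true_shape)
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    set.seed(seed * 5000L + i)
    init <- p_true + runif(length(p_true), -bound_halfwidth, bound_halfwidth)
    res <- optimize_shape(ref$rf, init, bound_halfwidth = bound_halfwidth,
                          max_evals = max_evals, seed = seed * 100L + i,
                          true_shape = ref$true_shape,
                          depth_range = c(8, 42), depth_step = 0.154)
    g <- glance(res)
    out <- tibble::tibble(rep = i, initial_mae_mm = g$initial_mae_mm,
                          final_mae_mm = g$final_mae_mm,
                          final_entropy_bits = g$best_entropy_bits)
    if (control) {
      ctl <- optimize_shape(ref$rf, init, bound_halfwidth = bound_halfwidth,
                            max_evals = max_evals, seed = seed * 100L + i,
                            direction = "minimize",
                            true_shape = ref$true_shape,
                            depth_range = c(8, 42), depth_step = 0.154)
      out$control_mae_mm <- glance(ctl)$final_mae_mm
    }
    out
  })
}

#' Point-target FWHM per wire on a scan-converted image
#'
#' For each nominal target position, finds the brightest in-region pixel
#' within a window around it and measures the lateral FWHM through that
#' peak. A profile that never falls back below half maximum inside the
#' scanned region is right-censored at the width of the available profile
#' (the censored value is a lower bound on the true width, flagged in the
#' `censored` column).
#'
#' @param raster A [scan_convert()] envelope raster.
#' @param targets Data frame with columns `x`, `z` (mm).
#' @param window_mm Half-width of the peak search window, mm.
#' @return Tibble with columns `x`, `z`, `fwhm_mm`, `censored`.
#' @export
fwhm_at_targets <- function(raster, targets, window_mm = 5) {
  purrr::pmap_dfr(targets[, c("x", "z")], function(x, z) {
    w <- which(outer(abs(raster$xs - x) <= window_mm,
                     abs(raster$zs - z) <= window_mm) & raster$mask,
               arr.ind = TRUE)
    if (nrow(w) == 0)
      return(tibble::tibble(x = x, z = z, fwhm_mm = NA_real_,
                            censored = NA))
    pk <- w[which.max(raster$pixels[w]), ]
    censored <- FALSE
    f <- tryCatch(
      lateral_fwhm(raster, c(raster$xs[pk[1]], raster$zs[pk[2]])),
      flexbeam_undefined_width = function(e) {
        censored <<- TRUE
        ok <- which(!is.na(raster$pixels[, pk[2]]))
        diff(range(raster$xs[ok]))
      })
    tibble::tibble(x = x, z = z, fwhm_mm = f, censored = censored)
  })
}

#' Defocusing-correction experiment
#'
#' Simulates the reference wire phantom on the 70 mm arc and beamforms the
#' same RF twice: under the true arc shape and under the uncorrected flat
#' assumption. Returns the per-wire lateral FWHMs; defocusing makes the
#' flat-assumption widths systematically larger.
#'
#' @param seed Integer seed.
#' @param R True arc radius, mm.
#' @return Tibble with columns `x`, `z`, `fwhm_mm`, `shape`
#'   (`"true"`/`"flat"`).
#' @export
defocus_experiment <- function(seed = 1L, R = 70) {
  sp <- reference_probe()
  true_shape <- arc_shape(R, sp)
  ph <- reference_phantom("wires")
  rf <- simulate_rf(true_shape, ph, sp, seed = seed * 1000L + 2L)
  flat <- polyline_shape(rep(0, sp$K - 1L), sp)
  purrr::map_dfr(list(true = true_shape, flat = flat), function(sh) {
    img <- das(rf, sh, build_grid(sh, c(5, 48), 0.154))
    rc <- scan_convert(img, spacing = 0.1)
    fwhm_at_targets(rc, ph$point_targets, window_mm = 5)
  }, .id = "shape")
}
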
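#' Physical and acquisition constants of a flexible array transducer
#'
#' Bundles the fixed properties of the probe and acquisition chain used
#' throughout the package. Defaults describe a 128-element, 5 MHz flexible
#' array with 1.0 mm pitch and 1.5 mm transducer thickness, sampled at
#' 20 MHz in a medium with uniform speed of sound 1540 m/s.
#'
#' @param K Number of array elements (integer, >= 2).
#' @param pitch Center-to-center element spacing, mm.
#' @param f0 Transmit center frequency, Hz.
#' @param fs RF sampling frequency, Hz. Must exceed 2 * `f0`.
#' @param c Speed of sound, m/s (assumed uniform).
#' @param thickness Transducer thickness, mm (distance from the element
#'   plane to the probe back surface where markers mount).
#' @param element_width Lateral element width, mm (sets the element
#'   directivity used by the RF simulator; 0 disables the width factor).
#' @param element_length Elevation length of one element, mm (informational).
#'
#' @return An object of class `probe_spec`: a named list with the fields
#'   above plus `lambda` (wavelength, mm).
#' @examples
#' spec <- probe_spec()
#' spec$lambda / 2  # half-wavelength focusing criterion, mm
#' @export
probe_spec <- function(K = 128L, pitch = 1.0, f0 = 5e6, fs = 20e6,
                       c = 1540, thickness = 1.5, element_width = 0.8,
                       element_length = 10) {
  K <- as.integer(K)
  if (is.na(K) || K < 2L) stop_flexbeam("K must be an integer >= 2", "invalid_spec")
  if (pitch <= 0) stop_flexbeam("pitch must be positive", "invalid_spec")
  if (f0 <= 0) stop_flexbeam("f0 must be positive", "invalid_spec")
  if (fs <= 2 * f0) stop_flexbeam("fs must exceed 2 * f0 (Nyquist)", "invalid_spec")
  if (c <= 0) stop_flexbeam("c must be positive", "invalid_spec")
  if (thickness < 0) stop_flexbeam("thickness must be non-negative", "invalid_spec")
  structure(
    list(K = K, pitch = pitch, f0 = f0, fs = fs, c = c,
         thickness = thickness, element_width = element_width,
         element_length = element_length, lambda = c / f0 * 1e3),
    class = "probe_spec"
  )
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf(
    "<probe_spec> K = %d elements, pitch = %g mm, f0 = %g MHz, fs = %g MHz,\n",
    x$K, x$pitch, x$f0 / 1e6, x$fs / 1e6))
  cat(sprintf("  c = %g m/s, thickness = %g mm, lambda = %.4g mm\n",
              x$c, x$thickness, x$lambda))
  invisible(x)
}

#' Half-wavelength element-position accuracy criterion
#'
#' Element-position errors above half the transmit wavelength cause summation
#' of wrongly delayed channels in opposite phase and hence signal loss; this
#' threshold is the standard accuracy requirement for array shape estimates.
#'
#' @param spec A [probe_spec()].
#' @return Half the wavelength, mm (0.154 mm at 5 MHz and 1540 m/s).
#' @export
half_wavelength <- function(spec = probe_spec()) spec$lambda / 2
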
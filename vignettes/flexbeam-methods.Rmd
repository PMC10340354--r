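---
title: "Shape estimation and beamforming for flexible ultrasound arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape estimation and beamforming for flexible ultrasound arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexbeam)
```

## The problem

A flexible array transducer conforms to the body surface, which makes it
attractive for wearable imaging and for abdominal motion monitoring during
radiotherapy — but it also means the element positions are unknown at
imaging time. Delay-and-sum (DAS) beamforming applies to each channel the
delay matching the two-way time of flight between transmit element, focal
point, and receive element; if an element's assumed position errs by more
than half a wavelength (`half_wavelength(probe_spec())` = 0.154 mm at 5 MHz
and 1540 m/s), its echoes are summed in opposite phase, and the image
defocuses and distorts.

flexbeam implements a two-stage shape estimate for a 128-element, 1 mm
pitch, 5 MHz flexible array:

1. **Optical stage** — passive marker spheres on the probe's back are
   localized in 3D by an infrared tracker. The markers are projected onto
   the array plane by PCA, a circle is fitted by Pratt's algebraic
   least-squares method, the radius is corrected from sphere centers down
   to the element surface (`r_fit - r_sphere - thickness`), and the shape
   is reported as a circular arc.
2. **Autofocus stage** — the arc estimate seeds a bounded, derivative-free
   search over the external-angle polyline model (K − 1 bend angles, each
   within ±π/720 rad of its start) that maximizes the Shannon entropy of
   the reconstructed B-mode image, with a budget of 200 objective
   evaluations.

Everything downstream of RF acquisition — DAS with nearest-sample
extraction, scan conversion, image-quality metrics — is implemented here,
and a synthetic RF simulator stands in for the hardware so that every stage
is testable end to end.

## Shape models and conventions

Distances are mm, angles radians, the speed of sound m/s; `z` increases
into the imaging region. The **arc model** places K elements on a circle of
radius R, equally spaced by the pitch along the arc, centered on the z
axis; the array is concave toward +z, the geometry of a probe wrapped
around a convex body. Consequently the element normals (the scan lines)
*converge* toward the arc center: focal points at depth u lie on the
concentric circle of radius R − u. The **polyline model** chains K − 1
unit-pitch segments with external bend angles Δα; positive bends curl the
chain toward +z. The two models differ only by an O(p³/R²) arc-vs-chord
discrepancy (about 2 × 10⁻⁴ mm at R = 70 mm) and a rigid transform.

Both models expose an azimuth per element, the signed angle from the
element normal to +z with scan-line direction `(sin α, cos α)`. The two
source parameterizations orient their angle differently; flexbeam stores
the azimuth consistently (the polyline's cumulative tangent angle enters
with a minus sign), so `das()` and `build_grid()` never need to know which
model produced a shape.

Because the arc model is centered on the z axis while the polyline starts
at element 1, `shape_mae()` first removes the rigid difference with a
closed-form 2D Procrustes alignment (rotation + translation, no scaling,
no reflection) and then averages the element-wise distances. The frame
difference carries no physical information, which is why the alignment is
built into the metric.

## The forward model (and what it is not)

`simulate_rf()` is a point-scatterer superposition model: each scatterer
contributes a Gaussian-windowed sinusoid (−6 dB fractional bandwidth 0.6)
delayed by the exact two-way time of flight, with geometric
`1/(d_tx · d_rx)` spreading and a per-element directivity
`cos θ · sinc(w sin θ / λ)` built from the 0.8 mm element width. The width
factor matters: at 1 mm pitch (3.2 λ) a bare point-element model produces
grating lobes nearly as strong as the main lobe, which no physical probe
with 0.8 mm elements exhibits. The default transmit scheme is full
synthetic aperture (each element fires alone, all receive), the simplest
scheme exercising every transmit–receive path; a focused walking-aperture
mode (64 active elements, virtual-source delays) is available.

The simulator does **not** model diffraction, attenuation, elevation
focusing, or heterogeneous sound speed. Passing tests therefore show that
the *focusing logic* is correct under the model's own physics; they do not
certify performance on tissue. Speckle is emulated with uniformly placed
scatterers of Gaussian amplitude (3/mm², several per resolution cell, so
the envelope statistics are Rayleigh-like), and elliptical inclusions
rescale scatterer amplitudes (0 = anechoic, >1 = hyperechoic).

## DAS and scan conversion choices

- **Nearest-sample extraction** is canonical: each channel contributes the
  single sample whose receive time is nearest the time of flight;
  half-sample ties round away from zero (a fixed, documented convention —
  the extraction rule admits both neighbors at exactly half a sample).
  Out-of-record delays contribute zero. A linear-interpolation mode exists
  behind a flag but is off by default.
- All K channels are summed with unit apodization; the envelope is the
  magnitude of the analytic signal along each scan line, and the display is
  that envelope max-normalized and log-compressed to 60 dB. The envelope
  method and dynamic range are package conventions (standard B-mode
  practice), exposed as parameters.
- **Scan conversion** inverts the fan geometry per Cartesian pixel. Within
  the bracketing pair of scan lines the angular fraction solves the exact
  quadratic inverse of position-bilinear interpolation, so affine test
  patterns are reproduced exactly for arc and polyline fans alike;
  interpolated values are always convex combinations of the four
  surrounding nodes. Pixels outside the closed fan region are masked;
  boundary pixels are included. Default raster spacing is λ/2 ≈ 0.154 mm.

## The entropy objective

The image entropy is `H = −Σ p_i log2 p_i` over a 256-bin histogram of the
normalized image. Which pixel values to histogram is a genuine design
choice, and we settled it empirically on the package's speckle phantom
(32 elements, 70 mm arc): with the element-width directivity in the
forward model, the *max-normalized linear envelope* entropy correlates
negatively with element-position error at every tested perturbation scale
(Spearman about −0.4 at the optimization-bound scale), i.e. the shape
nearest the truth yields the richest amplitude distribution — mis-delayed
summation destroys coherent amplitude and flattens the histogram. The
*log-compressed* (display) domain correlates more weakly and changes sign
at larger errors. flexbeam therefore computes entropy on the envelope by
default (`on = "envelope"`), keeping `on = "display"` available for
comparison. A caution from our own experiments: in a forward model without
element directivity, grating lobes dominate the image and the envelope
correlation flips positive (the minimum-entropy convention familiar from
synthetic-aperture-radar autofocus); the sign of the error-entropy link is
a property of the imaging chain, which is why `entropy_error_scan()`
exists to verify it before trusting the optimizer. The minimizing control
run (`direction = "minimize"`) is the built-in falsification test: it
should — and does — end farther from the truth.

`entropy_error_scan()` characterizes this relationship at the optimizer's
own scale (default perturbation half-width π/720, the bound below), which
is the regime the search actually explores.

## The optimizer

`optimize_shape()` is a seeded, bounded, derivative-free search: candidate
batches are drawn around the incumbent at an adaptive scale, clipped to the
box `init ± π/720`, ranked by a cubic radial-basis surrogate fitted to all
evaluated points, and only the top candidate pays for a full DAS
reconstruction; the proposal scale expands on success, contracts on
failure, and a uniform exploration draw restarts it after 40 stagnant
evaluations. The contract the rest of the package relies on: every
evaluated point respects the bounds, the best-so-far objective is monotone
along the trace, the trace length never exceeds the budget, and a rerun
with the same seed reproduces the trace exactly. "200 iterations" is
interpreted as 200 objective evaluations, each one full beamforming pass.

A grid-decimation option (every 2nd line/depth during objective evaluation)
exists for exploration but defaults to off: at the package's study scale
decimation visibly weakens the error–entropy link and the recovery fails,
so fidelity wins over speed.

## Metrics

Defocusing is measured by the lateral FWHM of point targets (linear
envelope, sub-pixel half-max crossings by linear interpolation; a profile
that never falls below half maximum within the scan region is
right-censored at the measurable profile width). Distortion is measured by
the aspect ratio of a segmented inclusion (bounding-extent widths), and by
Dice, Jaccard (`J = DSC/(2−DSC)` exactly), and the Hausdorff distance
(8-connected boundary pixels, Euclidean mm; symmetric by default, directed
behind a flag) after a closed-form rigid pre-registration (centroid +
principal axes, 180° ambiguity and degenerate cases resolved by maximizing
Dice, with the identity always among the candidates so registration never
hurts). Contrast uses CNR in dB and the distribution-overlap GCNR with 256
shared bins; both are computed on the linear envelope by default, since the
quantities feeding them are amplitudes.

## Study conditions for the built-in experiments

The packaged experiments run at a desk scale chosen once: a 32-element
probe (all other constants as the full device) on a 70 mm arc — an adult
abdominal curvature — with a 36 × 34 mm speckle phantom (3 scatterers/mm²,
one anechoic and one hyperechoic inclusion) for the autofocus experiments,
and four axial wires (10–40 mm) for resolution work; the imaging grid spans
8–42 mm at λ/2 depth steps. Marker simulations use five spheres of radius
6 mm (a typical passive-sphere size; the bench value is not public) with
0.25 mm isotropic jitter, the nominal accuracy of a clinical infrared
tracker. With these conditions the within-bounds initial shape error is a
few hundredths of a millimetre — comparable to what the optical stage
leaves at this aperture — and the full 128-element device at the same
bounds would start several times higher.

## Numerical and degenerate-input conventions

Collinear or coincident markers raise a degenerate-configuration error
(the circle fit is undefined); the Pratt fit centers and scales its data
for conditioning and stays exact on noiseless circles across radii 10 to
10⁴ mm, including shallow arcs. An all-zero image has zero entropy and an
all-floor display. CNR returns −Inf for equal means and +Inf for zero
pooled deviation (documented sentinels). Scan-region membership uses a
10⁻⁹ mm tolerance so pixels lying exactly on a boundary scan line stay
inside the closed region.

## Known limitations

The acoustic model is geometric, so absolute image-quality numbers (CNR,
GCNR, FWHM in mm) are not comparable to hardware measurements; only
directions and identities are. At the desk scale the autofocus stage
*maintains* rather than improves the shape estimate: a 32-element array
started within the ±π/720 bounds already errs by only a few hundredths of
a millimetre — an order of magnitude below the half-wavelength criterion —
which is beneath the entropy objective's resolution, so the maximizing run
ends statistically tied with its start (and an order of magnitude inside
the criterion) while the minimizing control measurably degrades it. The
full 128-element device starts with errors several times larger, where the
objective has resolvable signal. Entropy-based autofocus inherits the
sound-speed confound: a wrong uniform speed of sound mimics a shape error
and the optimizer would partially absorb it. The array is treated as planar
in elevation. The optical stage assumes the first and last markers sit at
the array ends; lateral placement between markers is otherwise
unconstrained, and the arc is centered between the end markers by
convention.
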
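---
title: "Methods: simulation and reconstruction for ring-array liver imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and reconstruction for ring-array liver imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and problem

`ringtomo` implements a complete synthetic test bench for hybrid ring-array
imaging of murine fatty liver disease (NAFLD). A single 512-element circular
transducer (40 mm radius, 5 MHz centre, 60% bandwidth, 40 MS/s) supports
three modes: multispectral optoacoustic tomography (MSOT; pulsed-light
excitation, acoustic detection), reflection ultrasound computed tomography
(RUCT; synthetic transmit aperture pulse-echo with multi-view compounding),
and transmission ultrasound computed tomography (speed-of-sound mapping by
waveform inversion). Because no real acquisitions are distributed, the
package also contains a first-class phantom/cohort generator whose defaults
encode the study's printed group statistics: liver speed of sound (SoS)
1538 +/- 18 m/s for controls, 1475 +/- 34 and 1473 +/- 26 m/s for NAFLD at
24 and 36 weeks; cross-sectional areas 333 +/- 21, 562 +/- 29 and
598 +/- 25 mm^2; weights 30.7, 42.3 and 42.9 g; ex vivo liver SoS
1525 +/- 15 (control) and 1495 +/- 12 m/s (NAFLD) with a 47% lipid
contrast; in vivo lipid contrasts of 16% and 37%.

## Forward models

Both acoustic simulators use straight-ray kinematics. This matches the path
model of the inversion, keeps simulations desk-scale, and makes analytic
time-of-flight oracles exact; refraction and full-wave diffraction are
declared non-goals. The band-limited transmit/receive pulse is modelled
analytically as a zero-phase cosine carrier at the centre frequency under a
Gaussian envelope whose spectral FWHM equals the fractional bandwidth;
having an analytic, smooth, zero-phase pulse makes the waveform-inversion
gradient exact, lets the matching-pursuit picker reach well below 0.05
samples, and lets delay-and-sum sample the wavelet maximum at exact focus
(an odd-phase wavelet would put a zero crossing there).

**MSOT.** The initial pressure is `p0 = mu_a(x, lambda) * Phi(x)` with
`mu_a` assembled from the phantom's chromophore concentration maps and the
packaged spectra, and `Phi` a modified-Bessel disc fluence model
(`I0(mu_eff rho)/I0(mu_eff R)` on the equal-area disc of the body mask) --
the same model the reconstruction divides out, so the correction is
model-consistent by construction. Each element trace is the circular-mean
projection of `p0` using the two-medium (water/tissue) delay table shared
with the back-projector, time-differentiated (the thermoelastic pressure is
the time derivative of the spherical mean -- this is also what makes the
universal back-projection weighting focus), and convolved with the array
band response. The
Grueneisen coefficient and pulse energy are folded into one arbitrary-unit
constant; only ratios are quantitative.

**STA.** Each transmission produces a through-transmission wave (pulse
delayed by the slowness line integral along the chord, amplitude
`1/sqrt(path)`) and scatterer echoes (two-leg straight-ray delays,
reflectivity over two-leg geometric spreading). The record length must
contain the diametric arrival (~53 us at 80 mm); the packaged configuration
for transmission work therefore uses 2400 samples rather than the 2030 of
the native MSOT record, which is explicitly allowed to vary. An optional
receive-aperture restriction (`rx_aperture_deg`) records only the channels
the pulse-echo beamformer will use, which keeps full-ring pulse-echo
simulations affordable.

## Phantoms and cohorts

Bodies are smoothly perturbed ellipses (ex vivo: a 20 mm agarose-style
cylinder) with area drawn from the group Normal distribution; the liver is
a smooth blob occupying 15-30% of the body with a constant SoS drawn from
the group distribution; non-liver tissue sits at a configurable 1540 m/s
soft-tissue default, with an optional smooth heterogeneity field (sd 8 m/s,
~3 mm correlation) for in vivo groups; water is 1523 m/s, the value for the
34 C tank temperature (the temperature is stated by the study, the water
speed is this package's choice). Liver area fraction and vessel density
have no reported values; those defaults are package decisions. Weights
are Normal with a 10% coefficient of variation around the printed means
(group standard deviations are not printed).

Scatterers: the interior field has density ~3/mm^2 (capped to 200-1000),
chosen so pulse-echo speckle is fully developed (at least ~1.5 scatterers
per resolution cell; sparser fields leave dark holes that corrupt boundary
detection); the skin is a chain of brighter scatterers placed exactly on
the parametric contour at 0.4 mm arc spacing, and the liver capsule a
weaker one.

Chromophore concentrations were set so the reconstructed region-of-interest
spectra reproduce the reported qualitative behaviour: a control liver
spectrum decreases monotonically over 740-940 nm while the disease lipid
contrast lifts a distinct bump at 920 nm. Because the reconstruction's
band-pass removes the lowest spatial frequencies, it slightly suppresses
spatially smooth (lipid-like) components relative to vascular structure;
the ex vivo baseline (0.030 relative units against ~0.3 hemoglobin) was
placed in the middle of the discrimination window computed from the
reconstruction's own linear response, giving roughly +/-20% margins on both
sides. This margin is realization-dependent: extreme liver geometries can
tip the control spectrum marginally non-monotone, which is the same
borderline regime the real measurement sits in.

Every phantom is deterministic given `(spec, section_index, seed)`, and the
random draws are made in a fixed order before any group parameter is
applied, so two specs differing only in their distribution parameters yield
geometrically paired phantoms under the same seed -- exactly what the paired
ex vivo lipid comparison requires. A consequence is that cohorts of
different groups under one seed are section-wise correlated; group-level
statistics (means, standard deviations, t-tests) are unaffected in
expectation, and the statistical-power property holds either way.

## MSOT reconstruction

Per wavelength: zero-phase Butterworth band-pass (0.1-6 MHz), motion-frame
rejection by normalized cross-correlation of each frame's sinogram with the
median sinogram (threshold 0.90), frame averaging, universal back-projection
(`b(t) = p(t) - t p'(t)`, linear trace interpolation) with the two-medium
delay table (water outside the body mask, tissue inside), then the
modified-Bessel fluence correction. The reported protocol applies
adaptive histogram equalization and a Frangi vesselness filter before
masking; since histogram equalization is non-linear and would destroy the
spectral linearity unmixing relies on, this package keeps two products: the
quantitative stack (no enhancement) feeding `unmix_linear()`, and a display
composite (`enhance_and_composite()`, CLAHE + Frangi at 0.1-0.5 mm scales)
for visualisation only. Which product fed the original unmixing is not
stated; the quantitative stack is the physically defensible reading.

Unmixing solves a non-negative least-squares problem per pixel against the
four-column spectra matrix (full column rank on the 11-wavelength grid is
checked and reported). The lipid metric removes the "non-distinct"
background as the median unmixed lipid value over the body outside the
liver -- the phrase being emulated is qualitative, and the median convention is
this package's explicit choice (documented so percentile or offset variants
can be substituted); the metric is the background-subtracted liver mean,
clipped at zero.

## RUCT reconstruction and body segmentation

Per transmission, delay-and-sum over `round(n * 90/360)` contiguous
receive channels centred on the transmitter (128 at full scale) with Hann
apodization and uniform water-speed delays; all views are summed
coherently, enveloped by absolute value, and log-compressed to 40 dB. The
direct transmitted wave is ~20x stronger than tissue echoes and is gated
out around its known water arrival time before beamforming.

Manual outlining of the skin boundary cannot be reproduced here; the
automatic stand-in is validated only against synthetic truth and works in
polar coordinates: the
body edge on each ray from the envelope-weighted centroid is the steepest
descent of the smoothed envelope from speckle plateau to water clutter
floor, with internal interfaces rejected by requiring the outside level to
drop below 80% of the plateau; a truncated Fourier contour (order 4, then
6 after refinement at finer smoothing) is fitted with trimmed least
squares. The classic Otsu-threshold/morphology recipe is retained as
`method = "otsu"`, but at desk scale (128 elements, 32-channel apertures)
the compounded image's clutter floor is only ~8 dB below the speckle
plateau and region thresholding is unreliable; the contour method is the
default. The fitted contour is shrunk by 0.27 mm -- half the two-way
point-spread width, calibrated once against synthetic ground truth on a
validation set of sections disjoint from any test -- which removes the
outward bias of edge detection on a one-sided clutter halo. Segmentation
quality depends on sampling the point-spread function: pulse-echo grids
should use ~0.25 mm pixels (the package does so in its own analyses).

## Speed-of-sound reconstruction

Water-reference waveforms for every emitter/receiver pair in the 60-degree
opposite arc (171 of 512 elements; 43 of 128 at desk scale) are water-path
acquisitions with analytic travel time `d/c_water`. Arrival times are
picked by matching pursuit: the measured trace is iteratively decomposed
into scaled, time-shifted copies of the reference waveform via
cross-correlation peak extraction (at most 5 components, stopping at 5%
residual energy or 20% relative amplitude), the pick being the minimum
retained shift with parabolic sub-sample refinement -- robust to
overlapping multipath arrivals where a plain peak picker is not. Picks
outside [0.8, 1.25] of the water time are invalidated rather than
propagated.

The travel-time system `L ds = dt` (bilinear path-length matrix in sparse
form) is solved by 20 damped SIRT sweeps, clamped to [1300, 1700] m/s, and
restricted to a support mask (the dilated body). This initializes a
gradient-descent waveform inversion: each pair's waveform is predicted as
the average of the reference pulse shifted by the travel time of 7 paths
(straight ray plus fan rays through control points laterally offset within
the first Fresnel-zone half-width at the mean pair distance, ~2.4 mm);
the loss is the mean squared sample error in a window of +/-3 pulse
durations around the water arrival (window short enough to exclude most
scattered energy); the gradient distributes each path's shift sensitivity
over the traversed pixels (exact for the bilinear parameterization and the
analytic pulse, verified against finite differences at 1e-4); the step uses
a Barzilai-Borwein secant with backtracking halving (at most 8), so the
loss history is non-increasing by construction; 40 iterations are the
default. The gradient is preconditioned by the straight-ray coverage
density, which equalizes update magnitudes between well- and
poorly-sampled pixels. The fan-path count, Fresnel fan geometry and loss
window are package choices with no reported counterpart. With the
straight-ray data simulator, `n_paths = 1` makes the forward model exactly
consistent with the data; the fan default of 7 is retained as the method's
finite-frequency sensitivity model and recovers liver means equally well.

## Statistics

Per-section liver means feed group summaries (sample mean, n-1 standard
deviation) and pooled-variance Student t-tests (Welch by flag); the
reported analysis used an unpaired t-test without a stated variant, with
raw pairwise p-values without multiple-testing correction, which is
mirrored. Statistics are computed per cross-section (20 per group),
following the printed phrasing; per-mouse aggregation is possible from the
`mouse_id` column. The reported p-values themselves cannot be reconciled
with any standard t-test variant at the printed means, STDs and n, so
p-values are treated as non-targets; what is reproduced instead is the
statistical-power property (the control vs NAFLD-24w comparison reaches
p < 0.001 in at least 95% of seeded replicates at n = 20 per group).

## Numerical choices and scales

All positions are mm, times seconds, speeds m/s; element 1 of a ring sits
on the +x axis with counter-clockwise ordering (no origin convention is
reported). Line integrals use midpoint sampling at half a
pixel; image interpolation is linear; the SoS clamp [1300, 1700] m/s is a
stabilization prior, a package choice, not a reported value. Signal containers are a
self-describing single-file binary format (JSON header + IEEE-754 float64
payload) with bit-exact round trips; images export as 32-bit float TIFF
(written directly by the package, since the available TIFF writer clamps
floats to [0, 1]) with a CSV sidecar carrying mode, units and pixel
geometry. The exported functions and this vignette are the package's
interface; no shell entry point is shipped.

The package's own analyses run at desk scale: a 128-element ring, 96x96
SoS grids (0.31-0.375 mm pixels), 192x192 pulse-echo grids (0.25 mm), and
11-wavelength MSOT at 128x128 (0.25 mm). At these sizes a full
speed-of-sound reconstruction takes about a minute per section on one CPU
and the full acceptance analysis runs in well under twenty minutes.

## Known limitations

Straight-ray acoustics cannot reproduce refraction or diffraction
artifacts; phantom speckle is statistical, not tissue-realistic; the
fluence model is wavelength-independent, so spectral coloring with depth is
absent (and correction is exact only because forward and inverse share the
model); the automatic body segmentation assumes a star-convex body seen
from its centroid; passing tests on these phantoms demonstrates
correctness of the algorithms under the stated models, not performance on
real acquisitions.

The packaged chromophore spectra are synthetic analytic approximations of
the literature near-infrared shapes (file
`chromophore_spectra_synthetic_v1.csv`), preserving the features the
analysis depends on -- the 920 nm lipid maximum on the acquisition grid,
the hemoglobin crossing, monotone melanin -- not digitized measurements.
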
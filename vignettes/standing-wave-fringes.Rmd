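---
title: "Standing-wave fringe analysis: model, measurement chain and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standing-wave fringe analysis: model, measurement chain and design notes}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swfringe)
```

## The optical model

When a coherent excitation beam of vacuum wavelength $\lambda$ reflects off
a plane mirror through a medium of refractive index $n$, the direct and
reflected fields interfere into an axial standing wave. A perfect mirror
imposes a $\pi$ phase shift on reflection, so the mirror surface is the
first *node*; the intensity at height $z$ above the mirror is

$$I(z) = \sin^2\!\left(\frac{2\pi n z}{\lambda}\right),$$

with antinodal (bright) planes at $z_k = (2k+1)\lambda/4n$, spaced
$\lambda/2n$ apart, each with an axial full width at half maximum of
$\lambda/4n$. A fluorescently labelled surface above the mirror therefore
lights up where it cuts the antinodal planes: the 2D image of a smooth
dyed surface is a set of height contours at exactly known, regularly
spaced heights. For 488 nm excitation in aqueous mounting medium
($n = 1.34$) the FWHM is about 91 nm — several-fold finer than the axial
response of a confocal pinhole.

`detected_intensity()` implements three detection modes:

* **`broadband_excitation_only`** — a wide detection band averages away
  any emission-side interference, leaving the excitation standing wave
  above.
* **`emission_only`** — the excitation standing wave is suppressed (a
  notch-type reflector transmitting the excitation line) and only the
  *self-interference* of each emitted photon with its mirror image
  survives, a $\sin^2$ pattern at the selected emission wavelength,
  averaged over the detection band.
* **`narrowband_moire`** — both fields are present. With a detection band
  of a few nanometres the product of the two $\sin^2$ factors carries a
  beat at the difference frequency

$$\frac{1}{L} = \frac{1}{\lambda_{ex}} - \frac{1}{\lambda_{em}},$$

  so the fringe *amplitudes*, read at successive antinodes, trace an
  envelope with height period $L/2n$. For the 514/580 nm pair,
  $L \approx 4517$ nm and the envelope repeats every $\approx 2258$ nm of
  height.

Whether the directly observed beat is multiplicative or additive in the
two fields is not decided by a period measurement: both the product
$\sin^2\!A\,\sin^2\!B$ and the difference $\sin^2\!A-\sin^2\!B$ beat with
the identical period $L/2n$ (a test verifies this numerically). We render
the direct moiré as a product with equal weights, expose the
subtraction route separately (`simulate_subtraction_pair()`), and treat
only the beat period as the validated observable.

Simplifications, stated once: antinodal planes are taken as flat at every
numerical aperture (no NA-dependent axial compression); the emission
spectrum is flat across the detection band, integrated by midpoint
quadrature with at least 21 points; dipole-orientation, quantum-yield and
lifetime effects near the mirror are neglected.

## Specimen geometry

**Spherical cap.** A planoconvex lens of curvature radius $R$ resting on
the mirror has surface height $L(r) = R - \sqrt{R^2 - r^2}$ at lateral
distance $r$ from the contact point, so successive bright fringes of
radii $r_1 > r_2$ are separated in height by
$\sqrt{R^2-r_2^2} - \sqrt{R^2-r_1^2}$. Fringes crowd with increasing
radius — equal height steps map to shrinking radial steps — which is the
signature of a spherical shell cut by evenly spaced planes.

**Discocyte.** The red-cell membrane is modelled as an infinitesimally
thin biconcave shell: an Evans–Fung-style thickness profile
$T(\rho) = \sqrt{1-\rho^2}\,(C_0 + C_2\rho^2 + C_4\rho^4)$ with
$\rho = 2r/D$. Only three printed dimensions constrain the family
(diameter $\approx 7.8\ \mu$m, centre thickness $1\ \mu$m, maximal rim
thickness $2.5\ \mu$m), so $C_0$ is set by the centre thickness and
$C_2, C_4$ are solved (a linear 2×2 system) so the maximum thickness
equals the rim value at $\rho^\ast = 0.85$, the rim position of the
classical parametrisation. The solve is validated numerically
(positivity, correct interior minimum) and rejects incompatible inputs.
The shell's lowest point rests at a configurable standoff above the
mirror (default 0 nm — cells settled onto an adhesive-coated mirror; no
measured value exists for this gap, so it is exposed as a parameter).

## The synthetic imager

`render_monolayer_image()` and `render_membrane_image()` turn surfaces
into images: per pixel, the standing-wave response at the local surface
height (summed over the two membrane sheets with equal weight, the dye
partitioning between leaflets being unknown), multiplied by the areal
foreshortening $1/\cos(\text{slope})$ of a uniformly dyed sheet. The
foreshortening factor is capped at 20 to keep near-vertical rim pixels
finite at finite resolution. An optional lateral Gaussian blur stands in
for the scanning PSF; all antinodes are summed with equal weight (no
axial PSF envelope), matching the simultaneous multiplanar visibility
the method exploits. Noise is Poisson shot noise on
`photon_scale * intensity + background` plus optional Gaussian read
noise, fully determined by a recorded seed.

What the generator does *not* emulate: detector nonlinearity and
flat-field structure, scanner distortion, out-of-focus haze, spectral
crosstalk, membrane fluctuations, and mirror imperfections. Passing the
recovery tests therefore demonstrates correctness of the measurement
chain under the stated optical model, not robustness to every real-world
artefact.

Default fixtures are 512×512 (1024×1024 for the 37-fringe scene, which
needs ~7 samples per fringe period at the field edge); these sizes keep
full renders and analyses in the seconds range while leaving the outer
fringes comfortably oversampled.

## The measurement chain

1. **Centre finding** (`find_fringe_center()`): the contact point is the
   centre of radial symmetry. A candidate centre is scored by the
   variance of azimuthal bin means, normalised by the total pixel
   variance — concentric structure keeps fringe contrast in the bin
   means; a wrong centre averages it away. Nelder–Mead refinement from
   the intensity centroid gives subpixel accuracy (≤ 0.5 px on the test
   scenes); a score below 0.05 raises *centre-not-found* (a uniform or
   structureless image).
2. **Radial profiling** (`radial_profile()`): azimuthal means over
   annular bins, default one pixel wide. Azimuthal averaging is the
   default because it suppresses shot noise by $\sqrt{2\pi r}$; a
   single-ray mode is kept for strict fidelity to a line profile.
3. **Peak detection** (`detect_peaks()`): local maxima filtered by
   topographic prominence (default 10 % of the profile range), then
   refined by bounded minimisation of the negated cubic-interpolated
   profile within one bin either side — the classical
   flip-and-`fminbnd` trick, with cubic interpolation chosen for its
   smooth derivative. A test pins the refinement against a 100×
   oversampled brute-force argmax (≤ 0.1 bin).
4. **Height mapping** (`radii_to_heights()`): radii pass through the cap
   geometry; antinode indices follow height order. Peaks closer than
   $\lambda/8n$ in height (possible double detections where fringes
   crowd at the field edge) are merged, keeping the stronger.
5. **Spacing** (`estimate_spacing()`): slope of the least-squares fit of
   height against antinode index. Regression was chosen over the mean of
   successive differences because the slope estimator pools all peaks
   (successive differences telescope to the endpoints); both are
   exposed.
6. **Envelope** (`estimate_envelope_period()`): the beat period is the
   mean spacing of the refined maxima of the amplitude-versus-height
   sequence — deliberately the peak-amplitude route rather than Hilbert
   demodulation of the raw profile, since the fringe peaks are where the
   specimen actually samples the field. An amplitude sequence without
   maxima of at least 10 % relative prominence raises an error: that is
   exactly the emission-suppressed control, in which the modulation is
   absent.

## Contour-based 3D reconstruction

`extract_fringe_contours()` finds ridge crests of the smoothed image:
pixels whose transverse (most negative Hessian eigen-) curvature
dominates the along-ridge curvature, whose gradient is small compared
with that curvature (a true crest lies within half a pixel of the
stationary line, while flank pixels carry the full fringe slope), and
which survive non-maximum suppression along the transverse direction.
Chains shorter than 10 px are dropped; each chain is ordered by angle
about its centroid, which is exact for the closed, near-circular
contours these specimens produce (self-intersecting or strongly
non-convex contours are out of scope).

`assign_antinode_indices()` requires a strict nesting (every pair of
contours fully contained or fully disjoint, verified by point-in-polygon
sampling; anything else raises *ambiguous-topology*) and assigns
consecutive indices along the nesting order. Heights follow as
$(2\,\text{index}+1)\lambda/4n$ — every assigned height is an exact
antinode height, so the reconstruction error budget is contour
localisation plus inter-contour interpolation.

Two deliberate limitations are reported rather than hidden:

* **Absolute index.** A single broadband image cannot reveal which
  antinode is the first visible one; `base_index` defaults to 0 and is
  recorded in the output metadata. When the amplitudes carry a moiré
  envelope, `rank_base_index()` scores candidate bases against the
  mirror-locked envelope phase $\cos^2(2\pi n z/L)$ — the
  amplitude-based disambiguation of fringe order.
* **Nesting direction.** A surface rising outward and one falling
  outward produce the same contours. We found no intrinsic smoothness
  criterion that breaks this tie — a surface and its axial mirror image
  have identical curvature statistics, so "pick the smoother mode"
  cannot work in general — hence the direction is an explicit parameter
  (default `nested_outward`, the physics of a specimen touching the
  mirror at a central contact), with the envelope-phase hint available
  when a moiré is present. On ground-truthed scenes the wrong direction
  inflates RMSE by well over 2×, which the tests assert.

`interpolate_surface()` interpolates linearly *between contour lines*:
each grid point takes the distance-weighted mean of its two nearest
contours' heights, $z = (d_2 z_1 + d_1 z_2)/(d_1+d_2)$, computed from
Euclidean distance maps of the rasterised contours. This is the
classical contour-map-to-DEM interpolation; it reproduces exact
linearity between adjacent levels, is bounded by the assigned heights,
and needs no triangulation. Outside the convex hull of the contour
points the surface is masked. A smoothing alternative was considered and
rejected: with contour heights exact by construction, smoothing only
blurs the one place the data are authoritative. Membrane images in
principle contain two sheets; the default reconstruction treats the
visible contour family as a single surface, a documented simplification.

## Numerical choices and degenerate inputs

* Band integration: midpoint rule, ≥ 21 points; a 5 nm band is resolved
  to well below 1 %.
* Peak refinement interval: one bin either side of the discrete
  maximum; ties on plateaus break toward the first sample.
* `moire_period()` refuses equal wavelengths (the period diverges) and
  reversed ordering; `detected_intensity()` refuses negative heights;
  masked (NA) surface points render as background.
* Degenerate shells (`upper == lower`) are legal and simply double the
  sheet signal; a lower sheet above the upper one is a hard error.
* All RNG use is localised: renders restore the caller's RNG state and
  record their seed in the image metadata.

## Problem sizes used in the tests

Unit and property tests run on 96–512 px scenes (seconds each); the
37-fringe scene uses 1024 px once. The end-to-end recovery property uses
twenty 256 px noisy fixtures for the spacing and two 512 px fixtures for
the envelope. At these sizes the whole suite completes in about a
minute of CPU time, with every quantitative bound met with margin.

## Worked example

```{r example, eval = FALSE}
fx <- cap_fixture(n_antinodes = 22, image_size = 512,
                  photon_scale = 500, background = 5, seed = 0)
rep <- analyze_fringe_image(fx$image, fx$spec, fx$cfg)
c(rep$n_peaks, rep$spacing_nm, rep$rel_error_pct)

rec <- reconstruct_surface(fx$image, fx$cfg)
reconstruction_rmse(rec$surface, fx$surface)
```
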
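# swfringe

Standing-wave fluorescence fringe analysis and membrane surface
reconstruction.

Placing a plane mirror under a fluorescent specimen in a laser-scanning
microscope sets up an axial standing wave: the excitation beam interferes
with its reflection, giving a sin² intensity pattern with its first node
at the mirror and bright antinodal planes at heights

    z_k = (2k + 1) · λ / 4n,     spacing λ / 2n,     axial FWHM λ / 4n

(λ excitation wavelength, n medium refractive index). A dyed surface —
a calibration lens resting on the mirror, or the membrane of a red blood
cell — lights up where it crosses these planes, so its 2D fringe image is
a contour map with exactly known, ~quarter-wavelength-spaced height
levels (FWHM ≈ 91 nm for 488 nm excitation at n = 1.34). With a narrow
detection band a second effect appears: the emitted fluorescence
self-interferes with its own mirror image, and the two standing-wave
fields beat at the Stokes-shift difference frequency,

    1/L = 1/λ_ex − 1/λ_em,

modulating successive fringe amplitudes with a height period of L/2n —
an amplitude signature that can rank the absolute fringe order.

`swfringe` is for microscopists and image analysts working with such
mirror-backed ("standing-wave" / fluorescence-interference) data. It
provides:

* **forward optics** — `optics_config()`, `antinode_spacing()`,
  `axial_fwhm()`, `moire_period()`, `detected_intensity()` with
  broadband, emission-only and narrowband-moiré detection modes;
* **specimen geometry** — spherical-cap calibration specimens and a
  biconcave (Evans–Fung-style) red-cell membrane shell, as gridded
  height maps;
* **a synthetic imager** — seeded, noise-modelled fringe-image renders
  of monolayers and membrane shells, including the
  excitation-only / emission-only subtraction experiment;
* **the measurement chain** — subpixel fringe-centre finding, azimuthal
  radial profiling, prominence-filtered peak detection with bounded
  cubic refinement, radius→height conversion, regression spacing
  estimation and moiré-envelope period estimation;
* **3D reconstruction** — fringe-ridge contour extraction, nested
  antinode-index assignment, contour-to-surface interpolation and RMSE
  scoring against ground truth.

## Worked example

```r
library(swfringe)

cfg <- optics_config(514, refractive_index = 1)
antinode_spacing(cfg)        # 257      (nm, λ/2n)
moire_period(514, 580)       # 4516.97  (nm, beat period L)
axial_fwhm(optics_config(488, refractive_index = 1.34))  # 91.04478 (nm)

# a noisy synthetic calibration scene: dyed spherical cap (R = 30 mm) on
# the mirror, 512×512, 22 antinodes across the field, Poisson noise
fx  <- cap_fixture(n_antinodes = 22, image_size = 512,
                   photon_scale = 500, background = 5, seed = 0)
rep <- analyze_fringe_image(fx$image, fx$spec, fx$cfg)
#> n_peaks = 22,  spacing = 257.03 ± 0.02 nm,  rel_error = 0.010 %

rec <- reconstruct_surface(fx$image, fx$cfg)
reconstruction_rmse(rec$surface, fx$surface)
#> 21.7 (nm)
```

The analysis recovers the theoretical 257 nm antinode spacing to 0.01 %
from the noisy image, and the contour-based reconstruction of the cap is
accurate to ~22 nm RMS — well below the λ/8n ≈ 64 nm half-step of the
fringe ladder. A narrowband-detection render of the same geometry
(`mode = "narrowband_moire"`, detection 580 ± 2.5 nm) analysed with
`envelope = TRUE` returns an amplitude-envelope beat period of
`envelope_L_nm ≈ 4479` nm against the 4517 nm closed form.

## Command line

A thin CLI over the same functions ships in `inst/cli/swfringe.R`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "swfringe.R", package = "swfringe"))')
Rscript $CLI simulate    --config cap.yaml --seed 0 --out sim/
Rscript $CLI analyze     --image sim/image.tif --config cap.yaml --report report.json
Rscript $CLI reconstruct --image sim/image.tif --config cap.yaml --truth sim/truth.tif --out rec/
```

Exit codes: 0 ok, 2 config error, 3 analysis failure, 4 I/O error.
Images travel as grayscale TIFF (16-bit counts; 32-bit float + mask for
height maps) with JSON sidecars carrying pixel size, full config, config
hash and seed; every run is bit-reproducible for a fixed seed.

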
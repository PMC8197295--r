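---
title: "Models and numerical choices in the SPOT-FTS pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in the SPOT-FTS pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotfts)
```

This vignette explains the models behind `spotfts`, the parameters that
matter, the numerical decisions taken where the design was genuinely
open, and what the synthetic-data tests do and do not demonstrate about
real acquisitions.

## The imaging model

A snapshot projection optical tomography (SPOT) system places a
micro-lens array in a plane conjugate to the objective back focal plane
(BFP). Each lenslet selects a patch of the pupil and therefore forms a
parallel-projection image of the sample along its own direction; a
single camera frame tiles all of these sub-images. The image formed by
lenslet $(m,n)$ is modeled as

$$ I_{m,n}(x, y) = \big(P_{m,n} O\big)(x,y) * h(x,y), $$

a line-integral projection of the 3D fluorophore density $O$ followed by
a 2D blur $h$. The viewing direction has the slopes
$(\tan\alpha_m, \tan\beta_n, 1)$ with

$$ \alpha_m = \arctan\frac{m\,p}{\sqrt{f_1^2 - (m^2+n^2)\,p^2}}, $$

and $\beta_n$ analogously, where $f_1$ is the objective focal length and
$p$ the lenslet pitch *referred to the BFP*.

A Michelson interferometer in the detection path converts every pixel
into a Fourier-transform spectroscopy (FTS) channel: over an
optical-path-difference (OPD) sweep $\delta$, an incoherent emitter of
brightness $B$ and unit-integral spectral density $S(\sigma)$ produces

$$ I(\delta) = B \int S(\sigma)\,\big[1 + \cos(2\pi\sigma\delta)\big]\,d\sigma, $$

so $I(0) = 2B$ and the oscillating part is the cosine transform of the
spectrum. Spectra of distinct fluorophores mix linearly along rays, as
incoherent fluorescence adds in intensity.

## Optical geometry

The default `spot_config()` encodes a 60x/NA 1.4 oil objective (200 mm
reference tube convention, so $f_1 = 10/3$ mm), a 2.86x pupil-relay
demagnification, a 500 µm pitch / 13.8 mm focal MLA acting as tube lens,
a 4x second relay, and 13 µm camera pixels. Derived figures: overall
magnification 47.36, per-lenslet field of view 42.2 µm, camera pixel
0.274 µm at the sample, lenslet diffraction limit 1.235 µm (aperture
width) or 0.874 µm (aperture diagonal) at 530 nm.

Two decisions deserve comment.

* **Reference plane of the pitch.** The angle formula needs the lenslet
  position in the space where the objective's focal sphere lives; the
  pitch is therefore referred to the BFP, $p = 500\,\mu m \times 2.86 =
  1.43$ mm. Only this reading keeps the interior lenslets' angles
  bounded by the objective aperture.
* **Excluded lenslets.** On the 6×6 half-integer grid, lenslets whose
  centre radius exceeds the pupil radius $\mathrm{NA}\cdot f_1$, or
  reaches $f_1$ (where the direction model's square root turns
  imaginary), are flagged and *excluded* rather than silently clamped.
  For the default configuration this leaves 16 of 36 lenslets with
  defined viewing directions, up to 57° in $\alpha$; reconstructions use
  that valid set. The exclusion is configurable through
  `lenslet_grid()`'s index argument.

## Interferogram processing

Each masked pixel's interferogram goes through: linear detrend →
envelope-peak centering → apodization → non-uniform Fourier transform,
with the amplitude spectrum retained. Parameters and choices:

* **Signal mask** (`build_signal_mask`): a pixel is kept when its
  max-over-OPD intensity exceeds the median plus $k$ MADs of the
  max-image; default $k = 6$, chosen as a conventional robust outlier
  threshold — the mask only needs to separate emitting pixels from the
  noise floor.
* **Envelope** (`upper_envelope`): natural cubic spline through the
  local maxima, held at the outermost peak values instead of
  extrapolating (spline extrapolation overshoots at the scan edges);
  with fewer than four peaks the analytic-signal magnitude is used.
  A spline through sampled maxima can only track envelopes whose
  carrier is sampled several times per cycle; tests therefore exercise
  it with carriers at or above ~10 samples per cycle.
* **Zero-OPD centering** (`detrend_and_center`): the envelope peak is
  refined to sub-sample precision with a three-point parabolic fit, and
  the OPD axis is shifted so the peak sits at $\delta = 0$. Peaks tied
  within 0.1% are broken toward the scan centre — this makes the
  operation deterministic for monochromatic sources, whose envelope is
  flat (the amplitude spectrum is invariant to the choice; only the
  apodization window placement depends on it). A burst found only at a
  scan boundary is an error: the zero-OPD position was not captured.
* **Apodization** (`apodize`): Norton–Beer family
  $A(u) = \sum_i c_i (1-u^2)^i$ with the literature-standard
  coefficient sets; medium ($c_0 = 0.152442$, $c_1 = -0.136176$,
  $c_2 = 0.983734$) is the default. Coefficients sum to one, so zero
  OPD keeps unit weight.
* **Transform** (`nufft_spectrum`): the stage sweep is slightly
  non-uniform, so the spectrum is evaluated as a type-1 non-uniform
  discrete Fourier transform via Gaussian-kernel gridding onto a 2x
  oversampled grid, an FFT, and kernel deconvolution. The default
  spreading half-width of 12 fine-grid points gives ~1e-10 relative
  agreement with the direct nonuniform sum (tested against a
  brute-force oracle); phase correction is deliberately omitted and the
  magnitude reported.
* **Wavenumber grid** (`wavenumber_grid`): 2048 uniform points from the
  red edge of a 400–750 nm window up to the Nyquist wavenumber
  $1/(2\,\bar{\Delta\delta})$; requests beyond Nyquist are errors.

### Spectral resolution

The instrument line shape (ILS) is the transform of the apodization
window over the finite, centered, double-sided span $[-L/2, +L/2]$. The
stated maximum OPD of 200 µm is interpreted as that total double-sided
span: this is the reading under which boxcar truncation gives the
closed-form FWHM $1.2067/L \approx 60\ \mathrm{cm^{-1}}$, with
Norton–Beer medium 1.40x wider (84 cm⁻¹), i.e. 3.4 nm at 632.8 nm and
2.0 nm at 488 nm via $\Delta\lambda = \lambda^2 \Delta\sigma$.
`instrument_line_shape_fwhm()` computes these numerically (trapezoidal
quadrature on a 2001-point OPD grid, half-maximum crossings by linear
interpolation on a 3000-point wavenumber grid; both resolved far beyond
the quoted precision).

## Forward simulation

Phantoms are labelled voxel grids (`make_shell_bead`,
`make_point_bead`, `make_pollen_phantom`) on isotropic voxels defaulting
to the camera pixel at the sample (0.274 µm):

* the 6 µm surface-stained bead is a spherical shell of thickness
  0.54 µm (two voxels — the thinnest cleanly representable layer, in the
  sub-micron range typical of surface-stained polystyrene beads)
  centred on the nominal radius;
* the 0.5 µm bead is a solid ball with partial-volume anti-aliasing;
* the pollen-like phantom is a solid core (540 nm band) inside a
  concentric shell (620 nm band);
* the default emission band peaks at 530 nm with hard cutoffs at
  512/545 nm emulating an emission-filter window; laser sources are
  single-wavenumber spectra.

Projection (`project_phantom`) shears each z slice by
$(-\tan\alpha, -\tan\beta)(z - z_0)$ and sums. Shifts are applied in the
Fourier domain by default — exact for band-limited, interior-supported
volumes and exactly consistent with the Fourier-slice insertion used in
reconstruction — with a bilinear spatial path available for comparison.
Content sheared beyond half the lateral grid is an error rather than a
wrap-around. Snapshot frames tile the projections of all valid lenslets;
excluded lenslet tiles stay dark.

The OPD axis (`sample_opd_axis`) is nominally uniform with seeded
Gaussian jitter on interior points (endpoints pinned, so the mean step
is exact), emulating stage-positioning nonlinearity. Camera noise
(`noise_model`) is scaled-Poisson shot noise plus Gaussian read noise,
parameterized by the photon budget at the brightest pixel (default 2000,
read noise 2 photons — a bright cooled-EMCCD regime); the EM gain
register's excess-noise statistics are not modeled. All stochastic
operations are reproducible bit-for-bit from their seeds.

## Reconstruction

`reconstruct_tomogram()` runs, per wavelength plane:

1. **Richardson–Lucy deconvolution** of each sub-image (default 10
   iterations) with an isotropic Gaussian `psf_model()` whose FWHM is
   the lenslet diffraction limit (1.235 µm); a square-aperture sinc²
   kernel is available. RL is multiplicative, flux-conserving, and
   non-negative; convolutions are FFT-based (circular), so objects must
   sit away from tile borders.
2. **Fourier-slice insertion**: the 2D FFT of each projection is placed
   on the plane $k_z = -(k_x\tan\alpha + k_y\tan\beta)$ — each sample
   lands on its exact $(k_x, k_y)$ column and is spread linearly over
   the two neighbouring $k_z$ planes, with weights accumulated for
   normalization (overlaps average). Out-of-band $k_z$ wraps, matching
   the discrete forward model's aliasing exactly (verified against a
   brute-force 3D DFT oracle to machine precision away from the lateral
   Nyquist row, <2% overall).
3. **Inversion**: weight-normalized inverse 3D FFT; never-touched cells
   (the missing cone) stay zero. The grid is an isotropic cube with the
   sub-image side and pixel pitch; the z origin sits on the centre
   slice.
4. **Positivity refinement** (default 50 iterations): alternating
   projections that clip negative intensities in real space and restore
   the measured Fourier planes, stopping early when the negativity
   energy falls below 1e-4 of the total. The measured-plane residual is
   non-increasing.

## What the synthetic tests do and do not show

The closed-loop tests (simulate → process → reconstruct) verify the
*consistency and correctness of the algorithms*: laser lines land on
their wavelengths at the predicted linewidth, the shell phantom's ring
(invisible in any single projection) reappears in the tomogram mid-plane
at its true diameter, and the two-compartment phantom separates
spectrally in the reconstructed planes.

They deliberately do not reproduce a real instrument's measured spatial
resolution. The simulator uses the same depth-independent blur that the
deconvolution assumes, and no wave-optical image formation, defocus, or
chromatic variation (all out of scope). Under such matched, high-SNR
conditions Richardson–Lucy plus the positivity constraint legitimately
*super-resolve* a compact bright object: a simulated 0.5 µm bead
reconstructs with a transverse Gaussian-fit FWHM near 0.7 µm — sharper
than the 1 µm-scale resolution a physical system shows — and the sparse
set of 16 steep viewing directions leaves the missing-cone energy in
faint axial tails rather than a broadened axial core, so the familiar
axial-over-transverse elongation of real systems is not reproduced
either. Tests that depend on these instrument-specific effects are
asserted at the model's honest values and discussed rather than forced.

Problem sizes were chosen for quick desk-scale runs: 64³ voxel volumes
and 16 projections for reconstruction tests, 2000-sample interferograms
for spectral tests, and 40–48³ volumes for the end-to-end spectral
separation test.

## Known limitations

* No Mertz/Forman phase correction (magnitude spectra only).
* No depth-dependent or wavelength-dependent PSF; no wave-optical
  lenslet model; no EMCCD gain-register noise.
* Circular convolutions and Fourier shears assume interior-supported
  objects; content near tile borders wraps.
* TIFF + YAML sidecar is the interchange format; 32-bit TIFF storage
  normalizes to [0, 1] with the scale recorded in the sidecar
  (quantization ~5e-10 of the data range).
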
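---
title: "Aberration correction on time-gated reflection matrices: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aberration correction on time-gated reflection matrices: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classao)
```

This vignette is the package's account of the science it implements: the
forward model, the correction algorithm and its guarantees, the knobs that
matter, and the limits of what the synthetic tests demonstrate.

## The physical model

A time-gated reflection matrix collects, at a fixed optical path delay
$\tau_0$, one complex backscattered field map per plane-wave illumination:
$E(\mathbf r_o; \mathbf k_i, \tau_0)$. The package's forward model
(`simulate_reflection_field()`) is scalar single scattering through two
aberrating pupils:

1. the illumination $e^{-i\mathbf k_i\cdot\mathbf r}$ acquires the input
   pupil phase $e^{i\,\theta_{in}(\mathbf k_i)}$ (a single phase per
   illumination — a pure pupil model with no field-position dependence;
   position dependence across the field of view is produced only by
   tile-wise processing);
2. the object reflectivity $O(\mathbf r)$ multiplies the incident field
   (first Born approximation in reflection);
3. the return pass is filtered by the output pupil: a binary NA mask times
   $e^{i\,\theta_{out}(\mathbf k)}$ on $|\mathbf k| \le k_0\,\mathrm{NA}$.

Time gating is modeled implicitly: the simulated matrix *is* the gated
field at the target depth. Multiple scattering within the gate — the part
of the backscattering that no deterministic pupil model captures — is
emulated as independent circular-Gaussian speckle per illumination, band
limited to the output pupil, with power $\gamma$ times the column's signal
power (`noise_spec()`). Independence across illuminations is the worst
case for the correction, which relies on angle-to-angle consistency of
single scattering. $\gamma$ is a simulator knob, not a tissue model: real
gated multiple scattering may be partially correlated across angles, so
noise robustness measured here does not translate quantitatively to
tissue.

All modules share one discrete convention (`grid_spec()`): a square
$n\times n$ position grid of pitch $p$ with the origin at index $n/2+1$,
its discrete Fourier grid for wavevectors, unitary centred transforms, and
the pupil as the set of frequency nodes with $|\mathbf k|\le
k_0\,\mathrm{NA}$. The pitch must satisfy $p \le \lambda/(4\,\mathrm{NA})$
so the double-pass intensity PSF is Nyquist sampled. Defaults follow the
acquisition geometry the package targets: $\lambda = 515$ nm,
$\mathrm{NA} = 0.8$, medium index 1.33.

## Rotating-reference interferograms and demodulation

With a diffraction-grating reference that co-rotates with the
illumination, the camera records
$I = |E_S + E_R^0 e^{-i(\mathbf k_i+\mathbf k_{DG})\cdot\mathbf r_o}|^2$.
Sideband demodulation (`hilbert_demodulate()`) windows the frame spectrum
in a disk about $+\mathbf k_{DG}$ and recentres the carrier to zero,
yielding the rotating-frame map
$E_{GM} = E_S\,(E_R^0 e^{-i\mathbf k_i\cdot\mathbf r_o})^*$;
`to_lab_frame()` divides the reference factor out.

Numerical choices:

* **Hard circular window, no apodization.** The true signal is already
  band limited by the pupil; apodization would bias the pupil edge, where
  the aberration estimates live. The cost is sidelobe leakage for
  carriers that fall between frequency bins — the suite measures that this
  off-grid degradation stays bounded, and on-grid carriers are exact.
* **Window radius** defaults to $2 k_0 \mathrm{NA}$, the full signal band
  of the co-rotating acquisition (the sideband sits at
  $\mathbf k_i + \mathbf k_{DG}$ with $|\mathbf k_i| \le k_0\mathrm{NA}$
  and pupil half-width $k_0\mathrm{NA}$). Two inequalities are enforced:
  $|\mathbf k_{DG}| > 2k_0\mathrm{NA}$ (conjugate-sideband separation, at
  construction) and
  $\text{band radius} + 2k_0\mathrm{NA} \le |\mathbf k_{DG}|$ (DC-term
  separation, at demodulation, reported with the violated inequality).
* **Camera grid.** Frames are synthesized on a grid twice as fine as the
  field grid (same extent), so the carrier band fits under the camera
  Nyquist limit; band-limited resampling between the grids is exact. The
  default carrier, 4.2 pupil radii snapped to a camera frequency node,
  satisfies both inequalities at any Nyquist-valid pitch.
* **Carrier calibration.** For diffusive-sample frames the sideband
  spectrum is a speckle-filled disk translated by $\mathbf k_i$; its
  brightest pixel is uniformly distributed over the disk and useless as an
  estimator. `estimate_illumination_wavevector()` therefore correlates the
  thresholded spectral support with the pupil-disk template and refines
  the correlation peak by quadratic interpolation over $3\times 3$ bins;
  point-like spectra (e.g. a pure ramp) fall back to the intensity
  centroid. The suite requires sub-bin accuracy over the full pupil.

## The correction algorithm

Write the confocal (diagonal) amplitude of the matrix as a sum of
per-illumination contributions,
$D(\mathbf r) = \tfrac1n\sum_j E(\mathbf r; \mathbf k_j)\,
e^{i\mathbf k_j\cdot\mathbf r}$.
The correction seeks phase-only factors $e^{i\theta(\mathbf k_i)}$ on the
columns and $e^{i\theta(\mathbf k_o)}$ on the rows that maximize the total
confocal intensity $\sum_r |D(\mathbf r)|^2$ — single scattering adds
coherently on the diagonal once the pupils are flat, while multiple
scattering does not.

The maximizer is not unique in the literature; this package uses an exact
coordinate-ascent form. For one mode with contribution $c$ and the sum of
all other contributions $S$, the total intensity
$\|c\,e^{i\theta} + S\|^2$ is maximized in closed form by
$\theta = -\mathrm{Arg}\langle c, S\rangle$. Updates are applied
**Gauss–Seidel** (sequentially, with immediate update, in ascending
$|\mathbf k|$ so low-order structure settles first), which makes every
single update provably non-decreasing in the objective — the monotone
intensity trace asserted by the tests to $10^{-9}$ relative tolerance is a
theorem for this update, whereas a simultaneous (Jacobi) update has no
such guarantee. The **self-term is excluded** from the reference $S$:
including it adds a constant positive bias that pins updates to zero when
few modes are available. One input sweep and one output sweep form one
iteration (`input_correction_step()`, `output_correction_step()`);
`run_class()` alternates them until the relative intensity change falls
below `tol` (default $10^{-3}$) or `max_iter` (default 30) is reached, and
accumulates the per-iteration maps into the aberration estimates.

Properties worth stating precisely:

* **Iteration is essential.** With aberrations on *both* pupils, the
  single-sweep input estimate is biased by the uncorrected output screen
  (the contribution inner products acquire the phases of the aberrated
  pupil's autocorrelation), and vice versa; alternating sweeps contract
  this bias geometrically. On a noise-free point target the iteration
  converges to machine-precision recovery of both screens; the suite
  asserts sub-$10^{-6}$ rad residuals at convergence. No update rule
  consistent with the confocal-intensity objective recovers both screens
  exactly in a single input+output round.
* **Gauge.** Piston on either pupil and a *common* tip/tilt pair (which
  only shifts the image) are invisible to the objective. `run_class()`
  fixes the gauge: the shared tilt of the accumulated maps — found
  robustly via the transform-domain peak of the phasor field, then
  polished by least squares on the wrapped residual (`compare_to_truth()`
  uses the same fit) — is excluded from the estimates, so the corrected
  matrix keeps the registration of its input. The differential tilt, a
  genuine input/output asymmetry, is retained. A consequence of gauge
  removal: the chance correlation between *independent* smooth screens
  after piston/tilt removal sits well above the raw phasor-overlap null
  $\sqrt{\pi/4N}$; the tests account for this.
* **Application is unitary and conservative.** Phases are *estimated* on
  the pupil-banded $k/k$-basis component, but *applied* to the original
  matrix as unitary operators that act as the identity outside the pupil.
  Zero estimated phases therefore reproduce the input exactly — in
  particular, nothing recorded in a windowed tile sub-matrix is discarded.
* **Degenerate inputs.** A zero matrix raises an error (no signal); a
  zero contribution or zero reference inside a sweep leaves that mode's
  phase unchanged; non-finite intensities abort with the iteration index.

## Tile-wise correction and its limits

Field-varying aberrations are handled by segmenting the position-basis
matrix into $m\times m$ tiles whose cores partition the field, each
enlarged to a square analysis window by an overlap margin (default 25%,
windows shifted inward at the field edges), correcting each tile
independently, and blending corrected tile images with linear feathering
normalized to unity (`tile_layout()`, `segment_field()`,
`correct_and_stitch()`). With correction disabled the stitch reproduces
the unsegmented confocal image exactly; a failing tile is passed through
uncorrected and flagged, never fatal. Tiles smaller than $8\times 8$
pixels are rejected — their local pupil raster is too coarse to represent
a correction.

Two intrinsic limits of windowed tiles, measured and documented rather
than hidden:

* a tile senses the screen averaged over its *coarser* local pupil bins,
  so screen structure finer than one tile bin is unrecoverable from a
  tile sub-matrix;
* re-applying a correction on a windowed sub-matrix is not the window of
  the globally corrected matrix: window edges couple to light from
  outside the tile and the tile's k-bin quantization smears the screen,
  so tiled and untiled corrections of a *uniform* aberration agree only
  up to a floor that grows roughly quadratically with aberration
  strength (a few percent RMS for weak screens at the problem sizes used
  here). The per-tile *maps* remain accurate; the floor lives in the
  image-domain reapplication.

## Volumetric processing

`angular_spectrum_propagate()` uses the exact non-paraxial kernel
$e^{i\,dz\sqrt{(n k_0)^2-|\mathbf k|^2}}$ with evanescent modes zeroed —
at NA 0.8 the paraxial approximation is not acceptable. The operator is
unitary on the propagating band and satisfies the group property, both
asserted to $10^{-10}$. Volume assembly fills the gaps between recorded
depths by propagating from the *nearer* recorded slice (ties to the
shallower): the simplest disclosed rule; the two-sided midpoint
consistency is a test, not part of the estimator. Correction runs only at
recorded planes; refocused intermediate slices inherit the nearest
plane's correction. Refocusing beyond half the coherence-gate width
(default bound 7.5 µm) warns rather than fails: the propagated field then
no longer represents the gated acquisition.

## Synthetic scenes: what they do and do not emulate

The generators (`make_specimen()`, `make_aberration()`,
`sample_illumination_angles()`) are first-class, seeded, pure functions of
their parameters. Scene presets cover the geometries the metrology needs
(ideal point, point grid, filament bundles mimicking myelinated axons,
fully developed speckle). Random screens are white Gaussian fields shaped
to a Gaussian autocorrelation of width `corr_length` $\times\,k_0
\mathrm{NA}$ across the pupil (default 0.3 — about a dozen independent
patches across the pupil, the "high-order" regime), piston removed,
rescaled exactly to the requested RMS; 1.5 rad RMS on both pupils is the
regime the acceptance fixtures probe. Illumination defaults to a Fermat
spiral snapped to distinct frequency nodes — uniform disk coverage at any
count; a grid pattern is available since the actual angular-scan pattern
of such systems varies. Requests beyond the number of resolvable pupil
nodes are errors, so "fill the pupil" means all ~200 nodes at the default
64-pixel/80-nm geometry.

What passing on these fixtures does *not* show: performance under
angle-correlated multiple scattering, depth-dependent index structure,
vectorial/polarization effects at high NA (the model is scalar),
amplitude (apodization) errors of the pupils (the correction is
phase-only), or detector physics beyond additive Gaussian camera noise.

## Problem sizes and defaults

The test suite and the acceptance script run at $64\times 64$ pixels of
80 nm (full-pupil illumination, 193 angles) for matched-geometry checks
and $16$–$48$ pixel grids for exhaustive/oracle comparisons; these sizes
keep brute-force direct-summation oracles (the independent checks for the
diffraction integrals and transforms) tractable while leaving every
physical ratio — pupil sampling, noise power, screen statistics — at the
values stated above. Convergence needs 3–7 iterations on these fixtures,
comfortably inside the default `max_iter = 30`.

I/O: a pipeline run (`run_pipeline()`) writes a self-contained run
directory — resolved YAML configuration and seed (the provenance record),
JSON metrics, RDS payloads for complex arrays, and 32-bit float TIFF
previews scaled to $[0,1]$ — because complex matrices round-trip
losslessly in native serialization while TIFF serves interoperability.
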
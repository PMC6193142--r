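---
title: "Multiscale structural analysis of beaded microfibrils: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale structural analysis of beaded microfibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

fibrilEM implements a complete desk-scale analysis chain for beaded
extracellular microfibrils imaged by electron microscopy, at three scales:

1. **single-particle averaging** of the ~59 nm axial repeat from 2D
   negative-stain projections, with 3D reconstruction by projection
   matching and weighted back-projection (WBP);
2. **region-masked sub-model refinement** of the bead, arm and interbead
   regions, with rotational cross-correlation detection of
   pseudo-symmetry;
3. **morphometry** of filaments in tomogram-like volumes (tracing,
   orientation, spacing, diameter, beading period) and of micrometre-scale
   fiber cross sections in serial-section stacks (ellipse minor-diameter
   measurement).

Every input the chain consumes can be simulated by the phantom generators,
whose defaults encode the measured values of the fibrillin
microfibril/ciliary-zonule system: a 59.2 nm bead-to-bead repeat, a
20.8 nm maximum bead diameter, four interbead arms, eight chains per
repeat with 2-fold axial symmetry and higher-order (4/8-fold)
pseudo-symmetry; filament bundles with 30 nm centre spacing, 11.4 nm
diameter and 60 nm beading; and zonule fibers of 2.06 ± 1.40 µm diameter
sectioned at 14 nm/px every 100 nm.  This makes every downstream statistic
checkable by parameter recovery.

## The single-particle model

A particle image is modelled as a projection of the 3D repeat `V` at an
unknown azimuth `φ` about the filament axis (z), rotated in plane by `ψ`,
shifted by `Δ`, and degraded by the contrast transfer function and noise:

```
I_i = shift(Δ_i) · rotate(ψ_i) · CTF * P_φi[V] + ε_i,   ε ~ N(0, σ²)
```

Preprocessing follows the classical negative-stain recipe in a fixed
order: phase-flip CTF correction (multiply each Fourier coefficient by the
sign of the CTF; an involution), edge-mean normalization (zero the mean of
the 1-px border ring, unit global SD), and a hard top-hat band-pass of
600 Å–20 Å.  The hard filter edges are kept deliberately, ringing and all;
no apodization is applied.

The CTF convention: printed negative defocus means underfocus, and
`CTF(k) = -(sqrt(1-A²) sin γ + A cos γ)` with
`γ(k) = -π λ z k² + (π/2) Cs λ³ k⁴`.  Amplitude contrast defaults to 0.10.

### Alignment: exhaustive masked NCC search on two engines

`align_particle()` searches every (reference × ψ × integer shift)
combination for the maximum masked normalized cross-correlation, with a
deterministic tie-break (lowest reference, smallest ψ, smallest shift) and
parabolic sub-grid polish.  Two engines implement the same search:

* the **cartesian engine** rotates the particle and evaluates the FFT
  masked-NCC map (`masked_ncc_map()`, local mean and variance under the
  mask at every offset) for every rotation — exact for arbitrary masks,
  used for contract tests and for region-masked sub-model refinement;
* the **polar engine** resamples the disk `r ∈ [2, n/2 − shift_max − 2]`
  around every candidate shifted centre onto a ring-weighted polar grid
  and scores the whole ψ grid at once through per-ring circular
  cross-correlations (small real DFTs evaluated as matrix products).  For
  a rotation-invariant disk mask this *is* the masked NCC, up to polar
  sampling; the radial stride defaults to 2 voxels, ample for images
  band-limited at 20 Å (2.5 voxels).  This engine makes the 400-particle
  refinement run minutes instead of hours on one CPU.

### Reconstruction and refinement

The initial template is the average of the unaligned stack; reference-free
alignment (5 rounds against the evolving average) then gives an aligned
average, which is rotated so its principal intensity axis is vertical and
converted to a cylindrical initial model: each axial row's 1D profile is
ramp-filtered and back-projected at all azimuths (exact filtered
back-projection of an axisymmetric section from its single projection),
then low-passed to 20 Å.

Refinement iterates: project the model at 5° azimuth increments (one
sector of 360°/n suffices once Cn is imposed, since projections repeat),
align every particle to every reference, reconstruct by ramp-weighted
back-projection of the per-azimuth class averages, impose C2 by averaging
the n azimuthal rotations, and low-pass to 20 Å.  Iteration stops at the
configured count, when fewer than 2% of particles change azimuth
assignment, or when the mean score drops twice in a row.  Two half-set
models (even/odd after a seeded shuffle) support FSC resolution estimation
at the 0.5 threshold.

### A fundamental limitation: azimuth is a gauge freedom

For projections that differ only by rotation about a single axis, all
Fourier slices intersect on the same meridian.  Any assignment of relative
azimuths to the particles is therefore tomographically self-consistent:
the data alone cannot determine them (helical reconstruction escapes this
only because helical symmetry couples azimuth to axial shift; this repeat
is not helical).  Two practical consequences, both verified on phantoms
and reflected in the test suite:

* **azimuth-insensitive structure is recovered reliably** — the axial
  repeat distance and the radial profile (hence the maximum transverse
  FWHM diameter) come out within a few percent from any refinement run,
  noisy or clean;
* **azimuthal detail is model-contingent** — starting from a cylindrical
  model the azimuth assignments never become coherent with the generating
  truth, so a from-scratch run cannot be expected to reproduce the
  phantom's strand-level azimuthal pattern.  The suite instead checks that
  a correct band-limited model is a stable fixed point (one refinement
  pass reproduces it with masked correlation > 0.9, measured 0.965).

When iteration-1 references are azimuthally degenerate (a cylindrical
start), assignments are spread uniformly over the azimuth grid rather than
letting the deterministic tie-break collapse them onto one view.

A related empirical note: the mean alignment score is *not* strictly
monotone across iterations — greedy reassignment against a changing model
fluctuates by 1–2% after the initial jump — so the suite checks net
improvement rather than per-step monotonicity.

## Sub-models and pseudo-symmetry

Region masks are axial bands in fractional repeat coordinates (bead
0–0.30, arms 0.30–0.45 and 0.85–1.0, interbead 0.45–0.85; the boundaries
are qualitative, read from the banding pattern).  `refine_submodel()`
repeats the refinement with scoring restricted to the region's 2D mask;
because a band mask is not rotation invariant the cartesian engine is
used, with ψ and azimuth searched locally (±2 grid steps) around the
incoming full-model alignment.  The returned sub-model is windowed to the
region.

`rotational_correlation_scan()` measures Cn (pseudo-)symmetry: in self
mode, mean correlation between model projections at φ and φ+Δ over the φ
grid; in data mode, mean correlation between each aligned particle and the
projection at its assigned azimuth plus Δ.  `detect_symmetry_orders()`
reports every order n for which all multiples of 360/n fall within one
grid step of a prominent local maximum (topographic prominence ≥ 0.1 of
the curve range by default).

## The phantom generators

The repeat phantom is an analytic density evaluated on a cubic grid
(default 128³ at 8 Å/voxel — the desk-scale stand-in for 512-px boxes at
4 Å/px), with a bead (Gaussian ring of outer half-maximum radius
`max_diameter/2`, plus a weaker central core), arms that bow outward, and
`n_strands` strand bundles in the interbead.  Its design principles:

* **dimensions by construction** — the transverse FWHM equals
  `max_diameter` and the axial profile is periodic with `periodicity`
  exactly (74 voxels at the defaults), with two beads inside the box;
* **exact Cn symmetry** — strands sit at uniform azimuths with an
  amplitude pattern periodic in `n_strands/axial_symmetry_order`, so the
  default (4 strands, C2) is exactly 2-fold with pseudo-4-fold character:
  the self-scan is 1.0 at 180° and ≈ 0.9995 at 90°, mirroring a strong
  2-fold peak with "further correlation" at 90°;
* **polar (asymmetric) banding** — the bead envelope falls off faster on
  one side and the bow and strand gain carry odd harmonics, so ψ and
  ψ+180° are distinguishable, as the real asymmetric banding is;
* **chirality** — the whole azimuthal pattern twists gently
  (±20° over one repeat), so projections at +φ and −φ differ; an achiral
  phantom has exactly tied scores at ±φ, which a deterministic tie-break
  would funnel pathologically;
* **hollowness** — on-axis interbead density is essentially zero, far
  below the strand density.

The projection simulator draws azimuths and in-plane rotations uniformly
on [0°, 360°) and continuous shifts up to ±`shift_max`, applies rotation
then shift, optionally multiplies by a CTF, and adds Gaussian noise of
variance (in-box signal variance)/SNR.  SNR defaults to 0.3 — the noise
level is a free parameter of the study conditions, chosen so single
particles are clearly noisy but class averages are interpretable.  The
acceptance simulation applies no CTF: at −0.75 µm and 120 kV the CTF
magnitude at the 59 nm repeat frequency is ≈ 0.1, which at SNR 0.3 erases
the banding polarity that phase flipping cannot restore (it corrects sign,
not magnitude); CTF simulation and phase-flip correction remain exercised
by the unit tests.

The tomogram phantom packs Gaussian tubes (transverse FWHM
= `filament_diameter`) on a jittered hexagonal lattice (jitter SD 0.3 nm;
larger jitter would bias the *minimum*-over-neighbours spacing below the
lattice constant), with per-filament tilts drawn N(0, dispersion) — 2° in
parallel mode, 30° in meshwork mode — pinned at mid-height so tilt does
not bias the mean spacing, and raised-cosine beading (depth 0.3) of the
requested period with random phase.  "SD of tangent tilt" is measured as
the RMS angle about the bundle axis, which equals the drawn dispersion.

The fiber-section generator draws true diameters from a lower-truncated
(0.1 µm) normal whose *post-truncation* mean and SD equal the requested
2.06/1.40 µm (the parent parameters are solved numerically; sampling is by
exact inverse CDF so the draw count is deterministic).  Each fiber appears
in every slice as an ellipse with minor axis equal to its true diameter
and major axis inflated by 1/cos(obliquity) (default 30°), at a random
orientation, with 0.5% radial contour noise.  Contours are rendered only
at the slices actually measured (every 100th by default) to keep the
tables small; the measurement subsampling in `fiber_diameter_summary()`
is still applied on top.

What the phantoms do *not* emulate: stain granularity, carbon support,
radiation damage, filament curvature and crossing in tomograms, SBF-SEM
charging, or fibers that merge/split between sections.  Passing recovery
tests therefore demonstrates correctness of the measurement chain, not
robustness to every pathology of real micrographs.

## Morphometry definitions

* **Tracing**: from each seed, step (2 voxels) along the local
  intensity-ridge direction — the eigenvector of the smallest eigenvalue
  of the structure tensor (gradient outer products over a ±2 voxel
  cube) — re-centring on the perpendicular intensity centroid within the
  search radius (4 voxels); stop at the volume margin, when the local peak
  falls below 0.2 of the volume maximum, or when the ridge direction
  becomes ambiguous (|cos| < 0.5 to the previous direction).
* **Bundle direction**: principal eigenvector of the summed tangent outer
  products; per-filament relative angle = arccos |mean tangent · bundle|.
* **Spacing**: per filament, the minimum over other traces of the mean
  perpendicular distance at matched axial samples (minimizing over the
  *mean* rather than per-sample distances keeps trace noise from biasing
  the minimum).
* **Diameter**: FWHM of the azimuthally averaged radial intensity profile
  perpendicular to the trace.  On volumes
  (`max_transverse_diameter()`) the diameter at each axial position is
  twice the outer half-maximum crossing radius of the radial profile, and
  only slices whose profile maximum reaches 50% of the global maximum are
  measured — signal-free slices would otherwise contribute noise-defined
  half-maxima.
* **Periodicity**: first genuine peak of the bias-normalized linear
  autocorrelation of the axial profile — the highest local maximum after
  the central lobe has decayed below half, with parabolic sub-sample
  interpolation.
* **Ellipse fitting**: direct least-squares conic fit constrained to an
  ellipse, after isotropic normalization for conditioning; the minor axis
  of an obliquely sectioned circular cylinder equals the true diameter,
  which is why minor diameters are reported.

## Numerical conventions

* Rotation centre is the grid point `(n+1)/2` on every axis, so 90°/180°
  rotations map the grid onto itself and imposed C2 is exact to machine
  precision; interpolation is bilinear (2D) / slice-wise bilinear (3D),
  and rotations are never composed on rasters — angles are composed first.
* Reconstruction weighting is the ramp `|k|` along the transverse
  direction, for both the filament geometry and the single-axis tilt
  geometry; with a ±65° tilt range the missing wedge makes the
  reconstruction anisotropic, which is expected and shows up as a clear
  fidelity gap against full ±90° coverage.
* Iso-levels for volume-fraction rendering are order statistics of the
  sorted densities (exact to one voxel); the reference volume comes from
  the protein partial specific volume, 1.21 Å³/Da (1.35 g/cm³).
* MRC files are written in mode 2 (32-bit float), little-endian, z
  slowest; only mode 2 is read back, keeping one numeric path and making
  round trips exact.
* The `.box` y origin is top-left by default; a flag converts from
  bottom-left, since the dialect varies across tools.

## Problem sizes

The suite and the acceptance script run at desk scale, chosen once:
400 particles in 128-px boxes with 5 refinement iterations for the
full-size recovery; 64-px boxes with a 28.8 nm repeat for fast refinement
properties; a 220³-voxel tomogram at 1 nm/voxel holding ≥ 50 filaments;
300 fibers over 1500 slices measured every 100th.  At these sizes the
recovered repeat and diameter land within ~3% of the generator targets,
spacing/diameter/period within ~2%, and the fiber mean within one
standard error of the 300-fiber sample (~0.08 µm, i.e. ~4% — the dominant
uncertainty for that target).
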
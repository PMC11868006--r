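---
title: "TOF single scatter simulation: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TOF single scatter simulation: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `tofsss`, the
conventions and numerical choices that a user relying on its output should
know, and the reasoning behind the design decisions that were genuinely
open.

## The single-scatter model

The estimator targets coincidences in which exactly one of the two
annihilation photons Compton-scattered exactly once. For detectors A, B and
a scatter point S the contribution separates into three factors: transport
of photons to S, scattering by the deflection angle θ of the path A–S–B,
and transport of both photons to the detectors. Emission on the S–A leg
sends the unscattered photon to A and the scattered one (energy
E′ = 511/(1 + (1 − cos θ))·keV-scaled) to B; the mirrored term swaps the
roles. Multiple scatter is *not* modelled: it is absorbed by the tail-fit
scale factor, under the standard assumption that it changes the height but
not the shape of the scatter distribution.

Assumptions worth making explicit:

* **Compton-dominated attenuation.** The attenuation map is given at
  511 keV; values at the scattered energy are obtained by scaling with the
  ratio of total Klein–Nishina cross-sections. Rayleigh scattering and the
  photoelectric effect are neglected, the usual approximation for soft
  tissue at annihilation energies. For bone or contrast agents this slightly
  misestimates the energy dependence.
* **Point detectors.** Crystals are points at their face coordinates;
  incidence-cosine factors on the crystal faces are available behind the
  `incidence_cosines` flag but default to off, since the tail fit absorbs
  the global scale and the relative modulation is small for thin objects.
* **Relative units.** All absolute constants (r_e², crystal areas, source
  branching) are dropped; cross-sections are in units of r_e². Only the
  shape of the scatter distribution matters — the tail fit supplies the
  scale.
* **Deflection angle.** The scattering angle used in the Klein–Nishina
  kernel and the energy formula is the deflection from the straight-through
  direction: zero when S lies on the segment A–B. (The angle at the vertex
  of the triangle A–S–B is its supplement; using the vertex angle would
  assign backscatter kinematics to unscattered geometry.)

## Sinogram convention

Crystal pairs are indexed in a crystal-difference *fan* convention: the
angle axis is the transaxial index of the first crystal (periodic, N values
for N crystals per ring) and the radial axis is the transaxial index
difference d ∈ 1..N−1; planes enumerate the full michelogram (ordered ring
pairs within the maximum ring difference). The decisive property of this
convention is that a uniformly strided crystal subset induces a *complete
rectilinear grid* in these coordinates, which is exactly what gridded
unit-grid interpolation needs; the classic view/signed-radial convention
forms a checkerboard (angle/radial parity coupling) and does not.

Each physical LOR owns one canonical bin (lower ring first; within a ring,
lower transaxial index first) plus a mirror alias bin with the crystals
swapped. Sinogram arrays store both, and the alias carries the *reversed*
TOF spectrum, because the TOF coordinate is t = t_A − t_B and the alias
swaps the roles of A and B. All reductions (totals, reconstruction,
tail fitting) operate on canonical bins only; alias bins exist so the 4D
interpolation sees a full (angle, radial, ring1, ring2) product grid.

## TOF model

TOF bins partition [−tof_range/2, +tof_range/2] (ps); bin 1 starts at the
most negative edge. Activity along each emission leg is split exactly at
the arc positions corresponding to bin edges (the cumulative line integral
is piecewise linear and is evaluated analytically, not sampled), and the
resulting histogram is convolved with a discretised Gaussian whose FWHM is
the coincidence timing resolution. The kernel integrates the Gaussian over
each destination bin, is truncated at 4σ (measured in bins), and is *not*
renormalised: mass smeared beyond the TOF range is lost, as it is in
measured data. Consequently TOF-summed output equals the non-TOF
computation only when the geometry keeps the spectrum ≥4σ away from the
range edges; tests that assert conservation use a wide range on purpose.

The same segment model — Siddon chord lengths distributed over bin windows
and smeared with the same kernel — builds the sparse system matrix used by
the trues simulator, the MLEM reconstructor, and the tail-fit
backprojection, so simulation and correction share one forward physics.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `energy_resolution_fwhm` | 0.108 | fraction of 511 keV | detector FWHM at 511 keV |
| `energy_lld_kev` | 435 | keV | lower discriminator; efficiency is the Gaussian window mass |
| `tof_resolution_ps` | 264 | ps FWHM | coincidence timing resolution |
| `tof_range_ps` / `n_tof_bins` | 1000 / 13 | ps / – | TOF window and binning |
| `downsample_factor` | 3 | – | isotropic block-mean map downsampling |
| `point_strides` | (3, 3, 2) | voxels | scatter-point lattice on the prepared map |
| `detector_fraction` | 1/4 | – | sampled crystals per ring (stride must divide N) |
| `n_sampled_rings` | 6 | – | always includes first and last ring |
| `axial_extent_factor` | 1.5 | × half axial FOV | axial clip for scatter points, per side |
| `mu_threshold` | 0.002 | 1/mm | object contour for the tail mask |
| `margin_bins` | 1 | TOF bins | extra erosion next to the object, on top of the kernel radius |

The energy resolution is scaled with energy as FWHM(E) ∝ √E (statistical
scintillator model, `resolution_model = "sqrt"`); a constant-relative
alternative is provided, as the reference specification fixes only the
value at 511 keV. Both photons' detection efficiencies are included. The
axial sampling extent is read as "per side": points with |z| up to 1.5×
half the axial FOV are kept, and both maps are cropped to the same extent so
out-of-FOV scatter media contribute.

## Tail fit

The object support is `mu > mu_threshold` forward-projected with the
*unsmeared* TOF segment model; a bin is usable for tail fitting only if its
support projection is zero after dilating the support bins along the TOF
axis by the timing-kernel truncation radius plus `margin_bins`. With this
construction, noiseless trues simulated with the package's own forward
model vanish *exactly* on masked-in bins — the property that makes the
noiseless scale-recovery test exact to rounding. Both the masked net trues
and the masked relative scatter estimate are backprojected (unfiltered,
TOF-weighted, on the prepared map grid — only relative spatial
distributions matter) and the single factor is the closed-form unweighted
least-squares slope over voxels with positive scatter backprojection. No
body-adjacent shell restriction is applied; voxels with zero scatter
backprojection carry no information about the factor and are excluded.

## Interpolation error reporting

`interp_error_report` compares interpolation from a reduced sampling plan
against an exhaustive full-grid estimation with the same scatter points (so
the comparison isolates LOR sampling). Relative errors are summarised over
bins whose exact value exceeds 1% of the maximum — relative error on
near-empty bins is noise — and the *interpolation domain* (the sampled
radial span) is reported separately from the clamped radial-edge
extrapolation bins: outside the sampled span the method is a constant
extrapolation by design, and near-tangent LORs would otherwise dominate the
statistic. Refinement comparisons (1/4 → 1/2 → 1 of detectors) are made on
a common radial span so every plan is judged on the same bins.

On the 16-crystal test scanner a quarter sampling plan leaves only three
radial samples (a clinical ring keeps ~190), so the sub-10% accuracy checks
use deliberately smooth study conditions: a broad centered activity blob in
a water cylinder reaching the outermost sampled radial bin, an open energy
window (300 keV LLD, 20% resolution — a tight 435 keV window restricts the
accepted deflection angles and sharpens the radial profile beyond what
three samples can carry), and a dense scatter-point lattice. This is a
statement about the toy geometry, not the algorithm: interpolation accuracy
is governed by field smoothness relative to sample spacing.

## Synthetic data: what it does and does not emulate

The simulator produces TOF-binned trues by attenuated forward projection,
injects single scatter computed by the package's own estimator at dense
settings (scaled to a target scatter fraction), and adds Poisson noise with
one draw per physical LOR bin. It therefore emulates: attenuated TOF
projection, a realistic relative scatter shape, count statistics, and the
prompts/randoms/normalization bookkeeping (randoms default to zero; a
uniform level is a knob). It does *not* emulate: multiple scatter,
out-of-window randoms structure, detector dead time, positron range,
non-collinearity, crystal efficiency variations, or Monte-Carlo photon
transport. Because the injected scatter comes from the same physics model,
scale-recovery and workflow tests are exact by construction — they verify
the pipeline's internal consistency and the fitting machinery, not the
physical fidelity of the kernel against measured data. Monte-Carlo-level
validation is out of scope for this package.

Test problem sizes were chosen to keep the full suite around a minute or
two on one core: 8–24 crystals per ring, two rings, 10³–24³ voxel maps,
tens to hundreds of scatter points, 5 TOF bins. The workflow study uses a
24-crystal ring with a 45 mm phantom and a 24 mm lung insert because a
16-crystal ring (23.6 mm crystal pitch) cannot resolve a NEMA-scaled
insert at all.

## Numerical choices and degenerate inputs

* Voxels are half-open boxes `[corner, corner + size)`; all geometry is in
  scanner coordinates (mm) with the isocenter at the origin. Ray traversal
  is exact (Siddon plane crossings); the dense midpoint sampler exists only
  as a test oracle.
* Deflections below `min_theta = 1e-3` rad and scatter points closer than
  one voxel to a crystal contribute zero (forward-scatter and 1/R²
  degeneracies). Scattered energies below lld − 4σ_E short-circuit to zero
  efficiency.
* Phantom rasterisation resolves boundary voxels by voxel-center
  membership (deterministic); an optional supersampling factor averages
  sub-voxel membership when smoother partial volumes are wanted.
* Block-mean downsampling zero-pads to a multiple of the factor, which
  conserves total activity exactly; axial crops beyond the volume zero-pad
  with a warning (attenuation outside the recorded volume is unknown and
  assumed zero).
* Work is partitioned by scatter point and accumulated by order-independent
  sums, so any parallel partitioning would reproduce the serial result;
  determinism is asserted by bit-identical rerun tests.
* OSEM subsets partition canonical LORs by angle index; voxels with zero
  subset sensitivity are frozen. With very few angles per subset the
  ordered-subset approximation degrades, so the toy studies use one or two
  subsets and more iterations.

## Known limitations

* Cylindrical ring geometries only; irregular block geometries can be
  supplied as explicit crystal coordinates but the unit-grid abstraction
  then carries an additional, unreported interpolation error.
* The radial-edge clamp biases the outermost (near-tangent) sinogram bins
  toward their nearest sampled neighbour; on toy scanners those bins are a
  noticeable fraction of the tails, which is why desk-scale workflow runs
  favour full detector sampling.
* Energy-dependent attenuation scaling is global (Compton-only); no
  material decomposition.
* The reconstructor is a minimal TOF-MLEM/OSEM for testing the correction
  loop, not a clinical reconstruction engine (no PSF modelling, no
  regularisation, no listmode).
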
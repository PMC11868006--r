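# tofsss — Time-of-flight single scatter simulation for 3D PET

Quantitative TOF-PET imaging needs scatter correction: in typical clinical
acquisitions 30–50% of measured coincidences involve a Compton-scattered
photon, and without correction the reconstructed images lose contrast and
quantification, most visibly in cold structures such as the lung insert of
an image-quality phantom. `tofsss` is a vendor-independent R implementation
of the model-based, TOF-aware **single scatter simulation** (SSS) algorithm
for arbitrary cylindrical ring geometries, together with everything needed
to exercise and test it without scanner data: a synthetic NEMA-IEC-like
phantom and scanner simulator, a TOF-MLEM/OSEM reconstructor with an
additive scatter term, and NEMA NU 2 style image-quality metrics.

## The model

For a detector pair A–B and a scatter point S inside the attenuating
object, the probability of recording a coincidence in which one photon
scattered once at S factorises into three components: how many photons
reach S, how many scatter by the deflection angle θ of the path A–S–B, and
how many survive to the detectors,

    P(A,B,S)[t] ∝ μ(S)/σ_KN · dσ/dΩ(θ) / (R_AS² R_BS²) · ε(511) ε(E′) ·
        { e^(−[∫_SA μ_511 + ∫_SB μ_E′]) · TOF_t(activity on S–A) + (A ↔ B) }

with the Klein–Nishina differential cross-section

    dσ/dΩ = ½ r_e² (λ/λ′)² [ λ/λ′ + λ′/λ − sin²θ ],
    λ/λ′ = E′/E = 1 / (1 + E/(m_e c²) (1 − cos θ)),

the scattered photon energy E′, a Gaussian detector energy response ε
integrated over the energy window, attenuation of the scattered photon
rescaled to E′ by the Klein–Nishina total cross-section ratio
(Compton-dominated medium), and the emission position localised along each
leg by the arrival-time difference t = t_A − t_B, Gaussian-smeared with the
coincidence timing resolution and histogrammed into TOF bins.

The estimator evaluates this kernel on a uniformly sampled subset of LORs
(a strided subset of crystals and rings) and scatter points, then fills the
complete michelogram sinogram — all angles, radial offsets, and allowed
ring differences — by 4D multilinear interpolation on **unit-grid**
coordinates, where consecutive sampled LORs are one unit apart along each
sinogram axis. The relative estimate is scaled to the measured data by an
image-domain **tail fit**: bins whose LOR/TOF window cannot intersect the
object (where net trues = prompts − randoms contain only scatter) are
backprojected — for both the masked net trues and the masked scatter
estimate — and a single global factor is obtained by voxel-wise linear
least squares. The scaled scatter sinogram enters reconstruction as an
additive term in the OSEM forward projection, and the loop
reconstruct → estimate → scale → reconstruct can be iterated.

## Worked example

A desk-scale study: a 24-crystal × 2-ring TOF scanner, a NEMA-like phantom
(one hot sphere at 4:1 contrast, one cold sphere, a low-density lung
insert), a noiseless simulated dataset with a 35% scatter fraction, and one
scatter-correction loop.

```r
library(tofsss)

scanner <- build_ring_scanner(24, 2, ring_radius_mm = 60, axial_pitch_mm = 16,
                              specs = scanner_specs(tof_resolution_ps = 200,
                                                    tof_range_ps = 1400,
                                                    n_tof_bins = 5))
index <- sinogram_index(scanner)
spec <- nema_phantom_spec(body_radius_mm = 45, body_length_mm = 96,
                          sphere_diameters_mm = c(8, 12),
                          sphere_ring_radius_mm = 22, n_cold = 1,
                          lung_radius_mm = 12, background_activity = 1000)
phantom <- make_nema_phantom(spec, voxel_size = 4, grid_shape = c(24, 24, 25))
sim <- simulate_dataset(scanner, phantom$activity, phantom$mu,
                        n_counts = 2e6, scatter_fraction = 0.35,
                        seed = 1, noise = FALSE, scatter_strides = c(3, 3, 2),
                        index = index)

params <- sss_params(downsample_factor = 1, point_strides = c(3, 3, 2),
                     detector_fraction = 1, n_sampled_rings = 2,
                     n_outer_iterations = 1)
loop <- run_workflow_loop(sim$prompts, sim$randoms, sim$norm, mu = phantom$mu,
                          scanner = scanner, index = index, params = params,
                          n_iter = 40, n_subsets = 1)
loop$fits[[1]]
#> <tofsss_scale_fit> factor 32828.6 over 728 voxels (residual 2.95e+03)

roi <- auto_roi_set(spec)
nema_iq_report(loop$images[[1]], roi, a_H = 4000, a_B = 1000)  # uncorrected
#> <tofsss_iq_report>
#>  sphere kind radius_mm contrast_recovery_pct background_var_pct
#>       1  hot         4                 27.28              4.629
#>       2 cold         6                 46.86              3.285
#>   lung residual error: 28.76%
nema_iq_report(loop$images[[2]], roi, a_H = 4000, a_B = 1000)  # corrected
#> <tofsss_iq_report>
#>  sphere kind radius_mm contrast_recovery_pct background_var_pct
#>       1  hot         4                 47.25             0.9916
#>       2 cold         6                 60.21             3.2983
#>   lung residual error: 27.42%
```

The tail fit pins the scatter estimate to the measured tails (here the
scaled estimate carries 95% of the injected scatter mass), and one
correction loop raises hot-sphere contrast recovery from 27% to 47%,
improves the cold sphere, and lowers the lung residual error — the expected
behaviour of scatter correction on this phantom.

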
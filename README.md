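# ustrain

Lagrangian cardiac strain estimation from radio-frequency (RF) ultrasound,
built around **Bayesian regularization of block-matching correlation
surfaces** — spatial (SBR) and spatiotemporal (STBR-1, STBR-2).

## Who this is for

Researchers in ultrasound elastography and cardiac strain imaging who want
a self-contained, testable implementation of multi-level 2-D NCC block
matching with correlation-surface regularization, plus the Lagrangian
strain machinery (mesh tracking, least-squares strain tensors,
radial/longitudinal decomposition, segmental curves) and the evaluation
statistics used in that literature (strain bias, normalized strain error
Δε, total temporal relative error TTR, elastographic SNR and strain-filter
curves).  A synthetic RF speckle phantom with analytic ground truth makes
the whole chain verifiable without access to clinical or simulator data.

## The method in brief

Block matching compares an RF kernel of the pre-deformation frame against
windows of the post-deformation frame by zero-normalized cross-correlation,
giving a similarity surface over integer lags per block — the similarity
metric image (SMI).  SMIs are mapped to probability densities
(`(NCC + 1) / sum`), and each block's posterior is

    Pr(u | N) ∝ Pr(u) · Π_{x' ∈ N} max_{‖v−u‖ ≤ 3σ} Pr_{x'}(v) · exp(−Δ²/2σ²)

with the neighbourhood N being the four adjacent blocks (SBR), the
past/future SMIs of the same block over four consecutive frames (the
temporal stage of STBR-1), or both simultaneously (STBR-2).  The spatial
Gaussian width couples to the maximum expected strain via the block spacing
(the "strain regularization sigma", SRS); the temporal width σ_t controls
how strongly the assumption of smooth velocity over a short time span is
enforced.  Displacements are read off by maximum a posteriori with
windowed-sinc sub-sample refinement inside a three-level coarse-to-fine
pyramid, then median filtered, accumulated from end-diastole along a
segmented myocardial mesh, and converted to radial/longitudinal Lagrangian
strain by a least-squares gradient estimator.

See `vignettes/methods.Rmd` for the full model description, parameter
discussion and design decisions.

## Worked example

Recover a known rigid shift (4 axial samples, 1 A-line) from a noiseless
speckle phantom, then compare estimators on a noisy cyclic-deformation
phantom:

```r
library(ustrain)

cfg <- imaging_config()                      # 8 MHz / 78.84 MHz, 0.2 mm pitch
dz  <- cfg$c / (2 * cfg$fs * 1000)           # axial mm per sample
sca <- generate_scatterers(c(-2, 8, -2, 8.4), density_per_mm2 = 30, seed = 1)
mot <- motion_model("rigid_shift", shift = c(4 * dz, 1 * cfg$pitch))
pre  <- simulate_rf_frame(sca, cfg, 0)
post <- simulate_rf_frame(deform_scatterers(sca, mot, 1), cfg, 1)
f <- estimate_displacement_multilevel(list(pre, post), bm_config(), "none")
median(f$ax[!f$flags]); median(f$lat[!f$flags])
#> [1] 4
#> [1] 1

# cyclic phantom at 5 dB sonographic SNR: plain NCC vs spatial Bayesian
for (reg in c("none", "sbr")) {
  r <- run_pipeline(pipeline_config(
    scene = phantom_scene(snr_bands = list(list(snr_db = 5))),
    regularizer = reg, seed = 1, reg = reg_params(sigma_t = c(0.1, 0.1))))
  cat(sprintf("%5s: displacement RMSE %.4f mm, radial TTR %.1f%%\n",
              reg, r$metrics$disp_rmse_mm, r$metrics$ttr_radial_mean))
}
#>  none: displacement RMSE 0.0827 mm, radial TTR 35.5%
#>   sbr: displacement RMSE 0.0821 mm, radial TTR 23.9%
```

The median interior-block displacement equals the prescribed shift exactly
(a perfect correlation peak is recognized as an exact match), and on the
noisy phantom spatial regularization lowers both the displacement RMSE and
the error of the radial strain curves relative to the analytic ground
truth.

A thin command-line driver wraps the same pipeline
(`inst/cli/csi.R {phantom|track|strain|evaluate|run}`), configured by a
single YAML file (see `load_pipeline_config`).

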
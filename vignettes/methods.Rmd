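---
title: "Spatiotemporal Bayesian regularization for cardiac strain imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal Bayesian regularization for cardiac strain imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ustrain)
```

## The estimation problem

Cardiac strain imaging derives myocardial deformation from sequences of
radio-frequency (RF) ultrasound frames acquired over the heart cycle.  The
processing chain implemented here is:

1. **Block matching.**  For each small RF kernel in the pre-deformation
   frame, zero-normalized cross-correlation (NCC) against equally sized
   windows of the post-deformation frame produces a 2-D similarity surface
   over integer (axial, lateral) lags — a *similarity metric image* (SMI).
   The displacement is the location of the surface maximum, refined to
   sub-sample precision.
2. **Bayesian regularization of the SMIs** (optional, the core of the
   package).  SMIs are noisy at low sonographic SNR; instead of filtering
   displacement estimates after the fact, the correlation surfaces
   themselves are regularized before the peak is read off.
3. **Lagrangian strain.**  Inter-frame displacement fields are median
   filtered, accumulated along tracked material points of a myocardial mesh
   from end-diastole (ED), converted to strain tensors by a least-squares
   (LS) gradient estimator, and projected onto the local wall directions to
   give radial ($e_r$) and longitudinal ($e_l$) strain and six-segment
   strain-versus-time curves.

## Bayesian regularization of correlation surfaces

An SMI is mapped to a probability density surface by adding one to every
NCC value and normalizing by the sum.  Writing $\Pr(u_x)$ for the prior PDF
of displacement $u$ at block $x$, the regularized (posterior) surface is

$$\Pr(u_x \mid u_{N}) \propto \Pr(u_x) \prod_{x' \in N} \Pr(u_{x'} \mid u_x),$$

where $N$ is a neighbourhood of surfaces and each factor is a likelihood
built from the neighbour's PDF:

$$\Pr(u_{x'} \mid u_x) \propto \max_{v:\,\|v - u\| \le 3\sigma}
  \Pr(v)\, e^{-\left(\frac{\Delta_a^2}{2\sigma_a^2} +
  \frac{\Delta_l^2}{2\sigma_l^2}\right)},$$

the maximum over displacements $v$ similar to the candidate $u$, weighted by
an anisotropic Gaussian in the displacement difference and truncated at
three widths per axis.  Three estimators share this machinery:

* **SBR** — spatial-only: the four adjacent block surfaces (left, right,
  top, bottom) form the neighbourhood.  Widths derive from the *strain
  regularization sigma* (SRS, `sigma_eps`): the displacement difference two
  adjacent blocks show at the maximum expected strain,
  $\sigma_u = \sigma_\varepsilon \times$ block spacing.
* **STBR-1** — spatial then temporal: one SBR pass on the past, present and
  future surfaces independently, then a second pass whose prior is the
  present SBR posterior and whose likelihoods come from the past/future SBR
  posteriors with temporal widths $\sigma_t$.
* **STBR-2** — simultaneous: a single posterior combining the unregularized
  prior, the four spatial likelihoods ($\sigma_\varepsilon$-coupled) and the
  two temporal likelihoods ($\sigma_t$-coupled).

Temporal neighbourhoods live in the SMI domain: a pair of frames gives one
SMI, so the minimal past/present/future set needs **four consecutive RF
frames**, and the estimated displacement is still the inter-frame motion of
the middle pair.  The first and last pairs of a sequence lack one temporal
neighbour and fall back to spatial-only regularization (flagged).
Displacement is finally read off each posterior by maximum a posteriori with
sub-sample sinc refinement.

All products are accumulated in the log domain after flooring likelihoods at
`likelihood_floor` ($10^{-12}$), so empty truncation windows never produce
$-\infty$; every posterior is renormalized to sum 1.  Updates are
synchronous (all likelihoods evaluated on the pre-iteration grid), which
makes the result independent of block visiting order, and a single
iteration is the default — with one iteration only adjacent neighbours are
consulted, and more aggressive iteration risks over-regularization.

### Parameter choices

* `sigma_eps` (SRS, unitless strain, default `c(0.1, 0.1)`): the coupling
  rule $\sigma_u = \sigma_\varepsilon \cdot$spacing must produce at least
  about one lag at each pyramid level.  RF correlation surfaces oscillate
  with the carrier; neighbouring blocks' peaks sit at fractional lags, so a
  sub-lag $\sigma_u$ makes the truncated Gaussian sample a neighbour's
  carrier *trough* instead of its peak and systematically suppresses true
  displacements (we verified this by brute-force evaluation of the
  posterior on real coarse-level surfaces).  A 10% maximum expected
  inter-block strain is consistent with values used for cardiac RF block
  matching and gives $\sigma_u \approx 0.8$–$2.4$ lags across the default
  levels.
* `sigma_t` (default `c(0.01, 0.01)`): the temporal width.  The value is
  dimensionless in its published uses without a stated unit; we resolve the
  ambiguity by applying the *same* block-spacing coupling as the SRS
  (`coupling_mode = "strain"`), with a direct lag-unit mode available.
  Smaller values enforce stronger temporal continuity; `c(0.1, 0.1)` is the
  appropriate choice for noisy data (it is what we use in the low-SNR
  comparative study), `c(0.01, 0.01)` for clean high-frame-rate data.
  The temporal window must cover the frame-to-frame *velocity change*;
  see the phantom cycle-length discussion below.
* `n_iterations` (default 1): see above.

## Multi-level block matching

The driver follows the standard coarse-to-fine design for RF speckle
tracking: RF frames are up-sampled by windowed-sinc interpolation (1:2
axial:lateral by default — lateral sampling is the scarce direction),
decimated into a three-level pyramid (axial factors 3/2/1, lateral 2/1/1
with an anti-alias low-pass), and matched level by level.  Kernel lengths
are 8/5/1 wavelengths axially (converted to odd sample counts via the
sampling-to-centre-frequency ratio of each level) and 15/12/10 A-lines
laterally, with 10% axial and 90% lateral overlap.

Two design points deserve explanation:

* **Level chaining.**  Coarse estimates seed finer levels as integer
  search-window offsets per block (recorded in each surface's
  `lag_offset`), rather than by fractionally resampling the post frame.
  Integer window alignment is exact — no interpolation error enters the
  data path — and at the inter-frame strains of interest (a few percent,
  under a lag of stretch across a kernel) the residual decorrelation is
  negligible.  Fractional align-and-stretch companding (`compand_rf`) is
  implemented and available (`bm_config(compand = TRUE)`) for large-strain
  use.  A practical consequence of the integer-alignment path: a noiseless
  pure translation is recovered *exactly*, because the finest-level window
  then matches the kernel bit for bit.
* **Sub-sample refinement.**  The integer argmax is refined by evaluating
  the surface's 2-D Hann-windowed-sinc interpolant (8-tap half-width, the
  same kernel used for RF up-sampling) on a two-stage grid reaching 1/100
  lag.  Ties between equal maxima break to the smallest Euclidean
  displacement, then the smallest axial lag.  Flat surfaces return zero
  displacement with a degenerate flag; boundary maxima return the integer
  lag, flagged.  When an integer-lag correlation reaches 1 within $10^{-9}$
  the match is exact and refinement is skipped — interpolating a perfect
  peak can only add error.  The interpolant's half-width is capped per axis
  at the available surface extent: letting the kernel overhang the surface
  edge truncates the sinc asymmetrically and biases the refined peak (we
  measured ~0.1 sample axial bias on analytic correlation shapes for
  5×3-lag surfaces without the cap, none with it).  Search half-ranges
  default to 10/5/2 samples axially and 5/3/1 lines laterally; widening the
  finest windows buys additional sub-sample precision (more interpolant
  support averages more data) at the cost of admitting larger outliers in
  noisy data, a trade the configuration leaves to the user.

Blocks whose kernel or search window leaves the frame are flagged, as are
degenerate (zero-variance) kernels; flagged blocks are excluded from all
evaluation statistics.

## The synthetic phantom

The generator emulates the statistical structure of simulated cardiac RF
data without an acoustic field simulator: point scatterers with standard
normal reflectivity at a density giving fully developed speckle, imaged by
a separable point-spread function (Gaussian envelope × cosine carrier
axially, Gaussian laterally), deformed by an analytic motion model, with
white Gaussian noise added at a prescribed sonographic SNR measured against
a reference ROI of the noiseless frame.  Depth-dependent SNR (the
anterior/posterior asymmetry caused by attenuation in real data) is
reproduced by applying different SNR levels to depth bands rather than by
modelling attenuation.

Defaults: 8 MHz centre frequency, **78.84 MHz sampling**, 0.2 mm pitch,
0.6 fractional bandwidth, 32 lines × 6 mm depth.  The sampling frequency
matters: with axial decimation by 3 the coarse-level RF must stay above
Nyquist ($f_s/3 > 2 f_0$ plus bandwidth), which a 40 MHz default would
violate — the anti-alias filter would then remove the RF band entirely and
coarse matching would peak-hop by whole wavelengths.  The field of view is
deliberately small so that full multi-method studies run on a desk machine;
the vignette's study sizes are 17-frame cycles, ~600-point meshes and
~4,000-block fields.

The `cyclic_wall` motion model applies a global affine scaling about the
wall centre with strain profile $\varepsilon(t) = \varepsilon_{peak}
\sin^2(\pi t / T)$, so the deformation closes exactly at the cycle end and
the Lagrangian ground truth (displacement mapping, uniform strain tensor,
segment curves) is available in closed form.  Default peaks are 4% radial
thickening and −2% longitudinal shortening over a 16-pair cycle.  Two
considerations fixed the cycle length: physiology would prefer larger
strains, but (i) desk-scale lateral resolution (0.2 mm pitch) caps
resolvable lateral motion, and (ii) the temporal regularizers *assume
smooth velocity between adjacent frame pairs* — the frame-to-frame velocity
change must stay within the temporal truncation window ($\pm 3\sigma_t$),
as it does in real acquisitions at hundreds of frames per cycle.  A short
cycle with large strain violates the method's stated operating assumption
and turns temporal likelihoods into noise.

What the phantom does **not** emulate: out-of-plane motion, anisotropic
fibre mechanics, attenuation and reverberation, phased-array geometry, and
partially decorrelated speckle.  Passing tests on the phantom therefore
demonstrate correctness of the estimation machinery under its stated
assumptions, not clinical performance.

## Lagrangian strain

The mesh fills the region between two wall contours with a transmural ×
arc-length lattice (six equal arc-length segments, base→apex→base).  The
longitudinal direction is the mid-wall tangent and the radial direction its
exact 90° rotation oriented endo→epi, so the wall frame is orthonormal by
construction and $e_r + e_l = \operatorname{tr} E$.

Displacement fields are median filtered (5×5 blocks) and accumulated:
$x_p(t{+}1) = x_p(t) + u_t(x_p(t))$ with bilinear interpolation from the
block grid; points leaving the grid are frozen and flagged.  Strain uses
the infinitesimal measure $E = (\nabla u + \nabla u^\top)/2$ fitted by
ordinary least squares over neighbours within a 0.5 mm × 1 mm kernel of ED
positions; the Green–Lagrange quadratic term is available
(`finite = TRUE`) but off by default, matching the gradient-based LS
lineage of the estimator and the small per-frame strains.  Points with
fewer than six neighbours or rank-deficient designs are flagged.

## Evaluation statistics

Strain bias $E[\varepsilon_{true} - \varepsilon_{est}]$ (percent-strain
inputs by convention), normalized strain error
$\sum|\varepsilon_{true} - \varepsilon_{est}| / \sum|\varepsilon_{true}|
\times 100$, and the total temporal relative error (TTR) — the same ratio
over a segmental strain-versus-time curve.  Both ratios are undefined
against identically zero truth; the pipeline reports the bias and the
maximum absolute error in that degenerate case.  Elastographic SNR,
$SNR_e = \mu/\sigma$ over a 5×9-point mesh window, feeds the strain filter:
the 2-D histogram $f(SNR_e, \varepsilon)$ normalized per strain bin gives
the conditional PDF, and bin-centre integration gives
$E(SNR_e \mid \varepsilon)$.  Binning defaults to 50 strain bins over the
observed range and 60 SNR bins over [0, 30].  Windows with $\sigma$ below
$10^{-12}$ and empty strain bins are flagged, never silently zeroed.

At desk scale the longitudinal direction deserves honesty: peak lateral
displacements are a fraction of a line, below what lateral speckle tracking
can localize (the lateral correlation peak is several up-sampled lines
wide), so longitudinal TTR is noise-dominated for *every* method and the
radial metrics carry the discriminative signal in our comparative study.
The same limitation caps the zero-motion jitter statement to the axial
component (median below 0.05 samples at 40 dB, measured with a
support-adequate finest search window); lateral jitter sits near 0.2 lines
for all methods.

## Reproducible study sizes

The comparative noise-robustness study (also what `scripts/acceptance.R`
re-runs) uses the default cyclic scene at SNR$_s$ = 5 dB, ten
scatterer/noise realizations, the four estimators at their defaults with
$\sigma_t = (0.1, 0.1)$, and reports the median displacement RMSE and
median radial TTR per estimator.  Translation recovery, uniform-strain
recovery (1% axial at 40 dB) and AWGN calibration complete the report.  All
randomness flows from one root seed through per-stage derived seeds, and
every pipeline artifact embeds its serialized configuration.

## Known limitations

* Linear-array geometry only; no phased-array/sector scan conversion.
* Temporal neighbourhood fixed at one past and one future SMI (four RF
  frames); longer neighbourhoods would need both more frames and adaptive
  widths to avoid over-regularization.
* $\sigma_t$ is a fixed tuning parameter, not adapted to local signal
  decorrelation.
* Lateral/longitudinal precision is resolution-limited at the desk-scale
  pitch, as discussed above.
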
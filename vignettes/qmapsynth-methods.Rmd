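---
title: "Methods: phantom-driven T1rho map synthesis from T2 maps"
author: "qmapsynth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-driven T1rho map synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

T1rho relaxation times of knee cartilage track proteoglycan loss and are
among the most promising quantitative biomarkers for early osteoarthritis,
but T1rho mapping is slow to acquire and far less available than T2
mapping. `qmapsynth` implements, end to end and at desk scale, a pipeline
that (i) simulates multi-echo spin-lock and T2-prepared knee acquisitions
over synthetic phantoms with known relaxation times, (ii) reconstructs
quantitative maps by voxelwise mono-exponential fitting, (iii) trains a
compact 2D U-Net to synthesize T1rho maps from T2 maps under a
cartilage-weighted loss, and (iv) quantifies agreement with the similarity
and Bland-Altman statistics used for quantitative imaging biomarkers,
including out-of-distribution (coil/scanner change) stress tests.

Real multi-institution MRI cohorts are not required (or shipped): the
phantom generator plays the role of the cohort, with full ground truth.

## Signal model and relaxometry

Both weighted series follow a two-parameter mono-exponential decay per
voxel,

$$ S(t) = S_0 \, e^{-t/T}, $$

with $t$ the spin-lock time (TSL) for T1rho weighting or the
T2-preparation time (TE) for T2 weighting. The default schedules are
TSL $= 0/10/40/80$ ms and TE $= 0/12.9/25.7/51.4$ ms — the 4-point
schedules shared by all acquisition settings this pipeline emulates.
Spin-lock frequency, TR, views per preparation and acceleration factors
are carried as metadata only; k-space acquisition is out of scope.

`fitMonoexponential()` solves the per-voxel least-squares problem with a
vectorized Levenberg-Marquardt iteration: every voxel advances
simultaneously, and the damped $2\times2$ normal equations are solved in
closed form. Initialization is a log-linear regression of
$\log\max(S,\varepsilon)$ on $t$; LM itself sees raw intensities.
Numerical choices, made once and documented here because no reference
prescribes them:

* fit bounds $T \in [1, 300]$ ms — wide enough for every cartilage value
  of interest (compartment means are $\approx$ 30–50 ms), tight enough to
  stabilize flat-decay voxels; this is distinct from the $[0, 150]$ ms
  display/clip range used for network inputs and outputs;
* relative step tolerance $10^{-8}$, at most 200 iterations; voxels that
  stop without meeting the tolerance, or that sit on a bound, are flagged
  non-converged — never silently filled;
* all-zero series (air without noise) are flagged with $T = T_{lo}$;
* no spatial regularization — fits are voxelwise independent.

Because the two free parameters are identifiable from two echoes, the fit
is exact on noiseless data (the test suite requires $10^{-6}$ relative
recovery); with 1% Gaussian noise the median cartilage error stays below
2%. A multiplicative constant on all echoes of a voxel changes $S_0$ only,
which is why a shared coil-bias field leaves fitted maps unchanged — the
basis of the domain-shift design below.

## The phantom generator

`generatePhantom()` builds a stylized sagittal knee: a disc of "bone"
surrounded by an annular cartilage band split into six angular sectors
(the six compartments MF, LF, MT, LT, PAT, TRO), a muscle annulus, and
background with $S_0 = 0$. The geometry is deliberately stylized — tests
need contiguous labeled bands, not anatomy — and is constant across
slices, giving contiguous curved 3D bands.

The statistical structure is what the synthesis task assumes:

* The T2 field is per-compartment mean (defaults 26–34 ms) plus a
  per-subject compartment shift (sd 1.5 ms), one smooth spatial field
  (sd 1.5 ms, smoothness 6 voxels) and bounded uniform jitter
  ($\pm 0.3$ ms).
* T1rho is a deterministic affine function of the T2 field per
  compartment, $T_{1\rho} = a\,T_2 + b_c$ with coupling slope $a = 1.2$
  and $b_c$ set so compartment-mean T1rho hits its configured target
  (defaults 30–52 ms, always above T2), plus its own bounded jitter.
  The learnable map is therefore exact up to jitter, which is what the
  end-to-end recovery tests rely on. The T1rho–T2 offsets deliberately
  vary across compartments (4–18 ms) — more strongly than healthy-knee
  compartment averages would suggest — so that the compartment identity
  carries T1rho-specific information that no single global rescaling of
  T2 can reproduce. In vivo that information lives in pathology,
  texture and compartment-dependent physiology; in this stylized
  phantom it is concentrated in the compartment offsets and the lesion
  model, and the information-gap test (trained model beats the
  rescaled-input baseline) depends on it.
* Focal OA-like lesions (Poisson count, default rate 1.5/subject,
  Gaussian radius 4 voxels — broad regional elevations rather than
  point defects) elevate T1rho by `lesionMagnitude` (default 25%) but
  T2 by only half of that, again giving T1rho content beyond T2.
* Noise is additive Gaussian by default (sd = `noiseSigma` × mean
  cartilage $S_0$; default 1%), because maps — not magnitude k-space
  images — are the working currency here and the fitting stays unbiased
  at these SNRs; a Rician option exists for sensitivity checks.

Tissue parameter values themselves are free knobs of the generator (no
reference quantifies the joint (T1rho, T2) distribution beyond
compartment means). The value ranges were chosen to be plausible for
knee cartilage at 3T; the spread of the compartment offsets was sized
so that the generator's defining premise — T1rho information that a
global rescaling of T2 cannot explain — is large enough for a trained
model to demonstrably exploit, which is what the information-gap test
measures.

All randomness flows from one root seed through named sub-streams
(`deriveSeed()`), so cohorts, echoes, splits and training are each
bit-reproducible and independently re-runnable.

### Domain shift

`applyDomainShift()` emulates a coil/scanner change: one smooth positive
multiplicative field $\exp(\alpha G)$ (shared across echoes, as a coil
sensitivity would be), an SNR rescaling that adds the exact additional
noise variance needed to reach `snrScale` times the original noise sd,
and optionally an additive ground-truth shift. Because the bias field is
shared across echoes it cancels in the decay and only the noise change
and its nonlinear interaction with fitting and inference degrade the
downstream maps — reproducing the *direction* of out-of-distribution
degradation, not any particular magnitude.

## Synthesis network

`buildModel()` constructs a 2D U-Net with, at depth $d$: $d$ encoder
convolutions (channels doubling per level, each followed by 2×2 max
pooling), a bottleneck convolution, $d$ decoder convolutions (2× nearest
upsampling + skip concatenation each) and a final linear 3×3 output
convolution — $2d+2$ convolutional layers, 8 at the default depth 3,
with ReLU activations and batch normalization after every convolution
except the output. "Eight convolutional layers" does not pin down widths
or depth, so the default is an interpretation: depth 3 with base width
16 (the `tinyUNetSpec()` preset uses base width 8, staying under $10^5$
parameters for desk-scale experiments). Convolutions are implemented in
compiled code (im2col + BLAS products) with exact hand-derived
backpropagation; the gradient is verified against finite differences in
the test suite.

### Loss

Training minimizes the region-weighted loss

$$ \mathcal{L} = 1.5 \times \mathrm{L2}(y_{cart}, \hat y_{cart})
   + \mathrm{L1}(y_{bg}, \hat y_{bg}), $$

with L2/L1 the mean squared / mean absolute error over the cartilage
mask and its complement ("background" = the remainder of the slice).
Reductions are per-region *means*, not sums, so the 1.5 weight is
comparable across mask sizes; slices without cartilage voxels train on
the L1 term alone (counted and logged). The loss is applied on
normalized intensities: maps are clipped to $[0, 150]$ ms (suppressing
background-noise fits) and divided by `intensityScale` (default 150).
Both the reduction convention and the normalized-scale application are
package decisions, documented as such.

### Protocol

* Subject-wise 65:15:20 train/validation/test split with
  largest-remainder rounding (ties resolved train > val > test); no
  subject's slices ever cross subsets, asserted on every run.
* Adam (default learning rate $2 \times 10^{-3}$) with early stopping
  when the validation loss has not improved for `earlyStopPatience`
  epochs (default 12) and a reduce-on-plateau schedule that halves the
  rate after `lrDecayPatience` stagnant epochs; the best-validation
  checkpoint is returned. The optimizer, batch size, epoch budget and
  channel widths are configuration defaults, not reference facts.
* 4-fold subject-level cross-validation over the train+validation pool
  (the test set stays untouched).
* `hyperparameterSearch()` evaluates a finite grid over loss variant,
  intensity scale and learning rate, selecting the lowest validation
  cartilage NMSE; the full leaderboard is persisted.

## Evaluation

Definitions fixed by this package (and therefore stated precisely):

* **NMSE** (%) $= 100 \sum_R (\hat y - y)^2 / \sum_R y^2$ over a region
  $R$; an RMS variant is available behind a flag for sensitivity checks.
* **PSNR** (dB) $= 10 \log_{10}(150^2 / \mathrm{MSE}_R)$ — the data
  range is fixed at the 150 ms clip ceiling rather than a per-image max,
  for cross-subject comparability.
* **SSIM**: standard Gaussian-window SSIM (11 taps, $\sigma = 1.5$,
  $K_1 = 0.01$, $K_2 = 0.03$), computed per slice on whole slices (no
  mask), borders cropped by the filter radius, averaged over slices.
* **CORR**: voxelwise Pearson r over the cartilage mask; compartment-level
  Pearson r over subject × compartment means with dof $n-2$ and the
  two-tailed t-transform p-value.
* **Bland-Altman**: differences of subject × compartment means
  (pred − truth); bias = mean difference; limits of agreement
  bias $\pm 1.96$ sample SD.
* **Quantification-error rate** (%): mean over subject × compartment
  units of $100\,|\bar{\hat y} - \bar y| / \bar y$, compared against the
  6.42% clinically-significant-change threshold for cartilage T1rho.
  The unit (subject × compartment, not voxel) is an interpretation,
  recorded here.

Per-patient metrics are computed per volume (not averaged over slices);
whole-volume and cartilage values are always reported together. On this
phantom, whole-volume NMSE is dominated by the background: with
$S_0 = 0$ air, background voxels of the fitted "ground truth" maps are
fits of pure noise, which no network can predict. Cartilage metrics are
the meaningful quantities, exactly as cartilage-specific analysis is the
meaningful level for the clinical question.

## Problem sizes and what the tests show

The shipped experiments use cohorts of 30 subjects at 64×64 pixels and
8 slices with the tiny U-Net preset — sizes chosen so the full pipeline
(simulate, fit ~1M voxel fits, train, predict, evaluate) completes in
minutes on one CPU while still exercising every contract. Passing tests
show that the implementation is correct and that the method recovers a
known generative rule under the phantom's assumptions (smooth
compartment fields, affine T1rho–T2 coupling, focal lesions, Gaussian
noise, stylized geometry). They do not show radiological realism:
real cartilage geometry, B0/B1 inhomogeneity, registration error,
scanner/coil variability beyond the stylized bias-field model, and
pathology heterogeneity are all absent by design. Reported paper-scale
results on real cohorts are not reproducible here and are not claimed.

## Known limitations

* Registration is out of scope: phantom echoes are registered by
  construction.
* The U-Net is 2D and slice-independent; no 3D context.
* No GAN/transformer/variational variants; no pretraining.
* The identity-shift operator needs the phantom truth to apply a
  ground-truth offset; on real data only bias-field and SNR shifts are
  available.
* Whole-volume NMSE on phantoms is inflated by noise-only background
  (see above) and should be read alongside cartilage NMSE.
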
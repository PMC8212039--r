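---
title: "Self-supervised denoising of complex-valued MRI: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-supervised denoising of complex-valued MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mrdenoise)
```

## The problem

MRI data are acquired in k-space, the 2-D spatial-frequency domain; the image
is its inverse Fourier transform and is complex-valued. Thermal noise enters
k-space additively as i.i.d. complex Gaussian noise, `y = x + n`, and —
because the Fourier transform is linear and (in the unitary convention)
variance-preserving — the same Gaussian model holds in the complex image.
Taking the per-pixel modulus would turn this into Rician noise, which is why
every method in this package operates on the two real channels (real,
imaginary) of the complex image, and magnitude is taken only for display and
evaluation.

No clean target exists for *in vivo* MRI: the scanner's thermal noise is part
of every acquisition, and no second independent sample of the same anatomy
can be assumed. The package therefore implements two self-supervised
denoisers that train on noisy data alone, a classical baseline, and the
machinery to evaluate all of them against simulated ground truth.

## Model 1: the MC-SURE U-Net

For a denoiser `h(y; theta)` under additive Gaussian noise of known
per-channel standard deviation `sigma`, Stein's unbiased risk estimator
replaces the unobservable supervised risk `(1/M) sum_j ||h(y_j) - x_j||^2`
with

```
(1/M) sum_j [ ||y_j - h(y_j)||^2 - K sigma^2 + 2 sigma^2 sum_i dh_i/dy_i ]
```

where `K` counts the real scalar entries per sample — `2*H*W` for a complex
slice, because the noise model is per-channel. The divergence is intractable
for a CNN and is estimated with a randomised finite difference
(Monte-Carlo SURE):

```
(2 sigma^2 / eps) * n~' [ h(y + eps n~) - h(y) ]
```

with one fresh standard-normal field `n~` per sample per step. Note the
`1/eps`: scaling *by* `eps` instead would make the probe vanish as
`eps -> 0` and cannot estimate the divergence; the package's unit tests pin
the convention to the brute-force operator trace of an explicit linear
filter (the probe's mean must equal `2 sigma^2 tr(A)` for `h(y) = A y`).
`eps` defaults to `1e-3` times the maximum magnitude of the batch, keeping
the finite difference meaningful under any data scale; for a linear denoiser
the estimator is exactly `eps`-invariant, and for the trained networks the
dependence is far below the Monte-Carlo noise over `[1e-4, 1e-2]` times the
data scale.

The network is a standard U-Net (`build_sure_unet()`): `depth` levels of 2x
max-pooling with feature doubling, 3x3 kernels, LeakyReLU after every
convolution except the final one, nearest-neighbour upsampling and skip
connections by channel concatenation. Two deliberate choices:

* **Residual parameterisation.** The output is `y + f(y)` with the final
  convolution zero-initialised, so the untrained network is exactly the
  identity. The identity's SURE loss equals the true noisy risk
  `K sigma^2`; training starts from the baseline it must beat and descends
  from there. This makes short training schedules well-behaved without
  changing what the converged network can express.
* **Scale sensitivity.** The SURE loss balances a residual term against
  `sigma^2`-weighted terms, so the absolute input scale matters. Each
  protocol fixes a scale factor (500 for raw knee k-space magnitudes of
  ~1e-5; 1/25000 for simulated brain intensities of ~1e3; 1/2000 for the
  desk phantom below). `denoise_sure()` reconciles units through the
  recorded training scale and warns when the input is off by more than two
  orders of magnitude.

## Model 2: the blindspot network with posterior-mean inference

The blindspot architecture makes the prediction at a pixel independent of
that pixel's own value, so the network can be trained on single noisy
images: the only way to reduce the training loss is to model the signal
structure in the pixel's context. The construction (`build_blindspot_net()`)
uses one shared convolution stack whose kernels are vertically shifted so an
output pixel sees only rows at or above its own, followed by a single
one-pixel downward shift that removes the centre row itself. Applied to the
four 90-degree rotations of the input and counter-rotated, the four branches
cover the four half-planes above / left / below / right of each pixel —
everything except the pixel itself — and are fused by 1x1 convolutions,
which add no spatial mixing. The centre-pixel exclusion is therefore exact
by construction, and the test suite verifies a numerically zero Jacobian
diagonal rather than trusting the construction.

The fused head predicts a per-pixel Gaussian prior for the clean signal:
two mean channels `mu` and two per-channel variances through a softplus map
plus a floor of `1e-8` (scaled units squared, guarding the closed form
below). Training minimises the negative log-likelihood of the observed pixel
under the predictive marginal `y ~ N(mu, var + sigma^2)` with `sigma` known
— in practice from `estimate_sigma_background()`. A diagonal (per-channel)
variance is used rather than a full 2x2 complex covariance: the noise model
treats the channels symmetrically and independently, and the diagonal form
keeps the posterior analytic.

At test time the centre pixel, unused during training, is recovered through
conjugate-Gaussian Bayes per pixel and channel:

```
E[x | y] = (mu * sigma^2 + y * var) / (var + sigma^2)
```

a convex combination of prediction and observation: flat regions (small
predicted `var`) trust the prior, edges and fine texture (large `var`) trust
the data. This is the mechanism behind the method's edge preservation. With
`sigma = 0` the observation is exact and the input is returned unchanged.

On "no activation function": applied literally to every convolution the
branches would be linear and could only express a linear predictor. The
package reads it the same way as for the U-Net — no activation on the final
(output) 1x1 convolution — and uses LeakyReLU elsewhere; the architecture
descriptor stored in every checkpoint records this.

The learning rate is halved (`lr_factor = 0.5`, a conventional choice for
plateau schedules) when the validation loss has not decreased for
`lr_patience` epochs (default 10, matching the reference protocol).

## Baseline: non-local means

`nlm_denoise()` replaces each pixel by a weighted average of the centre
pixels of all patches within `patch_distance`, with weights
`exp(-max(d2 - 2 sigma^2, 0) / (h sigma)^2)`, where `d2` is the mean squared
patch difference; the `2 sigma^2` subtraction is the usual variance
compensation (two noisy copies of the same patch differ by `2 sigma^2` per
pixel in expectation). The defaults are `h = 0.71`, 5x5 patches, distance 6.

`h` is dimensionless and scales the noise level: `h * sigma` is the
filtering bandwidth. An alternative reading — `h` relative to the
normalised image range — was tried first and rejected: on high-contrast
anatomy a range-relative bandwidth of 0.71 averages across tissue
boundaries so aggressively that the baseline fails to improve on the noisy
input at all, whereas the noise-relative bandwidth works at both raw-knee
(~1e-5) and simulated-brain (~1e3) scales with the same `h`. When no noise
level is available the range-relative fallback is kept; `sigma = 0` is the
zero-bandwidth limit and returns the input.

In the experiment driver the baseline runs on **magnitude** images by
default (`nlm_domain = "magnitude"`): traditional MRI denoisers operate in
the magnitude domain — that is precisely the practice the complex-space
methods here are positioned against — and in that domain the patch
statistics are Rician-corrupted, which reproduces the documented behaviour
of NLM on MRI: clearly positive denoising at every noise level, bought with
visible edge and tissue erosion. The per-channel complex variant
(`nlm_denoise_complex()`) is also exported; on a piecewise-constant phantom
with variance-compensated weights it is close to an oracle (patch
redundancy is exact) and will out-sharpen any learned method — a phantom
artefact worth keeping in mind when reading edge scores.

## The phantom generator

`phantom_spec()` / `generate_phantom_slice()` provide the ground truth that
licensed MRI datasets cannot: randomised Shepp-Logan-style anatomy — a head
ellipse with `tissue_count - 1` smooth-boundary tissue ellipses whose size
varies through-plane — with intensities drawn from `intensity_range`
(default up to 2000 arbitrary units, so sigma in {50, 100, 200} spans
visibly low to high corruption), a band-limited random phase field (the
complex-space claim of the methods is vacuous on real-valued data, so a
non-constant phase is mandatory), and an exactly-zero background outside
the head covering at least `background_margin` of the image (the property
the sigma estimator relies on). Everything is a deterministic function of
`(seed, subject, slice)`.

What the phantom does *not* emulate: tissue-specific MR contrast physics,
coil sensitivity profiles, acquisition artefacts, spatially varying or
non-Gaussian noise, and real anatomical texture. Passing the package's
tests therefore demonstrates the correctness of the estimators and the
qualitative ordering of the methods under the stated noise model — not
clinical performance on real scans.

## Noise-level estimation

`estimate_sigma_background()` exploits the zero-signal background: the
magnitude of pure complex Gaussian noise is Rayleigh. Selecting the
lowest-magnitude fraction of pixels truncates that distribution, so the
naive pooled standard deviation of the selection is biased low by a factor
of ~4 at fraction 0.1. The estimator instead iterates a self-consistent
threshold `t = 2 s`: pixels below `t` are treated as truncated-Rayleigh
noise, whose mean square determines `sigma` through
`E(r^2 | r <= t) = 2 sigma^2 g(rho)`, `rho = t^2 / (2 sigma^2)`. At the
fixed point the truncation is mild (`rho = 2`, 86% of noise pixels kept)
and the inversion is well-conditioned, unlike the deep-tail moment, which
carries almost no scale information. Monte-Carlo checks recover the
injected sigma to within a few percent at 192 x 192 whenever the true
background covers the selection fraction and the signal sits well above
`2 sigma`.

## The desk protocol (and why its numbers are what they are)

The `"desk"` preset of `experiment_config()` is the package's self-contained
study: 16 subjects (12 train / 4 test) of two 64 x 64 slices each, noise
levels {50, 100, 200} on intensities up to 2000, scale 1/2000, depth-2
networks with 16 base features trained 30 epochs. The optimiser settings
are deliberately faster than the full-size protocol's (SURE: batch 2,
learning rate 1e-3; blindspot: batch 1, learning rate 5e-3): a 30-epoch
schedule provides only a few hundred Adam steps, and — because Adam's
per-step movement is bounded by the learning rate — the blindspot variance
head in particular needs both the larger rate and a sensible starting
point to calibrate itself. Its bias is therefore initialised so the
initial prior variance equals the known `sigma^2`, the natural scale at
which the posterior balances prediction and observation; in the softplus
regime below zero the gradient is multiplicative, so training adjusts the
variance in log-space from there. These sizes keep the whole study — six
network trainings plus NLM and metrics — around ten minutes on a single
CPU while preserving every qualitative property of the full protocol: all
methods beat the noisy baseline at every noise level, the noisy
complex-space MSE equals `2 sigma^2` to within Monte-Carlo precision, and
the blindspot posterior preserves tissue edges better than magnitude-domain
NLM.
The full-size `"brain"` and `"knee"` presets carry the reference protocol
parameters (depth 5, 48 features, 300 epochs, batches 10/5, learning rate
3e-4, crops 320/192) and are meant for real or full-scale simulated
volumes.

Evaluation computes MSE, PSNR and SSIM on magnitude images with
`MAX` = the ground-truth volume's maximum magnitude (the metric domain is
switchable; magnitude is the convention under which published MSE scales
for simulated brain data are consistent), and additionally records the
complex-space MSE, whose noisy-row value `2 sigma^2` anchors the whole
pipeline. SSIM uses the standard constants `C1 = (0.01 MAX)^2`,
`C2 = (0.03 MAX)^2`, a 7-pixel Gaussian window of sd 1.5, and implements
both the general three-term form and the simplified single-fraction form,
which agree algebraically under the default exponents.

## Numerical choices and degenerate inputs

* Fourier transforms are unitary with the zero frequency centered; this
  preserves total power (Parseval) and noise variance across domains.
* Centre crops drop the extra row/column on the high-index side for odd
  remainders; k-space zero-padding centres the original block.
* U-Net inputs not divisible by `2^depth` are reflect-padded (without edge
  repetition) and cropped back after the forward pass.
* The blindspot variance head is floored at `1e-8` scaled units squared;
  `posterior_mean()` with `sigma = 0` short-circuits to the input.
* Training aborts with a diagnostic on a non-finite loss, which in practice
  means a wrong scale factor.
* Non-even pooling inputs, non-square blindspot inputs, negative sigmas,
  and out-of-range crop sizes raise immediate errors rather than silently
  degrading.

## Known limitations

* The gradients are computed by hand-written backpropagation over a small
  set of layer primitives; the layer set is exactly what the two
  architectures need, not a general framework.
* Only single-coil 2-D data are supported; no coil combination, no 3-D
  receptive fields, no Rician-domain processing.
* The SURE variant requires a known (or background-estimated) sigma; there
  is no blind variant.
* Training uses per-slice batching; per-volume batching is not
  implemented.
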
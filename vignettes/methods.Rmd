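---
title: "Methods: phantom simulation, network training and evaluation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom simulation, network training and evaluation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octenhance)
```

`octenhance` implements a complete desk-scale pipeline for neural
enhancement of retinal OCT B-scans: a synthetic phantom simulator that
produces paired (noisy, frame-averaged, clean) B-scans, the BRUNet 9.4
enhancement network and its three comparison architectures, the training
and multi-network distillation machinery, a test-time ensemble, and the
objective and intergrader evaluation statistics. This vignette records the
scientific choices behind each stage: the models, their assumptions, the
defaults, and what the synthetic experiments do and do not demonstrate.

## The image currency

All images are single-channel matrices of intensities in $[0, 1]$ (rows =
depth, columns = lateral position). File I/O maps 8- or 16-bit integer
samples linearly onto this range. Every corruption and enhancement step is
closed over this currency — outputs are clipped back to $[0, 1]$ — so any
stage can be composed with any other.

## Phantom simulation

Real clinical B-scans cannot ship with the package, so supervised
experiments run on layered retinal phantoms. A phantom consists of

* `n_layers` horizontal bands (default 6) delimited by smooth, non-crossing
  lateral boundary curves (sums of low-frequency cosines), one band bright
  (reflectivity 0.9) in the position of the retinal pigment epithelium;
* band-edge softening by a ~0.75 px sigmoid transition, because real layer
  interfaces are not step edges at OCT resolution;
* optional vessel shadows: Gaussian lateral darkening (strength 0.6) cast
  downward from the inner retina, mimicking blood-vessel attenuation;
* a choroid-like region below the deepest boundary whose intensity decays
  exponentially with depth (rate 0.05 per row), emulating signal loss in
  deeper tissue.

The generator returns the geometry (boundary curves, reflectivities,
vessel positions) alongside the image so tests can re-render the scene
independently. Phantoms are cosmetic stand-ins: they reproduce the
*statistical* structure a denoiser must cope with (piecewise-smooth bands,
a bright reference band, shadows, attenuation) but not OCT physics — no
A-scan formation, speckle decorrelation or polarization. Conclusions from
phantom experiments therefore transfer to real scans only qualitatively.

### Acquisition noise and frame averaging

Acquisition is simulated as additive noise per frame — Gaussian or
(mean-uncentered, nonnegative) Rayleigh — following the additive wording of
the training recipe; a multiplicative speckle-style variant exists behind
`noise_spec(multiplicative = TRUE)` but is off by default. The package's
standing acquisition condition for phantom datasets is additive Gaussian
noise with $\sigma = 0.1$ on $[0,1]$ images and $N = 9$ frames averaged,
matching the 9-times-averaged acquisition protocol of the clinical test
set; $\sigma = 0.1$ was chosen once as a plausible speckle scale for
normalized OCT exports and is not tuned anywhere.

`simulate_averaged_scan()` adds two imperfections that limit averaging in
practice:

* **Correlated noise.** A fraction `correlation` $= \rho$ of the noise
  variance is shared across frames
  ($n_i = \sqrt{\rho}\, s + \sqrt{1-\rho}\, e_i$), so the SNR gain of
  $N$-frame averaging falls below the i.i.d. $\sqrt{N}$ law.
* **Fixation jitter.** Each frame is shifted laterally by a uniform integer
  in $[-j, j]$ pixels (edge replication) before averaging, which blurs the
  average exactly as imperfect fixation does.

With $\rho = 0$ and $j = 0$ the window-SNR gain of the average over a
single frame is $\sqrt{N}$; this is enforced by tests for
$N \in \{4, 9, 16\}$. (Integer jitter with edge replication is the simplest
model producing averaging blur; sub-pixel motion is out of scope.)

Train/test splits are made *by phantom*, never by frame, so no geometry
seen in training can appear in evaluation.

## Augmentation

Training inputs pass through up to four corruption groups, each active
independently with probability 0.5 and redrawn once per mini-batch:

| group     | model                      | parameter ranges (defaults) |
|-----------|----------------------------|------------------------------|
| noise     | additive Gaussian/Rayleigh | $\sigma_g = 0.5$, $\sigma_r = 0.2$ |
| intensity | $a\,x^g + b$, clipped      | $a, b, g \in [0.5, 1.5]$    |
| geometric | rotate + scale about center| $r \in [-45^\circ, 45^\circ]$, $s \in [50\%, 150\%]$ |
| blur      | Gaussian, reflect boundary | $\sigma = 1.0$ px           |

Composition order is fixed (noise → intensity → geometric → blur) and every
draw is recorded, so a recorded parameter set replays bit-identically.
Noise before blur makes the harder curriculum (the network must undo
smeared noise). During supervised training the geometric draw is replayed
identically on input *and* target — a rotated input must map to the equally
rotated target — while noise, intensity and blur corrupt the input only;
this is the only self-consistent supervised reading. Note that
$b \in [0.5, 1.5]$ saturates heavily after clipping; the interval follows
the published recipe literally and is config-overridable.

## Architectures

Four encoder–decoder families are implemented as pure image-to-image
functions over a pyramid of `levels` scales (channels double per level from
`base_channels`):

* `unet` with transposed-convolution or bilinear upsampling —
  concatenation skips, the two standard baselines;
* `brunet` — the branch-residual U-shaped lineage: a concatenation-skip
  U-net that additionally *injects* the $2^k$-times mean-downsampled input
  image as an extra channel at every encoder level;
* `brunet94` — the 9.4 revision: two back-to-back 3×3 convolution blocks
  (convolution + rectifier) per level on both paths, a horizontal block of
  the same shape between the paths at the coarsest level, and **summation**
  skips instead of concatenation.

Where the published description is silent, the package fixes conventions
and exposes them as flags:

* *Downsampling*: 2×2 max pooling between encoder levels (the standard
  U-net choice); the injected input pyramid uses 2×2 mean pooling, since it
  is an image resize rather than a feature selection.
* *"every other" skip wording*: read as "each downsampling block's output
  is added to the corresponding upsampling block's input" at every level;
  the literal alternate-level variant is available via `alt_skips = TRUE`.
* *Channel matching for summation skips*: bilinear upsampling preserves
  channel counts, so a 1×1 channel-halving projection follows it
  (`project_on_upsample`); transposed convolutions halve channels
  themselves. Disabling the projection under summation skips is a
  construction-time error, which the audit enforces.
* *Normalization*: none; the rectifier is the only nonlinearity.
* *Output head*: a 1×1 convolution, **plus the network input** (a residual
  head, `residual_head = TRUE`), clamped to $[0, 1]$. The residual form was
  chosen because with a hard clamp and random initialization the head can
  saturate and extinguish all gradients, and because residual learning is
  the standard formulation for image denoisers; the head is
  zero-initialized so a freshly built network is exactly the identity map.
  The plain clamped head remains available via `residual_head = FALSE`.

Inputs whose dimensions are not divisible by $2^{L-1}$ are mirror-padded
and the output cropped back, so forward passes are always
shape-preserving. All parameters are He-initialized deterministically per
seed. The networks and their backpropagation are implemented directly in R
on (H·W)×C feature matrices with im2col/GEMM convolutions; gradient
correctness is verified against finite differences in the test suite for
every layer type.

## Training

The loss is `MAE + (1 − SSIM)` between output and the frame-averaged
target. The published phrase "the sum of the MAE and the SSIM" literally
rewards dissimilarity; the standard SSIM-dissimilarity form is used
instead (the alternatives −SSIM and DSSIM/2 differ only by an affine
transformation of the same gradient direction). SSIM uses the conventional
11×11 Gaussian window, $\sigma = 1.5$, $K_1 = 0.01$, $K_2 = 0.03$, dynamic
range 1, computed on the valid interior; its analytic gradient is derived
in closed form (see `ssim_with_grad`) and checked against finite
differences.

Optimization is mini-batch Adam. Faithful defaults are 500 epochs at
learning rate $10^{-4}$ with full augmentation and batch size 8 (batch
size is not specified in the recipe; 8 is a common choice at this image
size), with no early stopping. Desk-scale runs compress the schedule: the
package's reference experiment trains brunet94 (L = 3, 8 base channels) for
15 epochs on 200 phantom pairs of 64×64 pixels. Compressing ~31,000 Adam
steps into ~375 requires a proportionally larger step size, so desk runs
use learning rate $10^{-3}$ and disable augmentation (375 steps cannot
average over stochastic corruption); these are schedule-compression
choices fixed a priori, not tuned quantities. Training is reproducible per
seed under single-threaded BLAS.

### Distillation

`distill_synthetic_set()` reproduces the multi-network distillation scheme
at configurable scale: one network per cell of an
(architecture × dataset × noise model × augmentation tier) grid, each
trained to restore its dataset's clean images from the cell's corruption,
then all applied to the base images and pixel-wise averaged into new
training targets. Cells share the base seed and differ only by their
content, exactly as the 72-network full-scale grid differs by architecture,
dataset, noise model and augmentation tier; the distilled dataset always
has the size of the base dataset. The four-variant deployment recipe
(base, fine-tuned on either device set, fine-tuned on all) is expressed by
`train_ensemble_variants()`.

## Inference ensemble

`ensemble_enhance()` applies every member network to the unmodified input
and (by default) to its histogram-equalized variant and returns the
unweighted pixel-wise mean — with four members, the mean of eight images.
Equalization is global over 256 bins (not adaptive/CLAHE, which the recipe
does not mention); constant images are returned unchanged since they have
no histogram to flatten. The mean is computed once per variant, so the
output is invariant to member ordering, and a single-member ensemble
without equalization reduces bit-exactly to that member's forward pass.

## Evaluation statistics

* **Immerkaer noise estimate**: $\hat\sigma = \sqrt{\pi/2}\,
  \frac{1}{6(W-2)(H-2)} \sum |I * M|$ with the 3×3 second-difference mask
  $M$; exact zero on constant and planar images, unbiased for additive
  Gaussian noise (verified to within 5% at $\sigma \in \{0.05, 0.1,
  0.2\}$).
* **Window SNR**: mean(signal window) / sd(noise window), the conventional
  reading of comparing "a window in the noisy area" against "a region with
  signal" when no pure background is available. Default phantom windows
  put noise in the vitreous strip above the retina and signal across the
  bright band's rows; both are overridable. The ratio is scale-invariant
  and grows as $\sqrt{N}$ under uncorrelated averaging.
* **Paired comparisons**: two-sided paired Student's t-test on per-image
  metrics (delegated to `stats::t.test`); degenerate all-equal differences
  are rejected rather than reported as infinite statistics.
* **Cohen's kappa** per biomarker and condition from the 2×2 contingency,
  with $\kappa \equiv 1$ when both graders are constant and identical
  ($p_e = 1$); no inferential comparison between kappas is computed,
  matching the original analysis choice.
* **Wilcoxon signed-rank** for subjective 1–10 quality scores: zeros
  dropped, midranks for ties, exact two-sided p by convolving the
  signed-rank null over doubled midranks for $n \le 25$ nonzero
  differences, tie-corrected normal approximation beyond. These
  conventions are pinned explicitly (rather than delegated) so results are
  bit-reproducible under ties, which 1–10 integer scores produce
  constantly; the implementation is cross-checked against
  `stats::wilcox.test` and an exhaustive $2^8$ enumeration.

The grading simulator plants a known agreement structure (per-grader flip
probability $q$ over latent flags of prevalence 0.3), for which the
population kappa is analytic:
$p_o = (1-q)^2 + q^2$, $m = \pi + q(1 - 2\pi)$, $p_e = m^2 + (1-m)^2$,
$\kappa = (p_o - p_e)/(1 - p_e)$. Recovery of this value within ±0.05 at
2,000 images is part of the acceptance suite.

## Numerical choices and degenerate inputs

* Clipping to $[0, 1]$ after every corruption keeps the currency closed;
  the clamp's gradient is zero outside the open interval.
* SSIM shrinks its window to the largest odd size that fits when an image
  is smaller than 11 px — only relevant for toy inputs.
* Max-pool gradients split equally among tied maxima; ties have measure
  zero for noisy inputs but occur on constant test images.
* File encoding rounds half-to-even (base R `round`), stated so written
  PNGs/TIFFs are byte-reproducible; PNG output is 8-bit, 16-bit output
  uses TIFF.
* Geometric transforms resample bilinearly with reflect padding; the exact
  `r = 0, s = 1` call is short-circuited to the bit-identical input.

## Problem sizes

The reference experiments are sized for a single CPU: 64×64 phantoms, 200
training pairs, 15 epochs for the enhancement experiment; 2 000 simulated
images for agreement recovery; 10 seeds per Monte-Carlo estimate. These
sizes are the package's standing desk-scale conditions; the full-scale
recipe (thousands of clinical B-scans, 500 epochs, a 72-network grid) is
expressible with the same functions by changing the configuration.

## Known limitations

* Phantoms are not OCT physics; passing phantom tests demonstrates the
  machinery (losses, gradients, statistics, contracts), not clinical image
  quality. The headline clinical numbers (SNR 1.56 → 12.32, the per-
  biomarker kappas) depend on proprietary data, human graders and
  months-long training, and are out of scope by design.
* Desk-scale training cannot saturate the architectures; the enhancement
  experiment demonstrates noise reduction and SSIM improvement, not
  state-of-the-art denoising.
* The additive Rayleigh/Gaussian noise models ignore the multiplicative,
  spatially correlated character of real speckle (a multiplicative option
  exists but is untested against real data).
* Only two-rater agreement is implemented; multi-rater statistics (Fleiss)
  are out of scope.
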
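# octenhance

Neural enhancement of retinal OCT B-scans, with the evaluation machinery to
judge whether enhancement helps.

Optical coherence tomography images are limited by speckle noise; clinics
work around it by averaging N co-located scans, which buys roughly a √N
signal-to-noise gain at the cost of N-fold acquisition time, patient
fixation and residual blur. `octenhance` implements the alternative: a
compact encoder–decoder convolutional network (the BRUNet 9.4 design — two
back-to-back 3×3 convolution blocks per pyramid level, a horizontal block
at the coarsest level, summation skip connections and an injected input
pyramid) trained to map a single noisy B-scan to its frame-averaged
counterpart, with the loss

    L(ŷ, y) = MAE(ŷ, y) + (1 − SSIM(ŷ, y)),

mini-batch Adam, on-the-fly stochastic augmentation (additive
Gaussian/Rayleigh noise, a·x^g + b intensity manipulation, rotation/scale,
Gaussian blur, each active with probability ½), multi-network distillation
into a synthetic training set, and test-time ensembling: every member
network applied to the unmodified and the histogram-equalized input, the
mean of all (typically 4 × 2 = 8) outputs returned.

Because clinical scans cannot ship with a package, `octenhance` includes a
layered retinal phantom simulator (smooth non-crossing bands, a bright
RPE-like band, vessel shadows, depth attenuation, correlated noise and
fixation jitter, N-frame averaging) that produces paired
(noisy, averaged, clean) datasets for supervised experiments, plus the full
evaluation suite used to assess enhancement:

* objective: the Immerkaer noise estimator
  σ̂ = √(π/2) · Σ|I∗M| / (6(W−2)(H−2)), window SNR
  (mean(signal)/sd(noise)), SSIM, MAE, paired t-tests;
* intergrader: Cohen's κ = (p_o − p_e)/(1 − p_e) per biomarker
  (IRF, SRF, ERM, Drusen, RPD, GA, iRORA, PED, HE, SCAR_FIB) and condition,
  and the Wilcoxon signed-rank test on subjective 1–10 quality scores, with
  a planted-agreement simulator for calibration.

The intended users are image-analysis researchers who want a transparent,
dependency-light reference implementation of this enhancement-and-
evaluation pipeline that runs end-to-end on a desk CPU.

## Worked example

Train a small denoiser on synthetic phantoms and evaluate it on held-out
phantoms (about six minutes on one CPU):

```r
library(octenhance)

ds  <- make_paired_dataset(250, phantom_config(), seed = 101, split = 0.8)
net <- build_network(network_spec("brunet94", levels = 3, base_channels = 8),
                     seed = 102)
net <- train_network(net, ds$train,
                     train_config(epochs = 15, learning_rate = 1e-3,
                                  batch_size = 8, augmentation = NULL,
                                  seed = 103))
round(net$history, 4)
#>  [1] 0.5913 0.4550 0.3246 0.2848 0.2736 0.2676 0.2640 0.2612 0.2595 0.2575
#> [11] 0.2565 0.2550 0.2548 0.2533 0.2528

enh <- lapply(ds$test, function(s) predict(net, s$noisy))
noise_noisy <- sapply(ds$test, function(s) immerkaer_noise(s$noisy))
noise_enh   <- sapply(enh, immerkaer_noise)
median(noise_noisy); median(noise_enh)
#> [1] 0.09789366
#> [1] 0.01579864
paired_quality_stats(noise_noisy, noise_enh)
#> # A tibble: 1 x 5
#>   statistic  p_value    df mean_difference     n
#>       <dbl>    <dbl> <dbl>           <dbl> <int>
#> 1     -313. 1.49e-82    49         -0.0821    50
```

The training loss falls monotonically; on the 50 held-out phantoms the
median estimated noise drops from 0.098 (the simulated acquisition sigma
0.1) to 0.016, a sixfold reduction that the paired t-test confirms
decisively, and SSIM to the clean phantom improves in every image.
Ensembling and grading analysis follow the same pattern:

```r
ens <- oct_ensemble(list(net), use_histeq = TRUE)
out <- ensemble_enhance(ens, ds$test[[1]]$noisy)

rec <- simulate_grading_records(2000, q_original = 0.1, seed = 1)
agreement_report(rec)$kappa
```

`tidy()`, `glance()` and `autoplot()` methods cover trained networks,
quality reports and agreement reports; a thin command-line front end in
`inst/cli/octenhance.R` exposes `simulate`, `train`, `enhance`, `evaluate`
and `agree` subcommands over YAML configs.

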
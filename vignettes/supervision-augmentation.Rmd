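---
title: "Supervision augmentation: uncertainty-masked ensembles for lesion segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervision augmentation: uncertainty-masked ensembles for lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saen)
```

## The problem

Diffuse lesions such as white matter hyperintensities (WMH) on T2-FLAIR MRI
have genuinely ambiguous boundaries: periventricular lesions look sharp and
are annotated reliably, while deeper lesions fade gradually into normal
tissue, so a rater's outline there is partly arbitrary. With only one
annotation per image, a high-capacity segmentation network happily fits this
boundary noise and generalizes worse for it. Methods that pool several
raters' annotations fix this by exposing the model to *diverse* supervision
-- but multiple annotations rarely exist in practice.

Supervision augmentation manufactures that diversity from a single
annotation. The pipeline has two stages:

1. **Annotation-uncertainty estimation.** A Bayesian U-Net -- an ordinary
   U-Net with dropout kept active at inference (Monte-Carlo dropout) -- is
   trained on the full annotations. For a training image $x$ it is sampled
   $T$ times; writing $p_t(m)$ for the foreground softmax probability of
   pixel $m$ in sample $t$, the predictive mean and the *probability
   variation*
   $$\mathrm{Mean}(m) = \frac{1}{T}\sum_t p_t(m), \qquad
     \mathrm{Var}(m) = \Big(\frac{1}{T}\sum_t p_t(m)^2 -
     \mathrm{Mean}(m)^2\Big)^{1/2}$$
   are computed per pixel. Where the samples agree the model is certain and
   $\mathrm{Var}$ is exactly zero; where the annotation is ambiguous (lesion
   boundaries, small deep lesions) dropout perturbations flip the
   prediction and $\mathrm{Var}$ is large. Min-max normalization per image
   maps the variation onto $[0, 1]$, giving the uncertainty map $U(x)$.

2. **Masked-loss ensemble training.** For a threshold $\lambda$, the binary
   supervision mask
   $$\mathrm{Mask}(x_m) = \mathbf{1}\,[\,U(x_m) \le \lambda\,]$$
   keeps exactly the pixels whose annotation looks trustworthy. Each of $K$
   base U-Nets is trained with its own $\lambda$, drawn from the grid
   $\{0.1, 0.2, \ldots, 1.0\}$, under the mask-gated cross-entropy
   $$L = -\frac{1}{N}\frac{1}{M} \sum_n \sum_m \sum_c
     \mathrm{Mask}(x_{n,m})\, y_{n,m}^{(c)} \log p_{n,m}^{(c)},$$
   so the $K$ learners see $K$ different croppings of the same ground
   truth. At test time the member probability maps are averaged,
   $\bar p = \frac{1}{K}\sum_k p_k$, the segmentation is the class argmax
   of $\bar p$, and the per-pixel spread of the member foreground
   probabilities is reported as an epistemic uncertainty map.

The aleatoric (annotation) uncertainty lives in stage 1, the epistemic
(model) uncertainty in stage 2; the package exposes both.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `dropoutRate` (theta) | 0.5 | Bernoulli drop probability of the oracle's dropout layers; 0.5 is the classic Monte-Carlo dropout setting. Dropout sits before each max-pooling and after each up-convolution, so a depth-$d$ net has $d-1$ dropout layers per side. |
| `T` (`mcSamples`) | 20 | Monte-Carlo samples per image. The SD of a Bernoulli-perturbed probability stabilizes at a relative error of roughly $1/\sqrt{2T}$; 20 keeps that near 15% at tolerable cost. |
| `lambdaGrid` | 0.1 ... 1.0 | Candidate thresholds. $\lambda = 1$ keeps every pixel (full supervision); smaller values drop increasing amounts of boundary. Schedules sample *without replacement* while $K \le |grid|$ so members are guaranteed distinct supervision. |
| `K` | 5 | Ensemble size; the reference protocol uses five base models. |
| learning rate / weight decay / batch | 1e-4 / 1e-5 / 16 | The reference Adam protocol, kept as `trainConfig()` defaults. |
| patch shape | whole image | Training crops; the reference protocol crops 128 x 192 patches from MRI slices. Phantom images are 64 x 64, so the benchmark trains on whole images. |
| augmentation | flips + right-angle rotations | Flip probability 0.5 per axis, rotation uniform over 0/90/180/270 degrees. Right angles and flips are pure index permutations, so labels and masks stay exactly binary; a continuous-angle mode was deliberately not made the default for that reason. |

### Desk-scale learning rate

`benchmarkSpec()` overrides the learning rate to 5e-3 with batch size 8.
The reason is step-count arithmetic, not tuning: 60 images x 20 epochs /
batch 8 is about 150 Adam steps, and Adam moves each weight by roughly the
learning rate per step, so at 1e-4 the cumulative parameter motion (~0.015)
could never leave the Gaussian initialization (He scale, ~0.1-0.5). At
GPU scale (tens of thousands of steps) 1e-4 is the right protocol; at a
hundred steps the equivalent protocol needs a proportionally larger rate.

## The phantom generator

Real WMH data cannot ship with a package, and the acceptance properties
must be checkable offline, so the package generates two-channel 2D phantoms
that emulate the *uncertainty structure* of FLAIR+T1 slices:

* "periventricular" lesions: warped ellipses confined to a central vertical
  band, with hard intensity edges -- the regime where annotations are
  reliable;
* "deep" lesions: the same shapes placed outside the band with Gaussian
  intensity ramps (`boundaryBlurSigma`, default 1.5 px) -- the ambiguous
  regime;
* channel 1 carries full lesion contrast (amplitude 1 over background 0,
  noise SD 0.15, SNR ~ 6.7), channel 2 half contrast, forcing genuinely
  multi-channel input;
* the observed annotation is produced by thresholding the clean label's
  signed distance transform plus a smooth Gaussian random field (white
  noise smoothed at sigma = 3 px, rescaled to SD = `annotationJitterSigma`,
  clipped at twice that). This yields spatially correlated, rater-like
  boundary errors: every disagreement with the clean label provably lies
  within $3\sigma$ of a true boundary pixel and lesion cores are never
  relabelled.

What the phantoms do **not** emulate: anatomy (no ventricles, no bias
fields), 3D continuity across slices, scanner-specific intensity
distributions, or structured rater biases (systematic over-segmentation).
Tests passing on phantoms therefore demonstrate that the machinery is
correct and that the method's qualitative claims hold under
boundary-concentrated annotation noise -- not that any particular Dice
level transfers to clinical MRI.

## Numerical choices

* **Probability variation.** The predictive covariance reduces, for binary
  segmentation, to the per-pixel SD of the foreground probability; the
  population ($1/T$) convention is used so that identical samples give
  exactly zero. Normalization is per image (min-max), because lambda is
  drawn from one fixed $[0,1]$ grid and every image must occupy the same
  scale; a constant variation map normalizes to all zeros (fully certain).
* **Mask boundary.** $U \le \lambda$ is inclusive; the included-pixel count
  is a right-continuous step function of lambda with jumps exactly at
  observed uncertainty values.
* **Loss denominator.** The masked loss divides by the total pixel count
  $M$ (the literal formula), not the masked count; masking therefore only
  removes terms, and small-lambda members see a smaller effective loss.
  The alternative normalization is available (`normalizeBy = "masked"`)
  since it changes the effective learning rate per member.
* **Probabilities are clipped at 1e-7** before the log.
* **Fusion ties.** A fused foreground probability of exactly 0.5 resolves
  to foreground (documented and tested).
* **Sliding windows.** 50% overlap, uniform averaging, final window clamped
  to the image edge (no padding artifacts; border pixels are covered by
  more than two windows rather than padded).
* **H95.** Boundary pixels are foreground pixels with an 8-neighbor
  background pixel; directed distances use an exact Euclidean distance
  transform, the percentile is the type-7 sample quantile, and the larger
  directed percentile is reported. Empty masks return the image diagonal
  as a flagged sentinel; empty-vs-empty Dice is 1.
* **Precision and determinism.** The network engine runs in single
  precision (the standard working precision for CNN training) over BLAS
  gemm; everything else is double. All randomness flows from explicit
  seeds through R's RNG, including the C++ dropout masks, so every stage
  is bit-reproducible in a fixed environment; across BLAS builds or thread
  counts, floating-point summation order may differ, so cross-environment
  reproducibility of trained weights is stated at 1e-6 rather than
  bit-exactness.
* **Member seeds** derive from the master seed plus the member index --
  reproducible and sufficiently independent at this scale.
* **The oracle scores the images it was trained on.** This is the
  two-stage design being reproduced (the uncertainty is meant to describe
  the *training* annotations); it is intentional, not leakage into any
  test metric.

## Design choices where the design was open

* **Epochs** are a required training parameter (no reference value exists);
  the benchmark uses 20 with early stopping absent.
* **Lambda assignment** is without replacement for $K \le |grid|$:
  distinct thresholds per member maximize supervision diversity, which is
  the method's stated purpose. (With replacement is used only when $K$
  exceeds the grid.)
* **Masks are frozen**: computed once from the oracle before ensemble
  training, never refreshed -- the two-stage structure, not co-training.
* **Dropout in base members is off** by default; stochasticity there is
  not needed once the ensemble provides the epistemic spread.
* **Ensemble-size sweeps reuse nested member subsets** (sizes 1, 3, 5 share
  the trained members), mirroring protocols that train one base model per
  lambda and fuse increasing numbers of them.
* **Evaluation labels.** Benchmark metrics are computed against the *clean*
  phantom labels, while training only ever sees the jittered annotations;
  this measures exactly the denoising the method claims.

## The standard phantom benchmark

`benchmarkSpec()` defines the package's reference experiment: 60 training
and 15 test phantoms (64 x 64, jitter 1.5 px), depth-3 U-Nets with 8 base
filters (~29k parameters), K = 5, T = 20, 20 epochs, five repeats under
distinct master seeds, comparing the supervision-augmented ensemble against
a single fully supervised baseline (and optionally a
random-weight-initialization ensemble). These sizes were chosen so the full
five-repeat benchmark trains 35 networks on one CPU core in roughly a
quarter of an hour; the test suite runs this experiment once and checks
three patterns on it:

* the fused Dice is at least the mean member Dice in every run, and beats
  the single baseline in at least 4 of 5 seeds;
* the repeat-to-repeat SD of the fused Dice does not grow from K = 1 to
  K = 5 (within one standard error of an SD estimated from five repeats,
  $\mathrm{SE} \approx \mathrm{SD}/\sqrt{2(n-1)}$);
* the oracle's normalized uncertainty within 2 px of true lesion
  boundaries exceeds the lesion-interior mean in at least 4 of 5 seeds.

`scripts/acceptance.R` re-runs a two-repeat version of the same experiment
from a command-line seed and writes the headline numbers as JSON.

```{r, eval = FALSE}
spec <- benchmarkSpec()
bm <- runBenchmark(spec, outDir = "benchmark", verbose = TRUE)
bm$summary
```

## Known limitations

* 2D only; volumes are treated as independent slices.
* At the phantom scale the lesions are small (radii 4--9 px), so the
  uncertain boundary band that masking removes is a large fraction of each
  lesion's area: members trained at low lambda are measurably weaker than
  the fully supervised baseline, and the zero-mean annotation jitter is
  largely averaged out by the baseline itself over 60 training images. In
  this regime the benchmark shows the fused-vs-member gain and the
  variance-reduction pattern robustly, while the fused ensemble's margin
  over a *single* fully supervised model sits at the seed-to-seed noise
  floor (a fraction of a Dice point either way). Larger lesions relative
  to the uncertain band -- the realistic WMH situation -- are where the
  masking mechanism has room to pay off.
* The phantom noise model is symmetric around the true boundary; real
  raters can be systematically biased, which supervision masks cannot fix.
* Lambda is sampled, not optimized; on a new dataset the grid's range
  should be checked against the observed uncertainty histogram.
* The single-precision CPU engine is built for desk-scale experiments
  (tens of thousands of parameters); it is a faithful, tested substrate
  for the method, not a general-purpose deep-learning framework.
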
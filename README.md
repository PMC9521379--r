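# saen — supervision-augmented ensembles for lesion segmentation

Annotations of diffuse lesions — the motivating case is white matter
hyperintensity (WMH) segmentation on FLAIR/T1 brain MRI — are noisy exactly
where lesions are ambiguous: at blurry boundaries and around small deep
lesions. Trained on a single such annotation per image, a segmentation
network overfits the rater's boundary noise. `saen` implements *supervision
augmentation*: it manufactures diverse supervision signals from one
annotation and ensembles over them.

The method, in the field's standard notation:

1. **Annotation uncertainty.** A Bayesian U-Net (Monte-Carlo dropout, ratio
   θ, dropout before each max-pooling and after each up-convolution) is
   trained on the full annotations and sampled T times per training image.
   Per pixel, the mean probability and the *probability variation*

       Mean = (1/T) Σₜ Softmax[f(x; Ŵₜ)],
       Var  = sqrt( (1/T) Σₜ pₜ² − Mean² )

   are computed; Var, min-max normalized per image, is the annotation
   uncertainty map U(x).

2. **Masked-loss ensemble.** For thresholds λ drawn from
   {0.1, 0.2, …, 1.0} (without replacement), binary masks
   Mask(xₘ) = 1[U(xₘ) ≤ λ] gate the cross-entropy

       L = −(1/N)(1/M) Σₙ Σₘ Σ_c Mask(x₍ₙ,ₘ₎) y₍ₙ,ₘ₎ log p₍ₙ,ₘ₎^c ,

   so each of the K base U-Nets trains on a different trustworthy subset of
   the same ground truth. Predictions are fused by probability averaging,
   F(x) = argmax (1/K) Σₖ pₖ; the per-pixel spread of the member
   foreground probabilities is an epistemic uncertainty map.

Everything runs on synthetic lesion phantoms shipped as code (sharp
"periventricular" and blurry "deep" lesions with boundary-concentrated
annotation jitter), so the whole pipeline is testable without imaging data.
The package includes a compact single-precision 2D U-Net with analytic
gradients (C++ kernels, Adam), sliding-window inference with 50% overlap,
and the standard metrics: Dice, 95th-percentile Hausdorff distance, voxel
recall, lesion-wise F1, and recall stratified at the median lesion size.

## Worked example

Train the uncertainty oracle on 30 phantoms, build a 3-member ensemble, and
evaluate one held-out phantom (about two minutes on one core):

```r
library(saen)
cfg   <- phantomConfig()                     # 64 x 64, jitter 1.5 px
train <- generateDataset(cfg, 30, seed = 1)
test  <- generateDataset(cfg, 5,  seed = 2)

tc     <- trainConfig(learningRate = 5e-3, batchSize = 8, epochs = 20, seed = 1)
oracle <- trainUncertaintyOracle(train, bayesianUnetConfig(), tc)

u <- estimateUncertainty(oracle, gaussianNormalize(imageArray(train[[1]])),
                         T = 20, seed = 1)
makeMask(u, lambda = 0.4)
#> SupervisionMask 64 x 64, lambda 0.40, 93.2% of pixels kept

ens <- trainEnsemble(train, oracle, K = 3, unetConfig = unetConfig(),
                     trainConfig = tc, masterSeed = 7)
ens
#> EnsembleModel: K = 3, fusion = mean_probability
#>   lambdas: 1.0, 0.3, 0.7

pred <- predictEnsemble(ens, imageArray(test[[1]]))
round(computeMetrics(segmentationMap(pred), cleanLabel(test[[1]])), 3)
#>    dice h95 h95_empty recall lesion_recall lesion_f1 recall_large recall_small
#> 1 0.932   1         0  0.896             1         1            1            1
#>   median_lesion_size n_lesions_gt
#> 1                124            4
```

Reading the numbers: the fused segmentation overlaps the *clean* (noise-free)
label at Dice 0.932 although training only ever saw jittered annotations;
the boundary error is 1 px at the 95th percentile (H95); all four lesions,
large and small, are detected (lesion recall/F1 = 1). The mask at λ = 0.4
dropped the ~7% most uncertain pixels — almost all of them on lesion
boundaries. `epistemicUncertainty(pred)` returns the member-disagreement
map.

`runBenchmark(benchmarkSpec())` runs the full comparison — supervision-
augmented ensemble vs. a single fully supervised model across ensemble
sizes and five seeds — and `endToEnd()` runs the staged, resumable pipeline
(phantoms → oracle → uncertainty → masks → ensemble → prediction →
metrics) with NIfTI/JSON artifacts. A thin CLI wraps both:
`Rscript inst/cli/saen.R benchmark --help`.

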
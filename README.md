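# cinescar

Contrast-free prediction of myocardial scar from cine cardiac MR, in R.

Diagnosing myocardial infarction (MI) with cardiac MR today requires a
gadolinium contrast agent: infarct scar appears hyperintense on late
gadolinium enhancement (LGE) images acquired minutes after injection.
`cinescar` implements a pipeline that tries to recover that post-contrast
information from the *pre-contrast* cine short-axis (SAX) stack alone, for
researchers studying contrast-free MI detection: ground-truth preparation
(trigger-time frame matching and mutual-information affine registration of
LGE onto cine), engineered motion and texture features, weighted
segmentation/classification losses, classical and compact deep classifiers —
all exercisable end-to-end on a synthetic cine/LGE phantom so no clinical
data is needed.

## The method

**Ground truth.** Each cine frame carries a trigger time TT (ms after the
ECG R-wave). The cine frame with TT closest to the LGE image's TT is
selected, the LGE image is registered onto it with an affine transform
(translation, rotation, scale, shear) maximizing Mattes-style mutual
information under a (1+1) evolutionary strategy, stacks are padded to 32
frames with zero arrays, and alignment is scored by normalized
cross-correlation over the myocardium band.

**Features.** Dense Lucas–Kanade optical flow (8×8 window, 5×5/σ = 3
Gaussian weights) between frame pairs enumerated at skip interval *k*
(32 frames at *k* = 3 give 11 pairs); per-pixel displacement
*r* = *v·k·Δt*, PCA-compressed per map. The rate of myocardial area change
*aᵢ* = ΔA/(k·Δt) over the same pairs. Radiomics of the myocardium at the
end-diastolic, end-systolic and middle frames after 1.9 mm area resampling
and 1–99 % percentile quantization to 256 levels: 2D shape, first-order and
gray-level run-length (GLRLM) features, filtered by pairwise correlation
(|r| > 0.9 dropped) and outcome association (point-biserial, keep
p < 0.001).

**Models and losses.** Per-channel Dice
DSC = (2Σyŷ+ε)/(Σy+Σŷ+ε) and the channel-weighted Dice loss
L = Σ βᵢ(1−DSCᵢ) with β = (0.15, 0.25, 0.25, 0.35) for
background/myocardium/cavity/scar; inverse-frequency class weights
λᵢ = (N/C)/kᵢ and the class-weighted cross-entropy
E = −(1/N) Σ λ_c(n) log ŷₙ[c(n)]; RBF-kernel SVM and CART decision tree
with z-scoring fitted on the training split, evaluated by confusion-matrix
metrics, held-out and 10-fold cross-validated ROC/AUC, and permutation
feature importance (10 shuffles). A compact trainable UNet (own CNN engine
with verified backpropagation) trains against the weighted Dice loss; a
canonical ResNet50 architecture audit reports exact parameter counts.

## Worked example

```r
library(cinescar)

compute_class_weights(c(336, 170))
#> class weights (N = 506, C = 2): lambda_0 = 0.753, lambda_1 = 1.488

build_resnet50_classifier(input_channels = 32)
#> ResNet50 classifier spec: 32 input channels, 107 layers
#>   total parameters:     23,680,705
#>   trainable:            23,627,585
#>   non-trainable (BN):   53,120

# end-to-end on the default synthetic cohort (80 scar / 80 healthy,
# 64x64 32-frame phantoms; ~1.5 min on one CPU)
res <- run_pipeline(pipeline_config(seed = 1))
rp <- res$reports[["flow+area+radiomics"]]$svm
rp$classification$accuracy   # 0.938  held-out accuracy (32 test studies)
round(rp$cv$mean_auc, 3)     # 0.988  mean AUC over 10 CV folds
median(res$prep$reg_translation_err_px)  # 0.28 px median registration error
mean(res$prep$qc_pass)       # 0.94   alignment-QC pass rate
```

The class weights are the inverse-frequency weights of a 506-sample
training set with 336 no-scar and 170 scar members — the minority scar
class is up-weighted (1.488 vs 0.753). The ResNet50 audit counts every
parameter of the canonical 50-layer topology with a 32-channel stem and a
single sigmoid output unit; batch-norm moving statistics are the 53,120
non-trainable parameters. In the pipeline run, the SVM separates scar from
healthy phantoms at 0.94 held-out accuracy because the phantom's scar
sector genuinely contracts less, which the flow, area-rate and radiomics
features capture; the registration step recovers each study's simulated
LGE misalignment to sub-pixel median accuracy.

A thin CLI over the same functions ships in `inst/cli/cinescar`
(`cinescar run-all --out DIR --seed 1`).

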
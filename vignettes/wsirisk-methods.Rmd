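---
title: "wsirisk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wsirisk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`wsirisk` classifies a whole-slide image (WSI) of a papillary urothelial
lesion as low or high risk in two stages. First, four *one-vs-rest*
binary patch classifiers score every tissue patch for the four
histologic classes (PUNLMP, low-grade, high-grade, invasive). A patch's
four binary labels are fused by a confidence rule: the patch *resolves*
to a class only when exactly one classifier fires; with zero firings
(all "others" — normal or unrecognized tissue) or two or more firings
(conflicting evidence) it is *eliminated*. This rule needs no tuned
threshold beyond the per-classifier 0.5 binarization. Second, the
per-slide class-ratio vector — counts of resolved patches over all
tissue patches submitted to classification — feeds a Gaussian-process
(GP) binary classifier that returns the posterior probability of high
risk.

The survival module stratifies the *predicted* groups: product-limit
(Kaplan–Meier) curves, the two-group log-rank test (pooled-risk-set
O−E with hypergeometric variance, χ² with 1 df), and a univariate Cox
proportional-hazards fit maximizing the Breslow partial likelihood by
Newton iteration (|Δβ| < 1e−8), with a Wald 95% CI `exp(β ± 1.96·se)`.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| patch size | 224 px | standard CNN input tile for WSIs |
| window overlap | 1/3 (stride = ⌊224·⅔⌋ = 149 px) | dense coverage of lesion area |
| background threshold | all channels ≥ 220 | white glass |
| marker rule | HSV sat ≥ 0.55, value ≥ 0.6, green/blue hue windows | ink is bright *and* chromatic; dark nuclei are chromatic but not bright |
| per-patch background limit | > 0.5 dropped | patch must be mostly tissue |
| learning rate | 0.005 × 0.9^epoch | exponential decay per epoch |
| epochs | 100 (desk tests: 10) | full-scale default vs. CI budget |
| batch size | 64 | conventional default |
| validation split | 10% of slides | tuning partition at slide level |
| positive threshold | p ≥ 0.5 | ties binarize positive (documented) |
| GP kernel | RBF, hyperparameters by marginal-likelihood ascent | smooth monotone decision surface on ratios |
| risk threshold | P(high) ≥ 0.5 ⇒ high | exact ties called high risk: clinically conservative |
| bootstrap | 10 000 percentile replicates | CI for every metric |

## Design choices where the design was open

* **Backbone.** The supported numerical stack has no deep-learning
  framework, so the patch classifier backbone is a compiled (Rcpp/
  Armadillo) 3-conv-block network: 3×3 convolutions (8/16/32 channels),
  ReLU, 2×2 max-pooling, global average pooling, 2-logit softmax head.
  It consumes a block-averaged 28×28 copy of the normalized 224×224
  patch. An 18-layer residual backbone remains a configuration
  identifier (`backbone = "resnet18"`) that errors as unavailable in
  this build. He-style Gaussian init for convolutions; σ = 0.01
  Gaussian for the head. SGD uses momentum 0.9; under the balanced
  sampler an "epoch" is `⌈2·max(n₊, n₋)/batch⌉` draws, so each class is
  expected to be fully visited per epoch.
* **Best-epoch selection.** Validation balanced accuracy is logged per
  epoch and the best checkpoint is kept, ties resolving to the later
  epoch (longer-trained weights win on plateaus).
* **Colour normalization** is a per-channel affine map onto fixed
  reference statistics (means 182/146/167, sds 38/42/40 on the 0–255
  scale) rather than stain deconvolution: deterministic, idempotent,
  testable. A zero-variance channel is centred only. Note a real
  consequence, relevant to the synthetic world below: per-patch
  normalization *erases mean-colour differences between classes*, so
  any class signal must survive in spatial structure and cross-channel
  pattern.
* **Augmentation** (flips, 90° rotations, ±10% brightness/contrast/
  saturation jitter) is applied in the downsampled space during
  training: flips and quarter-turns commute with block-average pooling,
  and the jitter is an affine map per channel, so this is equivalent to
  augmenting at full resolution and ~60× cheaper.
* **Ratio denominator** includes eliminated patches (conservative
  ratios); a `"resolved"`-only denominator is a config option.
* **GP feature space** defaults to the combined 2-vector
  (low-risk ratio, high-risk ratio); the 4-vector of class ratios is a
  first-class option (`feature_mode = "per_class"`). Both feature
  spaces are legitimate; the combined form is the documented default
  because the slide decision is binary.
* **GP likelihood** is probit (not logistic): the Laplace-approximate
  predictive probability is then an exact Gaussian integral
  Φ(μ*/√(1+σ*²)), avoiding a second approximation.
* **Patient aggregation** takes the maximum slide probability — a
  patient is as risky as their riskiest slide: the clinically
  conservative pooling among the reasonable choices (max, mean, vote).
* **Tie handling in Cox fits** is Breslow by default (matches the grid
  oracle cheaply); Efron is available via `ties = "efron"`. Both are
  verified against the `survival` package in the test suite.
* **Serialization.** Configs, model checkpoints and the GP sidecar are
  JSON (the guaranteed stack has no YAML parser); rasters are PNG via a
  built-in minimal codec (zlib streams through `memCompress()`, CRC32
  and scanline filters in compiled code) because no PNG package is in
  the guaranteed dependency set. Round trips are bit-exact and
  cross-checked.

## What the synthetic generator emulates — and what it does not

The generator states a world with the statistical structure the
pipeline assumes:

* four visually distinguishable procedural textures on a pink base —
  dark "nuclei" discs whose *coverage* (≈2% / 13% / 40% / 93%) and blob
  radius (8/8/16/24 px) differ by class. Coverage and blob scale are
  precisely the features that survive per-patch colour normalization
  followed by 8× downsampling; mean colour, which normalization
  destroys, deliberately carries no necessary information;
* white background and optional saturated green/blue marker stripes
  (which the mask must remove);
* mixed-composition slides: contiguous vertical class strips inside a
  tissue band; ground truth follows the ≥5% rule computed on tissue
  area (background excluded);
* survival: exponential event times at the baseline hazard
  (0.01/month), multiplied by the hazard ratio (default 2) in the
  high-risk group; uniform censoring.

Deliberate departures from real data, hence the limits of a green test:
no stain physics, no pyramidal resolution, no spatial intermixing of
grades within a region (one contiguous strip per class), no CIS or
"others" categories, and textures far cleaner than histology. A passing
end-to-end criterion establishes that the *mechanism* — tiling, fusion,
ratios, GP, survival — recovers a recoverable signal; it says nothing
about accuracy on clinical slides.

One consequence of desk scale: a lesion at exactly 5% of tissue is
smaller than a single 224-px patch on a 1024² slide, so
threshold-adjacent compositions cannot be resolved by any patch-ratio
method at this resolution. The default cohort therefore draws high-risk
mixed slides with a high-grade + invasive share of tissue from
U(0.15, 0.7) and caps low-risk admixtures at 4%; the 5% rule itself is
verified exactly at the label-rule level (sweeping 0.049 → 0.051 flips
the label at the threshold). On real gigapixel slides the same rule is
resolvable because a 5% lesion still spans thousands of patches.

## Numerical notes

* All randomness derives from one global seed through named substreams
  (`substream_seed(seed, name)`, CRC32-based), so adding a consumer to
  one stream does not perturb the others; reruns are bit-identical.
* The 0-based, half-open coordinate convention is used everywhere;
  ASAP polygons are reduced to boxes with floor(min)/ceiling(max)
  rounding.
* Grid placement adds no border-flush window: origins are multiples of
  the stride with `origin + patch ≤ extent`. A remainder strip narrower
  than `patch − stride` may go uncovered; the 1/3 overlap makes this
  marginal.
* The GP adds 1e−8 jitter to the kernel diagonal; hyperparameters are
  optimized by Nelder–Mead from three fixed starts (deterministic, no
  random restarts).
* Cox Newton steps are damped to |step| ≤ 2 to survive wild first
  iterations; non-estimability (zero events overall, or either group
  event-free — monotone likelihood) is an explicit error, never a
  number.
* Bootstrap replicates where a metric is undefined are skipped and
  counted, and the count is reported on the interval.

## Known limitations

* The backbone is deliberately small; nothing in the package
  demonstrates that the architecture scales to real histology.
* The GP is exact (O(n³)) — fine for hundreds of slides, not for tens
  of thousands.
* Patch-level class assignment for training requires a region to cover
  ≥ 60% of a patch; very thin annotated regions yield no training
  patches at desk scale.
* The PNG codec handles exactly the formats the package writes (8-bit
  RGB, non-interlaced); it reads all five scanline filters but is not a
  general-purpose decoder.
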
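---
title: "Adversarial semi-supervised lung field segmentation: model, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial semi-supervised lung field segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pixel-level annotation of chest radiographs is expensive, so segmentation
datasets are typically small and only partly annotated; and models trained at
one imaging site degrade at others because acquisition differences shift the
intensity statistics of the images (domain shift). `usgan` implements a single
adversarial framework that addresses both: a generative adversarial network
whose discriminator is itself a U-shaped segmentation network assigning every
pixel one of three labels — lung, background, or fake. Unannotated images
contribute through the real-versus-fake pixel terms, and the same machinery
performs unsupervised domain adaptation (UDA) when the annotated pool is a
source domain and the unannotated pool is an unlabelled target domain.

## Model and losses

A generator $G$ maps noise $z \sim \mathcal N(0, I)$ to synthetic
radiograph-like images. The discriminator $D$ maps an image to a per-pixel
probability distribution over $\{\text{lung}, \text{background},
\text{fake}\}$, obtained by a channel softmax over three logits. There is no
dedicated "real" output: a pixel's real probability is the complement of its
fake probability, $1 - D(x)_{fake}$. The discriminator minimises

$$
L_D \;=\;
\underbrace{-\,\mathbb E_{(x,y)\sim p^l}\big[\log D(y\mid x)\big]}_{L_l,\ \text{annotated}}
\;\underbrace{-\,\mathbb E_{x\sim p^u}\big[\log\big(1 - D(x)_{fake}\big)\big]}_{L_u,\ \text{unannotated}}
\;\underbrace{-\,\mathbb E_{z}\big[\log D(G(z))_{fake}\big]}_{L_g,\ \text{generated}},
$$

and the generator minimises $L_G = \mathbb E_z[\log D(G(z))_{fake}]$. All
expectations are realised as flat arithmetic means over the pixels of the
batch, and the three $L_D$ terms are summed unweighted — no balancing
hyperparameters are introduced. Supervised training uses only $L_l$; UDA uses
exactly the semi-supervised objective with source images in the annotated
role and target images in the unannotated role.

Two interpretive choices were genuinely open and are resolved as follows.
First, annotated images enter only through $L_l$ and are not double-counted
in $L_u$; increasing $D(y|x)$ already lowers $D(x)_{fake}$ through the
softmax coupling, so the supervised term carries the unsupervised effect for
those pixels implicitly. Second, $L_G$ is implemented literally in its
saturating form ($+\log D_{fake}$, minimised); a non-saturating surrogate
$-\log(1 - D_{fake})$ with the same fixed points is available behind
`nonsaturating_generator` and is off by default.

At inference the fake channel is a training device, not a semantic label:
`predict_mask()` compares only the two real classes and labels a pixel lung
iff $p_{lung} > p_{background}$, with ties resolved to background.

## Architecture

The generator projects the noise vector to a small spatial map and applies
one generator block per schedule entry; a block is a pointwise (1×1)
convolution that narrows the channel width followed by two 4×4 fractionally
strided convolutions of stride 2, with instance normalisation and LeakyReLU
(slope 0.2) after every layer, and a 3×3 convolution with a rescaled tanh
producing unit-interval images. The pointwise narrowing is the parameter
lever: at the full scale (1024² output, noise dim 100, channels 2032 → 1008 →
504 → 252 → 126 with pointwise widths 328/164/82/41) the generator holds
13,493,659 trainable parameters, versus 134,148,465 for the identical
schedule without the pointwise layers — a 9.9× reduction. These two counts
are the design constraint the shipped default schedule was solved for; the
schedule itself (one free width per block) is otherwise not uniquely
determined and is exposed in `generator_spec()`.

The discriminator is U-shaped: an encoder, a four-block decoder, and skip
connections that concatenate encoder features into the decoder stage of
matching resolution (U-Net convention). Each decoder block is a 3×3
convolution, a pointwise connector that halves the width, and a 4×4
fractionally strided convolution of stride 2. Two encoders are provided: a
ResNet-50-style stack of bottleneck blocks (stride 32; the full-scale
choice), and a light four-stage CNN (stride 16) that mirrors the stage
layout at desk scale. Pretrained encoder weights are not bundled; the
ResNet-50 encoder initialises randomly, and `build_discriminator()` accepts a
weights file. Instance normalisation is used throughout both networks —
including the encoder — for per-image intensity invariance, which matters
under domain shift. Weight initialisation is $\mathcal N(0, 0.02)$ for all
convolutions.

`count_flops()` reports analytic per-image FLOPs under an explicit
convention: one multiply–accumulate counts as 2 operations, a convolution
costs `out_pixels × cout × (k² × cin) × 2` plus one operation per output
element for its bias, transposed convolutions are charged as their dual
convolution at the upsampled output, and normalisation/activation layers are
excluded. Published FLOP figures for comparable models depend strongly on
unstated conventions, so FLOPs here are for relative comparisons between
configurations, not for matching external numbers.

## Training schedule

The reference protocol is 500 epochs of alternating updates (one
discriminator step, one generator step per iteration) with Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rates 0.001 (generator) and
0.0001 (discriminator), both multiplied by 0.1 after epoch 200;
`full_scale_config()` selects it. An epoch is one pass over the larger pool
with the smaller pool sampled with replacement; annotated and unannotated
batches are drawn independently each iteration; batch size defaults to 16.
No early stopping is used — validation metrics are only logged — and no data
augmentation is applied.

The desk-scale default (`train_config()`) compresses this to 30 epochs at
64² with the small four-stage encoder, keeping the decay point at 40% of the
schedule and scaling both learning rates up tenfold (0.01/0.001). The
scaling compensates for the roughly sixteenfold shorter schedule: Adam's
per-step parameter displacement is bounded by the learning rate, so total
displacement scales like rate × steps, and at the paper-scale rates a
30-epoch run barely leaves initialisation. Desk-scale network widths are
deliberately thin (encoder 4/8/16/32, decoder 16/8/4/4, generator 64/32/16)
so a full training run takes on the order of a minute on one CPU core; the
experiment wrappers below train a dozen such models inside a test suite.

Runs are pure functions of (configuration, data): weight initialisation,
batching, noise, and splits all flow from the configuration seed, so two
identical runs produce bitwise-identical loss trajectories, and a checkpoint
(which stores weights, optimiser state, RNG state, and its spec as embedded
JSON) resumes into the identical trajectory.

## Phantoms: what they emulate, and what they do not

`generate_phantoms()` draws images with two non-overlapping dark ellipses
(the radiolucent lung fields, intensity 0.30) on a brighter background
(0.75) crossed by a horizontal sinusoidal "rib" texture (amplitude 0.08, 6
cycles per image) plus Gaussian noise (sd 0.05), at 64² by default. The
ground-truth mask is exactly the rasterised ellipse interiors, so metric
values carry no annotation error. Geometry is rejection-sampled (area
fraction 0.15–0.30 of the image, vertical/horizontal axis ratio 1.4–2.2,
centres jittered) and generation fails loudly if the configured geometry
cannot fit without overlap.

Domain shift is intensity-only: $x \mapsto \mathrm{clip}(c\,x^{\gamma} +
\text{bias} + \varepsilon)$ with a smooth random low-frequency bias surface
and optional extra noise. Spatial/anatomical shift is deliberately excluded
so the ground-truth masks remain valid in both domains. The UDA experiments
use $\gamma = 2$ with bias amplitude 0.45 at spatial scale 0.3 — calibrated
so that a source-trained model degrades on the target consistently across
bias-field realisations, since instance normalisation already absorbs purely
global intensity remaps and a weaker field degrades transfer only for some
images.

Phantoms exercise every code path — losses, splits, training modes,
evaluation — under exactly known truth, which is what the tests establish.
They do not establish clinical performance: real radiographs have anatomy
(mediastinum, costophrenic angles, devices), annotation ambiguity, and
spatial domain differences that phantoms deliberately lack. Published-scale
Dice values on clinical data are therefore not reproduced here; the
directions of the comparisons are.

## Experiment protocols

`run_semisup_experiment()` follows the annotation-fraction protocol:
fold-stratified assignment of the annotated subset
(⌈fraction × fold size⌉ per fold, so every training portion carries exactly
the nominal fraction), 5-fold cross-validation by default, or a single 70/30
holdout (`k_folds = 1`) when two modes must be paired on identical images
and splits, as in the semi-supervised versus supervised comparison. Rounding
of the annotated count is by ceiling. The full 500-epoch schedule is trained
per fold without early stopping; fold results are reported as mean ± sd of
per-image Dice and Jaccard (macro-averaged over images, matching the way
such results are conventionally tabulated; pooling pixels would weight large
lungs more).

`run_uda_experiment()` splits each domain 7:1:2 (train/validation/test),
trains a supervised model on annotated source training images and a UDA
model on source + unlabelled target training images, and reports four
evaluations: the supervised model on source test (`sup_source`) and target
test (`t_noda`, the no-adaptation transfer), and the UDA model on target
(`uda_target`) and source (`s_test`) test sets. In the package's checks on
phantoms the intensity shift reliably costs the no-adaptation transfer
roughly 0.2 Dice while `s_test` stays within ~0.005 of `sup_source`; the
adaptation gain on the target is directionally positive in a majority of
seeds but seed-variable at this scale — 30 epochs on 70 unlabelled target
images is a small budget for the adversarial alignment to act, and
individual runs can fail to improve on the transfer baseline. The shipped
checks therefore assert the majority direction and the source-maintenance
bound, not a per-run gain.

## Numerical choices and edge cases

* Probabilities are clamped below at $10^{-8}$ inside every logarithm, so
  one-hot maps (which do occur late in training) give finite losses.
* Both metrics define empty-∩-empty as 1 (perfect agreement on "no lung");
  `dice = 2·jaccard/(1+jaccard)` holds identically.
* Mask decoding thresholds at half the source maximum (so 0/1 and 0/255
  dialects decode identically) and resizes nearest-neighbour only; images
  resize bilinearly and are clipped to the unit interval.
* Instance-norm epsilon is $10^{-5}$; a bias parameter feeding an instance
  norm is a null direction of the loss and simply stays near zero.
* Non-finite losses abort training with the offending batch statistics
  rather than continuing silently.
* The annotated-fraction split requires every entry to carry a mask;
  validation rejects annotated/source manifest entries without one.

## Known limitations

* No photorealistic synthesis: the generator at desk scale produces blobby
  textures sufficient to exercise the adversarial dynamics, not plausible
  radiographs.
* Single foreground class; multi-class masks and lesion phantoms are out of
  scope.
* ImageNet-pretrained encoder weights are not distributed with the package;
  full-scale runs start the encoder from random initialisation unless
  weights are supplied.
* CPU-only: the layer kernels (im2col + GEMM via RcppArmadillo) are written
  for correctness and desk-scale speed, not for GPU-scale throughput.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` train at the desk scale stated
above: 200 phantoms (70/30 holdout) for the paired semi-supervised
comparison and 100 phantoms per domain (7:1:2) for the UDA comparison, 30
epochs, batch 16, three seeds each, with smaller configurations (6–10
phantoms, 1–4 epochs, resolution 32) for the behavioural unit tests. These
sizes were chosen so the complete suite runs on a single CPU core in tens of
minutes while still showing the directional effects.
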
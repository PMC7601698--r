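---
title: "Capsule-network adversarial synthesis of MR-like images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capsule-network adversarial synthesis of MR-like images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capgan)
```

## The problem

Supervised learning on medical images is chronically starved of annotated
examples: lesion cohorts number in the hundreds, and class imbalance (rare
pathology vs. common benign findings) makes things worse. One remedy is to
synthesise additional training images with a generative adversarial network
(GAN) and use them as augmentation. `capgan` implements such a model for
2-D grayscale MR-like images, with two distinctive ingredients:

1. the **discriminator is a capsule network** rather than a plain
   convolutional stack, on the argument that capsule vectors retain pose
   and spatial-relationship information that matters for fine-grained
   anatomical structure; and
2. both players are trained with **least-squares losses** instead of the
   original sigmoid cross-entropy, which avoids the vanishing-gradient
   regime of the saturated minimax game.

The package also implements a **KL-divergence quality metric** for
generated images: a texture classifier (HOG + LBP features, calibrated
SVM) is trained beforehand on a two-class image problem; real and
generated sets are pushed through it; and the Kullback–Leibler divergence
between the two binned probability distributions measures how far the
generated set is from the real one in a representation that is sensitive
to medically relevant structure but cheap to train — unlike Inception
Score or FID, which lean on a natural-image network that transfers poorly
to MR data.

## Model

### Capsule primitives

A capsule is a vector-valued unit: its norm encodes the probability that
an entity is present, its direction encodes pose. The primitives are:

* **squash** (`squash()`): $v = \dfrac{\lVert s\rVert^2}{1+\lVert s\rVert^2}
  \dfrac{s}{\lVert s\rVert}$ — direction-preserving, norm in $[0,1)$.
* **prediction vectors** (`predict_vectors()`): $\hat u_{ij} = W_{ij} u_i$.
* **routing by agreement** (`dynamic_routing()`): iterate
  $c_i = \mathrm{softmax}(b_i)$, $s_j = \sum_i c_{ij}\hat u_{ij}$,
  $v_j = f(s_j)$, $b_{ij} \mathrel{+}= \hat u_{ij}\cdot v_j$, with $b$
  initialised to zero. The activation $f$ is squash in the classic
  network; this model replaces the routing activation with LeakyReLU
  (slope 0.2) to avoid the norm compression that produces artifacts in
  generated images. Both modes are available
  (`discriminator_config(activation = )`) because the two conventions are
  both defensible: primary capsules keep the squash by default
  (`primary_squash = TRUE`), the routed output capsule uses LeakyReLU.
* **margin loss** (`margin_loss()`): the per-class hinge-squared loss on
  capsule lengths with margins $m^+ = 0.9$, $m^- = 0.1$ and
  down-weighting $\lambda = 0.5$. It is provided (and tested) as part of
  the capsule toolkit; the GAN itself trains on least-squares losses
  because real-vs-fake is a single entity, not a multi-class problem.

On the LeakyReLU convention: one printed form of the activation divides
negative inputs by the slope parameter ($x/0.2$), which *amplifies*
negatives five-fold and destabilises training. We treat 0.2 as a
multiplicative slope ($y = 0.2x$ for $x<0$), the universal convention, and
expose the literal division as `leaky_relu(mode = "literal")` for
completeness.

### Generator

DCGAN-style: a 100-dimensional latent vector (Gaussian by default,
uniform available — both priors appear in the literature on this model) is
projected by a dense layer to a $4\times4$ seed map and upsampled by
stride-2 transposed convolutions, one per doubling, to the target size.
Batch normalisation and ReLU follow every hidden layer; the output layer
is Tanh (no BN), so pixels live in $[-1,1]$ and are mapped to 8-bit range
by $y = (x+1)\cdot127.5$ (`to_pixels()`).

At $64\times64$ the seed map has 1024 channels and the four stages halve
channels to 512/256/128/1, matching the published architecture. We use
$4\times4$ kernels with stride 2 and symmetric padding 1: this is the
standard transposed-convolution geometry that doubles resolution exactly;
a $5\times5$ stride-2 kernel cannot (it needs asymmetric padding), so we
prefer the exact geometry. At desk scale ($16\times16$, the default for
the bundled experiments) the seed map is $4\times4\times64$ with stages
32/1: wide enough to learn the phantom distribution, small enough that a
few thousand update steps run in about a minute on one CPU core.

### Capsule discriminator

Four steps, mirroring the published design:

1. $9\times9$ convolution (stride 1, valid), batch norm, LeakyReLU — a
   large receptive field for low-level feature extraction.
2. primary capsules: a second convolution (stride 2) whose output
   channels are reshaped into 8-dimensional capsule vectors and squashed.
3. routing into a **single 16-dimensional output capsule**. Real-vs-fake
   is one entity, so one output capsule suffices; with a single output
   capsule the routing softmax is over one class and the coupling
   coefficients are identically 1, making the routed output
   $f(\sum_i \hat u_{ij})$ for any number of iterations. The package's
   general `dynamic_routing()` is cross-checked against the network's
   specialised path in the test suite.
4. the score is the L2 norm of the output capsule (`capsule_length()`),
   non-negative and, in squash mode, bounded below 1.

At $16\times16$ the post-step-1 feature map is $8\times8$, so the default
primary-capsule kernel shrinks from $9\times9$ to $5\times5$ (the
constructor checks the geometry and refuses configurations that do not
fit). A plain convolutional discriminator
(`discriminator_config(type = "conv")`) is included as the DCGAN/LSGAN
baseline, with a sigmoid head for cross-entropy training and a linear
head for least-squares.

### Objectives

For scores $D(x)$ the least-squares objectives are
$$V(D) = \tfrac12 E_{x\sim p_{data}}[(D(x)-1)^2] + \tfrac12 E_z[D(G(z))^2],
\qquad V(G) = \tfrac12 E_z[(D(G(z))-1)^2],$$
i.e. target codes 1 for real, 0 for fake, 1 for the generator's target.
The original minimax value, the optimal-discriminator density ratio
$D^*(x) = p_{data}/(p_{data}+p_g)$ and the identity
$C(G) = -\log 4 + 2\,\mathrm{JSD}(p_{data}\Vert p_g)$ are implemented in
`objectives` and used as analytic cross-checks of one another in the test
suite (the minimax value evaluated at $D^*$ on discrete toy densities must
equal the JSD form to $10^{-10}$).

### Why the networks are implemented in the package

The layers (convolution, transposed convolution, batch normalisation,
capsule squash/routing) ship with hand-derived reverse-mode gradients and
an Adam optimiser, all in vectorised R over precomputed gather/scatter
index maps. Activations are stored channel-fastest so that every
inter-layer reshape is a zero-copy reinterpretation; the arithmetic then
reduces to BLAS matrix products. Every layer's backward pass is validated
against central finite differences in the test suite. This keeps the
model, its gradients and its numerical behaviour fully inspectable.

## Training

`train_capgan()` alternates one discriminator update (both real and fake
batches, gradients summed) with one generator update, both via Adam with
learning rate $2\times10^{-4}$ and $\beta_1 = 0.5$ (the standard choice
for adversarial training; only the learning rate is prescribed by the
model). One master seed fans out into named substreams (parameter
initialisation, latent draws, batch shuffling), so runs are exactly
reproducible and checkpoints resume bit-identically (the checkpoint
stores the RNG state; "train $k$ then $m$ steps" equals "train $k+m$").
Non-finite losses abort with a diagnostic snapshot. The published
training length ("50,000 epochs") is interpreted as update steps, the
usual reading for small datasets; the bundled experiments use 2,000 steps
at $16\times16$, which we found sufficient for the generator to move from
structureless output to recognisable phantom-like images.

Transfer learning is supported by `warm_start()`: pretrain on an
augmented pool, restore the weights exactly (optimiser state reset), and
fine-tune on the originals — the five-step pipeline used for scarce
lesion data.

## The KL quality metric

`evaluate_generated(real, fake, model, n_bins)` requires equally sized
sets, scores each image with a pre-trained two-class classifier, bins the
positive-class probabilities into `n_bins = 10` equal-width bins on
$[0,1]$, and returns $\mathrm{KL}(P\Vert Q) = \sum_i P_i\log(P_i/Q_i)$
with real as $P$ and generated as $Q$ (the published description is
directionless; we fix this orientation and document it). The features are

* **HOG**: 9 unsigned orientation bins, $8\times8$ cells, $2\times2$-cell
  blocks with L2 normalisation (at $16\times16$ the experiments use
  $4\times4$ cells so that more than one block exists);
* **LBP**: uniform rotation-invariant patterns over the direct
  8-neighborhood, a 10-bin normalised histogram, invariant to monotone
  gray-level changes.

The classifier is a radial-basis SVM (cost 1) with Platt-scaled
probabilities — the logistic calibration is fit by `glm` on the decision
values, which keeps training deterministic (the library's built-in
probability option uses an internal randomised cross-validation).

Two numerical choices deserve note. The continuous KL integral is
discretised as a binned sum, and each bin receives an additive
$1/(10n)$ before normalisation ($n$ = number of images): this keeps
$Q_i > 0$ everywhere so the divergence is always finite, while perturbing
well-populated bins negligibly. Because bin count and smoothing are free
parameters of the metric, absolute KL values are comparable only within a
fixed protocol — the package therefore always reports the protocol
(`n_bins`, feature parameters) alongside the value, and the bundled
experiments compare KLs computed under identical settings.

For the phantom experiments the two-class problem is "phantom vs
structureless noise" (`generate_noise_images()` provides white and
box-smoothed uniform noise as the negative class): the classifier then
measures *phantom-likeness*, and the KL between real held-out phantoms
and generator output falls as the generator learns. For lesion cohorts
the natural two-class problem (malignant vs benign) is used directly.

## Synthetic data

`generate_phantoms()` draws nested-ellipse intensity phantoms: 3 shells
by default with gray levels 60/130/200 on a background of 20, per-image
jitter of center, axes and orientation (10% by default), and additive
Gaussian noise (sd 8 gray levels). These emulate the gross geometry of
axial T1 brain slices — concentric tissue compartments of distinct mean
intensity — while remaining fully parametric and seeded.

`generate_lesion_dataset()` emulates an imbalanced lesion-patch cohort
(default 75 malignant : 250 benign, $35\times35$ patches): both classes
are bright blobs on a dark background; malignant lesions are larger,
more irregular (lobulated margins), higher-contrast and speckled, benign
ones rounder and smoother. A `separability` knob interpolates the
malignant parameters onto the benign ones; at 0 the two labels index the
same distribution (a trained classifier scores chance-level AUC, which
the tests verify), at 1 the classes are cleanly separable (held-out
accuracy ≥ 0.9 in the acceptance suite).

What the synthetic data does *not* emulate: scanner noise statistics
(Rician, bias fields), genuine anatomical variability, partial-volume
effects, or any modality-specific contrast. Passing tests on these
fixtures demonstrates that the adversarial machinery, the evaluation
metric and the data pipeline behave as specified — not that the model
reaches any particular quality on real MR data.

The pipeline operators follow the published bookkeeping: `roi_crop()`
extracts $35\times35$ patches centred on the lesion (reflect-padded at
borders — boundary behaviour is unspecified in the source, and reflection
avoids introducing flat artificial regions); `augment()` applies seeded
rotation/translation/scale warps (defaults ±15°, ±3 px, 0.9–1.1, chosen
mild to preserve anatomy) plus Gaussian noise;
`expand_with_originals()` implements "increase by 20×" as originals plus
20 augmented copies each (so 260 training patches become
$260\times21 = 5460$ images), while the 10-fold phantom expansion is 10
outputs per original ($1400 \to 14000$) — the two conventions match the
published counts and are selected per experiment. `split_dataset()`
stratifies with round-to-nearest per class, reproducing the 60/200 vs
15/50 split of the 75/250 cohort. Manifest CSVs store 0-based (row, col)
lesion centers, stated in the file header; the R API is 1-based.

## Problem sizes and determinism

The bundled experiments (test suite and `scripts/acceptance.R`) run at
$16\times16$ with 1,000 phantoms, batch 16 and 2,000 generator steps —
sizes chosen so a full five-seed training-progress experiment completes
in minutes on a single CPU core while still showing an unambiguous KL
improvement (untrained ≈ 15 nats, trained < 1 nat under the bundled
protocol). All randomness flows from explicit seeds; single-threaded runs
are bit-reproducible.

## Known limitations

* Training gradients are implemented for the single-output-capsule
  discriminator; multi-capsule classification heads (and the capsule
  reconstruction decoder) are out of scope.
* 2-D grayscale only; volumes are handled by slicing (`slice_volume()`).
* Absolute KL values depend on the binning/smoothing protocol and on the
  evaluation classifier; only within-protocol comparisons are meaningful.
* The pure-R implementation is desk-scale: $64\times64$ configurations
  run, but at GPU-scale step counts they are impractical.
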
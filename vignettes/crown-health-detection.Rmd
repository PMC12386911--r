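---
title: "Detecting declining pine crowns in UAV imagery: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting declining pine crowns in UAV imagery: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownwatch)
```

## The problem

Woodwasp infestation (*Sirex noctilio*) and related biotic stressors produce
a visible phenotypic gradient in pine stands: healthy crowns are dense and
deep green, weakened crowns yellow and thin from the top, dead crowns are
bare and gray-brown. Surveying this from the ground is slow; low-altitude
UAV RGB imagery makes it fast, but automatic detection must cope with three
specific difficulties:

* crowns are **elongated** — especially in oblique captures, where a tree
  occupies a tall, narrow box (height/width commonly 2-5);
* **context matters** — a weakened crown is recognized partly by contrast
  with its surroundings, so long-range information helps;
* crown sizes are **strongly bimodal across view regimes** — nadir
  orthophotos yield small, near-square boxes while oblique frames yield
  large tall ones, which destabilizes standard IoU-family box losses for
  the small targets.

crownwatch implements the three corresponding architectural responses as a
tested, desk-scale toolkit: strip (directional depthwise) convolution
blocks in the backbone, channel-aware context attention (CAA) in the
fusion neck, and the size-adaptive SDIoU bounding-box loss in the head —
plus the surrounding machinery (annotation I/O, evaluation statistics,
ground-survey validation, and a synthetic scene generator standing in for
the original imagery, which is not public).

## The network components

### StripBlock

Strip attention factors a large square kernel into one horizontal `1 x k`
and one vertical `k x 1` depthwise convolution after a `5 x 5` depthwise
aggregation, then gates its input multiplicatively through a pointwise
mix:

$$\mathrm{Attn}(x) = x \odot \mathrm{Conv}_{1\times1}\!\big(\mathrm{DW}_{k\times1}(\mathrm{DW}_{1\times k}(\mathrm{DW}_{5\times5}(x)))\big)$$

A channel-mixing MLP (pointwise expansion, `3 x 3` depthwise, GELU,
dropout, pointwise projection) complements it, and the block combines both
in a *parallel* dual residual with learnable per-channel layer scales
$\gamma_1, \gamma_2$:

$$\hat{x} = x + \gamma_1\,\mathrm{Attn}(\mathrm{BN}_1(x)) + \gamma_2\,\mathrm{MLP}(\mathrm{BN}_2(x))$$

Design choices worth stating (the parts a formula leaves open):

* **k = 10** by default — a long receptive field at depthwise cost. An even
  kernel has no center, so "same" padding is necessarily asymmetric: we pad
  `floor((k-1)/2)` on the leading edge and `ceiling((k-1)/2)` on the
  trailing edge, in both orientations. Shape preservation is exact and
  tested for odd and even extents down to 1 x 1.
* The dual residual is implemented as printed above — both branches read
  the block input — rather than the sequential metaformer arrangement; the
  sequential variant is a documented alternative, not built.
* The gate multiplier inside strip attention is the branch input (the
  tensor after BN1); with the final pointwise mix zeroed the block output
  collapses to the residual, which the suite checks.
* Layer scales initialize to `1e-2` (common layer-scale practice), giving
  near-identity blocks at the start of training; with scales exactly zero
  the block *is* the identity in evaluation mode, to machine precision.
* The 5 x 5 depthwise aggregation carries no extra normalization or
  activation.

### Channel-aware attention (CAA)

A CAA unit squeezes local context and re-weights its input through a
sigmoid gate:

$$\mathrm{CAA}(x) = x \odot \sigma\!\big(\mathrm{Conv}_{1\times1}(\mathrm{DW}_{k\times1}(\mathrm{DW}_{1\times k}(\mathrm{Conv}_{1\times1}(\mathrm{AvgPool}_{7}(x)))))\big)$$

* The 7 x 7 average pool is **local** (stride 1, padding 3). A global pool
  would collapse the map to one pixel and leave nothing for the
  directional kernels to traverse; the local read keeps the operator
  shape-preserving while still mixing a 7-pixel neighborhood before the
  strips extend the reach along each axis.
* The directional order follows the gate formula (horizontal `1 x k`
  first, then vertical `k x 1`).
* Because the gate is a sigmoid, $|\mathrm{CAA}(x)| \le |x|$ holds
  elementwise for *any* weights — the suite asserts this on random
  weight/input draws, and separately that a saturated gate passes the
  input through unchanged.
* The container brings the input to a hidden width (half the output
  channels, the usual split-transform convention), applies `n` CAA units,
  concatenates them with the stream and fuses pointwise. `n` follows the
  stage's block-depth parameter, as the count is otherwise unspecified.
* The long-range contract is tested as a span: perturbing one pixel
  changes the gate over a window at least `floor(7/2) + (k-1)` pixels wide
  along each axis (the pool plus strip extents; with the asymmetric even
  kernel the reach splits unevenly across the two directions, so the span,
  not the one-sided offset, is the meaningful quantity).

### SDIoU box similarity and loss

For a predicted box $b_1$ and target $b_2$,

$$\mathrm{SDIoU} = (\delta-\beta) + (1-\delta+\beta)\,\mathrm{IoU}
 - \alpha v - (1+\delta-\beta)\,\rho^2/c^2$$

with $v$ the arctan aspect-ratio penalty, $\alpha = v/(1-\mathrm{IoU}+v)$,
$\rho^2$ the squared center distance, $c^2$ the squared diagonal of the
smallest enclosing box, and the size-aware coefficient

$$\beta = \delta\,\Big(1 - \frac{\log(1+\mathrm{area}(b_2))}{\log(1+S_{max})}\Big),\qquad \delta = 0.5,\; S_{max} = 90^2.$$

$S_{max}$ is interpreted in squared pixels at the 640-px network input —
the largest crown labeled in nadir orthophotos — so small ortho targets
get $\beta \approx \delta$ (strong extra supervision) and large oblique
targets get $\beta \to 0$. Numerical choices:

* $\alpha$ is 0/0 at a perfect match; the product $\alpha v$ is defined as
  0 whenever $v = 0$ (the convention the aspect term inherits).
* $\beta$ would go negative for areas above $S_{max}$; it is clamped to
  $[0, \delta]$.
* The logarithm base is immaterial in the ratio; natural log is used.
* The training loss is the standard subtraction, $1 - \mathrm{SDIoU}$.
* Degenerate zero-size boxes are rejected, not epsilon-patched; the
  decode path cannot produce them (softplus keeps distances positive).
* The loss gradient with respect to the predicted box is computed by
  central finite differences with a step of `1e-4` of the box scale. The
  surface is smooth almost everywhere, so the approximation error
  (~1e-8) is far below optimizer noise; a property test confirms seeded
  gradient descent under this gradient recovers the target box within a
  pixel in at least 95 of 100 trials.

The suite pins the implementation to an independently written
straight-line evaluation of the definitions on a thousand seeded pairs
(agreement to 1e-6) and to a pixel-rasterization IoU oracle on integer
boxes, and checks the size-adaptivity claim in testable form: for targets
far below $S_{max}$ at low IoU, the center gradient under the SDIoU loss
exceeds that of a plain $1-\mathrm{IoU}$ loss (which flattens to zero once
boxes are disjoint).

## Detector, assignment and training

The detector is a conventional three-level pyramid (strides 8/16/32):
a strided convolutional stem and four stages whose split-transform-concat
containers host StripBlocks in the backbone; a top-down plus bottom-up
neck whose containers host CAA units; and a per-cell anchor-free head
predicting four box values and one logit per class. Head internals are
deliberately simple (the box-loss substitution is the point, and it stays
isolated): distances to the four box sides pass through a softplus and are
scaled by the stride; assignment is center-region based — a ground-truth
box supervises the cells of its best-matching stride whose centers fall in
its central half, plus the cell containing its center, with ties going to
the smaller box. There is no objectness channel and no distribution-focal
component; classification is one-vs-all binary cross-entropy normalized by
the number of assigned cells.

Everything — convolution, batch norm, the gates, the containers, the full
graph — carries a hand-written backward pass, checked end to end against
central finite differences. Training is plain SGD with momentum **0.8**
and learning rate **0.01** (the published regime's values, kept as
printed — the momentum is unusually low but is part of the regime) with
cosine decay, batch 16 and 300 epochs in the full-scale configuration.

The builder exposes three independent toggles — strip blocks vs plain
bottlenecks, CAA vs plain bottlenecks, SDIoU vs plain `1 - IoU` — so all
eight ablation combinations build and train.

## The synthetic stand

The study's imagery is not deposited, so the generator emulates its
structure: cluttered green/brown ground texture, layered soft-ellipse
crowns in three health classes (healthy: dense dark green; weakened:
yellow-green, thinned toward the top; dead: gray-brown, speckled sparse),
partial occlusion by draw order, and the two view regimes — ortho
(near-square boxes, aspect 0.8-1.25, largest side capped at 90 px at the
640-px reference) and oblique (width 25-60 px, height/width 2-5, with a
visible trunk). Defaults chosen once as the study conditions: 8-16 trees
per scene; class mix 40% healthy / 35% weakened / 25% dead (an active
outbreak stand — enough annotated crowns per scene to train on, healthy
canopy still the largest class); occlusion budget 0.3; crown sizes
specified at the 640-px reference and scaled by `image_size/640`, so
smaller desk-scale scenes keep the same scene statistics.

Two deliberate annotation decisions mirror the original labeling scheme:
healthy crowns are rendered but **never annotated** (only Weak and Dead
labels exist; healthy canopy is background the detector must ignore), and
boxes cover the **visible extent** of a crown under occlusion, as an
annotator boxes what is seen.

What the generator does *not* emulate — and therefore what passing tests
do and do not show: real needle texture, illumination and shadow,
off-nadir geometric distortion, other vegetation species, and trunk-level
symptoms invisible at canopy scale. A detector scoring well here
demonstrates that the architecture, losses, assignment, decoding and
metrics are implemented correctly and can be learned end to end; it says
nothing quantitative about performance on real UAV imagery.

## Desk-scale study sizes

The test suite and the acceptance script exercise a deliberately small
regime, chosen once and documented here as the package's own sizes: scenes
at 128 px (constant ground-sampling fraction relative to 640), 200
training and 50 held-out scenes mixed ortho/oblique, the pico width
(base channels 8-64, about 0.2 M parameters), batch 8, 30 epochs. Under
these conditions the held-out mAP@0.5 clears 0.6, which is the smoke
criterion the suite asserts. The full-scale regime (640 px, width
multiples, 300 epochs, batch 16) is retained in the configuration objects
but not exercised by the tests.

## Evaluation and survey validation conventions

* mAP is computed at IoU 0.5 (the convention of the source literature's
  single-threshold tables), with **all-points** interpolation of the
  precision-recall envelope, not the 11-point variant.
* Matching is the standard greedy descending-confidence protocol, each
  ground truth matched at most once. On non-overlapping annotations (the
  generator's and any disciplined annotator's case) this provably attains
  the exhaustive-search optimum at threshold 0.5, which the suite checks
  by brute force on small instances.
* The per-class point metrics (P, R, F1) are reported at the
  F1-maximizing confidence, since the table convention behind a single F1
  number does not state its threshold; the PR curves carry the full
  sweep.
* A pooled all-classes row merges both classes' detections and truths
  into one matching problem, mirroring "All"-column reporting.
* Survey validation filters detections at confidence **strictly greater
  than 0.60**, matches survey points by boundary-inclusive
  point-in-box containment against **Weak** boxes only (the surveyed,
  damaged trees are weakened living hosts; Dead detections are tallied
  separately), and reports AR = 100·SD/DT rounded half-up to two
  decimals. The overall AR comes from the summed counts, never the mean
  of category rates. On the shipped worked example (70 previously damaged
  trees, 68 covered; 11 newly damaged, 10 covered) this yields 97.14%,
  90.91% and 96.30% overall.

```{r survey}
ex <- surveyWorkedExample()
buildSurveyReport(ex$points, ex$detections)
```

## Known limitations

* The engine is CPU-only R/C++ and sized for desk-scale experiments;
  full-scale 640-px training at published epoch counts is expressible but
  not practical here.
* The SDIoU gradient is numerical (by design, see above); exotic uses
  that differentiate through the *loss gradient* itself are out of scope.
* The greedy-equals-optimal matching guarantee holds for non-overlapping
  ground truth; heavily overlapping annotations can make greedy matching
  drop below the exhaustive optimum, as with every standard evaluator
  using this protocol.
* Checkpoints are R serializations of the parameter state; they are not
  interchangeable with any external deep-learning framework.
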
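---
title: "Forward-Forward training of convolutional networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward-Forward training of convolutional networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffcnn)
```

## The model

Backpropagation trains every layer of a deep network from one global loss
by chaining gradients backwards. The Forward-Forward (FF) algorithm
replaces this with purely local learning: each layer judges, on its own,
whether the sample it is looking at is *positive* (an image carrying its
true class label) or *negative* (the same image carrying a deliberately
wrong label), and adjusts only its own weights accordingly.

The judgement is based on the layer's *goodness*, the squared length of
its activity vector,

$$ g \;=\; \sum_{i=1}^{N} y_i^2, $$

where the $y_i$ are the $N$ post-rectifier activations the layer produces
for one sample. Goodness is compared against a threshold $\theta$, taken
equal to the neuron count $N$, through a logistic function: the layer's
probability that a sample belongs to its designated set is
$\sigma(g-\theta)$ on positive data and $\sigma(\theta-g)$ on negative
data. Each layer's loss is the binary cross-entropy of this probability
against target 1; positive data should have large goodness, negative data
small. The reported *combined* loss sums the per-layer losses of the loss
layers (all layers except the first; see below).

Between layers, only the *orientation* of the activity vector may pass —
otherwise a layer could succeed by simply measuring the length of its
predecessor's activity, which already encodes the predecessor's decision.
Layer normalization enforces this:

$$ y_{i,\mathrm{norm}} = \frac{y_i}{\sqrt{\tfrac{1}{N}\sum_i y_i^2}}, $$

leaving a vector of root-mean-square exactly 1. Crucially, the normalized
output is handed to the next layer *detached*: no gradient flows back
through it. Locality is therefore exact — in this implementation it is a
structural fact, because each layer's gradient is computed analytically
from its own activations only and no mechanism for cross-layer gradients
exists at all. The test suite verifies this both by finite differences
(with the detached input held fixed, a later layer's loss is constant in
earlier weights) and by bitwise comparisons against single-layer
recomputation.

### Spatially-extended labels

A convolutional filter sees only a small window, so the corner one-hot
labels of fully-connected FF are invisible at almost every filter
position. The package embeds the class label across the *whole* image, in
one of two ways:

* **Fourier labels** — each class is a gray-value wave with its own
  frequency $f$ (cycles per image side), orientation $\alpha$ and phase
  $\varphi$; pixel $(r,c)$ of the pattern is
  $0.5 + 0.5\sin\!\big(2\pi f (c\cos\alpha + r\sin\alpha)/\mathrm{side} +
  \varphi\big)$.
* **Morphology labels** — each class is a fixed, deterministic program of
  image transforms (quarter-turn rotation, flips, cyclic shift, intensity
  inversion, grayscale dilation/erosion) applied to the input image
  itself. Because the label is carried by a transformation of the image's
  own content, a network cannot satisfy the discrimination objective by
  detecting an injected pattern; it must attend to image morphology.

Either label component is blended into the image as the convex
combination $(1-K)\,\mathrm{image} + K\,\mathrm{label}$, followed by
per-image min–max renormalization to $[0,1]$. The *label intensity* $K$
is thereby interpretable as the relative contribution of the label in
both modes; this is also why morphology labels are blended rather than
used pure — the alternative (pure transformed image) would make $K$
meaningless in one of the two modes. A constant blend renormalizes to
all-zeros rather than dividing by zero.

### Training and inference

Each epoch, every training image yields one positive sample and one
negative sample whose wrong label is redrawn uniformly from the $M-1$
other classes (hard negative mining is deliberately not implemented).
Per batch, both sets are forward-passed and every layer takes one Adam
step on its own loss; one optimizer per layer, which under locality is
equivalent to a single optimizer over the disjoint parameter partition.
The learning rate is constant for the first half of training, then cools
down linearly, $lr(e) = \tfrac{2\,lr}{E}(1+E-e)$ — applied only after the
halfway epoch, since applying the formula from $e=1$ would double the
rate at the start.

The first layer is special: it trains on its own local loss but is
excluded from the combined loss and from all inference. The length of the
first activity vector separates positive from negative data too easily;
normalizing it away forces the deeper layers to learn genuinely new
features.

Two inference modes are provided:

* **Goodness inference** — embed the image with each candidate label in
  turn and pick the label maximizing $f_m = \sum g_l$ over layers
  $2..L$. This costs one forward pass per label (verified by an internal
  pass counter).
* **Linear head** — a softmax classifier on the concatenated layer-$2..L$
  activations of a single forward pass, trained post hoc by cross-entropy
  with the FF weights frozen. The image is embedded with a *neutral*
  label (the mean of all rendered patterns in Fourier mode; the
  untransformed image in morphology mode) so no class is hinted at.

### Class activation maps

Because every convolution is same-padded, feature-map pixels align 1:1
with image pixels, and the head weight attached to each activation
directly quantifies that pixel's evidence for a class. The CAM of layer
$l$ for class $c$ sums weight × activation over the layer's channels at
each pixel; the aggregate map sums the layers. The construction satisfies
an exact conservation identity — total aggregate CAM + bias = the class
score — which the tests assert to $10^{-5}$ and `run_cam()` logs for
every exported map. Per-layer maps are reported separately because
different layers contribute similar but distinct evidence.

### Many-class label sets

With many classes, label distinctiveness becomes the bottleneck. The
package generates a large pool of unique random candidates
(`generate_candidates()`) and selects a subset minimizing the maximal
internal |Pearson correlation| between rendered patterns (Fourier) or
transformed probe images (morphology, probed with the mean training
image). Exhaustive selection of, say, 100 from 2000 is infeasible, so the
selection is greedy: seed with the least-correlated pair, then repeatedly
add the candidate whose worst correlation against the selection is
smallest, ties broken toward the lower candidate index. On enumerable
pools the tests confirm the greedy pick lands within the top 3 of all 20
possible 3-of-6 subsets and beats the median of random subsets on 3-of-8.

## Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `K` | label contribution in the blend, unitless fraction | 0.35 (tiny preset: 0.40) | 0.35 is the full-scale MNIST value; the tiny preset uses a slightly stronger label so the much smaller network converges reliably within its 30-epoch budget |
| `kernel` | convolution kernel side, pixels | 7 (tiny preset) | near-global receptive field by layer 3; matches the full-scale MNIST kernel |
| `lr` | base Adam learning rate | 1e-3 (tiny preset) | compensates the small step budget of a desk-scale run |
| `batch_size` | samples per Adam step | 10 (tiny preset) | FF convergence is step-hungry; small batches give 2400 steps in 30 epochs on 800 images |
| `epochs` | passes over the data | 30 (tiny preset) | desk-scale cap; the full MNIST configuration uses 200 |
| `theta` | goodness threshold | $N$, the layer's activation count | the standard FF choice; not user-tunable |
| `norm` | `layer_norm` or `batch_norm` | `layer_norm` | batch norm (before each convolution, affine parameters trained locally) is the deeper-network variant |

The `mnist` and `cifar` presets in `ff_presets()` carry the full-scale
published configurations (3×128 filters, 7×7, 200 epochs, batch 50, lr
5e-5, K 0.35; and 6 layers, batch norm, 100 epochs, batch 32, constant lr
1e-4, K 0.30 respectively). They are documented full-scale experiments:
running them requires the external MNIST/CIFAR downloads and multi-hour
training, which this package deliberately does not automate. The CIFAR
preset's filter count (64) and kernel (3×3) are package choices, as the
source configuration does not pin them.

## What the synthetic generator emulates — and what it does not

`generate_synthetic()` draws one geometric primitive per class (disk,
cross, bar, ring, wedge, diagonal, square outline, X) with random
translation jitter and additive Gaussian noise, clipped to $[0,1]$. The
acceptance-scale set uses 4 classes, 16×16 pixels, noise sd 0.05, 200
training and 100 test images per class. This emulates the essential
structure of an image-classification benchmark — learnable spatial class
structure, within-class variability, label-image pairing — at a size
where everything runs on one CPU in minutes.

It does **not** emulate natural-image statistics: no texture, clutter,
scale or illumination variation, and classes are linearly separable on
raw pixels (a property the tests verify deliberately, since it calibrates
what "learnable" means here). Passing tests therefore demonstrate the
correctness of the training mechanics and the qualitative phenomena, not
benchmark-level performance; the full-scale presets exist for the latter.

The `hard = TRUE` variant lowers template contrast, doubles jitter and
adds a random distractor bar, giving finer class evidence. It exists to
reproduce the shortcut phenomenon: with a dominant Fourier wave (K =
0.80) the early loss layer discriminates positive from negative better
than the late layer — the network finds it easier to detect the injected
pattern than to relate it to image content, and this ordering persists
through training — while with morphology labels, whose information *is*
image content, the ordering reverses and depth pays off. Both networks
train for 60 epochs at the tiny-preset settings; the test asserts only
the two orderings, not magnitudes. At moderate label contrast (K around
0.6) the shortcut is transient at this scale: the late layer eventually
overtakes, which is why the diagnostic deliberately uses a high-contrast
bank.

## Numerical choices

* Binary cross-entropies are computed from logits via a stable softplus,
  never by exponentiating large goodness offsets (a layer's $g-\theta$
  can be in the hundreds early in training).
* Layer normalization adds $\varepsilon = 10^{-8}$ under the root; an
  all-zero activity vector maps to zero. Homogeneity is exact up to this
  guard.
* Batch-norm inference uses running averages (momentum 0.1); training
  uses batch statistics. Only the affine parameters receive gradients —
  the normalization statistics are data, not parameters, from the layer's
  local viewpoint.
* Goodness is computed on pre-normalization, post-rectifier activations;
  computing it after normalization would pin every goodness at $N$ and
  make the objective vacuous.
* Prediction ties (equal scores, probability exactly 0.5) resolve toward
  the smaller class index / count as incorrect, respectively.
* He-style uniform fan-in initialization; biases are trained and start at
  zero.
* A single run seed fans out to all random streams via
  `derive_seed(seed, offset)` with fixed documented offsets, so modules
  are testable in isolation while runs stay globally reproducible.

## Problem sizes used by the shipped checks

The test suite and the acceptance script train the 3-layer × 8-filter
network on the 800-image synthetic training set for 30 epochs (about
four minutes on one CPU), fit the linear head for 60 epochs, and evaluate
400 test images under both inference modes. Gradient checks run on
8×8 two-layer toy networks; selection checks on 6–8 candidate pools;
uniformity checks on 10 000 generated pairs. These sizes were chosen so
the complete suite exercises every mechanism at full fidelity while
remaining comfortable on a laptop.

## Known limitations

* Goodness inference is $M$ forward passes per image; for many classes
  the linear head is the practical mode (the same trade-off the
  full-scale experiments report).
* Morphology labels assume square images for odd quarter-turns (degraded
  to 180° otherwise) and near-involutive programs can collide on highly
  symmetric probe images; the bank constructor rejects exact duplicates
  and the correlation probe should be a representative image.
* The desk-scale configuration makes no claim about benchmark accuracy;
  the published full-scale numbers require the real datasets and
  multi-hour training via the presets.
* Networks deeper than 8 layers, pooling, hard negatives, and symmetric
  losses are out of scope.
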
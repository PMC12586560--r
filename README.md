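# ffcnn — Forward-Forward training of convolutional neural networks

`ffcnn` trains convolutional image classifiers **without backpropagation**,
using the Forward-Forward (FF) algorithm: every layer learns from a purely
local objective, and no gradient ever crosses a layer boundary. It is aimed
at researchers studying backprop-free and biologically inspired learning —
the regime relevant to neuromorphic hardware, where a backward pass is
often impossible — and at anyone who wants a small, fully inspectable FF
implementation whose every mechanism is unit-tested against independent
oracles.

## The method in brief

Training data come in two polarities. A *positive* sample is an image
blended with the spatial label pattern of its true class; a *negative*
sample carries a wrong label drawn uniformly from the other classes. Each
convolutional layer computes its *goodness*

$$ g = \sum_{i=1}^{N} y_i^2 , $$

the squared norm of its \(N\) rectified activations, and is trained so that
\(\sigma(g-\theta)\) is large on positive and small on negative data, with
threshold \(\theta = N\). Losses are per-layer binary cross-entropies;
layer normalization \(y_i / \sqrt{\sum_i y_i^2 / N}\) passes only the
*orientation* of the activity vector to the next layer, detached, so each
layer's Adam update is exactly local. The learning rate cools down
linearly after the halfway epoch: \(lr(e) = \frac{2\,lr}{E}(1+E-e)\).

Because convolutional filters see only a small window, corner one-hot
labels are invisible at most filter positions. `ffcnn` therefore embeds
labels across the whole image, either as **Fourier labels** (a gray-value
wave with class-specific frequency, orientation and phase) or as
**morphology labels** (a class-specific deterministic program of image
transforms — inversion, dilation, erosion, shifts, rotations — applied to
the input itself). The blend \((1-K)\,\mathrm{image} + K\,\mathrm{label}\)
is renormalized per image; \(K\) is the label intensity.

Inference is either **goodness-based** (embed each candidate label, pick
the class maximizing summed goodness over layers 2..L — one forward pass
per class) or via a **linear head** (softmax on the concatenated
layer-2..L activations of a single neutral-label pass). The head weights
double as **class activation maps**: per-pixel, per-layer signed evidence
that conserves the class score exactly. For many-class problems, label
sets are built by greedy min-max-correlation selection from a large
candidate pool.

## Worked example

```r
library(ffcnn)

train <- generate_synthetic(n_classes = 4, images_per_class = 200,
                            image_side = 16, noise_sd = 0.05,
                            seed = derive_seed(1, 11))
test  <- generate_synthetic(4, 100, 16, 0.05, seed = derive_seed(1, 13),
                            split = "test")

fit <- ff_fit(train, K = 0.40, n_layers = 3, n_filters = 8, kernel = 7,
              epochs = 30, lr = 1e-3, batch_size = 10, seed = 1)
summary(fit)
#> Forward-Forward convolutional network fit
#> <ff_network> 3 conv layers (layer_norm), input 16x16x1
#>   layer 1: 7x7 kernel, 1 -> 8 channels, theta = 2048 (excluded from loss)
#>   layer 2: 7x7 kernel, 8 -> 8 channels, theta = 2048
#>   layer 3: 7x7 kernel, 8 -> 8 channels, theta = 2048
#>   label bank: 4 fourier labels, K = 0.40
#>   30 epochs; final combined loss 1.4294; training accuracy 0.985 (goodness inference)
#>   linear head fitted
#>
#> Final per-layer discrimination (training data):
#>  layer disc. loss disc. accuracy
#>      2  1.1245737       0.913125
#>      3  0.3048168       0.962500
mean(predict(fit, test, type = "goodness") == test$class_ids)
#> [1] 0.9775
mean(predict(fit, test, type = "linear") == test$class_ids)
#> [1] 1
```

The per-layer rows show how well each loss layer separates positive from
negative training samples (probability \(\sigma(g-\theta) > 0.5\) counted
correct); the two predictions are the exhaustive goodness evaluation (four
forward passes per image) and the single-pass linear head. A class
activation map for a test image:

```r
cam <- compute_cam(fit, array(test$images[, , , 1], c(16, 16, 1)), class = 0)
cam
#> <ff_cam> class 0, 2 layer map(s) 16x16; score 17.8302 (map total 17.8241 + bias 0.0061)
plot(cam)
```

The printed identity — map total + bias = class score — holds to 1e-5 for
every map and is asserted by the tests.

## Command line

A thin wrapper over the same functions lives at `inst/cli/ffcnn.R`:

```sh
Rscript inst/cli/ffcnn.R train --preset tiny --out runs/tiny --seed 1
Rscript inst/cli/ffcnn.R eval  --run runs/tiny
Rscript inst/cli/ffcnn.R cam   --run runs/tiny --indices 1,2
```

Every run freezes its resolved configuration (`config.yaml`), label bank
(`label_bank.txt`), history CSV and checkpoint; re-running from the frozen
configuration reproduces the checkpoint bit for bit.

## Package layout

* `R/datasets.R` — IDX/CIFAR/PNG readers, synthetic shape generator,
  positive/negative pair construction
* `R/labels.R` — Fourier and morphology labels, embedding, correlation,
  candidate generation, greedy min-max selection, sidecar serialization
* `R/conv.R`, `R/ffnet.R`, `R/train.R` — the FF core: im2col convolution,
  goodness/probability/loss, layer and batch normalization, local
  gradients, Adam, `ff_fit()` and its methods
* `R/heads.R` — goodness inference, linear head, CAMs, discrimination
  reports
* `R/cli.R` — presets, config resolution, train/eval/cam workflows
* `vignettes/forward-forward-cnn.Rmd` — the methods vignette: model,
  assumptions, parameter choices, limitations
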
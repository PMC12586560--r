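# Forward-Forward core: goodness, local losses, normalization, learning-rate
# cooldown, and the layer-local forward/gradient machinery.
#
# The defining property of FF training is locality: a layer's weights are
# updated only from its own loss, computed on its own activations. Here this
# is enforced by construction -- each layer consumes the (normalized)
# activations of the previous layer as plain numbers, and gradients are
# derived analytically per layer; no gradient ever crosses a layer boundary.

.ffcnn_env <- new.env(parent = emptyenv())
.ffcnn_env$passes <- 0L

#' Forward-pass counter
#'
#' Every call of [ff_forward] increments an internal counter; useful for
#' verifying that goodness inference costs exactly one forward pass per
#' candidate label.
#'
#' @param reset logical; reset the counter to zero after reading
#' @return the number of forward passes since the last reset
#' @export
ff_pass_count <- function(reset = FALSE) {
  n <- .ffcnn_env$passes
  if (reset) .ffcnn_env$passes <- 0L
  n
}

#' Goodness of a layer's activations
#'
#' The sum of squared post-rectifier activations, per sample: the squared
#' Euclidean norm of the layer's activity vector.
#'
#' @param y activations: a vector (one sample) or an (H, W, C, n) array
#' @return a scalar, or a length-n vector for batched input
#' @export
goodness <- function(y) {
  d <- dim(y)
  if (is.null(d) || length(d) < 2L) return(sum(y^2))
  n <- d[length(d)]
  colSums(matrix(y, ncol = n)^2)
}

#' Per-layer membership probability
#'
#' The logistic function of the goodness offset against the threshold:
#' `sigmoid(g - theta)` for positive data, `sigmoid(theta - g)` for negative
#' data. Values above 0.5 mean the layer assigns the sample to its
#' designated (positive or negative) set.
#'
#' @param g goodness value(s)
#' @param theta goodness threshold, conventionally the layer's neuron count N
#' @param polarity "positive" or "negative"
#' @return probability vector the length of `g`
#' @export
layer_probability <- function(g, theta, polarity = c("positive", "negative")) {
  polarity <- match.arg(polarity)
  stopifnot(theta >= 0)
  if (polarity == "positive") stats::plogis(g - theta) else stats::plogis(theta - g)
}

#' Combined discrimination loss over loss layers
#'
#' Binary cross-entropy of each included layer's membership probability
#' against target 1, summed over layers and averaged over the batch.
#'
#' @param p probabilities: a vector (one layer) or an n x L matrix with one
#'   column per included layer
#' @return scalar loss
#' @export
combined_loss <- function(p) {
  if (length(p) == 0) stop_ffcnn("no layer contributes to the loss", "ffcnn_config_error")
  p <- as.matrix(p)
  mean(rowSums(-log(p)))
}

#' Layer normalization of an activity vector
#'
#' Divides each of a sample's N activations by their root mean square
#' `sqrt(sum(y^2)/N)`, so only the orientation of the activity vector -- not
#' its length, which carries the goodness -- is passed to the next layer.
#' An epsilon of 1e-8 is added under the root to guard an all-zero vector.
#'
#' @param y a vector (one sample) or an (H, W, C, n) array
#' @return normalized activations, same shape
#' @export
layer_normalize <- function(y) {
  d <- dim(y)
  if (is.null(d) || length(d) < 2L) {
    return(y / sqrt(mean(y^2) + 1e-8))
  }
  n <- d[length(d)]
  m <- matrix(y, ncol = n)
  rms <- sqrt(colMeans(m^2) + 1e-8)
  array(sweep(m, 2, rms, "/"), d)
}

#' Learning-rate schedule with linear cooldown
#'
#' The base rate is kept for the first half of training and then decays
#' linearly: for e > E/2 the rate is `(2 * lr / E) * (1 + E - e)`, which is
#' continuous at the halfway point and reaches `2 * lr / E` at the final
#' epoch.
#'
#' @param e current epoch (1-based)
#' @param E total number of epochs
#' @param lr base learning rate
#' @return the learning rate for epoch e
#' @export
lr_schedule <- function(e, E, lr) {
  stopifnot(e >= 1, e <= E, lr > 0)
  if (e <= E / 2) lr else (2 * lr / E) * (1 + E - e)
}

# ---- network ---------------------------------------------------------------

#' Construct an untrained FF convolutional network
#'
#' A stack of same-padded, stride-1 convolutional layers (so spatial size
#' and hence each layer's neuron count N are constant), each followed by a
#' rectifier. Between layers either layer normalization (after the
#' rectifier) or batch normalization (before the next convolution) is
#' applied. Each layer's goodness threshold is its neuron count
#' `theta = channels * height * width`. Weights use He-style uniform fan-in
#' initialization. The first layer is by default excluded from the combined
#' loss and from goodness inference.
#'
#' @param input_shape c(height, width, channels) of the (label-embedded)
#'   input images
#' @param n_layers number of convolutional layers
#' @param n_filters filters per layer (scalar, or vector of length n_layers)
#' @param kernel odd kernel size
#' @param norm "layer_norm" or "batch_norm"
#' @param include_first_in_loss logical; include layer 1 in the combined loss
#' @param seed RNG seed for weight initialization
#' @return an object of class `ff_network`
#' @export
ff_network <- function(input_shape, n_layers = 3, n_filters = 8, kernel = 3,
                       norm = c("layer_norm", "batch_norm"),
                       include_first_in_loss = FALSE, seed = 1) {
  norm <- match.arg(norm)
  stopifnot(kernel %% 2 == 1, n_layers >= 1)
  n_filters <- rep_len(n_filters, n_layers)
  H <- input_shape[1]; W <- input_shape[2]
  set.seed(seed)
  layers <- vector("list", n_layers)
  cin <- input_shape[3]
  for (l in seq_len(n_layers)) {
    cout <- n_filters[l]
    fan_in <- kernel * kernel * cin
    lim <- sqrt(6 / fan_in)
    layers[[l]] <- list(
      W = array(stats::runif(fan_in * cout, -lim, lim), c(kernel, kernel, cin, cout)),
      b = numeric(cout),
      norm = norm,
      theta = as.numeric(cout) * H * W,
      include_in_loss = if (l == 1L) include_first_in_loss else TRUE,
      gamma = rep(1, cin), beta = numeric(cin),
      run_mean = numeric(cin), run_var = rep(1, cin),
      ii = im2col_index(H, W, cin, kernel))
    cin <- cout
  }
  structure(list(layers = layers, input_shape = input_shape, kernel = kernel,
                 norm = norm, n_layers = n_layers), class = "ff_network")
}

#' @export
print.ff_network <- function(x, ...) {
  cat(sprintf("<ff_network> %d conv layers (%s), input %s\n", x$n_layers,
              x$norm, paste(x$input_shape, collapse = "x")))
  for (l in seq_len(x$n_layers)) {
    ly <- x$layers[[l]]
    cat(sprintf("  layer %d: %dx%d kernel, %d -> %d channels, theta = %d%s\n",
                l, dim(ly$W)[1], dim(ly$W)[2], dim(ly$W)[3], dim(ly$W)[4],
                ly$theta, if (ly$include_in_loss) "" else " (excluded from loss)"))
  }
  invisible(x)
}

bn_forward <- function(layer, x, training) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])   # rows: (H,W,n), cols: channels
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(sweep(m, 2, mu)^2)
    layer$run_mean <- 0.9 * layer$run_mean + 0.1 * mu
    layer$run_var <- 0.9 * layer$run_var + 0.1 * va
  } else {
    mu <- layer$run_mean
    va <- layer$run_var
  }
  xhat <- sweep(sweep(m, 2, mu), 2, sqrt(va + 1e-5), "/")
  out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  to_arr <- function(m) aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(layer = layer, out = to_arr(out), xhat = xhat)
}

#' Forward pass through an FF network
#'
#' Runs a batch through the stack. Each layer consumes the normalized
#' output of the previous layer as a constant (the numerical equivalent of
#' gradient detachment): goodness is computed on the pre-normalization,
#' post-rectifier activations, and only the normalized orientation is passed
#' on. In batch-norm mode normalization happens before each convolution
#' instead, using batch statistics while `training = TRUE` and running
#' averages otherwise.
#'
#' @param net an [ff_network]
#' @param x input batch, array (H, W, C, n) of label-embedded images
#' @param training logical; use batch statistics and update running averages
#' @param want_patches keep the im2col patch matrices needed for gradients
#' @return a list with `net` (running statistics possibly updated) and
#'   `layers`, one entry per layer holding `y` (post-rectifier activations),
#'   `g` (per-sample goodness), and gradient caches when requested
#' @export
ff_forward <- function(net, x, training = FALSE, want_patches = FALSE) {
  .ffcnn_env$passes <- .ffcnn_env$passes + 1L
  if (!all(dim(x)[1:3] == net$input_shape))
    stop_ffcnn("input batch shape does not match the network input shape",
               "ffcnn_consistency_error")
  out <- vector("list", net$n_layers)
  cur <- x
  for (l in seq_len(net$n_layers)) {
    layer <- net$layers[[l]]
    bn <- NULL
    if (layer$norm == "batch_norm") {
      bn <- bn_forward(layer, cur, training)
      net$layers[[l]] <- layer <- bn$layer
      xin <- bn$out
    } else {
      xin <- cur
    }
    cf <- conv_forward(xin, layer$W, layer$b, layer$ii, want_patches = want_patches)
    y <- pmax(cf$z, 0)
    g <- goodness(y)
    out[[l]] <- list(y = y, g = g, P = cf$P,
                     xhat = if (want_patches && !is.null(bn)) bn$xhat else NULL)
    cur <- if (layer$norm == "layer_norm") layer_normalize(y) else y
  }
  list(net = net, layers = out)
}

# Per-layer local gradients of the FF objective for one positive and one
# negative batch. Layer l's loss is
#   mean_pos BCE(sigmoid(g - theta), 1) + mean_neg BCE(sigmoid(theta - g), 1),
# whose gradient w.r.t. g is -sigmoid(theta - g)/B on positives and
# +sigmoid(g - theta)/B on negatives. Gradients touch only layer l's own
# parameters; earlier layers' parameters receive exactly zero by
# construction.
ff_gradients <- function(net, x_pos, x_neg, training = TRUE) {
  fp <- ff_forward(net, x_pos, training = training, want_patches = TRUE)
  net <- fp$net
  fn <- ff_forward(net, x_neg, training = training, want_patches = TRUE)
  net <- fn$net
  n_pos <- dim(x_pos)[4]; n_neg <- dim(x_neg)[4]
  grads <- vector("list", net$n_layers)
  stats <- vector("list", net$n_layers)
  for (l in seq_len(net$n_layers)) {
    layer <- net$layers[[l]]
    gp <- fp$layers[[l]]$g; gn <- fn$layers[[l]]$g
    sp <- gp - layer$theta; sn <- layer$theta - gn
    loss <- mean(bce_from_logit(sp)) + mean(bce_from_logit(sn))
    acc <- (sum(sp > 0) + sum(sn > 0)) / (n_pos + n_neg)
    dg_pos <- -stats::plogis(-sp) / n_pos
    dg_neg <- stats::plogis(-sn) / n_neg
    gz_of <- function(y, dg) {
      d <- dim(y)
      y * rep(dg, each = prod(d[1:3])) * 2 * (y > 0)
    }
    gz_p <- gz_of(fp$layers[[l]]$y, dg_pos)
    gz_n <- gz_of(fn$layers[[l]]$y, dg_neg)
    pg_p <- conv_param_grad(fp$layers[[l]]$P, gz_p)
    pg_n <- conv_param_grad(fn$layers[[l]]$P, gz_n)
    gW <- array(pg_p$W + pg_n$W, dim(layer$W))
    gb <- pg_p$b + pg_n$b
    ggamma <- gbeta <- NULL
    if (layer$norm == "batch_norm") {
      cin <- dim(layer$W)[3]
      gx_p <- conv_input_grad(gz_p, layer$W, layer$ii, n_pos)
      gx_n <- conv_input_grad(gz_n, layer$W, layer$ii, n_neg)
      flat <- function(a) matrix(aperm(a, c(1, 2, 4, 3)), ncol = cin)
      gxm <- rbind(flat(gx_p), flat(gx_n))
      xhat <- rbind(fp$layers[[l]]$xhat, fn$layers[[l]]$xhat)
      ggamma <- colSums(gxm * xhat)
      gbeta <- colSums(gxm)
    }
    grads[[l]] <- list(W = gW, b = gb, gamma = ggamma, beta = gbeta)
    stats[[l]] <- list(loss = loss, accuracy = acc)
  }
  list(net = net, grads = grads, stats = stats)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(param) list(m = param * 0, v = param * 0)

adam_step <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}
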
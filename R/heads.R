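# Inference and explainability on a trained FF network: per-label goodness
# evaluation, the linear classifier head, and class activation maps.

loss_layer_ids <- function(net) {
  which(vapply(net$layers, `[[`, logical(1), "include_in_loss"))
}

#' Goodness inference
#'
#' Classifies by exhaustive label evaluation: each image is embedded with
#' every candidate label in turn and forward passed; the per-label score
#' `f_m` is the goodness summed over all loss layers (all layers except the
#' first, by default), and the prediction is the label with maximal f_m.
#' Ties break toward the smaller class index. Costs exactly one forward
#' pass per candidate label.
#'
#' @param net an [ff_network] (or the `network` of an [ff_fit])
#' @param data an [image_set]
#' @param bank the [label_bank] used in training
#' @param K label intensity used in training
#' @return list with `class` (0-based integer predictions) and `f`
#'   (n x M goodness score matrix)
#' @export
infer_goodness <- function(net, data, bank, K) {
  M <- length(bank$specs)
  n <- dim(data$images)[4]
  f <- matrix(0, n, M)
  lids <- loss_layer_ids(net)
  for (m in seq_len(M)) {
    emb <- embed_with_bank(data$images, bank, rep(m - 1L, n), K)
    fw <- ff_forward(net, emb, training = FALSE)
    for (l in lids) f[, m] <- f[, m] + fw$layers[[l]]$g
  }
  list(class = max.col(f, ties.method = "first") - 1L, f = f)
}

# Concatenated per-sample activations of all loss layers (post-rectifier,
# pre-normalization), as an n x H feature matrix. Feature order: layers in
# index order, each flattened in array order (row fastest, then column,
# then channel).
ff_features <- function(net, images_embedded) {
  fw <- ff_forward(net, images_embedded, training = FALSE)
  lids <- loss_layer_ids(net)
  n <- dim(images_embedded)[4]
  mats <- lapply(lids, function(l) t(matrix(fw$layers[[l]]$y, ncol = n)))
  do.call(cbind, mats)
}

# Embed a batch with the neutral (class-uninformative) label component.
embed_neutral <- function(images, bank, K) {
  d <- dim(images)
  out <- images
  comp_shared <- if (bank$mode == "fourier")
    neutral_label_component(bank, array(0, d[1:3]))
  for (i in seq_len(d[4])) {
    img <- array(images[, , , i], d[1:3])
    comp <- comp_shared %||% img
    out[, , , i] <- embed_label(img, comp, K)
  }
  out
}

#' Fit the linear classifier head
#'
#' Trains a softmax (multinomial cross-entropy) classifier on the
#' concatenated activations of all loss layers -- every layer except the
#' first -- while the FF weights stay frozen. Inputs are embedded with a
#' neutral label carrying no class information: the mean of all rendered
#' patterns in Fourier mode, the untransformed image in morphology mode.
#' Weights initialize at zero and are optimized with Adam; the problem is
#' convex, so zero initialization is canonical.
#'
#' @param object an [ff_fit] (or a list with `network`, `bank`, `config$K`)
#' @param data an [image_set] with the same class count as the fit
#' @param epochs passes over the data
#' @param lr Adam learning rate
#' @param batch_size minibatch size
#' @param seed RNG seed (batch shuffling)
#' @return an object of class `ff_head`: list with `W` (M x H), `b`
#'   (length M), and the per-layer feature offsets needed for CAMs
#' @export
fit_linear_head <- function(object, data, epochs = 60, lr = 1e-2,
                            batch_size = 100, seed = 1) {
  net <- object$network
  bank <- object$bank
  K <- object$config$K
  M <- length(bank$specs)
  if (data$n_classes != M)
    stop_ffcnn("class counts of data and fit differ", "ffcnn_consistency_error")
  emb <- embed_neutral(data$images, bank, K)
  X <- ff_features(net, emb)
  n <- nrow(X); H <- ncol(X)
  Y <- matrix(0, n, M); Y[cbind(seq_len(n), data$class_ids + 1L)] <- 1
  W <- matrix(0, M, H); b <- numeric(M)
  sW <- adam_init(W); sb <- adam_init(b); t <- 0L
  set.seed(seed)
  for (e in seq_len(max(epochs, 0L))) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      Xi <- X[idx, , drop = FALSE]
      L <- Xi %*% t(W) + matrix(b, length(idx), M, byrow = TRUE)
      L <- L - apply(L, 1, max)
      P <- exp(L); P <- P / rowSums(P)
      G <- (P - Y[idx, , drop = FALSE]) / length(idx)
      gW <- t(G) %*% Xi
      gb <- colSums(G)
      t <- t + 1L
      up <- adam_step(W, gW, sW, lr, t); W <- up$param; sW <- up$state
      up <- adam_step(b, gb, sb, lr, t); b <- up$param; sb <- up$state
    }
  }
  lids <- loss_layer_ids(net)
  lens <- vapply(lids, function(l) net$layers[[l]]$theta, numeric(1))
  structure(list(W = W, b = b, layers = lids,
                 offsets = cumsum(c(0, lens[-length(lens)])), lengths = lens),
            class = "ff_head")
}

#' @export
print.ff_head <- function(x, ...) {
  cat(sprintf("<ff_head> %d classes x %d features (layers %s)\n",
              nrow(x$W), ncol(x$W), paste(x$layers, collapse = ", ")))
  invisible(x)
}

#' Linear-head inference
#'
#' One forward pass with the neutral label; class scores are the linear
#' head applied to the concatenated loss-layer activations.
#'
#' @param object an [ff_fit] with a fitted head
#' @param data an [image_set]
#' @return list with `class` (0-based predictions, ties toward the smaller
#'   index) and `scores` (n x M)
#' @export
infer_linear <- function(object, data) {
  head <- object$head
  if (is.null(head)) stop_ffcnn("no linear head fitted", "ffcnn_config_error")
  emb <- embed_neutral(data$images, object$bank, object$config$K)
  X <- ff_features(object$network, emb)
  S <- X %*% t(head$W) + matrix(head$b, nrow(X), nrow(head$W), byrow = TRUE)
  list(class = max.col(S, ties.method = "first") - 1L, scores = S)
}

#' Class activation maps from the linear head
#'
#' For each requested loss layer, the CAM at image pixel (r, c) is the sum
#' over that layer's channels of head weight times activation -- the signed
#' per-pixel evidence the head accumulates for the class. Because all
#' convolutions are same-padded, feature maps align 1:1 with image pixels
#' and no upsampling is needed. The aggregate map is the pixel-wise sum
#' over the selected layers, and when all loss layers are selected the
#' conservation identity `sum(aggregate) + bias = class score` holds
#' exactly.
#'
#' @param object an [ff_fit] with a fitted head
#' @param image a single image: matrix or (H, W, C) array
#' @param class 0-based class the map explains
#' @param layers which layers to include (subset of the head's layers;
#'   default all). Layer 1 is not connected to the head and cannot be
#'   requested.
#' @param normalize also store min-max normalized \[0,1\] display maps
#' @return an object of class `ff_cam`: list with `per_layer` (named list of
#'   signed H x W maps), `aggregate`, `class`, `score`, `bias`, and
#'   `normalized` when requested
#' @export
compute_cam <- function(object, image, class, layers = NULL, normalize = FALSE) {
  head <- object$head
  if (is.null(head)) stop_ffcnn("no linear head fitted", "ffcnn_config_error")
  net <- object$network
  layers <- layers %||% head$layers
  if (any(!(layers %in% head$layers)))
    stop_ffcnn("requested a layer not connected to the head (layer 1 is excluded)",
               "ffcnn_capability_error")
  if (length(dim(image)) == 2L) dim(image) <- c(dim(image), 1L)
  d <- dim(image)
  arr <- array(image, c(d, 1L))
  emb <- embed_neutral(arr, object$bank, object$config$K)
  fw <- ff_forward(net, emb, training = FALSE)
  wrow <- head$W[class + 1L, ]
  per_layer <- list()
  for (l in layers) {
    k <- match(l, head$layers)
    wl <- wrow[head$offsets[k] + seq_len(head$lengths[k])]
    y <- fw$layers[[l]]$y   # (H, W, C, 1)
    dy <- dim(y)
    contrib <- array(wl, dy[1:3]) * array(y, dy[1:3])
    per_layer[[paste0("layer", l)]] <- apply(contrib, c(1, 2), sum)
  }
  aggregate <- Reduce(`+`, per_layer)
  emb1 <- emb
  X <- ff_features(net, emb1)
  score <- drop(X %*% wrow) + head$b[class + 1L]
  out <- list(per_layer = per_layer, aggregate = aggregate,
              class = class, score = score, bias = head$b[class + 1L])
  if (normalize)
    out$normalized <- c(lapply(per_layer, minmax01),
                        list(aggregate = minmax01(aggregate)))
  structure(out, class = "ff_cam")
}

#' @export
print.ff_cam <- function(x, ...) {
  cat(sprintf("<ff_cam> class %d, %d layer map(s) %s; score %.4f (map total %.4f + bias %.4f)\n",
              x$class, length(x$per_layer),
              paste(dim(x$aggregate), collapse = "x"),
              x$score, sum(x$aggregate), x$bias))
  invisible(x)
}

#' Display a class activation map
#'
#' @param x an [ff_cam]
#' @param which "aggregate" or a per-layer name such as "layer2"
#' @param ... passed to [graphics::image]
#' @export
plot.ff_cam <- function(x, which = "aggregate", ...) {
  m <- if (which == "aggregate") x$aggregate else x$per_layer[[which]]
  # flip rows so the top-left origin renders upright
  graphics::image(t(m[nrow(m):1, ]), axes = FALSE, asp = 1,
                  col = grDevices::hcl.colors(64, "PiYG"),
                  main = sprintf("CAM class %d (%s)", x$class, which), ...)
  invisible(x)
}

#' Per-layer discrimination report
#'
#' For a positive/negative pair set, reports per layer the fraction of
#' samples whose polarity-matched membership probability exceeds 0.5
#' (ties count as incorrect) and the mean binary cross-entropy.
#'
#' @param net an [ff_network] or [ff_fit]
#' @param pairs a `pos_neg_set` from [build_pos_neg]
#' @return data frame with columns layer, accuracy, loss, include_in_loss
#' @export
discrimination_report <- function(net, pairs) {
  if (inherits(net, "ff_fit")) net <- net$network
  fp <- ff_forward(net, pairs$positive, training = FALSE)
  fn <- ff_forward(net, pairs$negative, training = FALSE)
  rows <- lapply(seq_len(net$n_layers), function(l) {
    th <- net$layers[[l]]$theta
    sp <- fp$layers[[l]]$g - th
    sn <- th - fn$layers[[l]]$g
    data.frame(layer = l,
               accuracy = mean(c(sp, sn) > 0),
               loss = mean(bce_from_logit(c(sp, sn))),
               include_in_loss = net$layers[[l]]$include_in_loss)
  })
  do.call(rbind, rows)
}
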
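# The model-fitting interface: ff_fit() trains an FF convolutional network
# and returns a classed object with the usual print/summary/coef/predict/
# plot methods.

#' Fit a Forward-Forward convolutional network
#'
#' Trains a stack of convolutional layers with the Forward-Forward
#' algorithm: each epoch the training images are embedded with their true
#' label (positive set) and with a wrong label drawn uniformly at random
#' (negative set, resampled every epoch). Per batch, both sets are forward
#' passed and every layer takes one Adam step on its own local goodness
#' loss; the reported combined loss sums the losses of the loss layers
#' (by default all layers except the first, which still trains on its own
#' local loss but is excluded from the combined loss and from inference).
#'
#' @param data an [image_set] of training images
#' @param bank a [label_bank]; defaults to [default_fourier_bank] of the
#'   class count
#' @param K label intensity in \[0,1\]
#' @param n_layers,n_filters,kernel,norm architecture, see [ff_network]
#' @param epochs total training epochs E
#' @param lr base Adam learning rate
#' @param batch_size minibatch size
#' @param cooldown logical; apply the linear learning-rate cooldown after
#'   the halfway epoch (see [lr_schedule])
#' @param include_first_in_loss logical; include layer 1 in the combined loss
#' @param seed master seed; all randomness (weight init, negative label
#'   draws, batch shuffling) is derived from it
#' @param fit_head logical; fit the linear classifier head after training
#' @param head_epochs,head_lr linear-head training parameters
#' @param track_accuracy logical; record goodness-inference training
#'   accuracy each epoch (on at most `accuracy_subsample` images)
#' @param accuracy_subsample subsample cap for the per-epoch accuracy
#' @param verbose print per-epoch progress
#' @return an object of class `ff_fit`: list with `network`, `bank`, `head`
#'   (or NULL), `history` (data frame: epoch, layer, loss, accuracy, lr;
#'   layer NA rows hold the combined loss and training accuracy), and
#'   `config`
#' @export
ff_fit <- function(data, bank = NULL, K = 0.35, n_layers = 3, n_filters = 8,
                   kernel = 3, norm = c("layer_norm", "batch_norm"),
                   epochs = 30, lr = 5e-4, batch_size = 50, cooldown = TRUE,
                   include_first_in_loss = FALSE, seed = 1,
                   fit_head = TRUE, head_epochs = 60, head_lr = 1e-2,
                   track_accuracy = TRUE, accuracy_subsample = 400,
                   verbose = FALSE) {
  norm <- match.arg(norm)
  stopifnot(inherits(data, "image_set"))
  bank <- bank %||% default_fourier_bank(data$n_classes)
  if (length(bank$specs) != data$n_classes)
    stop_ffcnn("label bank size must match the class count", "ffcnn_consistency_error")
  net <- ff_network(dim(data$images)[1:3], n_layers = n_layers,
                    n_filters = n_filters, kernel = kernel, norm = norm,
                    include_first_in_loss = include_first_in_loss,
                    seed = derive_seed(seed, 1L))
  opt <- lapply(net$layers, function(ly) list(
    W = adam_init(ly$W), b = adam_init(ly$b),
    gamma = adam_init(ly$gamma), beta = adam_init(ly$beta), t = 0L))
  n <- dim(data$images)[4]
  hist_rows <- list()
  acc_idx <- NULL
  if (track_accuracy) {
    set.seed(derive_seed(seed, 3L))
    acc_idx <- sort(sample.int(n, min(accuracy_subsample, n)))
  }
  for (e in seq_len(epochs)) {
    lr_e <- if (cooldown) lr_schedule(e, epochs, lr) else lr
    pairs <- build_pos_neg(data, bank, K, seed = derive_seed(seed, 100L + e))
    set.seed(derive_seed(seed, 10000L + e))
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    lsum <- numeric(net$n_layers); asum <- numeric(net$n_layers); wsum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      res <- ff_gradients(net,
                          pairs$positive[, , , idx, drop = FALSE],
                          pairs$negative[, , , idx, drop = FALSE])
      net <- res$net
      for (l in seq_len(net$n_layers)) {
        st <- res$stats[[l]]
        if (!is.finite(st$loss))
          stop_ffcnn(sprintf("non-finite loss in layer %d at epoch %d", l, e),
                     "ffcnn_numeric_error")
        opt[[l]]$t <- opt[[l]]$t + 1L
        for (pn in c("W", "b", if (norm == "batch_norm") c("gamma", "beta"))) {
          up <- adam_step(net$layers[[l]][[pn]], res$grads[[l]][[pn]],
                          opt[[l]][[pn]], lr_e, opt[[l]]$t)
          net$layers[[l]][[pn]] <- up$param
          opt[[l]][[pn]] <- up$state
        }
        lsum[l] <- lsum[l] + st$loss * length(idx)
        asum[l] <- asum[l] + st$accuracy * length(idx)
      }
      wsum <- wsum + length(idx)
    }
    layer_loss <- lsum / wsum; layer_acc <- asum / wsum
    incl <- vapply(net$layers, `[[`, logical(1), "include_in_loss")
    train_acc <- NA_real_
    if (track_accuracy) {
      sub <- subset_image_set(data, acc_idx)
      pred <- infer_goodness(net, sub, bank, K)$class
      train_acc <- mean(pred == sub$class_ids)
    }
    for (l in which(incl))
      hist_rows[[length(hist_rows) + 1L]] <- data.frame(
        epoch = e, layer = l, loss = layer_loss[l], accuracy = layer_acc[l],
        lr = lr_e)
    hist_rows[[length(hist_rows) + 1L]] <- data.frame(
      epoch = e, layer = NA_integer_, loss = sum(layer_loss[incl]),
      accuracy = train_acc, lr = lr_e)
    if (verbose)
      message(sprintf("epoch %3d  combined loss %8.4f  disc acc %s  train acc %s",
                      e, sum(layer_loss[incl]),
                      paste(sprintf("%.3f", layer_acc[incl]), collapse = "/"),
                      ifelse(is.na(train_acc), "-", sprintf("%.3f", train_acc))))
  }
  fit <- structure(list(network = net, bank = bank, head = NULL,
                        history = do.call(rbind, hist_rows),
                        config = list(K = K, epochs = epochs, lr = lr,
                                      batch_size = batch_size, cooldown = cooldown,
                                      norm = norm, kernel = kernel,
                                      n_layers = n_layers, n_filters = n_filters,
                                      include_first_in_loss = include_first_in_loss,
                                      n_classes = data$n_classes, seed = seed)),
                   class = "ff_fit")
  if (fit_head)
    fit$head <- fit_linear_head(fit, data, epochs = head_epochs, lr = head_lr,
                                seed = derive_seed(seed, 5L))
  fit
}

#' @export
print.ff_fit <- function(x, ...) {
  cat("Forward-Forward convolutional network fit\n")
  print(x$network)
  cat(sprintf("  label bank: %d %s labels, K = %.2f\n",
              length(x$bank$specs), x$bank$mode, x$config$K))
  if (!is.null(x$history)) {
    last <- x$history[x$history$epoch == max(x$history$epoch), ]
    comb <- last[is.na(last$layer), ]
    cat(sprintf("  %d epochs; final combined loss %.4f", x$config$epochs, comb$loss))
    if (!is.na(comb$accuracy))
      cat(sprintf("; training accuracy %.3f (goodness inference)", comb$accuracy))
    cat("\n")
  }
  cat(if (is.null(x$head)) "  no linear head fitted\n" else "  linear head fitted\n")
  invisible(x)
}

#' @export
summary.ff_fit <- function(object, ...) {
  last <- object$history[object$history$epoch == max(object$history$epoch), ]
  out <- list(fit = object,
              final = last,
              layer_table = last[!is.na(last$layer),
                                 c("layer", "loss", "accuracy")])
  class(out) <- "summary.ff_fit"
  out
}

#' @export
print.summary.ff_fit <- function(x, ...) {
  print(x$fit)
  cat("\nFinal per-layer discrimination (training data):\n")
  tab <- x$layer_table
  names(tab) <- c("layer", "disc. loss", "disc. accuracy")
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
coef.ff_fit <- function(object, ...) {
  out <- lapply(object$network$layers, function(ly) list(W = ly$W, b = ly$b))
  names(out) <- paste0("layer", seq_along(out))
  if (!is.null(object$head)) out$head <- list(W = object$head$W, b = object$head$b)
  out
}

#' Predict classes for new images
#'
#' @param object an [ff_fit]
#' @param newdata an [image_set]
#' @param type "linear" (single forward pass through the classifier head),
#'   "goodness" (one forward pass per candidate label, argmax of summed
#'   goodness over the loss layers), or "both"
#' @param ... unused
#' @return for "linear"/"goodness", an integer vector of 0-based class
#'   predictions with the per-class score matrix as attribute `scores`;
#'   for "both", a named list of the two
#' @export
predict.ff_fit <- function(object, newdata,
                           type = c("linear", "goodness", "both"), ...) {
  type <- match.arg(type)
  lin <- function() {
    if (is.null(object$head))
      stop_ffcnn("no linear head fitted; rerun ff_fit() with fit_head = TRUE or call fit_linear_head()",
                 "ffcnn_config_error")
    r <- infer_linear(object, newdata)
    structure(r$class, scores = r$scores)
  }
  good <- function() {
    r <- infer_goodness(object$network, newdata, object$bank, object$config$K)
    structure(r$class, scores = r$f)
  }
  switch(type, linear = lin(), goodness = good(),
         both = list(linear = lin(), goodness = good()))
}

#' Plot training history
#'
#' Two panels in the style of per-layer training diagnostics: the
#' discrimination loss of every loss layer plus the combined loss, and the
#' per-layer discrimination accuracy plus the goodness-inference training
#' accuracy.
#'
#' @param x an [ff_fit]
#' @param ... passed to [graphics::matplot]
#' @export
plot.ff_fit <- function(x, ...) {
  h <- x$history
  layers <- sort(unique(h$layer[!is.na(h$layer)]))
  epochs <- sort(unique(h$epoch))
  lmat <- sapply(layers, function(l) h$loss[!is.na(h$layer) & h$layer == l])
  amat <- sapply(layers, function(l) h$accuracy[!is.na(h$layer) & h$layer == l])
  comb <- h[is.na(h$layer), ]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(epochs, cbind(lmat, comb$loss), type = "l", lty = 1,
                    col = c(seq_along(layers) + 1L, 1L),
                    xlab = "epoch", ylab = "discrimination loss", ...)
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c(seq_along(layers) + 1L, 1L),
                   legend = c(paste("layer", layers), "combined"))
  graphics::matplot(epochs, cbind(amat, comb$accuracy), type = "l", lty = 1,
                    col = c(seq_along(layers) + 1L, 1L), ylim = c(0, 1),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", bty = "n", lty = 1,
                   col = c(seq_along(layers) + 1L, 1L),
                   legend = c(paste("layer", layers, "(discrimination)"),
                              "training (goodness)"))
  invisible(x)
}
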
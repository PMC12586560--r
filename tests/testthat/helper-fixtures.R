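# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Write an IDX image/label pair (optionally gzipped) for round-trip tests.
# imgs: array (H, W, n) with values in [0,1].
write_idx_fixture <- function(imgs, labels, images_path, labels_path) {
  d <- dim(imgs)
  con <- file(images_path, "wb")
  writeBin(c(2051L, d[3], d[1], d[2]), con, size = 4L, endian = "big")
  # IDX is row-major per image: write each image's rows contiguously
  for (i in seq_len(d[3]))
    writeBin(as.integer(round(t(imgs[, , i]) * 255)), con, size = 1L)
  close(con)
  con <- file(labels_path, "wb")
  writeBin(c(2049L, length(labels)), con, size = 4L, endian = "big")
  writeBin(as.integer(labels), con, size = 1L)
  close(con)
}

# Write CIFAR-style binary records. imgs: array (32, 32, 3, n) in [0,1].
write_cifar_fixture <- function(imgs, labels, path, coarse = NULL) {
  n <- dim(imgs)[4]
  con <- file(path, "wb")
  for (i in seq_len(n)) {
    if (!is.null(coarse)) writeBin(as.integer(coarse[i]), con, size = 1L)
    writeBin(as.integer(labels[i]), con, size = 1L)
    for (ch in 1:3)
      writeBin(as.integer(round(t(imgs[, , ch, i]) * 255)), con, size = 1L)
  }
  close(con)
}

# A small random image set (not learnable; for plumbing tests).
random_image_set <- function(n = 20, side = 8, n_classes = 4, channels = 1,
                             seed = 1) {
  set.seed(seed)
  imgs <- array(runif(side * side * channels * n), c(side, side, channels, n))
  image_set(imgs, rep_len(0:(n_classes - 1), n), n_classes)
}

# Reference convolution by explicit loops (independent of the im2col path).
naive_conv <- function(x, W, b) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  p <- k %/% 2
  xp <- array(0, c(H + 2 * p, Wd + 2 * p, C))
  xp[p + 1:H, p + 1:Wd, ] <- x
  out <- array(0, c(H, Wd, Cout))
  for (o in seq_len(Cout)) for (r in seq_len(H)) for (cc in seq_len(Wd)) {
    acc <- b[o]
    for (ch in seq_len(C)) for (dr in 0:(k - 1)) for (dc in 0:(k - 1))
      acc <- acc + xp[r + dr, cc + dc, ch] * W[dr + 1, dc + 1, ch, o]
    out[r, cc, o] <- acc
  }
  out
}

# The local FF loss of one layer, recomputed from forward passes only
# (finite-difference oracle target).
local_layer_loss <- function(net, l, x_pos, x_neg) {
  fp <- ff_forward(net, x_pos)
  fn <- ff_forward(net, x_neg)
  th <- net$layers[[l]]$theta
  mean(ffcnn:::bce_from_logit(fp$layers[[l]]$g - th)) +
    mean(ffcnn:::bce_from_logit(th - fn$layers[[l]]$g))
}

# One shared, fully trained desk-scale model for the expensive end-to-end
# checks; trained at most once per test run.
.shared <- new.env(parent = emptyenv())
shared_synthetic_fit <- function() {
  if (!is.null(.shared$fit)) return(.shared$fit)
  train <- generate_synthetic(4, 200, 16, 0.05, seed = derive_seed(1, 11),
                              split = "train")
  test <- generate_synthetic(4, 100, 16, 0.05, seed = derive_seed(1, 13),
                             split = "test")
  fit <- ff_fit(train, K = 0.40, n_layers = 3, n_filters = 8, kernel = 7,
                epochs = 30, lr = 1e-3, batch_size = 10, seed = 1,
                track_accuracy = FALSE, fit_head = TRUE)
  .shared$fit <- list(fit = fit, train = train, test = test)
  .shared$fit
}
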
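test_that("goodness is the squared norm of the activity vector", {
  expect_equal(goodness(c(0, 0, 0)), 0)
  expect_equal(goodness(c(1, 2)), 5)
  set.seed(1)
  y <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  expect_equal(goodness(y),
               c(sum(y[, , , 1]^2), sum(y[, , , 2]^2)), tolerance = 1e-12)
})

test_that("membership probabilities are logistic in the goodness offset", {
  expect_equal(layer_probability(10, 10, "positive"), 0.5)
  expect_equal(layer_probability(10, 10, "negative"), 0.5)
  expect_equal(layer_probability(13, 10, "positive"), stats::plogis(3),
               tolerance = 1e-12)
  g <- c(3, 8, 12)
  expect_equal(layer_probability(g, 7, "positive") +
                 layer_probability(g, 7, "negative"), rep(1, 3),
               tolerance = 1e-12)
})

test_that("the combined loss is summed per-layer cross-entropy averaged over the batch", {
  expect_equal(combined_loss(0.5), log(2), tolerance = 1e-12)
  expect_lt(combined_loss(1 - 1e-12), 1e-9)
  p <- matrix(c(0.7, 0.4, 0.9, 0.2), 2, 2)
  expect_equal(combined_loss(p),
               mean(c(-log(0.7) - log(0.9), -log(0.4) - log(0.2))),
               tolerance = 1e-12)
  expect_error(combined_loss(numeric(0)), class = "ffcnn_config_error")
})

test_that("layer normalization fixes the root mean square at one", {
  expect_equal(layer_normalize(c(3, 4)), c(3, 4) / sqrt(12.5), tolerance = 1e-6)
  set.seed(2)
  y <- array(rexp(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  z <- layer_normalize(y)
  rms <- sqrt(colMeans(matrix(z, ncol = 3)^2))
  expect_equal(rms, rep(1, 3), tolerance = 1e-6)
  # homogeneity: the length is removed, only the orientation survives
  # (exact up to the epsilon guard under the root)
  expect_equal(layer_normalize(10 * y), z, tolerance = 1e-6)
  # the all-zero vector maps to zero instead of dividing by zero
  expect_equal(layer_normalize(rep(0, 5)), rep(0, 5))
})

test_that("the learning rate holds, then cools down linearly", {
  expect_equal(lr_schedule(1, 100, 1e-3), 1e-3)
  expect_equal(lr_schedule(50, 100, 1e-3), 1e-3)
  # continuous at the halfway epoch
  expect_equal(lr_schedule(51, 100, 1e-3), (2e-3 / 100) * 50)
  expect_equal(lr_schedule(100, 100, 1e-3), 2e-5)
})

test_that("forward matches a loop-based convolution oracle", {
  set.seed(3)
  net <- ff_network(c(6, 6, 2), n_layers = 1, n_filters = 3, kernel = 3, seed = 4)
  x <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  fw <- ff_forward(net, x)
  for (i in 1:2) {
    ref <- pmax(naive_conv(x[, , , i], net$layers[[1]]$W, net$layers[[1]]$b), 0)
    expect_equal(array(fw$layers[[1]]$y[, , , i], dim(ref)), ref,
                 tolerance = 1e-10)
    expect_equal(fw$layers[[1]]$g[i], sum(ref^2), tolerance = 1e-8)
  }
})

test_that("a zero network produces zero goodness everywhere", {
  net <- ff_network(c(8, 8, 1), n_layers = 2, n_filters = 4, kernel = 3, seed = 1)
  for (l in 1:2) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  x <- array(runif(8 * 8 * 1 * 3), c(8, 8, 1, 3))
  fw <- ff_forward(net, x)
  expect_equal(fw$layers[[1]]$g, rep(0, 3))
  expect_equal(fw$layers[[2]]$g, rep(0, 3))
})

test_that("theta equals the layer's activation count and stays consistent", {
  net <- ff_network(c(12, 10, 1), n_layers = 3, n_filters = c(4, 6, 2), kernel = 5)
  x <- array(runif(12 * 10 * 1 * 2), c(12, 10, 1, 2))
  fw <- ff_forward(net, x)
  for (l in 1:3) {
    d <- dim(fw$layers[[l]]$y)
    expect_equal(net$layers[[l]]$theta, prod(d[1:3]))
  }
})

test_that("per-layer gradients match finite differences of the local loss", {
  set.seed(10)
  net <- ff_network(c(8, 8, 1), n_layers = 2, n_filters = 3, kernel = 3, seed = 3)
  xp <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  xn <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  res <- ffcnn:::ff_gradients(net, xp, xn)
  h <- 1e-6
  for (l in 1:2) {
    for (i in sample(length(net$layers[[l]]$W), 4)) {
      up <- net; up$layers[[l]]$W[i] <- up$layers[[l]]$W[i] + h
      dn <- net; dn$layers[[l]]$W[i] <- dn$layers[[l]]$W[i] - h
      fd <- (local_layer_loss(up, l, xp, xn) - local_layer_loss(dn, l, xp, xn)) / (2 * h)
      expect_equal(res$grads[[l]]$W[i], fd, tolerance = 1e-4)
    }
    # bias gradient too
    upb <- net; upb$layers[[l]]$b[1] <- upb$layers[[l]]$b[1] + h
    dnb <- net; dnb$layers[[l]]$b[1] <- dnb$layers[[l]]$b[1] - h
    fdb <- (local_layer_loss(upb, l, xp, xn) - local_layer_loss(dnb, l, xp, xn)) / (2 * h)
    expect_equal(res$grads[[l]]$b[1], fdb, tolerance = 1e-4)
  }
})

test_that("training is local: later losses contribute nothing to earlier weights", {
  set.seed(11)
  net <- ff_network(c(8, 8, 1), n_layers = 2, n_filters = 3, kernel = 3, seed = 5)
  xp <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  xn <- array(runif(8 * 8 * 3), c(8, 8, 1, 3))
  # layer 2's loss as a function of layer-1 weights, with layer 2's input
  # held at the values layer 1 emitted (the detached forward contract):
  # any perturbation of layer-1 weights leaves it exactly unchanged
  base_fw <- ff_forward(net, xp)
  detached_in <- layer_normalize(base_fw$layers[[1]]$y)
  l2_loss_detached <- function(w1_perturbed) {
    n2 <- net
    n2$layers[[1]]$W <- w1_perturbed
    one <- ff_network(c(8, 8, 3), n_layers = 1, n_filters = 3, kernel = 3)
    one$layers[[1]] <- n2$layers[[2]]
    fw <- ff_forward(one, detached_in)
    mean(ffcnn:::bce_from_logit(fw$layers[[1]]$g - one$layers[[1]]$theta))
  }
  W1 <- net$layers[[1]]$W
  pert <- W1; pert[5] <- pert[5] + 1e-3
  expect_identical(l2_loss_detached(W1), l2_loss_detached(pert))

  # and the implementation's layer-1 gradient is independent of layer 2:
  # replacing layer-2 weights entirely leaves layer 1's gradient bitwise equal
  res1 <- ffcnn:::ff_gradients(net, xp, xn)
  net2 <- net
  net2$layers[[2]]$W[] <- stats::rnorm(length(net2$layers[[2]]$W))
  res2 <- ffcnn:::ff_gradients(net2, xp, xn)
  expect_identical(res1$grads[[1]], res2$grads[[1]])
})

test_that("combined-loss gradients equal per-layer gradients computed in isolation", {
  # dual route: extract layer l's detached input, rebuild layer l as a
  # standalone single-layer network, and compare gradients
  set.seed(12)
  net <- ff_network(c(8, 8, 1), n_layers = 2, n_filters = 3, kernel = 3, seed = 6)
  xp <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  xn <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  full <- ffcnn:::ff_gradients(net, xp, xn)
  inp <- layer_normalize(ff_forward(net, xp)$layers[[1]]$y)
  inn <- layer_normalize(ff_forward(net, xn)$layers[[1]]$y)
  solo <- ff_network(c(8, 8, 3), n_layers = 1, n_filters = 3, kernel = 3)
  solo$layers[[1]] <- net$layers[[2]]
  alone <- ffcnn:::ff_gradients(solo, inp, inn)
  expect_equal(alone$grads[[1]]$W, full$grads[[2]]$W, tolerance = 1e-10)
  expect_equal(alone$grads[[1]]$b, full$grads[[2]]$b, tolerance = 1e-10)
})

test_that("scaling a layer's activations leaves downstream inputs unchanged", {
  set.seed(13)
  y <- array(rexp(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  for (cst in c(0.5, 10, 1000))
    expect_equal(layer_normalize(cst * y), layer_normalize(y), tolerance = 1e-6)
})

test_that("short training reduces the combined loss and is seed-reproducible", {
  ds <- generate_synthetic(2, 40, 12, 0.05, seed = 21)
  fit <- ff_fit(ds, K = 0.35, n_layers = 2, n_filters = 4, kernel = 5,
                epochs = 5, lr = 1e-3, batch_size = 10, seed = 2,
                track_accuracy = FALSE, fit_head = FALSE)
  comb <- fit$history$loss[is.na(fit$history$layer)]
  # monotone decrease over the first epochs, allowing at most one
  # non-decreasing step
  expect_lte(sum(diff(comb) >= 0), 1)
  fit2 <- ff_fit(ds, K = 0.35, n_layers = 2, n_filters = 4, kernel = 5,
                 epochs = 5, lr = 1e-3, batch_size = 10, seed = 2,
                 track_accuracy = FALSE, fit_head = FALSE)
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$history, fit2$history)
})

test_that("batch-norm layers train with exact local gradients too", {
  set.seed(14)
  net <- ff_network(c(8, 8, 1), n_layers = 2, n_filters = 3, kernel = 3,
                    norm = "batch_norm", seed = 7)
  xp <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  xn <- array(runif(8 * 8 * 4), c(8, 8, 1, 4))
  res <- ffcnn:::ff_gradients(net, xp, xn)
  # finite differences for the affine batch-norm parameters of layer 2.
  # bn_loss replays the exact forward used by ff_gradients (batch stats).
  bn_loss <- function(net, l) {
    fp <- ff_forward(net, xp, training = TRUE)
    fn <- ff_forward(fp$net, xn, training = TRUE)
    th <- net$layers[[l]]$theta
    mean(ffcnn:::bce_from_logit(fp$layers[[l]]$g - th)) +
      mean(ffcnn:::bce_from_logit(th - fn$layers[[l]]$g))
  }
  h <- 1e-5
  for (l in 1:2) for (pn in c("gamma", "beta")) {
    up <- net; up$layers[[l]][[pn]][1] <- up$layers[[l]][[pn]][1] + h
    dn <- net; dn$layers[[l]][[pn]][1] <- dn$layers[[l]][[pn]][1] - h
    fd <- (bn_loss(up, l) - bn_loss(dn, l)) / (2 * h)
    expect_equal(res$grads[[l]][[pn]][1], fd, tolerance = 1e-4)
  }
  # inference mode uses running averages, not batch statistics
  tr <- ff_forward(net, xp, training = TRUE)
  inf1 <- ff_forward(tr$net, xp, training = FALSE)
  inf2 <- ff_forward(tr$net, xp, training = FALSE)
  expect_identical(inf1$layers[[2]]$g, inf2$layers[[2]]$g)
  fitbn <- ff_fit(generate_synthetic(2, 20, 12, 0.05, seed = 22),
                  K = 0.35, n_layers = 2, n_filters = 4, kernel = 3,
                  norm = "batch_norm", epochs = 3, lr = 1e-3, batch_size = 10,
                  seed = 3, track_accuracy = FALSE, fit_head = FALSE)
  expect_true(all(is.finite(fitbn$history$loss)))
})
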
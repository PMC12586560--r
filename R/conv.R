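# Same-padded 2-D convolution via im2col/col2im.
#
# Images are arrays with dim (H, W, C, n): row-major raster, origin at the
# top-left (IDX convention), channels third, samples last. With padding
# k %/% 2 and stride 1 the spatial size is preserved, so a layer's neuron
# count -- and hence its goodness threshold -- never changes.

# Precompute, for one image of shape (H, W, C), the linear indices into the
# zero-padded image that gather the k x k x C receptive field of every output
# pixel. Feature columns are ordered (dr fastest, then dc, then channel) to
# match the memory layout of a (k, k, C, Cout) weight array.
im2col_index <- function(H, W, C, k) {
  p <- k %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  rc <- expand.grid(r = seq_len(H), c = seq_len(W))
  off <- expand.grid(dr = 0L:(k - 1L), dc = 0L:(k - 1L), ch = 0L:(C - 1L))
  idx <- matrix(0L, nrow = H * W, ncol = k * k * C)
  for (f in seq_len(nrow(off))) {
    idx[, f] <- off$ch[f] * (Hp * Wp) +
      (rc$c + off$dc[f] - 1L) * Hp +
      (rc$r + off$dr[f])
  }
  list(idx = idx, Hp = Hp, Wp = Wp, p = p, H = H, W = W, C = C, k = k)
}

# Gather the im2col patch matrix for a batch: (H*W*n) x (k*k*C), with rows
# grouped by sample and ordered (r fastest, then c) within a sample.
im2col_patches <- function(x, ii) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; n <- d[4]
  xp <- array(0, c(ii$Hp, ii$Wp, C, n))
  xp[ii$p + seq_len(H), ii$p + seq_len(W), , ] <- x
  dim(xp) <- NULL
  per <- ii$Hp * ii$Wp * C
  offs <- rep((seq_len(n) - 1L) * per, each = H * W)
  IDX <- ii$idx[rep(seq_len(H * W), n), , drop = FALSE] + offs
  matrix(xp[IDX], nrow = H * W * n)
}

# Forward convolution. W has dim (k, k, Cin, Cout), b length Cout.
# Returns activations (H, W, Cout, n); patches are kept when gradients will
# be needed.
conv_forward <- function(x, W, b, ii, want_patches = FALSE) {
  d <- dim(x)
  H <- d[1]; Wd <- d[2]; n <- d[4]
  k <- dim(W)[1]; Cin <- dim(W)[3]; Cout <- dim(W)[4]
  P <- im2col_patches(x, ii)
  Z <- P %*% matrix(W, nrow = k * k * Cin)
  Z <- Z + matrix(b, nrow(Z), Cout, byrow = TRUE)
  A <- array(Z, c(H, Wd, n, Cout))
  A <- aperm(A, c(1L, 2L, 4L, 3L))
  list(z = A, P = if (want_patches) P else NULL)
}

# Gradients of a scalar objective w.r.t. the convolution parameters, given
# the gradient gz (H, W, Cout, n) at the pre-activation output and the patch
# matrix P of the same forward pass.
conv_param_grad <- function(P, gz) {
  d <- dim(gz)
  G <- aperm(gz, c(1L, 2L, 4L, 3L))
  dim(G) <- c(d[1] * d[2] * d[4], d[3])
  list(W = crossprod(P, G), b = colSums(G))
}

# Gradient w.r.t. the convolution input (needed only for trainable batch-norm
# parameters placed before the convolution). Scatter-adds patch gradients
# back into the padded image; within one feature column every output pixel
# maps to a distinct padded pixel, so plain indexed addition is exact.
conv_input_grad <- function(gz, W, ii, n) {
  H <- ii$H; Wd <- ii$W; C <- ii$C; k <- ii$k
  Cout <- dim(W)[4]
  G <- aperm(gz, c(1L, 2L, 4L, 3L))
  dim(G) <- c(H * Wd * n, Cout)
  gP <- G %*% t(matrix(W, nrow = k * k * C))
  per <- ii$Hp * ii$Wp * C
  offs <- rep((seq_len(n) - 1L) * per, each = H * Wd)
  gxp <- numeric(per * n)
  base <- ii$idx[rep(seq_len(H * Wd), n), , drop = FALSE]
  for (f in seq_len(ncol(gP))) {
    pos <- base[, f] + offs
    gxp[pos] <- gxp[pos] + gP[, f]
  }
  gxp <- array(gxp, c(ii$Hp, ii$Wp, C, n))
  gxp[ii$p + seq_len(H), ii$p + seq_len(Wd), , , drop = FALSE]
}
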
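# Dataset containers and readers.

#' Construct an image set
#'
#' The common container for image-classification data: an array of
#' intensities in \[0,1\] with dim (height, width, channels, n), integer class
#' ids in 0..M-1 and a split tag. Images use row-major raster orientation
#' with the origin at the top-left (the IDX convention); all modules share
#' this orientation.
#'
#' @param images numeric array, dim (H, W, C, n), values in \[0,1\]
#' @param class_ids integer vector of length n, values in 0..n_classes-1
#' @param n_classes number of classes M
#' @param split split tag, e.g. "train" or "test"
#' @return an object of class `image_set`
#' @export
image_set <- function(images, class_ids, n_classes, split = "train") {
  if (length(dim(images)) == 3L) dim(images) <- c(dim(images), 1L)
  stopifnot(length(dim(images)) == 4L)
  n <- dim(images)[4]
  class_ids <- as.integer(class_ids)
  if (length(class_ids) != n)
    stop_ffcnn("image count and label count differ", "ffcnn_consistency_error")
  if (any(images < 0 | images > 1))
    stop_ffcnn("image intensities must lie in [0,1]", "ffcnn_consistency_error")
  if (any(class_ids < 0L) || any(class_ids >= n_classes))
    stop_ffcnn("class ids must lie in 0..n_classes-1", "ffcnn_consistency_error")
  structure(list(images = images, class_ids = class_ids,
                 n_classes = as.integer(n_classes), split = split),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<image_set> %d images, %dx%dx%d, %d classes, split '%s'\n",
              d[4], d[1], d[2], d[3], x$n_classes, x$split))
  invisible(x)
}

#' @export
dim.image_set <- function(x) dim(x$images)

# Subset an image_set by sample index.
subset_image_set <- function(data, idx) {
  image_set(data$images[, , , idx, drop = FALSE], data$class_ids[idx],
            data$n_classes, data$split)
}

read_u32be <- function(con) {
  b <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(b) < 4L) stop_ffcnn("truncated IDX header", "ffcnn_format_error")
  sum(b * c(16777216, 65536, 256, 1))
}

#' Read an MNIST-style IDX image/label pair
#'
#' Parses the IDX container format used by MNIST: a big-endian magic number
#' (0x00000803 for images, 0x00000801 for labels), dimensions, then raw
#' unsigned bytes. Pixel bytes are rescaled to \[0,1\] by division by 255.
#' Gzip-compressed files are handled transparently.
#'
#' @param images_path path to the idx3-ubyte image file (optionally .gz)
#' @param labels_path path to the idx1-ubyte label file (optionally .gz)
#' @param n_classes number of classes; defaults to max(label) + 1
#' @return an [image_set]
#' @export
read_idx <- function(images_path, labels_path, n_classes = NULL) {
  open_idx <- function(path) {
    con <- gzfile(path, "rb")
    con
  }
  con <- open_idx(images_path)
  on.exit(close(con), add = TRUE)
  magic <- read_u32be(con)
  if (magic != 2051)
    stop_ffcnn(sprintf("not an IDX image file (magic %d, expected 2051)", magic),
               "ffcnn_format_error")
  n <- read_u32be(con); H <- read_u32be(con); W <- read_u32be(con)
  raw_px <- readBin(con, "integer", n = n * H * W, size = 1L, signed = FALSE)
  if (length(raw_px) != n * H * W)
    stop_ffcnn("truncated IDX image payload", "ffcnn_format_error")

  con2 <- open_idx(labels_path)
  on.exit(close(con2), add = TRUE)
  magic2 <- read_u32be(con2)
  if (magic2 != 2049)
    stop_ffcnn(sprintf("not an IDX label file (magic %d, expected 2049)", magic2),
               "ffcnn_format_error")
  nl <- read_u32be(con2)
  if (nl != n)
    stop_ffcnn(sprintf("image count (%d) and label count (%d) differ", n, nl),
               "ffcnn_consistency_error")
  labels <- readBin(con2, "integer", n = nl, size = 1L, signed = FALSE)

  # IDX stores each image row-major (rows contiguous); R arrays are
  # column-major, so read as (W, H) per image and transpose via aperm.
  imgs <- array(raw_px / 255, c(W, H, n))
  imgs <- aperm(imgs, c(2L, 1L, 3L))
  dim(imgs) <- c(H, W, 1L, n)
  image_set(imgs, labels, n_classes %||% (max(labels) + 1L))
}

#' Read a CIFAR-10/100 binary batch
#'
#' Each CIFAR-10 record is 1 label byte + 3072 pixel bytes (channel-major
#' R,G,B planes of a 32x32 image, row-major within a plane); CIFAR-100
#' records carry a coarse label byte then a fine label byte. The fine label
#' is used as the class id and the coarse label is ignored. Pixels are
#' rescaled to \[0,1\].
#'
#' @param path path to a binary batch file
#' @param variant "cifar10" or "cifar100"
#' @return an [image_set]
#' @export
read_cifar_binary <- function(path, variant = c("cifar10", "cifar100")) {
  variant <- match.arg(variant)
  label_bytes <- if (variant == "cifar10") 1L else 2L
  rec <- label_bytes + 3072L
  sz <- file.size(path)
  if (is.na(sz) || sz == 0 || sz %% rec != 0)
    stop_ffcnn(sprintf("file size %d is not a multiple of the %d-byte record",
                       sz, rec), "ffcnn_format_error")
  n <- as.integer(sz %/% rec)
  raw_all <- readBin(path, "integer", n = sz, size = 1L, signed = FALSE)
  m <- matrix(raw_all, nrow = rec, ncol = n)
  labels <- m[label_bytes, ]           # fine label is the last label byte
  px <- m[(label_bytes + 1L):rec, , drop = FALSE] / 255
  # per record: 3 channel planes of 1024 bytes, each plane row-major 32x32,
  # so the natural fill order is (column, row); swap to (row, column)
  imgs <- aperm(array(px, c(32L, 32L, 3L, n)), c(2L, 1L, 3L, 4L))
  image_set(imgs, labels, max(labels) + 1L)
}

#' Read a directory of PNG images with a class manifest
#'
#' @param dir directory containing PNG files
#' @param manifest path to a tab-separated file with columns
#'   `filename` and `class_id` (no header)
#' @param n_classes number of classes; defaults to max(class_id) + 1
#' @return an [image_set]
#' @export
read_png_dir <- function(dir, manifest, n_classes = NULL) {
  man <- utils::read.table(manifest, sep = "\t", col.names = c("filename", "class_id"),
                           stringsAsFactors = FALSE)
  imgs <- lapply(man$filename, function(f) {
    a <- png::readPNG(file.path(dir, f))
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    a[, , seq_len(min(dim(a)[3], 3L)), drop = FALSE]  # drop alpha
  })
  d0 <- dim(imgs[[1]])
  if (!all(vapply(imgs, function(a) identical(dim(a), d0), logical(1))))
    stop_ffcnn("all PNG images must share one shape", "ffcnn_consistency_error")
  arr <- array(unlist(imgs), c(d0, length(imgs)))
  image_set(arr, man$class_id, n_classes %||% (max(man$class_id) + 1L))
}

# ---- synthetic shape images ------------------------------------------------

# Each class is a distinct geometric primitive drawn on a blank canvas.
# Templates are defined on a unit grid and rendered at any image side.
shape_template <- function(class_id, side, hard = FALSE) {
  g <- expand.grid(r = seq_len(side), c = seq_len(side))
  cx <- (side + 1) / 2
  s <- side
  fg <- if (hard) 0.6 else 1
  m <- matrix(0, side, side)
  set_px <- function(mask) { m[matrix(c(g$r[mask], g$c[mask]), ncol = 2)] <<- fg }
  rad <- s / 4
  switch(class_id + 1L,
    { # 0: filled disk
      set_px((g$r - cx)^2 + (g$c - cx)^2 <= rad^2)
    },
    { # 1: cross (plus sign)
      w <- max(1, round(s / 10))
      set_px(abs(g$r - cx) <= w | abs(g$c - cx) <= w)
    },
    { # 2: horizontal bar
      set_px(abs(g$r - cx) <= max(1, round(s / 8)))
    },
    { # 3: ring (annulus)
      d2 <- (g$r - cx)^2 + (g$c - cx)^2
      set_px(d2 <= rad^2 & d2 >= (rad * 0.55)^2)
    },
    { # 4: corner wedge (upper-left triangle)
      set_px(g$r + g$c <= s)
    },
    { # 5: main diagonal bar
      set_px(abs(g$r - g$c) <= max(1, round(s / 8)))
    },
    { # 6: square outline
      lo <- round(s / 4); hi <- s - lo + 1
      inside <- g$r >= lo & g$r <= hi & g$c >= lo & g$c <= hi
      border <- inside & (g$r <= lo + 1 | g$r >= hi - 1 | g$c <= lo + 1 | g$c >= hi - 1)
      set_px(border)
    },
    { # 7: X (both diagonals)
      w <- max(1, round(s / 8))
      set_px(abs(g$r - g$c) <= w | abs(g$r + g$c - (s + 1)) <= w)
    },
    stop_ffcnn(sprintf("only %d primitive templates available, class %d requested",
                       8L, class_id), "ffcnn_capability_error")
  )
  m
}

#' Generate a synthetic multi-class shape dataset
#'
#' Each class is a distinct geometric primitive (disk, cross, bar, ring,
#' wedge, diagonal, square outline, X -- at most 8 classes). Every image is
#' the class template with a random integer translation jitter plus additive
#' Gaussian noise, clipped to \[0,1\]. Deterministic given the seed.
#'
#' The `hard` variant renders low-contrast templates, doubles the jitter and
#' overlays a random distractor bar per image, producing finer, more
#' texture-like class evidence; it is used to probe shortcut learning.
#'
#' @param n_classes number of classes (2..8)
#' @param images_per_class images generated per class
#' @param image_side image side length in pixels (>= 8)
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   intensity units
#' @param seed RNG seed
#' @param split split tag recorded on the returned set
#' @param hard logical; render the harder fine-featured variant
#' @return an [image_set]
#' @export
generate_synthetic <- function(n_classes = 4, images_per_class = 50,
                               image_side = 16, noise_sd = 0.05, seed = 1,
                               split = "train", hard = FALSE) {
  if (image_side < 8) stop_ffcnn("image_side must be >= 8", "ffcnn_consistency_error")
  if (n_classes < 2) stop_ffcnn("need at least 2 classes", "ffcnn_consistency_error")
  if (noise_sd < 0) stop_ffcnn("noise_sd must be >= 0", "ffcnn_consistency_error")
  if (n_classes > 8) stop_ffcnn("only 8 primitive templates available",
                                "ffcnn_capability_error")
  set.seed(seed)
  templates <- lapply(seq_len(n_classes) - 1L, shape_template,
                      side = image_side, hard = hard)
  n <- n_classes * images_per_class
  imgs <- array(0, c(image_side, image_side, 1L, n))
  cls <- rep(seq_len(n_classes) - 1L, each = images_per_class)
  jmax <- max(1L, image_side %/% (if (hard) 6L else 8L))
  for (i in seq_len(n)) {
    tpl <- templates[[cls[i] + 1L]]
    dr <- sample(-jmax:jmax, 1L)
    dc <- sample(-jmax:jmax, 1L)
    im <- shift_clip(tpl, dr, dc)
    if (hard) {
      # distractor bar at a random row or column, unrelated to class
      pos <- sample(seq_len(image_side), 1L)
      amp <- stats::runif(1, 0.2, 0.4)
      if (stats::runif(1) < 0.5) im[pos, ] <- pmin(1, im[pos, ] + amp)
      else im[, pos] <- pmin(1, im[, pos] + amp)
    }
    if (noise_sd > 0)
      im <- im + matrix(stats::rnorm(image_side^2, 0, noise_sd), image_side)
    imgs[, , 1L, i] <- clip01(im)
  }
  image_set(imgs, cls, n_classes, split)
}

# Translate a matrix by (dr, dc), filling exposed pixels with 0.
shift_clip <- function(m, dr, dc) {
  out <- matrix(0, nrow(m), ncol(m))
  rs <- seq_len(nrow(m)); cs <- seq_len(ncol(m))
  rsrc <- rs - dr; csrc <- cs - dc
  ok_r <- rsrc >= 1 & rsrc <= nrow(m)
  ok_c <- csrc >= 1 & csrc <= ncol(m)
  out[rs[ok_r], cs[ok_c]] <- m[rsrc[ok_r], csrc[ok_c]]
  out
}

#' Build the paired positive/negative dataset for FF training
#'
#' For every image the positive sample embeds the true class label and the
#' negative sample embeds a wrong label drawn uniformly from the M-1 other
#' classes. Deterministic given the seed.
#'
#' @param data an [image_set]
#' @param bank a [label_bank] with one label per class
#' @param K label intensity in \[0,1\] (relative contribution of the label
#'   component to the blended image)
#' @param seed RNG seed for the wrong-class draw
#' @return an object of class `pos_neg_set`: list with `positive` and
#'   `negative` image arrays (same dim as `data$images`), `true_class` and
#'   `negative_class` integer vectors
#' @export
build_pos_neg <- function(data, bank, K, seed = 1) {
  M <- data$n_classes
  if (M < 2) stop_ffcnn("no wrong class exists for M < 2", "ffcnn_capability_error")
  if (length(bank$specs) != M)
    stop_ffcnn("label bank size must equal the class count", "ffcnn_consistency_error")
  set.seed(seed)
  n <- dim(data$images)[4]
  true_cls <- data$class_ids
  # uniform draw over the M-1 wrong classes
  u <- sample.int(M - 1L, n, replace = TRUE) - 1L
  neg_cls <- ifelse(u >= true_cls, u + 1L, u)
  pos <- embed_with_bank(data$images, bank, true_cls, K)
  neg <- embed_with_bank(data$images, bank, neg_cls, K)
  structure(list(positive = pos, negative = neg,
                 true_class = true_cls, negative_class = as.integer(neg_cls),
                 K = K, mode = bank$mode),
            class = "pos_neg_set")
}

#' @export
print.pos_neg_set <- function(x, ...) {
  cat(sprintf("<pos_neg_set> %d pairs, K = %.2f, %s labels\n",
              length(x$true_class), x$K, x$mode))
  invisible(x)
}
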
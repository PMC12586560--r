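# Spatially-extended class labels.
#
# A label is either a Fourier gray-value wave (distinct frequency,
# orientation, phase per class) rendered at the image size, or a
# deterministic program of morphological transforms applied to the input
# image itself. Either way the label covers every pixel, so every position
# of a convolutional filter sees class information -- unlike one-hot corner
# encodings, which only the filters covering the corner can read.

#' Fourier label specification
#'
#' @param frequency wave frequency in cycles per image side (> 0)
#' @param orientation wave orientation in radians, in \[0, pi)
#' @param phase phase offset in radians, in \[0, 2*pi)
#' @return an object of class `fourier_label`
#' @export
fourier_label <- function(frequency, orientation, phase = 0) {
  stopifnot(frequency > 0, orientation >= 0, orientation < pi,
            phase >= 0, phase < 2 * pi)
  structure(list(frequency = frequency, orientation = orientation,
                 phase = phase), class = "fourier_label")
}

#' @export
format.fourier_label <- function(x, ...)
  sprintf("fourier(f=%g, alpha=%g, phi=%g)", x$frequency, x$orientation, x$phase)

#' Render a Fourier label pattern
#'
#' Pixel (r, c) (0-based offsets from the top-left) takes the value
#' `0.5 + 0.5 * sin(2*pi*f*(c*cos(a) + r*sin(a))/side + phi)` with
#' `side = max(height, width)`, so values lie in \[0,1\].
#'
#' @param spec a [fourier_label]
#' @param height,width pattern size in pixels
#' @return a height x width matrix in \[0,1\]
#' @export
render_fourier <- function(spec, height, width) {
  stopifnot(height >= 1, width >= 1)
  side <- max(height, width)
  r <- matrix(0:(height - 1), height, width)
  cc <- matrix(0:(width - 1), height, width, byrow = TRUE)
  u <- cc * cos(spec$orientation) + r * sin(spec$orientation)
  0.5 + 0.5 * sin(2 * pi * spec$frequency * u / side + spec$phase)
}

# ---- morphology labels -----------------------------------------------------

# Vocabulary of deterministic, shape-preserving primitives. Rotations are
# restricted to quarter turns so that application is exact (no resampling).
morph_ops <- c("rotate", "flip_h", "flip_v", "shift", "invert", "dilate", "erode")

#' Morphology label specification
#'
#' An ordered, non-empty program of deterministic image transforms. Each
#' step is a list with an `op` field and parameters:
#' `rotate` (quarters: 1..3 quarter turns counter-clockwise), `flip_h`,
#' `flip_v`, `shift` (dx, dy: cyclic shift in pixels), `invert` (intensity
#' inversion 1 - x), `dilate` / `erode` (grayscale morphology with a disc
#' structuring element of radius r).
#'
#' @param steps list of step lists, applied in order
#' @return an object of class `morphology_label`
#' @export
morphology_label <- function(steps) {
  if (length(steps) == 0)
    stop_ffcnn("a morphology label needs at least one step", "ffcnn_consistency_error")
  for (s in steps)
    if (!(s$op %in% morph_ops))
      stop_ffcnn(sprintf("unknown morphology primitive '%s'", s$op),
                 "ffcnn_capability_error")
  structure(list(steps = steps), class = "morphology_label")
}

#' @export
format.morphology_label <- function(x, ...) {
  paste(vapply(x$steps, function(s) switch(s$op,
    rotate = sprintf("rotate(%d)", s$quarters),
    shift = sprintf("shift(%d,%d)", s$dx, s$dy),
    dilate = sprintf("dilate(%d)", s$r),
    erode = sprintf("erode(%d)", s$r),
    s$op), character(1)), collapse = "|")
}

# exact quarter-turn rotation (counter-clockwise)
rot_quarter <- function(m, quarters) {
  quarters <- quarters %% 4L
  if (quarters == 0L) return(m)
  for (i in seq_len(quarters)) m <- t(m)[ncol(m):1, , drop = FALSE]
  m
}

cyclic_shift <- function(m, dx, dy) {
  # dx: columns to the right, dy: rows down, both cyclic
  nr <- nrow(m); nc <- ncol(m)
  ri <- ((seq_len(nr) - 1L - dy) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L - dx) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

gray_morph <- function(m, r, what = c("dilate", "erode")) {
  what <- match.arg(what)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  if (what == "dilate") EBImage::dilate(m, brush) else EBImage::erode(m, brush)
}

apply_morph_channel <- function(m, steps) {
  for (s in steps) {
    m <- switch(s$op,
      rotate = rot_quarter(m, s$quarters),
      flip_h = m[, ncol(m):1, drop = FALSE],
      flip_v = m[nrow(m):1, , drop = FALSE],
      shift  = cyclic_shift(m, s$dx, s$dy),
      invert = 1 - m,
      dilate = gray_morph(m, s$r, "dilate"),
      erode  = gray_morph(m, s$r, "erode"),
      stop_ffcnn(sprintf("unknown morphology primitive '%s'", s$op),
                 "ffcnn_capability_error"))
  }
  m
}

#' Apply a morphology label program to an image
#'
#' Transforms are applied in the listed order, per channel, and the result
#' is clipped to \[0,1\]. Output shape equals input shape. For non-square
#' images quarter-turn rotations are replaced by a transpose-free 180-degree
#' rotation to preserve shape.
#'
#' @param spec a [morphology_label]
#' @param image matrix (H x W) or array (H x W x C) in \[0,1\]
#' @return transformed image, same shape
#' @export
apply_morphology <- function(spec, image) {
  d <- dim(image)
  is_mat <- length(d) == 2L
  if (is_mat) { dim(image) <- c(d, 1L); d <- dim(image) }
  steps <- spec$steps
  if (d[1] != d[2]) {
    steps <- lapply(steps, function(s) {
      if (s$op == "rotate" && s$quarters %% 2L == 1L) list(op = "rotate", quarters = 2L)
      else s
    })
  }
  out <- image
  for (ch in seq_len(d[3]))
    out[, , ch] <- clip01(apply_morph_channel(image[, , ch], steps))
  if (is_mat) dim(out) <- d[1:2]
  out
}

# ---- label bank ------------------------------------------------------------

#' Construct a label bank
#'
#' One label spec per class, all of one mode. Specs must be pairwise
#' distinct.
#'
#' @param specs list of [fourier_label] or [morphology_label] objects,
#'   ordered by class id
#' @param mode "fourier" or "morphology" (inferred from the specs if omitted)
#' @return an object of class `label_bank`
#' @export
label_bank <- function(specs, mode = NULL) {
  stopifnot(length(specs) >= 1)
  inferred <- if (inherits(specs[[1]], "fourier_label")) "fourier" else "morphology"
  mode <- mode %||% inferred
  keys <- vapply(specs, format, character(1))
  if (anyDuplicated(keys))
    stop_ffcnn("label bank specs must be pairwise distinct", "ffcnn_consistency_error")
  structure(list(specs = specs, mode = mode), class = "label_bank")
}

#' @export
print.label_bank <- function(x, ...) {
  cat(sprintf("<label_bank> %d %s labels\n", length(x$specs), x$mode))
  for (i in seq_along(x$specs))
    cat(sprintf("  class %d: %s\n", i - 1L, format(x$specs[[i]])))
  invisible(x)
}

#' @export
length.label_bank <- function(x) length(x$specs)

#' Default Fourier label bank
#'
#' Enumerates frequencies {2, 3, 4, 5} (cycles per side) crossed with
#' orientations {0, 45, 90, 135} degrees -- frequency-major order, i.e.
#' (f=2, 0deg), (f=2, 45deg), ..., (f=2, 135deg), (f=3, 0deg), ... -- with
#' phase 0, and takes the first M combinations. The enumeration spans
#' frequency/orientation space evenly and is fully reproducible.
#'
#' @param M number of classes (<= 16)
#' @return a [label_bank] in Fourier mode
#' @export
default_fourier_bank <- function(M) {
  if (M > 16) stop_ffcnn("the default Fourier bank has 16 combinations; use generate_candidates() + select_diverse_subset() for more classes",
                         "ffcnn_capability_error")
  freqs <- c(2, 3, 4, 5)
  orients <- c(0, 45, 90, 135) * pi / 180
  specs <- list()
  for (f in freqs) for (a in orients)
    specs[[length(specs) + 1L]] <- fourier_label(f, a, 0)
  label_bank(specs[seq_len(M)], "fourier")
}

#' Default morphology label bank
#'
#' A fixed, documented list of ten transformation programs; the first M are
#' used. All programs are deterministic and shape-preserving. The
#' enumeration puts the transforms whose action is most distinctive on
#' typical imagery first (intensity inversion, grayscale dilation and
#' erosion, cyclic shift) and the purely geometric ones -- which act
#' weakly on rotation- or reflection-symmetric content -- later.
#'
#' @param M number of classes (<= 10)
#' @return a [label_bank] in morphology mode
#' @export
default_morphology_bank <- function(M) {
  progs <- list(
    list(list(op = "invert")),
    list(list(op = "dilate", r = 1L)),
    list(list(op = "erode", r = 1L)),
    list(list(op = "shift", dx = 3L, dy = 3L)),
    list(list(op = "rotate", quarters = 1L)),
    list(list(op = "flip_h")),
    list(list(op = "rotate", quarters = 2L)),
    list(list(op = "flip_v"), list(op = "invert")),
    list(list(op = "rotate", quarters = 3L)),
    list(list(op = "shift", dx = -3L, dy = 2L), list(op = "invert"))
  )
  if (M > length(progs))
    stop_ffcnn("the default morphology bank has 10 programs; use generate_candidates() + select_diverse_subset() for more classes",
               "ffcnn_capability_error")
  label_bank(lapply(progs[seq_len(M)], morphology_label), "morphology")
}

#' One-hot corner label pattern (baseline)
#'
#' The classic encoding that marks class m by setting pixel (row 1,
#' column m+1) to 1 on an otherwise black pattern. Provided only as a
#' baseline for fully-connected sanity checks; it is unsuitable for
#' convolutional training because most filter positions never see it.
#'
#' @param class_id class id in 0..M-1
#' @param height,width pattern size
#' @return a height x width matrix
#' @export
onehot_label_pattern <- function(class_id, height, width) {
  m <- matrix(0, height, width)
  m[1, class_id + 1L] <- 1
  m
}

# ---- embedding -------------------------------------------------------------

#' Embed a label component into an image
#'
#' The labeled image is the convex blend `(1 - K) * image + K * label`,
#' followed by per-image min-max renormalization to \[0,1\] (a constant
#' blend maps to all zeros). With a Fourier bank the label component is the
#' rendered wave (broadcast across channels); with a morphology bank it is
#' the transformed input image itself, so K keeps the same meaning of a
#' relative label contribution in both modes.
#'
#' @param image matrix or (H x W x C) array in \[0,1\]
#' @param label_component matrix (broadcast over channels) or array of the
#'   image's shape
#' @param K label intensity in \[0,1\]
#' @return labeled image, same shape as `image`, values in \[0,1\]
#' @export
embed_label <- function(image, label_component, K) {
  stopifnot(K >= 0, K <= 1)
  d <- dim(image)
  is_mat <- length(d) == 2L
  if (is_mat) { dim(image) <- c(d, 1L); d <- dim(image) }
  if (length(dim(label_component)) == 2L) {
    if (!all(dim(label_component) == d[1:2]))
      stop_ffcnn("label pattern shape does not match the image", "ffcnn_consistency_error")
    label_component <- array(rep(label_component, d[3]), d)
  } else if (!all(dim(label_component) == d)) {
    stop_ffcnn("label component shape does not match the image", "ffcnn_consistency_error")
  }
  out <- minmax01((1 - K) * image + K * label_component)
  if (is_mat) dim(out) <- d[1:2]
  out
}

# Embed a batch with per-sample class ids; Fourier patterns are rendered
# once per class and reused.
embed_with_bank <- function(images, bank, class_ids, K) {
  d <- dim(images)
  out <- images
  patterns <- if (bank$mode == "fourier")
    lapply(bank$specs, render_fourier, height = d[1], width = d[2])
  for (i in seq_len(d[4])) {
    img <- array(images[, , , i], d[1:3])
    comp <- if (bank$mode == "fourier")
      patterns[[class_ids[i] + 1L]]
    else
      apply_morphology(bank$specs[[class_ids[i] + 1L]], img)
    out[, , , i] <- embed_label(img, comp, K)
  }
  out
}

# ---- correlation and selection --------------------------------------------

# Render/apply every spec at the probe and return the flattened pattern
# matrix (pixels x M).
bank_pattern_matrix <- function(specs, mode, probe) {
  if (mode == "fourier") {
    stopifnot(length(probe) >= 2)
    vap <- vapply(specs, function(s) as.vector(render_fourier(s, probe[1], probe[2])),
                  numeric(probe[1] * probe[2]))
  } else {
    vap <- vapply(specs, function(s) as.vector(apply_morphology(s, probe)),
                  numeric(length(probe)))
  }
  vap
}

#' Pairwise correlation matrix of a label bank
#'
#' Entry (i, j) is the Pearson correlation of the flattened rendered
#' patterns (Fourier mode, rendered at the probe shape) or of the flattened
#' transformed probe images (morphology mode). Symmetric with unit diagonal.
#'
#' @param bank a [label_bank] or plain list of specs
#' @param probe for Fourier mode a c(height, width) shape; for morphology
#'   mode a probe image (typically the mean training image)
#' @param mode label mode, inferred from `bank` when it is a [label_bank]
#' @return an M x M correlation matrix
#' @export
pairwise_correlation <- function(bank, probe, mode = NULL) {
  specs <- if (inherits(bank, "label_bank")) bank$specs else bank
  mode <- mode %||% if (inherits(bank, "label_bank")) bank$mode
    else if (inherits(specs[[1]], "fourier_label")) "fourier" else "morphology"
  X <- bank_pattern_matrix(specs, mode, probe)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop_ffcnn("a label pattern is constant; its correlation is undefined",
               "ffcnn_degenerate_error")
  stats::cor(X)
}

#' Generate random candidate label specs
#'
#' Fourier candidates sample frequency, orientation and phase uniformly from
#' the given ranges. Morphology candidates sample random programs of one to
#' three primitives with random parameters. Candidates are unique and the
#' draw is deterministic given the seed.
#'
#' @param mode "fourier" or "morphology"
#' @param n_candidates number of unique candidates to generate
#' @param ranges for Fourier mode a list with `frequency`, `orientation`,
#'   `phase` ranges (each c(min, max)); ignored for morphology mode
#' @param seed RNG seed
#' @return list of label specs
#' @export
generate_candidates <- function(mode = c("fourier", "morphology"),
                                n_candidates,
                                ranges = list(frequency = c(1, 8),
                                              orientation = c(0, pi),
                                              phase = c(0, 2 * pi)),
                                seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  out <- list(); seen <- character(0)
  max_tries <- 200L * n_candidates
  tries <- 0L
  while (length(out) < n_candidates && tries < max_tries) {
    tries <- tries + 1L
    spec <- if (mode == "fourier") {
      fourier_label(stats::runif(1, ranges$frequency[1], ranges$frequency[2]),
                    stats::runif(1, ranges$orientation[1], min(ranges$orientation[2], pi - 1e-9)),
                    stats::runif(1, ranges$phase[1], min(ranges$phase[2], 2 * pi - 1e-9)))
    } else {
      len <- sample(1:3, 1L)
      steps <- lapply(seq_len(len), function(i) {
        op <- sample(morph_ops, 1L)
        switch(op,
          rotate = list(op = "rotate", quarters = sample(1:3, 1L)),
          shift  = { d <- sample(c(-4:-1, 1:4), 2L, replace = TRUE)
                     list(op = "shift", dx = d[1], dy = d[2]) },
          dilate = list(op = "dilate", r = sample(1:2, 1L)),
          erode  = list(op = "erode", r = sample(1:2, 1L)),
          list(op = op))
      })
      morphology_label(steps)
    }
    key <- format(spec)
    if (!(key %in% seen)) { seen <- c(seen, key); out[[length(out) + 1L]] <- spec }
  }
  if (length(out) < n_candidates)
    stop_ffcnn("parameter ranges too small to yield the requested number of unique candidates",
               "ffcnn_capability_error")
  out
}

#' Greedy min-max-correlation subset selection
#'
#' Builds a label bank of `n_select` specs whose maximal internal absolute
#' Pearson correlation is (greedily) minimized: start from the candidate
#' pair with the lowest |correlation|, then repeatedly add the candidate
#' minimizing the maximum |correlation| against the already-selected set.
#' Ties are broken toward the lower candidate index.
#'
#' @param candidates list of label specs (one mode)
#' @param n_select number of specs to select
#' @param probe probe shape (Fourier) or probe image (morphology), as in
#'   [pairwise_correlation]
#' @return a [label_bank] with attributes `achieved` (the maximal internal
#'   |correlation| of the selection) and `selected` (candidate indices)
#' @export
select_diverse_subset <- function(candidates, n_select, probe) {
  stopifnot(n_select >= 2, n_select <= length(candidates))
  C <- abs(pairwise_correlation(candidates, probe))
  n <- nrow(C)
  # seed pair: lowest |correlation|, scanning i < j in index order
  best <- c(1L, 2L); bestv <- Inf
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (C[i, j] < bestv) { bestv <- C[i, j]; best <- c(i, j) }
  sel <- best
  while (length(sel) < n_select) {
    rest <- setdiff(seq_len(n), sel)
    worst <- vapply(rest, function(cnd) max(C[cnd, sel]), numeric(1))
    sel <- c(sel, rest[which.min(worst)])   # which.min takes the first = lowest index
  }
  sel <- sort(sel)
  achieved <- if (length(sel) >= 2) max(C[sel, sel][upper.tri(diag(length(sel)))]) else 0
  bank <- label_bank(candidates[sel])
  attr(bank, "achieved") <- achieved
  attr(bank, "selected") <- sel
  bank
}

# ---- sidecar serialization -------------------------------------------------

#' Write a label bank to a plain-text sidecar file
#'
#' One line per class: `mode<TAB>class_id<TAB>spec`, where spec is
#' `f orientation phase` for Fourier labels and the step program string for
#' morphology labels.
#'
#' @param bank a [label_bank]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_label_bank <- function(bank, path) {
  lines <- vapply(seq_along(bank$specs), function(i) {
    s <- bank$specs[[i]]
    if (bank$mode == "fourier")
      sprintf("fourier\t%d\t%.17g %.17g %.17g", i - 1L, s$frequency, s$orientation, s$phase)
    else
      sprintf("morphology\t%d\t%s", i - 1L, format(s))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

parse_morph_program <- function(txt) {
  steps <- lapply(strsplit(txt, "|", fixed = TRUE)[[1]], function(tok) {
    if (grepl("^rotate\\(", tok))
      list(op = "rotate", quarters = as.integer(sub("rotate\\((\\d+)\\)", "\\1", tok)))
    else if (grepl("^shift\\(", tok)) {
      v <- as.integer(strsplit(sub("shift\\(([^)]*)\\)", "\\1", tok), ",")[[1]])
      list(op = "shift", dx = v[1], dy = v[2])
    } else if (grepl("^dilate\\(", tok))
      list(op = "dilate", r = as.integer(sub("dilate\\((\\d+)\\)", "\\1", tok)))
    else if (grepl("^erode\\(", tok))
      list(op = "erode", r = as.integer(sub("erode\\((\\d+)\\)", "\\1", tok)))
    else list(op = tok)
  })
  morphology_label(steps)
}

#' Read a label bank from its sidecar file
#'
#' @param path file written by [write_label_bank]
#' @return a [label_bank]
#' @export
read_label_bank <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mode <- parts[[1]][1]
  specs <- lapply(parts, function(p) {
    if (p[1] == "fourier") {
      v <- as.numeric(strsplit(p[3], " ", fixed = TRUE)[[1]])
      fourier_label(v[1], v[2], v[3])
    } else parse_morph_program(p[3])
  })
  label_bank(specs, mode)
}

#' Neutral label component for linear-head inference
#'
#' When classifying through the linear head no class may be hinted at by the
#' embedded label. In Fourier mode the neutral component is the pixel-wise
#' mean of all M rendered patterns; in morphology mode it is the
#' untransformed image itself (program identity), so the blend leaves the
#' image unchanged up to renormalization.
#'
#' @param bank a [label_bank]
#' @param image the image the component is for (used for shape, and as the
#'   component itself in morphology mode)
#' @return an array/matrix of the image's spatial shape
#' @export
neutral_label_component <- function(bank, image) {
  d <- dim(image)
  if (bank$mode == "fourier") {
    pats <- lapply(bank$specs, render_fourier, height = d[1], width = d[2])
    Reduce(`+`, pats) / length(pats)
  } else {
    image
  }
}
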
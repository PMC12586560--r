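# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Numerically stable binary cross-entropy from a logit
#'
#' Computes -log(sigmoid(s)) = softplus(-s) without overflow for large |s|.
#' @param s numeric logit(s)
#' @return numeric of the same length
#' @keywords internal
bce_from_logit <- function(s) {
  out <- numeric(length(s))
  pos <- s > 0
  out[pos] <- log1p(exp(-s[pos]))
  out[!pos] <- -s[!pos] + log1p(exp(s[!pos]))
  out
}

# Per-image min-max rescaling to [0,1]; a constant image maps to all zeros.
minmax01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(x) %||% length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Derive a per-purpose seed from a single run seed
#'
#' A single run seed fans out deterministically to the independent random
#' streams the package uses (synthetic data, weight init, per-epoch negative
#' resampling, ...). The rule is `(seed * 1009 + 97 * offset) mod (2^31 - 1)`,
#' which keeps derived seeds inside the 32-bit integer range.
#'
#' @param seed integer master seed
#' @param offset integer stream offset (each purpose has a fixed documented
#'   offset)
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(offset)) %% 2147483647)
}

stop_ffcnn <- function(msg, class) {
  stop(structure(class = c(class, "ffcnn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
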
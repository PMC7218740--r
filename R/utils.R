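# Internal validation and padding helpers shared across modules.

stop_pyrfuse <- function(msg, class) {
  stop(structure(class = c(class, "pyrfuse_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_gray <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    stop_pyrfuse(sprintf("`%s` must be a numeric matrix (2-D grayscale image)", arg),
                 "pyrfuse_validation_error")
  if (!all(is.finite(img)))
    stop_pyrfuse(sprintf("`%s` contains non-finite values", arg),
                 "pyrfuse_validation_error")
  invisible(img)
}

check_same_shape <- function(a, b, what = c("a", "b")) {
  if (!identical(dim(a), dim(b)))
    stop_pyrfuse(sprintf("`%s` (%s) and `%s` (%s) must have identical dimensions",
                         what[1], paste(dim(a), collapse = "x"),
                         what[2], paste(dim(b), collapse = "x")),
                 "pyrfuse_validation_error")
  invisible(NULL)
}

# Reflection (symmetric about the edge pixel, no edge repeat) index map:
# positions 1..n extended to 1-pad .. n+pad.  Requires n > pad.
reflect_idx <- function(n, pad) {
  p <- seq(1 - pad, n + pad)
  p <- ifelse(p < 1, 2 - p, p)
  ifelse(p > n, 2 * n - p, p)
}

# Pad a matrix by `pad` pixels on every side with reflection.
reflect_pad <- function(x, pad) {
  x[reflect_idx(nrow(x), pad), reflect_idx(ncol(x), pad), drop = FALSE]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
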
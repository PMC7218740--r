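#' Build the 5-tap pyramid smoothing kernel
#'
#' Constructs the separable low-pass window used by the Gaussian and contrast
#' pyramids from its center weight.  The five taps \eqn{w(-2),\dots,w(2)} are
#' the unique solution of the four classical constraints: separability of the
#' 2-D window, normalization (taps sum to 1), symmetry, and equal contribution
#' of odd and even taps (\eqn{w(-2)+w(0)+w(2) = w(-1)+w(1)}).  These force
#' \eqn{w(\pm 1) = 1/4} and \eqn{w(\pm 2) = (1/2 - w(0))/2}, so the kernel is
#' parameterized by the center weight alone; the conventional choice
#' \eqn{w(0) = 3/8} yields the binomial-like kernel
#' \code{(1/16, 1/4, 3/8, 1/4, 1/16)}.
#'
#' @param center_weight Center tap \eqn{w(0)}, in \eqn{(0, 1/2]}.  The default
#'   3/8 gives the standard Gaussian-like window; 1/2 degenerates to a 3-tap
#'   triangle kernel.
#' @return A numeric vector of length 5 (class \code{"pyr_kernel"}) holding
#'   \eqn{w(-2),\dots,w(2)}.
#' @examples
#' build_kernel()            # 1/16 1/4 3/8 1/4 1/16
#' build_kernel(1/2)         # 0 1/4 1/2 1/4 0
#' @export
build_kernel <- function(center_weight = 3 / 8) {
  if (!is.numeric(center_weight) || length(center_weight) != 1L ||
      !is.finite(center_weight) || center_weight <= 0 || center_weight > 1 / 2)
    stop_pyrfuse("`center_weight` must be a scalar in (0, 1/2]: outside this range w(+/-2) would be negative or the kernel degenerate",
                 "pyrfuse_parameter_error")
  w2 <- (1 / 2 - center_weight) / 2
  taps <- c(w2, 1 / 4, center_weight, 1 / 4, w2)
  names(taps) <- c("-2", "-1", "0", "1", "2")
  structure(taps, class = "pyr_kernel")
}

#' 2-D window from a 5-tap kernel
#'
#' Outer product \eqn{w(m, n) = w(m) w(n)} of the separable kernel with
#' itself; a 5x5 matrix summing to 1.
#'
#' @param k A kernel from [build_kernel()].
#' @return A 5x5 numeric matrix.
#' @export
kernel_2d <- function(k = build_kernel()) {
  k <- as_kernel(k)
  outer(as.numeric(k), as.numeric(k))
}

as_kernel <- function(k) {
  if (inherits(k, "pyr_kernel")) return(k)
  if (is.numeric(k) && length(k) == 5L) return(structure(as.numeric(k), class = "pyr_kernel"))
  stop_pyrfuse("`kernel` must be a 5-tap kernel from build_kernel()",
               "pyrfuse_parameter_error")
}

#' @export
print.pyr_kernel <- function(x, ...) {
  cat("5-tap pyramid kernel (w(-2)..w(2)):", format(unclass(x)), "\n")
  invisible(x)
}
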
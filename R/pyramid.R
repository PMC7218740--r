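# Gaussian and contrast pyramids.
#
# REDUCE low-pass filters with the separable 5-tap window and keeps every
# other row/column (ceil-halving, so odd sizes round up).  EXPAND is the
# adjoint interpolation: zero-insertion upsampling followed by the same
# window with a gain of 4 (2 per axis), written here as an explicit sparse
# interpolation matrix per axis so any target size in {2d-1, 2d} is exact.
# Borders use reflection about the edge pixel in both directions.
#
# The contrast pyramid stores local luminance contrast
#   C_l = G_l / EXPAND(G_{l+1}) - 1,   C_N = G_N,
# and is exactly invertible by G_l = (C_l + 1) * EXPAND(G_{l+1}).  Because
# medical images routinely contain zero backgrounds, inputs are shifted by a
# small positive offset before the ratio is formed and shifted back after
# reconstruction; denominators additionally carry an epsilon guard.  The
# same guarded denominator is used in both directions, so the round trip is
# exact to floating-point precision.

max_pyramid_depth <- function(dim, min_size = 4L) {
  d <- as.integer(dim)
  n <- 0L
  while (all(ceiling(d / 2) >= min_size)) {
    d <- ceiling(d / 2)
    n <- n + 1L
  }
  n
}

#' Reduce an image one pyramid level
#'
#' Convolves with the separable 2-D window (reflected at borders) and
#' downsamples by keeping every other row and column.  An \eqn{H \times W}
#' image becomes \eqn{\lceil H/2\rceil \times \lceil W/2\rceil}.
#'
#' @param img Numeric matrix, at least 4x4.
#' @param kernel 5-tap kernel from [build_kernel()].
#' @return The reduced matrix.
#' @export
pyr_reduce <- function(img, kernel = build_kernel()) {
  check_gray(img)
  k <- as.numeric(as_kernel(kernel))
  H <- nrow(img); W <- ncol(img)
  if (H < 4L || W < 4L)
    stop_pyrfuse(sprintf("image (%dx%d) is too small to reduce; both dimensions must be >= 4", H, W),
                 "pyrfuse_depth_error")
  p <- reflect_pad(img, 2L)
  rows <- seq(1L, H, by = 2L)
  tmp <- 0
  for (m in -2:2) tmp <- tmp + k[m + 3L] * p[rows + m + 2L, , drop = FALSE]
  cols <- seq(1L, W, by = 2L)
  out <- 0
  for (n in -2:2) out <- out + k[n + 3L] * tmp[, cols + n + 2L, drop = FALSE]
  out
}

# Interpolation matrix mapping a length-h axis to length-H (H in {2h-1, 2h}).
# Row i (0-based) of the output draws from source samples (i+m)/2 for the
# kernel taps m with (i+m) even, reflected at the ends; the factor 2 per
# axis gives the overall EXPAND gain of 4.
expand_matrix <- function(h, H, k) {
  E <- matrix(0, H, h)
  for (i in 0:(H - 1L)) {
    if (i %% 2L == 0L) {
      ss <- c(i / 2 - 1, i / 2, i / 2 + 1); ww <- k[c(1L, 3L, 5L)]
    } else {
      ss <- c((i - 1) / 2, (i + 1) / 2); ww <- k[c(2L, 4L)]
    }
    ss <- ifelse(ss < 0, -ss, ss)
    ss <- ifelse(ss > h - 1, 2 * (h - 1) - ss, ss)
    for (t in seq_along(ss))
      E[i + 1L, ss[t] + 1L] <- E[i + 1L, ss[t] + 1L] + 2 * ww[t]
  }
  E
}

#' Expand an image one pyramid level
#'
#' Interpolates an image up to an explicit target shape (each target
#' dimension must be twice the source dimension or one less, so that odd
#' sizes round-trip exactly with [pyr_reduce()]).  Zero-inserted samples are
#' filtered with the 2-D window at a gain of 4.
#'
#' @param img Numeric matrix.
#' @param target_dim Integer vector \code{c(rows, cols)} of the output.
#' @inheritParams pyr_reduce
#' @return Matrix of dimension \code{target_dim}.
#' @export
pyr_expand <- function(img, target_dim, kernel = build_kernel()) {
  check_gray(img)
  k <- as.numeric(as_kernel(kernel))
  h <- nrow(img); w <- ncol(img)
  target_dim <- as.integer(target_dim)
  if (length(target_dim) != 2L ||
      !(target_dim[1] %in% c(2L * h, 2L * h - 1L)) ||
      !(target_dim[2] %in% c(2L * w, 2L * w - 1L)))
    stop_pyrfuse(sprintf("target shape %s is incompatible with a %dx%d source: each target dimension must be 2d or 2d-1",
                         paste(target_dim, collapse = "x"), h, w),
                 "pyrfuse_shape_error")
  Er <- expand_matrix(h, target_dim[1], k)
  Ec <- expand_matrix(w, target_dim[2], k)
  Er %*% img %*% t(Ec)
}

#' Gaussian pyramid
#'
#' Successive [pyr_reduce()] levels; level 1 of the returned list is the
#' source image (level 0 of the pyramid), level \code{depth + 1} the
#' coarsest.
#'
#' @param img Numeric matrix.
#' @param depth Number of reductions \eqn{N \ge 0}.
#' @inheritParams pyr_reduce
#' @return Object of class \code{"gaussian_pyramid"}: list of matrices.
#' @export
gaussian_pyramid <- function(img, depth = 4L, kernel = build_kernel()) {
  check_gray(img)
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 0L)
    stop_pyrfuse("`depth` must be a non-negative integer", "pyrfuse_parameter_error")
  maxd <- max_pyramid_depth(dim(img))
  if (depth > maxd)
    stop_pyrfuse(sprintf("depth %d is too deep for a %s image; the maximum feasible depth (coarsest level >= 4x4) is %d",
                         depth, paste(dim(img), collapse = "x"), maxd),
                 "pyrfuse_depth_error")
  levels <- vector("list", depth + 1L)
  levels[[1L]] <- img
  if (depth > 0L)
    for (l in seq_len(depth)) levels[[l + 1L]] <- pyr_reduce(levels[[l]], kernel)
  structure(list(levels = levels, depth = depth), class = "gaussian_pyramid")
}

#' Contrast-pyramid decomposition
#'
#' Decomposes an image into \code{depth} contrast levels plus the coarsest
#' Gaussian level.  Level \eqn{l} holds
#' \eqn{C_l = G_l / \mathrm{EXPAND}(G_{l+1}) - 1} (values may be negative);
#' the top is \eqn{C_N = G_N}.  The input is shifted by \code{offset} before
#' the ratio so that zero backgrounds stay well away from the singular
#' denominator; [contrast_reconstruct()] undoes the shift.
#'
#' @inheritParams gaussian_pyramid
#' @param offset Positive shift applied to the image before decomposition
#'   (default 0.01 for images in \eqn{[0,1]}).
#' @param eps Guard added to denominators (default 1e-12).
#' @return Object of class \code{"contrast_pyramid"} with fields
#'   \code{levels} (list of \code{depth} contrast matrices), \code{top}
#'   (coarsest Gaussian level), \code{depth}, \code{offset}, \code{eps}.
#' @examples
#' img <- matrix(runif(64 * 64), 64)
#' cp <- contrast_decompose(img, depth = 3)
#' max(abs(contrast_reconstruct(cp) - img))  # ~1e-16
#' @export
contrast_decompose <- function(img, depth = 4L, kernel = build_kernel(),
                               offset = 1e-2, eps = 1e-12) {
  check_gray(img)
  kernel <- as_kernel(kernel)
  g <- gaussian_pyramid(img + offset, depth, kernel)
  depth <- g$depth
  levels <- vector("list", depth)
  for (l in seq_len(depth)) {
    e <- pyr_expand(g$levels[[l + 1L]], dim(g$levels[[l]]), kernel)
    levels[[l]] <- g$levels[[l]] / (e + eps) - 1
  }
  structure(list(levels = levels, top = g$levels[[depth + 1L]], depth = depth,
                 offset = offset, eps = eps),
            class = "contrast_pyramid")
}

#' Reconstruct an image from a contrast pyramid
#'
#' Exact inverse of [contrast_decompose()]:
#' \eqn{G_N = C_N}; \eqn{G_l = (C_l + 1) \odot \mathrm{EXPAND}(G_{l+1})}
#' for \eqn{l = N-1, \dots, 0}, followed by removal of the decomposition
#' offset.
#'
#' @param cp A \code{"contrast_pyramid"}.
#' @inheritParams pyr_reduce
#' @return The reconstructed matrix (dimensions of the original image).
#' @export
contrast_reconstruct <- function(cp, kernel = build_kernel()) {
  if (!inherits(cp, "contrast_pyramid"))
    stop_pyrfuse("`cp` must be a contrast_pyramid", "pyrfuse_parameter_error")
  kernel <- as_kernel(kernel)
  g <- cp$top
  if (cp$depth > 0L)
    for (l in rev(seq_len(cp$depth))) {
      cl <- cp$levels[[l]]
      e <- pyr_expand(g, dim(cl), kernel)
      g <- (cl + 1) * (e + cp$eps)
    }
  g - cp$offset
}

#' @export
print.gaussian_pyramid <- function(x, ...) {
  cat("Gaussian pyramid, depth", x$depth, "- level sizes:",
      paste(vapply(x$levels, function(l) paste(dim(l), collapse = "x"), ""),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.contrast_pyramid <- function(x, ...) {
  cat("Contrast pyramid, depth", x$depth, "- level sizes:",
      paste(c(vapply(x$levels, function(l) paste(dim(l), collapse = "x"), ""),
              paste(dim(x$top), collapse = "x")), collapse = ", "),
      "(top is Gaussian)\n")
  invisible(x)
}
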
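# Region-energy / similarity fusion of corresponding pyramid levels.
#
# For each pixel of a level, a local window gives the two region energies
# E_A, E_B (sums of squared coefficients) and the normalized match measure
# M = 2*sum(CA*CB) / (E_A + E_B) in [-1, 1].  Below the similarity
# threshold the regions are considered distinct and the higher-energy
# source's coefficient is selected (choose-max); at or above it the regions
# are redundant and a weighted mean is used with the CNN weight map
# deciding the split: W_min = GW, W_max = 1 - GW, with W_max on the
# higher-energy source.  With the default T1 = 3 the bounded M can never
# reach the threshold, so every level but the top reduces to choose-max;
# the top (coarse Gaussian) level uses T2 = 0.6.

#' Fusion configuration
#'
#' @param depth Pyramid depth N (auto-capped so the coarsest level is at
#'   least \code{min_top} pixels per side).
#' @param T1 Similarity threshold for levels \eqn{0 \le l < N} (default 3:
#'   since \eqn{M \le 1}, lower levels always use choose-max).
#' @param T2 Similarity threshold for the top level (default 0.6).
#' @param window Odd side length of the local region (default 3).
#' @param center_weight Pyramid kernel center tap (default 3/8).
#' @param offset,eps Contrast-pyramid guards (see [contrast_decompose()]).
#' @param min_top Minimum coarsest-level side when capping \code{depth}.
#' @param similarity \code{"sum"} for the bounded match measure
#'   (denominator \eqn{E_A + E_B}); \code{"product"} keeps the literal
#'   \eqn{E_A E_B} denominator for comparison.
#' @return A list of class \code{"fusion_config"}.
#' @export
fusion_config <- function(depth = 4L, T1 = 3, T2 = 0.6, window = 3L,
                          center_weight = 3 / 8, offset = 1e-2, eps = 1e-12,
                          min_top = 8L, similarity = c("sum", "product")) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop_pyrfuse("`window` must be odd and >= 1", "pyrfuse_parameter_error")
  if (!is.finite(T1) || !is.finite(T2))
    stop_pyrfuse("thresholds must be finite", "pyrfuse_parameter_error")
  if (as.integer(depth) < 1L)
    stop_pyrfuse("`depth` must be >= 1", "pyrfuse_parameter_error")
  structure(list(depth = as.integer(depth), T1 = T1, T2 = T2, window = window,
                 center_weight = center_weight, offset = offset, eps = eps,
                 min_top = as.integer(min_top),
                 similarity = match.arg(similarity)),
            class = "fusion_config")
}

# Windowed sum with reflected borders (odd window).
window_sum <- function(x, window) {
  r <- (window - 1L) %/% 2L
  if (r == 0L) return(x)
  p <- reflect_pad(x, r)
  H <- nrow(x); W <- ncol(x)
  tmp <- 0
  for (m in -r:r) tmp <- tmp + p[seq_len(H) + r + m, , drop = FALSE]
  out <- 0
  for (n in -r:r) out <- out + tmp[, seq_len(W) + r + n, drop = FALSE]
  out
}

#' Local region energy
#'
#' \eqn{E(x, y) = \sum_{m,n} C(x+m, y+n)^2} over an odd window centered at
#' each pixel, with reflected borders.
#'
#' @param level Numeric matrix (a pyramid level).
#' @param window Odd window side (default 3).
#' @return Non-negative matrix of the same size.
#' @export
local_energy <- function(level, window = 3L) {
  check_gray(level, "level")
  window_sum(level^2, window)
}

#' Local similarity of two levels
#'
#' The normalized match measure
#' \eqn{M(x,y) = 2 \sum_{m,n} C_A C_B / (E_A + E_B)}, bounded in
#' \eqn{[-1, 1]}, with the all-zero-window case defined as 0.  The literal
#' product-denominator variant (\eqn{2\sum C_A C_B / (E_A E_B)}, unbounded)
#' is available for comparison via \code{form = "product"}.
#'
#' @param ca,cb Same-size numeric matrices.
#' @param window Odd window side (default 3).
#' @param form Denominator form, \code{"sum"} (default, bounded) or
#'   \code{"product"}.
#' @return Matrix of similarities (in \eqn{[-1,1]} for \code{form = "sum"}).
#' @export
local_similarity <- function(ca, cb, window = 3L, form = c("sum", "product")) {
  check_gray(ca, "ca"); check_gray(cb, "cb")
  check_same_shape(ca, cb, c("ca", "cb"))
  form <- match.arg(form)
  num <- 2 * window_sum(ca * cb, window)
  ea <- local_energy(ca, window)
  eb <- local_energy(cb, window)
  den <- if (form == "sum") ea + eb else ea * eb
  out <- matrix(0, nrow(ca), ncol(ca))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

#' Fuse one pyramid level
#'
#' Applies the thresholded rule per pixel: where the local similarity is
#' below \code{threshold}, the coefficient of the higher-energy source is
#' selected (ties go to \code{ca}); elsewhere the weighted mean
#' \eqn{W_{max} C_{larger} + W_{min} C_{smaller}} is used with
#' \eqn{W_{min} = GW} and \eqn{W_{max} = 1 - GW}.
#'
#' @param ca,cb Same-size coefficient matrices of the two sources.
#' @param gw Weight-map level, same size, values in \eqn{[0,1]}.
#' @param threshold Similarity threshold T for this level.
#' @param window Odd window side (default 3).
#' @param similarity Match-measure form passed to [local_similarity()].
#' @return Fused coefficient matrix.
#' @export
fuse_level <- function(ca, cb, gw, threshold, window = 3L,
                       similarity = c("sum", "product")) {
  check_gray(ca, "ca"); check_gray(cb, "cb"); check_gray(gw, "gw")
  check_same_shape(ca, cb, c("ca", "cb"))
  check_same_shape(ca, gw, c("ca", "gw"))
  if (any(gw < 0 | gw > 1))
    stop_pyrfuse("`gw` values must lie in [0, 1]", "pyrfuse_validation_error")
  ea <- local_energy(ca, window)
  eb <- local_energy(cb, window)
  m <- local_similarity(ca, cb, window, form = match.arg(similarity))
  a_larger <- ea >= eb
  wmin <- gw
  wmax <- 1 - gw
  weighted <- ifelse(a_larger, wmax * ca + wmin * cb, wmin * ca + wmax * cb)
  chosen <- ifelse(a_larger, ca, cb)
  ifelse(m < threshold, chosen, weighted)
}

#' Fuse two co-registered grayscale images
#'
#' Full pipeline: the Siamese net produces the weight map W; W is
#' decomposed by a Gaussian pyramid and each source by a contrast pyramid;
#' corresponding levels are fused with [fuse_level()] (threshold T1 below
#' the top, T2 at the top); the fused pyramid is reconstructed and clipped
#' to \eqn{[0,1]}.
#'
#' @param a,b Co-registered numeric matrices in \eqn{[0,1]}, same size, at
#'   least 16x16.
#' @param net A trained [siamese_net()].
#' @param config A [fusion_config()].
#' @return List of class \code{"pyrfuse_result"}: \code{fused} (the image),
#'   \code{weight_map}, and \code{depth} actually used.
#' @export
fuse_images <- function(a, b, net, config = fusion_config()) {
  check_gray(a, "a"); check_gray(b, "b")
  check_same_shape(a, b)
  if (!inherits(config, "fusion_config"))
    stop_pyrfuse("`config` must come from fusion_config()", "pyrfuse_parameter_error")
  k <- build_kernel(config$center_weight)
  depth <- min(config$depth, max_pyramid_depth(dim(a), config$min_top))
  if (depth < 1L)
    stop_pyrfuse("image too small for a 1-level pyramid with the configured top size",
                 "pyrfuse_depth_error")
  w <- weight_map(net, a, b)
  gw <- gaussian_pyramid(w, depth, k)
  ca <- contrast_decompose(a, depth, k, offset = config$offset, eps = config$eps)
  cb <- contrast_decompose(b, depth, k, offset = config$offset, eps = config$eps)
  fused_levels <- vector("list", depth)
  for (l in seq_len(depth))
    fused_levels[[l]] <- fuse_level(ca$levels[[l]], cb$levels[[l]],
                                    gw$levels[[l]], config$T1, config$window,
                                    config$similarity)
  fused_top <- fuse_level(ca$top, cb$top, gw$levels[[depth + 1L]],
                          config$T2, config$window, config$similarity)
  cf <- structure(list(levels = fused_levels, top = fused_top, depth = depth,
                       offset = config$offset, eps = config$eps),
                  class = "contrast_pyramid")
  fused <- clip01(contrast_reconstruct(cf, k))
  structure(list(fused = fused, weight_map = w, depth = depth,
                 config = config),
            class = "pyrfuse_result")
}

#' @export
print.pyrfuse_result <- function(x, ...) {
  cat(sprintf("Fused image %s (pyramid depth %d, T1 = %g, T2 = %g); mean weight %.3f\n",
              paste(dim(x$fused), collapse = "x"), x$depth, x$config$T1,
              x$config$T2, mean(x$weight_map)))
  invisible(x)
}
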
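# Objective fusion-quality metrics.
#
# All four operate on a source pair (a, b) and fused image f in [0,1]:
#   q_te  - Tsallis-entropy fusion index (generalized mutual information of
#           order q between each source and f, normalized by the sources'
#           Tsallis entropies); the raw Tsallis entropy of f is also exposed.
#   q_abf - Xydeas-Petrovic gradient-based edge-preservation index in [0,1].
#   q_mi  - mutual information MI(a,f) + MI(b,f) in bits.
#   q_vif - pixel-domain multi-scale visual-information-fidelity ratio
#           under the Gaussian-channel model, averaged over the two sources.
# Intensity histograms use 256 fixed bins.  All metrics are deterministic.

quantize256 <- function(x) {
  q <- floor(pmin(pmax(x, 0), 1) * 256)
  as.integer(pmin(q, 255))
}

hist256 <- function(x) tabulate(quantize256(x) + 1L, 256L) / length(x)

joint256 <- function(x, y) {
  tabulate(quantize256(x) * 256L + quantize256(y) + 1L, 65536L) / length(x)
}

shannon_mi <- function(x, y) {
  # joint256 cell index = qx*256 + qy + 1, so qy varies fastest: reshape
  # with y along rows.
  pm <- matrix(joint256(x, y), nrow = 256L)   # [qy+1, qx+1]
  op <- outer(hist256(y), hist256(x))
  nz <- pm > 0
  sum(pm[nz] * log2(pm[nz] / op[nz]))
}

tsallis_h <- function(p, q) {
  p <- p[p > 0]
  (1 - sum(p^q)) / (q - 1)
}

tsallis_mi <- function(x, y, q) {
  pm <- matrix(joint256(x, y), nrow = 256L)   # [qy+1, qx+1]
  op <- outer(hist256(y), hist256(x))
  nz <- pm > 0 & op > 0
  (1 - sum(pm[nz]^q * op[nz]^(1 - q))) / (1 - q)
}

#' Tsallis-entropy fusion index
#'
#' Default (\code{type = "index"}): the normalized order-\code{q}
#' generalized mutual information between each source and the fused image,
#' summed over the two sources.  With
#' \eqn{I_q(X;Y) = \frac{1}{1-q}\big(1 - \sum p(x,y)^q (p(x)p(y))^{1-q}\big)}
#' from 256-bin joint histograms, each term is
#' \eqn{I_q(X;F) / \sqrt{I_q(X;X)\, I_q(F;F)}} — a Tsallis analogue of a
#' correlation coefficient.  The index is symmetric in \code{(a, b)},
#' exactly 2 when \code{f} copies both sources, and near 0 when \code{f} is
#' independent of them.  \code{type = "entropy"} instead returns the raw
#' Tsallis entropy \eqn{H_q(F) = (1-\sum p^q)/(q-1)} of \code{f}.
#'
#' @param a,b,f Same-size matrices in \eqn{[0,1]}.
#' @param q Entropic order (default 1.85; must not be 1).
#' @param type \code{"index"} (default) or \code{"entropy"}.
#' @return Scalar; 0 with a warning when an image is constant.
#' @export
q_te <- function(a, b, f, q = 1.85, type = c("index", "entropy")) {
  check_gray(a, "a"); check_gray(b, "b"); check_gray(f, "f")
  check_same_shape(a, f, c("a", "f")); check_same_shape(b, f, c("b", "f"))
  if (q == 1) stop_pyrfuse("`q` must differ from 1", "pyrfuse_parameter_error")
  type <- match.arg(type)
  if (type == "entropy") return(tsallis_h(hist256(f), q))
  self_f <- tsallis_mi(f, f, q)
  term <- function(x) {
    self_x <- tsallis_mi(x, x, q)
    if (self_x <= 0 || self_f <= 0) {
      warning("constant image: Tsallis index term undefined, contributing 0")
      return(0)
    }
    tsallis_mi(x, f, q) / sqrt(self_x * self_f)
  }
  term(a) + term(b)
}

#' Mutual-information fusion metric
#'
#' \eqn{Q_{MI} = MI(a, f) + MI(b, f)} in bits, from 256-bin joint
#' histograms.  A constant image contributes 0.
#'
#' @inheritParams q_te
#' @return Non-negative scalar.
#' @export
q_mi <- function(a, b, f) {
  check_gray(a, "a"); check_gray(b, "b"); check_gray(f, "f")
  check_same_shape(a, f, c("a", "f")); check_same_shape(b, f, c("b", "f"))
  shannon_mi(a, f) + shannon_mi(b, f)
}

sobel_grad <- function(x) {
  p <- reflect_pad(x, 1L)
  H <- nrow(x); W <- ncol(x)
  i <- seq_len(H) + 1L; j <- seq_len(W) + 1L
  sx <- (p[i - 1L, j + 1L] + 2 * p[i, j + 1L] + p[i + 1L, j + 1L]) -
        (p[i - 1L, j - 1L] + 2 * p[i, j - 1L] + p[i + 1L, j - 1L])
  sy <- (p[i + 1L, j - 1L] + 2 * p[i + 1L, j] + p[i + 1L, j + 1L]) -
        (p[i - 1L, j - 1L] + 2 * p[i - 1L, j] + p[i - 1L, j + 1L])
  list(g = sqrt(sx^2 + sy^2), alpha = atan2(sy, sx))
}

abf_preservation <- function(gx, ax, gf, af,
                             gamma_g = 0.9994, kappa_g = -15, sigma_g = 0.5,
                             gamma_a = 0.9879, kappa_a = -22, sigma_a = 0.8) {
  gmax <- pmax(gx, gf)
  G <- ifelse(gmax > 0, pmin(gx, gf) / pmax(gmax, .Machine$double.xmin), 0)
  d <- abs(ax - af)
  d <- pmin(d, 2 * pi - d)
  d <- pmin(d, pi - d)                 # opposite directions = same edge
  A <- 1 - d / (pi / 2)
  qg <- gamma_g / (1 + exp(kappa_g * (G - sigma_g)))
  qa <- gamma_a / (1 + exp(kappa_a * (A - sigma_a)))
  norm <- (gamma_g / (1 + exp(kappa_g * (1 - sigma_g)))) *
          (gamma_a / (1 + exp(kappa_a * (1 - sigma_a))))
  pmin(qg * qa / norm, 1)
}

#' Gradient-based edge-preservation metric (QAB/F)
#'
#' Xydeas-Petrovic index: per pixel, Sobel gradient strength and
#' orientation of each source are compared with the fused image; relative
#' strength and orientation agreement are passed through sigmoids and the
#' resulting preservation factors are averaged with the source edge
#' strengths as weights.  The sigmoids (constants
#' \eqn{\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5;
#' \Gamma_\alpha = 0.9879, \kappa_\alpha = -22, \sigma_\alpha = 0.8}) are
#' normalized by their value at perfect preservation so that
#' \code{q_abf(a, b, a)} with \code{b = a} equals 1.
#'
#' @inheritParams q_te
#' @return Scalar in \eqn{[0, 1]}; 0 with a warning for flat images.
#' @export
q_abf <- function(a, b, f) {
  check_gray(a, "a"); check_gray(b, "b"); check_gray(f, "f")
  check_same_shape(a, f, c("a", "f")); check_same_shape(b, f, c("b", "f"))
  ga <- sobel_grad(a); gb <- sobel_grad(b); gf <- sobel_grad(f)
  qaf <- abf_preservation(ga$g, ga$alpha, gf$g, gf$alpha)
  qbf <- abf_preservation(gb$g, gb$alpha, gf$g, gf$alpha)
  wa <- ga$g; wb <- gb$g
  den <- sum(wa + wb)
  if (den == 0) {
    warning("flat source images: edge-preservation undefined, returning 0")
    return(0)
  }
  sum(qaf * wa + qbf * wb) / den
}

valid_sep_filter <- function(x, g) {
  r <- length(g)
  H <- nrow(x) - r + 1L; W <- ncol(x) - r + 1L
  tmp <- 0
  for (m in seq_len(r)) tmp <- tmp + g[m] * x[seq_len(H) + m - 1L, , drop = FALSE]
  out <- 0
  for (n in seq_len(r)) out <- out + g[n] * tmp[, seq_len(W) + n - 1L, drop = FALSE]
  out
}

# Pixel-domain VIF between a reference and a distorted image on the 0-255
# scale, Gaussian channel noise variance sigma_nsq; scales that no longer
# fit the image are skipped.
vifp_pair <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    g <- exp(-((seq_len(N) - (N + 1) / 2)^2) / (2 * (N / 5)^2))
    g <- g / sum(g)
    if (scale > 1) {
      if (nrow(ref) < N || ncol(ref) < N) break
      ref <- valid_sep_filter(ref, g)
      dist <- valid_sep_filter(dist, g)
      ref <- ref[seq(1L, nrow(ref), 2L), seq(1L, ncol(ref), 2L), drop = FALSE]
      dist <- dist[seq(1L, nrow(dist), 2L), seq(1L, ncol(dist), 2L), drop = FALSE]
    }
    if (nrow(ref) < N || ncol(ref) < N) break
    mu1 <- valid_sep_filter(ref, g); mu2 <- valid_sep_filter(dist, g)
    s1 <- pmax(valid_sep_filter(ref * ref, g) - mu1^2, 0)
    s2 <- pmax(valid_sep_filter(dist * dist, g) - mu2^2, 0)
    s12 <- valid_sep_filter(ref * dist, g) - mu1 * mu2
    gg <- s12 / (s1 + 1e-10)
    sv <- s2 - gg * s12
    gg[s1 < 1e-10] <- 0; sv[s1 < 1e-10] <- s2[s1 < 1e-10]; s1[s1 < 1e-10] <- 0
    gg[s2 < 1e-10] <- 0; sv[s2 < 1e-10] <- 0
    sv[gg < 0] <- s2[gg < 0]; gg[gg < 0] <- 0
    sv[sv < 1e-10] <- 1e-10
    num <- num + sum(log10(1 + gg^2 * s1 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s1 / sigma_nsq))
  }
  if (den == 0) return(0)
  num / den
}

#' Visual-information-fidelity fusion metric (QVIF)
#'
#' Multi-scale pixel-domain VIF: for each source, the ratio of the
#' information the fused image carries about that source to the source's
#' self-information under a Gaussian-channel model (channel gain and noise
#' estimated from local window statistics; additive noise variance 2 on the
#' 0-255 scale), averaged over the two sources.  Equals 1 when the fused
#' image copies both sources.
#'
#' @inheritParams q_te
#' @return Non-negative scalar.
#' @export
q_vif <- function(a, b, f) {
  check_gray(a, "a"); check_gray(b, "b"); check_gray(f, "f")
  check_same_shape(a, f, c("a", "f")); check_same_shape(b, f, c("b", "f"))
  if (min(dim(a)) < 32L)
    stop_pyrfuse("images must be at least 32 pixels per side for the VIF scale stack",
                 "pyrfuse_validation_error")
  (vifp_pair(a * 255, f * 255) + vifp_pair(b * 255, f * 255)) / 2
}

#' All four fusion metrics at once
#'
#' @inheritParams q_te
#' @return Object of class \code{"fusion_metrics"}: named list with
#'   \code{q_te}, \code{q_abf}, \code{q_mi}, \code{q_vif}.
#' @export
fusion_metrics <- function(a, b, f) {
  structure(list(q_te = q_te(a, b, f), q_abf = q_abf(a, b, f),
                 q_mi = q_mi(a, b, f), q_vif = q_vif(a, b, f)),
            class = "fusion_metrics")
}

#' @export
print.fusion_metrics <- function(x, ...) {
  for (nm in names(x)) cat(sprintf("%s\t%.6f\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.fusion_metrics <- function(x, ...) {
  data.frame(q_te = x$q_te, q_abf = x$q_abf, q_mi = x$q_mi, q_vif = x$q_vif)
}
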
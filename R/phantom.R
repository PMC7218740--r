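# Synthetic fixtures: multimodal-like phantom pairs and clear/blurred
# training corpora.  Phantoms are parametric geometric scenes (rotated
# ellipses and bars) rendered twice with complementary contrast: one
# pseudo-modality emphasizes bone-like rims and sharp boundaries, the other
# soft-tissue-like interiors with smooth shading plus fine speckle.  They
# share geometry (co-registered by construction) but not intensity, which
# is the property the fusion rules are exercised against; no anatomical
# realism is attempted or needed.

#' Generate a co-registered pseudo-multimodal phantom pair
#'
#' @param shape Image size \code{c(rows, cols)}, at least 32x32.
#' @param n_shapes Number of random ellipses/bars in the scene.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed RNG seed; \code{NULL} uses the current RNG state (so callers
#'   building many phantoms stay reproducible from one upstream seed).
#' @return List with matrices \code{a} (rim-weighted modality) and \code{b}
#'   (interior-weighted modality), values in \eqn{[0,1]}.
#' @export
phantom_pair <- function(shape = c(128L, 128L), n_shapes = 6L,
                         noise_sd = 0.02, seed = NULL) {
  shape <- as.integer(shape)
  if (any(shape < 32L))
    stop_pyrfuse("`shape` must be at least 32x32", "pyrfuse_validation_error")
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]
  x <- matrix(rep(seq_len(W), each = H), H, W) / W
  y <- matrix(rep(seq_len(H), times = W), H, W) / H
  a <- matrix(0.05, H, W)
  b <- 0.10 + 0.15 * sqrt((x - 0.5)^2 + (y - 0.5)^2)
  for (s in seq_len(n_shapes)) {
    cx <- runif(1, 0.2, 0.8); cy <- runif(1, 0.2, 0.8)
    ax <- runif(1, 0.06, 0.28); ay <- runif(1, 0.06, 0.28)
    th <- runif(1, 0, pi)
    bar <- runif(1) < 0.3           # occasionally a ribbon instead of an ellipse
    u <- cos(th) * (x - cx) + sin(th) * (y - cy)
    v <- -sin(th) * (x - cx) + cos(th) * (y - cy)
    r <- if (bar) pmax(abs(u) / ax, abs(v) / (0.25 * ay)) else
      sqrt((u / ax)^2 + (v / ay)^2)
    interior <- r <= 1
    rim <- abs(r - 1) < 0.12
    ia <- runif(1, 0.5, 1); ib <- runif(1, 0.35, 0.9)
    a <- a + ia * rim + 0.15 * ib * interior
    b <- b + ib * interior + 0.10 * ia * rim
  }
  # fine speckle detail carried by modality b inside structures only
  b <- b + 0.05 * matrix(rnorm(H * W), H, W) * (b > 0.25)
  a <- a + matrix(rnorm(H * W, sd = noise_sd), H, W)
  b <- b + matrix(rnorm(H * W, sd = noise_sd), H, W)
  list(a = clip01(a), b = clip01(b))
}

#' Iterated Gaussian blur stack
#'
#' Repeatedly applies a Gaussian filter (standard deviation \code{sigma},
#' \code{size} x \code{size} support, reflected borders), feeding each
#' output back in as the next input, producing progressively blurrier
#' versions of the image.
#'
#' @param img Numeric matrix, at least 16x16.
#' @param n_levels Number of blurred versions (default 5).
#' @param sigma Gaussian standard deviation (default 2).
#' @param size Odd filter support (default 7).
#' @return List of \code{n_levels + 1} matrices; element 1 is the input.
#' @export
blur_stack <- function(img, n_levels = 5L, sigma = 2, size = 7L) {
  check_gray(img)
  if (nrow(img) < 16L || ncol(img) < 16L)
    stop_pyrfuse("image must be at least 16x16", "pyrfuse_validation_error")
  if (n_levels < 1L)
    stop_pyrfuse("`n_levels` must be >= 1", "pyrfuse_parameter_error")
  r <- (as.integer(size) - 1L) %/% 2L
  g <- exp(-((-r):r)^2 / (2 * sigma^2))
  g <- g / sum(g)
  out <- vector("list", n_levels + 1L)
  out[[1L]] <- img
  for (k in seq_len(n_levels)) out[[k + 1L]] <- sep_filter(out[[k]], g)
  out
}

# Separable symmetric filter with reflected borders.
sep_filter <- function(x, g) {
  r <- (length(g) - 1L) %/% 2L
  p <- reflect_pad(x, r)
  H <- nrow(x); W <- ncol(x)
  tmp <- 0
  for (m in -r:r) tmp <- tmp + g[m + r + 1L] * p[seq_len(H) + r + m, , drop = FALSE]
  out <- 0
  for (n in -r:r) out <- out + g[n + r + 1L] * tmp[, seq_len(W) + r + n, drop = FALSE]
  out
}

#' Sample labeled clear/blurred patch pairs
#'
#' Draws \code{n} random co-located 16x16 patch positions and emits each
#' twice: once with the clear patch first (label 1, a positive example) and
#' once with the blurred patch first (label 0), so classes are exactly
#' balanced.
#'
#' @param clear,blurred Same-size matrices, at least 16x16.
#' @param n Number of patch positions (default 20).
#' @param patch Patch side (default 16).
#' @param seed RNG seed; \code{NULL} uses the current RNG state.
#' @return List with arrays \code{p1}, \code{p2} (\code{patch x patch x 2n})
#'   and the 0/1 vector \code{label}.
#' @export
sample_patch_pairs <- function(clear, blurred, n = 20L, patch = 16L,
                               seed = NULL) {
  check_gray(clear, "clear"); check_gray(blurred, "blurred")
  check_same_shape(clear, blurred, c("clear", "blurred"))
  if (nrow(clear) < patch || ncol(clear) < patch)
    stop_pyrfuse(sprintf("images must be at least %dx%d", patch, patch),
                 "pyrfuse_validation_error")
  if (!is.null(seed)) set.seed(seed)
  r0 <- sample.int(nrow(clear) - patch + 1L, n, replace = TRUE)
  c0 <- sample.int(ncol(clear) - patch + 1L, n, replace = TRUE)
  p1 <- array(0, c(patch, patch, 2L * n))
  p2 <- array(0, c(patch, patch, 2L * n))
  for (i in seq_len(n)) {
    pc <- clear[r0[i]:(r0[i] + patch - 1L), c0[i]:(c0[i] + patch - 1L)]
    pb <- blurred[r0[i]:(r0[i] + patch - 1L), c0[i]:(c0[i] + patch - 1L)]
    p1[, , 2L * i - 1L] <- pc; p2[, , 2L * i - 1L] <- pb
    p1[, , 2L * i] <- pb;      p2[, , 2L * i] <- pc
  }
  list(p1 = p1, p2 = p2, label = rep(c(1L, 0L), n),
       rows = rep(r0, each = 2L), cols = rep(c0, each = 2L))
}

#' Build a training corpus from synthetic phantoms
#'
#' For each of \code{n_images} phantoms, an iterated 5-level blur stack is
#' formed and \code{n_pairs} co-located 16x16 patch pairs are sampled for
#' every (clear, blurred-level) combination, labeled both ways — so each
#' image contributes \code{n_levels * n_pairs * 2} balanced examples (200
#' with the defaults).
#'
#' @param n_images Number of phantom images.
#' @param shape Phantom size (default 64x64).
#' @param n_pairs Patch positions per blur level (default 20).
#' @param n_levels Blur levels (default 5).
#' @param sigma,size Gaussian blur parameters (defaults 2 and 7).
#' @param seed RNG seed for the whole corpus.
#' @return List with arrays \code{p1}, \code{p2} and vector \code{label}.
#' @export
training_corpus <- function(n_images, shape = c(64L, 64L), n_pairs = 20L,
                            n_levels = 5L, sigma = 2, size = 7L, seed = 1L) {
  if (n_images < 1L)
    stop_pyrfuse("`n_images` must be >= 1", "pyrfuse_parameter_error")
  set.seed(seed)
  per_img <- n_levels * n_pairs * 2L
  n_tot <- n_images * per_img
  p1 <- array(0, c(16L, 16L, n_tot))
  p2 <- array(0, c(16L, 16L, n_tot))
  label <- integer(n_tot)
  at <- 0L
  for (i in seq_len(n_images)) {
    ph <- phantom_pair(shape = shape, seed = NULL)
    img <- if (i %% 2L == 1L) ph$a else ph$b
    stack <- blur_stack(img, n_levels = n_levels, sigma = sigma, size = size)
    for (k in seq_len(n_levels)) {
      pp <- sample_patch_pairs(stack[[1L]], stack[[k + 1L]], n = n_pairs,
                               seed = NULL)
      m <- length(pp$label)
      p1[, , at + seq_len(m)] <- pp$p1
      p2[, , at + seq_len(m)] <- pp$p2
      label[at + seq_len(m)] <- pp$label
      at <- at + m
    }
  }
  list(p1 = p1, p2 = p2, label = label)
}
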
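# Shared fixtures, built once per test run.
#
# shared_net() trains one small Siamese classifier on a modest phantom
# corpus and converts it to dense form; tests that only need *a* trained
# net (weight maps, fusion, CLI) reuse it instead of retraining.

.fixture_cache <- new.env(parent = emptyenv())

shared_net <- function() {
  if (is.null(.fixture_cache$net)) {
    corpus <- training_corpus(12L, shape = c(64L, 64L), seed = 401L)
    net <- siamese_net("small", seed = 402L)
    net <- train_siamese(net, corpus, epochs = 3L, seed = 403L)
    .fixture_cache$net <- to_dense(net)
  }
  .fixture_cache$net
}

# Loop-based double-sum REDUCE oracle (0-based indices as in the defining
# sum, reflected borders), independent of the separable implementation.
reduce_oracle <- function(img, k) {
  w2 <- outer(as.numeric(k), as.numeric(k))
  H <- nrow(img); W <- ncol(img)
  refl <- function(p, n) { p <- ifelse(p < 0, -p, p); ifelse(p > n - 1, 2 * (n - 1) - p, p) }
  OH <- ceiling(H / 2); OW <- ceiling(W / 2)
  out <- matrix(0, OH, OW)
  for (i in 0:(OH - 1)) for (j in 0:(OW - 1)) {
    s <- 0
    for (m in -2:2) for (n in -2:2) {
      r <- refl(2 * i + m, H); c <- refl(2 * j + n, W)
      s <- s + w2[m + 3, n + 3] * img[r + 1, c + 1]
    }
    out[i + 1, j + 1] <- s
  }
  out
}

# Loop-based EXPAND oracle: out(i,j) = 4 sum w(m,n) img((i+m)/2, (j+n)/2)
# over integer source indices, reflected at the source borders.
expand_oracle <- function(img, target_dim, k) {
  w2 <- outer(as.numeric(k), as.numeric(k))
  h <- nrow(img); w <- ncol(img)
  refl <- function(p, n) { p <- ifelse(p < 0, -p, p); ifelse(p > n - 1, 2 * (n - 1) - p, p) }
  out <- matrix(0, target_dim[1], target_dim[2])
  for (i in 0:(target_dim[1] - 1)) for (j in 0:(target_dim[2] - 1)) {
    s <- 0
    for (m in -2:2) for (n in -2:2) {
      if ((i + m) %% 2 == 0 && (j + n) %% 2 == 0) {
        r <- refl((i + m) / 2, h); c <- refl((j + n) / 2, w)
        s <- s + w2[m + 3, n + 3] * img[r + 1, c + 1]
      }
    }
    out[i + 1, j + 1] <- 4 * s
  }
  out
}

# Scalar per-pixel fusion-rule oracle: energies and the match measure are
# accumulated column-of-window first then across the window columns, the
# same summation order as the vectorized path, so agreement is exact.
fuse_level_oracle <- function(ca, cb, gw, threshold, window = 3L) {
  H <- nrow(ca); W <- ncol(ca)
  r <- (window - 1L) %/% 2L
  refl <- function(p, n) { p <- ifelse(p < 1, 2 - p, p); ifelse(p > n, 2 * n - p, p) }
  win_sum <- function(x, i, j) {
    tot <- 0
    for (n in -r:r) {
      colsum <- 0
      for (m in -r:r) colsum <- colsum + x[refl(i + m, H), refl(j + n, W)]
      tot <- tot + colsum
    }
    tot
  }
  out <- matrix(0, H, W)
  for (i in 1:H) for (j in 1:W) {
    ea <- win_sum(ca^2, i, j)
    eb <- win_sum(cb^2, i, j)
    den <- ea + eb
    m <- if (den > 0) 2 * win_sum(ca * cb, i, j) / den else 0
    if (m < threshold) {
      out[i, j] <- if (ea >= eb) ca[i, j] else cb[i, j]
    } else {
      wmin <- gw[i, j]; wmax <- 1 - wmin
      out[i, j] <- if (ea >= eb) wmax * ca[i, j] + wmin * cb[i, j]
      else wmin * ca[i, j] + wmax * cb[i, j]
    }
  }
  out
}
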
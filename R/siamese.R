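# Siamese patch classifier.
#
# Two parameter-sharing branches (conv 3x3 -> ReLU -> conv 3x3 -> ReLU ->
# 2x2 max-pool -> conv 3x3 -> ReLU) score which of two co-located 16x16
# patches is the clearer one; branch features are concatenated and mapped to
# a 2-vector by one fully connected layer, then a softmax.  Class 1 means
# "the first patch is clear".  Training is plain momentum SGD with weight
# decay on the softmax cross-entropy, following the schedule: momentum 0.9,
# weight decay 5e-4, batch size 128, learning rate 1e-4 cut to 10% whenever
# the epoch loss plateaus.  Convolution forward/backward lives in compiled
# code (im2col + GEMM); everything else is plain R matrix algebra.

#' Numerically stable 2-class softmax
#'
#' \eqn{f(p_i) = e^{p_i} / \sum_j e^{p_j}}, computed after subtracting the
#' row maximum so arbitrarily large scores stay finite.
#'
#' @param scores A numeric 2-vector, or an n x 2 matrix of score rows.
#' @return Probabilities of the same shape; each pair sums to 1.
#' @examples
#' softmax2(c(0, 0))   # 0.5 0.5
#' softmax2(c(1, 2))   # 0.2689414 0.7310586
#' @export
softmax2 <- function(scores) {
  if (is.matrix(scores)) {
    if (ncol(scores) != 2L || !all(is.finite(scores)))
      stop_pyrfuse("`scores` must be finite with two columns", "pyrfuse_validation_error")
    m <- pmax(scores[, 1L], scores[, 2L])
    e <- exp(scores - m)
    e / rowSums(e)
  } else {
    if (length(scores) != 2L || !all(is.finite(scores)))
      stop_pyrfuse("`scores` must be a finite 2-vector", "pyrfuse_validation_error")
    e <- exp(scores - max(scores))
    e / sum(e)
  }
}

xavier_init <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Construct an untrained Siamese patch classifier
#'
#' Layer shapes are configuration, not fixed by the method: the default
#' "paper"-scale preset uses 64/128/256 feature maps (channel counts grow
#' with depth); the "small" preset (16/32/64) is the desk-scale default used
#' throughout the test-suite and is ample for the clear-vs-blurred task.
#' Convolution weights are Xavier-uniform initialized, biases zero.
#'
#' @param channels Integer 3-vector of feature-map counts for the three
#'   convolutional layers, or one of the presets \code{"paper"}
#'   (64, 128, 256) / \code{"small"} (16, 32, 64).
#' @param patch Patch side length in pixels (16; other sizes must keep the
#'   post-pool feature map at least 1x1).
#' @param seed Optional RNG seed for reproducible initialization.
#' @return Object of class \code{"siamese_net"}.
#' @export
siamese_net <- function(channels = "small", patch = 16L, seed = NULL) {
  if (is.character(channels))
    channels <- switch(match.arg(channels, c("small", "paper")),
                       small = c(16L, 32L, 64L),
                       paper = c(64L, 128L, 256L))
  channels <- as.integer(channels)
  if (length(channels) != 3L || any(channels < 1L))
    stop_pyrfuse("`channels` must be three positive feature-map counts",
                 "pyrfuse_parameter_error")
  patch <- as.integer(patch)
  feat_hw <- (patch - 4L) %/% 2L - 2L   # conv,conv,pool,conv with 3x3 valid kernels
  if (feat_hw < 1L)
    stop_pyrfuse("`patch` too small for the conv/pool stack", "pyrfuse_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  k2 <- 9L
  c1 <- channels[1]; c2 <- channels[2]; c3 <- channels[3]
  d1 <- feat_hw * feat_hw * c3          # per-branch flattened feature size
  params <- list(
    W1 = xavier_init(k2 * 1L, c1, k2 * 1L, k2 * c1),  b1 = numeric(c1),
    W2 = xavier_init(k2 * c1, c2, k2 * c1, k2 * c2),  b2 = numeric(c2),
    W3 = xavier_init(k2 * c2, c3, k2 * c2, k2 * c3),  b3 = numeric(c3),
    Wfc = xavier_init(2L * d1, 2L, 2L * d1, 2L),      bfc = numeric(2L))
  structure(list(channels = channels, patch = patch, feat_hw = feat_hw,
                 params = params, trained = FALSE, history = NULL),
            class = "siamese_net")
}

# One shared branch over a batch: x is (H, W, 1, B).  Returns the conv3
# feature stack and, when keep = TRUE, every intermediate needed by backprop.
branch_forward <- function(net, x, keep = FALSE) {
  p <- net$params
  a1 <- conv2d_forward(x, dim(x), p$W1, p$b1, 3L, 3L)
  r1 <- a1; r1[r1 < 0] <- 0
  a2 <- conv2d_forward(r1, dim(r1), p$W2, p$b2, 3L, 3L)
  r2 <- a2; r2[r2 < 0] <- 0
  pl <- maxpool2_forward(r2, dim(r2))
  a3 <- conv2d_forward(pl$out, dim(pl$out), p$W3, p$b3, 3L, 3L)
  r3 <- a3; r3[r3 < 0] <- 0
  if (keep)
    list(feat = r3, x = x, a1 = a1, r1 = r1, a2 = a2, r2 = r2, pl = pl, a3 = a3)
  else list(feat = r3)
}

# Forward pass over n patch pairs (p1, p2: 16 x 16 x n arrays) -> n x 2 scores.
siamese_scores <- function(net, p1, p2, keep = FALSE) {
  n <- dim(p1)[3]
  ps <- net$patch
  x <- array(c(p1, p2), dim = c(ps, ps, 1L, 2L * n))
  br <- branch_forward(net, x, keep = keep)
  d1 <- prod(dim(br$feat)[1:3])
  fm <- matrix(br$feat, nrow = d1)              # d1 x 2n
  X <- rbind(fm[, seq_len(n), drop = FALSE],
             fm[, n + seq_len(n), drop = FALSE])  # 2*d1 x n
  scores <- crossprod(X, net$params$Wfc)
  scores <- sweep(scores, 2L, net$params$bfc, "+")
  if (keep) list(scores = scores, X = X, br = br, n = n) else list(scores = scores)
}

#' Classify patch pairs
#'
#' @param net A (typically trained) [siamese_net()].
#' @param p1,p2 Arrays \code{patch x patch x n} of co-located patches.
#' @param chunk Pairs per forward pass (bounds memory).
#' @return An n x 2 matrix of class probabilities; column 2 is the
#'   probability that \code{p1} is the clear patch.
#' @export
predict_pairs <- function(net, p1, p2, chunk = 512L) {
  if (length(dim(p1)) == 2L) p1 <- array(p1, c(dim(p1), 1L))
  if (length(dim(p2)) == 2L) p2 <- array(p2, c(dim(p2), 1L))
  n <- dim(p1)[3]
  out <- matrix(NA_real_, n, 2L)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    sc <- siamese_scores(net, p1[, , s:e, drop = FALSE],
                         p2[, , s:e, drop = FALSE])$scores
    out[s:e, ] <- softmax2(sc)
  }
  out
}

#' Pair-classification accuracy
#'
#' @inheritParams predict_pairs
#' @param label 0/1 vector; 1 means \code{p1} is the clear patch.
#' @return Fraction of pairs classified correctly.
#' @export
pair_accuracy <- function(net, p1, p2, label, chunk = 512L) {
  pr <- predict_pairs(net, p1, p2, chunk)
  mean((pr[, 2L] > pr[, 1L]) == (label == 1L))
}

siamese_grads <- function(net, p1, p2, label) {
  fw <- siamese_scores(net, p1, p2, keep = TRUE)
  n <- fw$n
  probs <- softmax2(fw$scores)
  # Loss is the SUM of -log f(p_label) over the batch, so the gradient is
  # not divided by the batch size; the stated learning rate (1e-4) is
  # calibrated to this scale.
  loss <- -sum(log(pmax(probs[cbind(seq_len(n), label + 1L)], 1e-300)))
  Y <- matrix(0, n, 2L); Y[cbind(seq_len(n), label + 1L)] <- 1
  dsc <- probs - Y                             # n x 2
  dWfc <- fw$X %*% dsc
  dbfc <- colSums(dsc)
  dX <- net$params$Wfc %*% t(dsc)              # 2*d1 x n
  d1 <- nrow(dX) / 2L
  dfm <- cbind(dX[seq_len(d1), , drop = FALSE],
               dX[d1 + seq_len(d1), , drop = FALSE])
  br <- fw$br
  dr3 <- array(dfm, dim(br$a3))
  da3 <- dr3 * (br$a3 > 0)
  g3 <- conv2d_backward(br$pl$out, dim(br$pl$out), net$params$W3, da3, 3L, 3L, TRUE)
  dr2 <- maxpool2_backward(g3$dx, br$pl$idx, dim(br$r2))
  da2 <- dr2 * (br$a2 > 0)
  g2 <- conv2d_backward(br$r1, dim(br$r1), net$params$W2, da2, 3L, 3L, TRUE)
  da1 <- g2$dx * (br$a1 > 0)
  g1 <- conv2d_backward(br$x, dim(br$x), net$params$W1, da1, 3L, 3L, FALSE)
  list(loss = loss,
       grads = list(W1 = g1$dw, b1 = g1$db, W2 = g2$dw, b2 = g2$db,
                    W3 = g3$dw, b3 = g3$db, Wfc = dWfc, bfc = dbfc))
}

#' Train the Siamese classifier by momentum SGD
#'
#' Minimizes the softmax cross-entropy over clear/blurred patch pairs with
#' the update \eqn{v \leftarrow 0.9 v - 0.0005\,\alpha w - \alpha \nabla L},
#' \eqn{w \leftarrow w + v}.  The learning rate starts at \code{lr} and is
#' cut to \code{lr_drop} of its value whenever the mean epoch loss improves
#' by less than \code{plateau_tol} relative to the previous epoch.  The loss
#' is summed over each batch (so the stated learning rate is tied to the
#' batch size of 128); reported epoch losses are per-example means.
#'
#' @param net A [siamese_net()].
#' @param corpus List with arrays \code{p1}, \code{p2}
#'   (\code{patch x patch x n}) and 0/1 vector \code{label}, e.g. from
#'   [training_corpus()] or [sample_patch_pairs()].
#' @param epochs Training epochs; 0 returns \code{net} unchanged.
#' @param lr Initial learning rate (default 1e-4).
#' @param batch_size Examples per SGD step (default 128).
#' @param momentum,weight_decay SGD hyperparameters (defaults 0.9, 5e-4).
#' @param lr_drop Multiplier applied to the learning rate at a plateau.
#' @param plateau_tol Relative epoch-loss improvement below which the
#'   learning rate is dropped (default 0.01).
#' @param seed Optional seed controlling batch shuffling.
#' @param verbose Print per-epoch loss.
#' @return The trained net, with \code{$history} holding per-epoch mean loss
#'   and learning rate.
#' @export
train_siamese <- function(net, corpus, epochs = 10L, lr = 1e-4,
                          batch_size = 128L, momentum = 0.9,
                          weight_decay = 5e-4, lr_drop = 0.1,
                          plateau_tol = 0.01, seed = NULL, verbose = FALSE) {
  if (!inherits(net, "siamese_net"))
    stop_pyrfuse("`net` must be a siamese_net", "pyrfuse_parameter_error")
  n <- length(corpus$label)
  if (n < 1L)
    stop_pyrfuse("training corpus is empty", "pyrfuse_validation_error")
  if (!is.null(seed)) set.seed(seed)
  vel <- lapply(net$params, function(p) p * 0)
  hist_loss <- numeric(0); hist_lr <- numeric(0)
  prev_loss <- NA_real_
  for (ep in seq_len(as.integer(epochs))) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      g <- siamese_grads(net,
                         corpus$p1[, , idx, drop = FALSE],
                         corpus$p2[, , idx, drop = FALSE],
                         corpus$label[idx])
      if (!is.finite(g$loss))
        stop_pyrfuse(sprintf("training diverged (non-finite loss) in epoch %d", ep),
                     "pyrfuse_divergence_error")
      ep_loss <- ep_loss + g$loss
      for (nm in names(net$params)) {
        vel[[nm]] <- momentum * vel[[nm]] - weight_decay * lr * net$params[[nm]] -
          lr * g$grads[[nm]]
        net$params[[nm]] <- net$params[[nm]] + vel[[nm]]
      }
    }
    ep_loss <- ep_loss / n
    hist_loss <- c(hist_loss, ep_loss); hist_lr <- c(hist_lr, lr)
    if (verbose)
      message(sprintf("epoch %d: loss %.5f (lr %.2g)", ep, ep_loss, lr))
    if (!is.na(prev_loss) && (prev_loss - ep_loss) < plateau_tol * prev_loss)
      lr <- lr * lr_drop
    prev_loss <- ep_loss
  }
  net$trained <- TRUE
  net$history <- data.frame(epoch = seq_along(hist_loss), loss = hist_loss,
                            lr = hist_lr)
  net
}

#' Save / load a Siamese model checkpoint
#'
#' A checkpoint is a single-file archive of the named parameter arrays plus
#' the architecture configuration; saving and reloading round-trips the
#' model bit-exactly.
#'
#' @param net A [siamese_net()].
#' @param path File path for the checkpoint.
#' @return \code{load_siamese()} returns the restored net.
#' @export
save_siamese <- function(net, path) {
  if (!inherits(net, "siamese_net"))
    stop_pyrfuse("`net` must be a siamese_net", "pyrfuse_parameter_error")
  saveRDS(net, path)
  invisible(path)
}

#' @rdname save_siamese
#' @export
load_siamese <- function(path) {
  net <- readRDS(path)
  if (!inherits(net, "siamese_net"))
    stop_pyrfuse(sprintf("'%s' is not a siamese_net checkpoint", path),
                 "pyrfuse_io_error")
  net
}

#' @export
print.siamese_net <- function(x, ...) {
  cat(sprintf("Siamese patch classifier: %dx%d patches, channels %s, %s\n",
              x$patch, x$patch, paste(x$channels, collapse = "/"),
              if (x$trained) sprintf("trained (%d epochs, final loss %.4f)",
                                     nrow(x$history), utils::tail(x$history$loss, 1))
              else "untrained"))
  invisible(x)
}
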
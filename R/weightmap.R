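# Dense (fully convolutional) application of the patch classifier and the
# per-pixel weight map.
#
# The fully connected head is algebraically rewritten as one convolution
# whose kernel size equals the per-branch feature map of a single patch
# (feat_hw x feat_hw over the concatenated branch channels), so any-size
# image pairs are scored in one pass.  Because the branch contains one 2x2
# pooling stage, adjacent dense predictions correspond to 16x16 source
# windows 2 pixels apart.  Each prediction is binarized (clear side -> 1)
# and assigned to its whole source window; overlapping windows are
# averaged, and the uncovered right/bottom margin (at most a pixel-wide
# strip when sizes are odd) inherits the nearest covered weight.

#' Convert the fully connected head to convolutional form
#'
#' Rewrites the FC layer as an equivalent convolution so the network can
#' score every 16x16 window of an arbitrary image pair in one pass.  On a
#' single patch pair, the dense form reproduces the original head scores to
#' floating-point precision.
#'
#' @param net A [siamese_net()].
#' @return The net with a \code{$dense} field holding the head kernel.
#' @export
to_dense <- function(net) {
  if (!inherits(net, "siamese_net"))
    stop_pyrfuse("`net` must be a siamese_net", "pyrfuse_parameter_error")
  fh <- net$feat_hw
  c3 <- net$channels[3]
  d1 <- fh * fh * c3
  if (nrow(net$params$Wfc) != 2L * d1)
    stop_pyrfuse("FC layer shape does not match the branch feature map",
                 "pyrfuse_conversion_error")
  # FC rows are ordered (di, dj, c) per branch, branch A then branch B;
  # conv rows must be (di, dj, channel) with channels = [A channels, B channels].
  di <- rep(seq_len(fh), times = fh * 2L * c3)
  dj <- rep(rep(seq_len(fh), each = fh), times = 2L * c3)
  ch <- rep(seq_len(2L * c3), each = fh * fh)
  conv_row <- ((ch - 1L) * fh + (dj - 1L)) * fh + di         # target position
  fc_row <- ifelse(ch <= c3,
                   di + fh * (dj - 1L) + fh * fh * (ch - 1L),
                   d1 + di + fh * (dj - 1L) + fh * fh * (ch - c3 - 1L))
  Whead <- matrix(0, 2L * d1, 2L)
  Whead[conv_row, ] <- net$params$Wfc[fc_row, ]
  net$dense <- list(Whead = Whead, bhead = net$params$bfc, k = fh)
  net
}

# Dense scores for an image pair: returns gh x gw x 2 array of head scores;
# grid cell (i, j) corresponds to the 16x16 window with top-left pixel
# (2(i-1)+1, 2(j-1)+1).
dense_scores <- function(net, a, b) {
  if (is.null(net$dense)) net <- to_dense(net)
  fa <- branch_forward(net, array(a, c(dim(a), 1L, 1L)))$feat
  fb <- branch_forward(net, array(b, c(dim(b), 1L, 1L)))$feat
  fd <- dim(fa)
  feat <- array(c(fa, fb), c(fd[1], fd[2], 2L * fd[3], 1L))
  k <- net$dense$k
  s <- conv2d_forward(feat, dim(feat), net$dense$Whead, net$dense$bhead, k, k)
  array(s, dim(s)[1:3])
}

#' Per-pixel fusion weight map
#'
#' Applies the Siamese classifier densely to a co-registered image pair and
#' turns the grid of patch decisions into a per-pixel weight map for source
#' \code{a} (source \code{b} implicitly receives \eqn{1 - W}).  Each dense
#' prediction is binarized — 1 when the net judges the \code{a}-patch
#' clearer — spread over its 16x16 source window, and overlapping windows
#' are averaged.
#'
#' @param net A trained [siamese_net()] (converted with [to_dense()] on the
#'   fly if needed).
#' @param a,b Co-registered numeric matrices of identical size, at least
#'   16x16, values in \eqn{[0,1]}.
#' @return Matrix of the same size as the inputs with values in \eqn{[0,1]}.
#' @export
weight_map <- function(net, a, b) {
  check_gray(a, "a"); check_gray(b, "b")
  check_same_shape(a, b)
  ps <- net$patch
  if (nrow(a) < ps || ncol(a) < ps)
    stop_pyrfuse(sprintf("images must be at least %dx%d", ps, ps),
                 "pyrfuse_validation_error")
  s <- dense_scores(net, a, b)
  wgrid <- (s[, , 2L] >= s[, , 1L]) * 1
  if (is.null(dim(wgrid))) wgrid <- matrix(wgrid, dim(s)[1], dim(s)[2])
  overlap_average(wgrid, dim(a), win = ps, stride = 2L)
}

# Spread a grid of window weights (windows of side `win`, top-left corners
# stride apart starting at pixel 1) over the image, averaging overlaps and
# replicating the last covered row/column into any uncovered margin.
overlap_average <- function(wgrid, img_dim, win, stride) {
  H <- img_dim[1]; W <- img_dim[2]
  gh <- nrow(wgrid); gw <- ncol(wgrid)
  placed <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  rr <- stride * (seq_len(gh) - 1L) + 1L
  cc <- stride * (seq_len(gw) - 1L) + 1L
  placed[rr, cc] <- wgrid
  cnt[rr, cc] <- 1
  sums <- box_sum_back(placed, win)
  cnts <- box_sum_back(cnt, win)
  wmap <- matrix(0, H, W)
  covered <- cnts > 0
  wmap[covered] <- sums[covered] / cnts[covered]
  rmax <- stride * (gh - 1L) + win
  cmax <- stride * (gw - 1L) + win
  if (rmax < H) wmap[(rmax + 1L):H, ] <- wmap[rep(rmax, H - rmax), ]
  if (cmax < W) wmap[, (cmax + 1L):W] <- wmap[, rep(cmax, W - cmax)]
  wmap
}

# box_sum_back(x, k)[i, j] = sum of x over [i-k+1, i] x [j-k+1, j]
# (zero outside), via an integral image.
box_sum_back <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  I <- matrix(0, H + 1L, W + 1L)
  I[-1L, -1L] <- apply(apply(x, 2L, cumsum), 1L, cumsum) |> t()
  i1 <- pmax(seq_len(H) - k, 0L) + 1L
  j1 <- pmax(seq_len(W) - k, 0L) + 1L
  I[seq_len(H) + 1L, seq_len(W) + 1L] -
    I[i1, seq_len(W) + 1L] -
    I[seq_len(H) + 1L, j1] +
    I[i1, j1]
}
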
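test_that("softmax2 matches the closed form and is stable for large gaps", {
  expect_equal(softmax2(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax2(c(1, 2)), exp(c(1, 2)) / sum(exp(c(1, 2))))
  expect_equal(softmax2(c(1, 2))[2], 0.73106, tolerance = 1e-5)
  big <- softmax2(c(0, 800))
  expect_equal(sum(big), 1)
  expect_lt(big[1], 1e-300)
  m <- softmax2(matrix(c(0, 1, 0, 2), 2))
  expect_equal(rowSums(m), c(1, 1))
  expect_error(softmax2(c(NaN, 1)), class = "pyrfuse_validation_error")
})

test_that("network construction is seeded, Xavier-scaled, with zero biases", {
  n1 <- siamese_net("small", seed = 5)
  n2 <- siamese_net("small", seed = 5)
  expect_identical(n1$params, n2$params)
  expect_identical(n1$params$b1, numeric(16))
  expect_identical(n1$params$bfc, numeric(2))
  lim <- sqrt(6 / (9 + 9 * 16))
  expect_true(all(abs(n1$params$W1) <= lim))
  expect_gt(sd(n1$params$W1), 0)
  expect_equal(siamese_net("paper")$channels, c(64L, 128L, 256L))
})

test_that("analytic gradients agree with finite differences on a tiny net", {
  net <- siamese_net(c(2L, 2L, 2L), seed = 7)
  set.seed(8)
  p1 <- array(runif(16 * 16 * 4), c(16, 16, 4))
  p2 <- array(runif(16 * 16 * 4), c(16, 16, 4))
  lab <- c(1L, 0L, 1L, 0L)
  g <- pyrfuse:::siamese_grads(net, p1, p2, lab)
  loss_at <- function(params) {
    net2 <- net; net2$params <- params
    pyrfuse:::siamese_grads(net2, p1, p2, lab)$loss
  }
  checked <- 0L
  for (nm in names(net$params)) {
    p <- net$params[[nm]]
    ix <- sample(length(p), min(6L, length(p)))
    for (i in ix) {
      eps <- 1e-5
      pp <- net$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- net$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      f0 <- g$loss
      fd_fwd <- (loss_at(pp) - f0) / eps
      fd_bwd <- (f0 - loss_at(pm)) / eps
      # ReLU and max-pooling make the loss piecewise smooth; when the two
      # one-sided differences disagree the coordinate straddles a kink and
      # only a subgradient is defined there, so skip it
      if (abs(fd_fwd - fd_bwd) > 1e-3 * max(1, abs(fd_fwd))) next
      fd <- (fd_fwd + fd_bwd) / 2
      expect_equal(as.numeric(g$grads[[nm]][i]), fd, tolerance = 1e-4)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 20L)
})

test_that("zero training epochs leave the parameters unchanged", {
  net <- siamese_net("small", seed = 9)
  corpus <- training_corpus(1L, seed = 10)
  out <- train_siamese(net, corpus, epochs = 0L, seed = 11)
  expect_identical(out$params, net$params)
})

test_that("loss decreases over the first epochs on separable synthetic data", {
  corpus <- training_corpus(4L, seed = 20)
  net <- siamese_net("small", seed = 21)
  net <- train_siamese(net, corpus, epochs = 3L, seed = 22)
  expect_true(all(diff(net$history$loss) < 0))
  expect_lt(net$history$loss[3], net$history$loss[1])
})

test_that("training is reproducible under a fixed seed", {
  corpus <- training_corpus(2L, seed = 30)
  n1 <- train_siamese(siamese_net("small", seed = 31), corpus, epochs = 1L, seed = 32)
  n2 <- train_siamese(siamese_net("small", seed = 31), corpus, epochs = 1L, seed = 32)
  expect_identical(n1$params, n2$params)
})

test_that("the learning rate is cut to 10% at a loss plateau", {
  corpus <- training_corpus(1L, seed = 40)
  # zero learning rate cannot improve, so every epoch after the first is a
  # plateau and the recorded rate decays by lr_drop
  net <- train_siamese(siamese_net("small", seed = 41), corpus, epochs = 3L,
                       lr = 0, seed = 42)
  expect_equal(net$history$lr, c(0, 0, 0))
  # the first possible cut is after epoch 2 (epoch 1 has no predecessor),
  # so with a vanishing learning rate the recorded rate drops at epoch 3
  net2 <- train_siamese(siamese_net(c(2L, 2L, 2L), seed = 41), corpus,
                        epochs = 3L, lr = 1e-12, seed = 42)
  expect_equal(net2$history$lr[2], net2$history$lr[1])
  expect_equal(net2$history$lr[3] / net2$history$lr[2], 0.1, tolerance = 1e-10)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- shared_net()
  path <- tempfile(fileext = ".rds")
  save_siamese(net, path)
  back <- load_siamese(path)
  expect_identical(back$params, net$params)
  expect_identical(back$channels, net$channels)
  unlink(path)
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_siamese(bad), class = "pyrfuse_io_error")
  unlink(bad)
})
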
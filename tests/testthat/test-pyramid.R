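k <- build_kernel()

test_that("reduce matches the loop-based double-sum oracle on small images", {
  set.seed(10)
  for (d in list(c(8L, 8L), c(9L, 9L), c(16L, 12L), c(7L, 13L))) {
    img <- matrix(runif(prod(d)), d[1], d[2])
    expect_lt(max(abs(pyr_reduce(img, k) - reduce_oracle(img, k))), 1e-12)
  }
})

test_that("expand matches the loop-based oracle and honors the target shape", {
  set.seed(11)
  for (case in list(list(c(4L, 4L), c(8L, 8L)), list(c(5L, 7L), c(9L, 13L)),
                    list(c(6L, 4L), c(12L, 7L)))) {
    img <- matrix(runif(prod(case[[1]])), case[[1]][1], case[[1]][2])
    out <- pyr_expand(img, case[[2]], k)
    expect_equal(dim(out), case[[2]])
    expect_lt(max(abs(out - expand_oracle(img, case[[2]], k))), 1e-12)
  }
  expect_error(pyr_expand(matrix(0, 4, 4), c(10L, 8L)),
               class = "pyrfuse_shape_error")
})

test_that("reduce and expand preserve constant images exactly", {
  cimg <- matrix(0.37, 10, 14)
  r <- pyr_reduce(cimg, k)
  expect_equal(dim(r), c(5L, 7L))
  expect_true(all(abs(r - 0.37) < 1e-15))
  e <- pyr_expand(r, c(10L, 14L), k)
  expect_true(all(abs(e - 0.37) < 1e-15))
})

test_that("reduce of a centered impulse reproduces the 2-D window at even offsets", {
  img <- matrix(0, 9, 9); img[5, 5] <- 1
  out <- pyr_reduce(img, k)
  w2 <- kernel_2d(k)
  # out(i,j) = w(6-2i) w(6-2j) for taps within range (1-based)
  expected <- matrix(0, 5, 5)
  for (i in 2:4) for (j in 2:4) expected[i, j] <- w2[6 - 2 * i + 3, 6 - 2 * j + 3]
  expect_equal(out, expected, tolerance = 1e-14)
})

test_that("expand(reduce(.)) approximates smooth images", {
  set.seed(12)
  img <- blur_stack(matrix(runif(64 * 64), 64), n_levels = 2)[[3]]
  back <- pyr_expand(pyr_reduce(img, k), c(64L, 64L), k)
  expect_lt(sqrt(mean((back - img)^2)) / sd(img), 0.25)
})

test_that("gaussian pyramid obeys the shape chain and depth errors name the cap", {
  img <- matrix(runif(64 * 64), 64)
  g <- gaussian_pyramid(img, 3, k)
  expect_equal(vapply(g$levels, nrow, 0L), c(64L, 32L, 16L, 8L))
  expect_identical(g$levels[[1]], img)
  g0 <- gaussian_pyramid(img, 0, k)
  expect_length(g0$levels, 1L)
  expect_identical(g0$levels[[1]], img)
  cimg <- matrix(0.5, 32, 32)
  gc <- gaussian_pyramid(cimg, 3, k)
  for (l in gc$levels) expect_true(all(abs(l - 0.5) < 1e-14))
  err <- tryCatch(gaussian_pyramid(img, 10, k), error = identity)
  expect_s3_class(err, "pyrfuse_depth_error")
  expect_match(conditionMessage(err), "maximum feasible depth")
})

test_that("contrast decomposition: constant images give zero contrast and the top is Gaussian", {
  cimg <- matrix(0.5, 32, 32)
  cp <- contrast_decompose(cimg, 2, k)
  for (l in cp$levels) expect_lt(max(abs(l)), 1e-10)
  img <- matrix(runif(64 * 64), 64)
  cp2 <- contrast_decompose(img, 3, k)
  g <- gaussian_pyramid(img + cp2$offset, 3, k)
  expect_identical(cp2$top, g$levels[[4]])
  expect_error(contrast_decompose(matrix(c(NaN, runif(255)), 16), 2, k),
               class = "pyrfuse_validation_error")
})

test_that("decompose -> reconstruct is an exact round trip across sizes and depths", {
  set.seed(13)
  for (i in 1:25) {
    h <- sample(16:96, 1); w <- sample(16:96, 1)
    img <- matrix(runif(h * w), h, w)
    N <- sample(seq_len(pyrfuse:::max_pyramid_depth(c(h, w))), 1)
    cp <- contrast_decompose(img, N, k)
    expect_lt(max(abs(contrast_reconstruct(cp, k) - img)), 1e-9)
  }
})

test_that("reconstruction from zero contrast with constant top is constant", {
  cp <- contrast_decompose(matrix(0.25, 32, 32), 2, k)
  for (l in seq_along(cp$levels)) cp$levels[[l]] <- cp$levels[[l]] * 0
  out <- contrast_reconstruct(cp, k)
  expect_true(all(abs(out - 0.25) < 1e-10))
})

test_that("perturbing one coarse coefficient only changes its support region", {
  set.seed(14)
  img <- matrix(runif(64 * 64) + 0.5, 64)
  cp <- contrast_decompose(img, 3, k)
  base <- contrast_reconstruct(cp, k)
  cp$levels[[3]][8, 8] <- cp$levels[[3]][8, 8] + 1   # level 2, 16x16
  pert <- contrast_reconstruct(cp, k)
  diff <- abs(pert - base) > 1e-12
  # level-2 pixel (8,8) expands through two EXPAND stages; its footprint at
  # level 0 stays within a centered block of about (2*2+1)*2+1 = 11 pixels
  # per stage around 4*(8-1)+1
  touched <- which(diff, arr.ind = TRUE)
  expect_true(all(touched[, 1] >= 21 & touched[, 1] <= 37))
  expect_true(all(touched[, 2] >= 21 & touched[, 2] <= 37))
  expect_gt(sum(diff), 0)
})
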
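test_that("masked average pooling equals the brute-force masked mean", {
  # hand-checkable 2x2 grid: prototype of positions a, b is (a+b)/2
  f <- array(0, dim = c(3, 2, 2))
  a <- c(1, 2, 3); b <- c(4, 5, 6); cc <- c(7, 8, 9); d <- c(10, 11, 12)
  f[, 1, 1] <- a; f[, 1, 2] <- b; f[, 2, 1] <- cc; f[, 2, 2] <- d
  mask <- matrix(c(1, 0, 0, 1), 2, 2)  # selects (1,1) and (2,2)
  expect_equal(masked_average_pool(f, mask), (a + d) / 2)
  mask_ab <- matrix(c(1, 0, 1, 0), 2, 2)  # selects (1,1) and (1,2)
  expect_equal(masked_average_pool(f, mask_ab), (a + b) / 2)

  # spatially constant features give back the constant vector
  fc <- array(rep(c(2, -1, 0.5), 4 * 4), dim = c(3, 4, 4))
  expect_equal(masked_average_pool(fc, random_mask(4, 0.6) | 1), c(2, -1, 0.5))

  expect_error(masked_average_pool(f, matrix(0, 2, 2)), "empty mask")

  # random 64x64x256 grid vs an explicit double loop
  set.seed(4)
  big <- array(rnorm(256 * 64 * 64), dim = c(256, 64, 64))
  m <- matrix(as.integer(runif(64 * 64) < 0.3), 64, 64)
  oracle <- numeric(256); n <- 0
  for (j in 1:64) for (i in 1:64) if (m[i, j] == 1) {
    oracle <- oracle + big[, i, j]; n <- n + 1
  }
  expect_equal(masked_average_pool(big, m), oracle / n, tolerance = 1e-6)
})

test_that("similarity scores are scaled negative cosines", {
  set.seed(2)
  rho <- rnorm(8)
  f <- array(0, dim = c(8, 2, 2))
  f[, 1, 1] <- 3 * rho                      # same direction
  f[, 2, 1] <- -rho                         # opposite
  orth <- rnorm(8); orth <- orth - sum(orth * rho) / sum(rho^2) * rho
  f[, 1, 2] <- orth                         # orthogonal
  f[, 2, 2] <- 0                            # zero vector
  R <- similarity_map(f, rho, alpha = 20)
  expect_equal(R[1, 1], -20)
  expect_equal(R[2, 1], 20)
  expect_equal(R[1, 2], 0, tolerance = 1e-12)
  expect_equal(R[2, 2], 0)
  expect_true(all(R >= -20 & R <= 20))

  # invariance to positive rescaling of features and prototype
  set.seed(9)
  g <- array(rnorm(8 * 3 * 3), dim = c(8, 3, 3))
  R1 <- similarity_map(g, rho)
  R2 <- similarity_map(g * 7.3, rho * 0.02)
  expect_equal(R1, R2, tolerance = 1e-12)

  # oracle: direct -alpha * cosine at every pixel
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    v <- g[, i, j]
    oracle[i, j] <- -20 * sum(v * rho) / sqrt(sum(v^2) * sum(rho^2))
  }
  expect_equal(unclass(R1), oracle, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(similarity_map(g, numeric(8)), "nonzero")
})

test_that("soft thresholding pivots at exactly 0.5 and is monotone", {
  for (beta in c(-10, 0, 5)) {
    expect_identical(soft_threshold(matrix(beta, 1, 1), beta)[1, 1], 0.5)
  }
  # closed-form sigmoid tail: R - beta = -20
  expect_equal(soft_threshold(matrix(-30, 1, 1), -10)[1, 1],
               1 - 2.0611536e-9, tolerance = 1e-15)
  r <- seq(-20, 20, length.out = 101)
  m <- soft_threshold(matrix(r, 1), beta = -10)
  expect_true(all(diff(as.vector(m)) < 0))
  expect_true(all(m > 0 & m < 1))
  expect_equal(soft_threshold(matrix(1e6, 1, 1), 0)[1, 1], 0)
})

test_that("grid resizing honours bilinear and nearest contracts", {
  x <- matrix(rnorm(32 * 32), 32)
  expect_identical(resize_to_mask(x, c(32, 32)), x)
  const <- matrix(4.2, 5, 7)
  expect_equal(resize_to_mask(const, c(11, 13)), matrix(4.2, 11, 13))
  up <- resize_to_mask(matrix(c(0, 1, 0, 1), 2, 2), c(4, 4))
  expect_true(all(abs(up - up[, 1]) < 1e-12))            # column-constant
  expect_true(all(diff(up[, 1]) >= 0))                   # rows monotone
  expect_equal(up[, 1], c(0, 1 / 3, 2 / 3, 1))
  m <- downsample_mask(matrix(as.integer(runif(256 * 256) < 0.4), 256), c(32, 32))
  expect_true(all(m %in% c(0, 1)))
})

test_that("a support slice scored against its own prototype separates classes", {
  set.seed(12)
  # separable features: foreground vectors cluster around u, background around v
  u <- rnorm(16); v <- rnorm(16)
  f <- array(0, dim = c(16, 8, 8))
  mask <- matrix(0L, 8, 8); mask[3:5, 4:7] <- 1L
  for (i in 1:8) for (j in 1:8)
    f[, i, j] <- (if (mask[i, j] == 1) u else v) + rnorm(16, 0, 0.1)
  rho <- masked_average_pool(f, mask)
  M <- soft_threshold(similarity_map(f, rho), beta = -10)
  expect_gt(mean(M[mask == 1]), mean(M[mask == 0]))
})
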
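test_that("a 2x2 window retains its maximum and the diagonal partner", {
  w <- matrix(c(5, 1, 2, 3), 2, 2, byrow = TRUE)
  p <- max_diagonal_pool(w)
  expect_equal(as.numeric(p$max_map), 5)
  expect_equal(as.numeric(p$diag_map), 3)
  expect_equal(as.integer(p$max_idx), 0L) # row-major position of (0, 0)
  expect_equal(as.integer(p$diag_idx), 3L)
})

test_that("ties resolve to the first row-major cell", {
  w <- matrix(7, 2, 2)
  p <- max_diagonal_pool(w)
  expect_equal(as.integer(p$max_idx), 0L)
  expect_equal(as.integer(p$diag_idx), 3L)
  expect_equal(as.numeric(p$max_map), 7)
  expect_equal(as.numeric(p$diag_map), 7)
})

test_that("pooling matches the per-window brute-force oracle", {
  set.seed(42)
  for (k in 1:50) {
    x <- matrix(rnorm(64), 8, 8)
    p <- max_diagonal_pool(x)
    o <- oracle_maxdiag_pool(x)
    expect_identical(unname(p$max_map), o$max_map)
    expect_identical(unname(p$diag_map), o$diag_map)
    expect_identical(array(as.integer(p$max_idx), dim(o$max_idx)), o$max_idx)
    expect_identical(array(as.integer(p$diag_idx), dim(o$diag_idx)), o$diag_idx)
  }
})

test_that("pooling halves dims per channel and unpooling restores them", {
  set.seed(1)
  x <- array(rnorm(16 * 12 * 3 * 2), c(16, 12, 3, 2))
  p <- max_diagonal_pool(x)
  expect_equal(dim(p$max_map), c(8, 6, 3, 2))
  expect_equal(dim(p$diag_map), c(8, 6, 3, 2))
  u <- max_diagonal_unpool(pool = p)
  expect_equal(dim(u), c(16, 12, 3, 2))
})

test_that("stored indices are in-plane diagonal partners", {
  set.seed(2)
  x <- matrix(rnorm(100), 10, 10)
  p <- max_diagonal_pool(x)
  mi <- as.integer(p$max_idx); di <- as.integer(p$diag_idx)
  expect_true(all(mi >= 0 & mi < 100))
  expect_true(all(di >= 0 & di < 100))
  expect_true(all(mi != di))
  # diagonal partners: local offsets within the window sum to (1, 1)
  mr <- mi %/% 10; mc <- mi %% 10
  dr <- di %/% 10; dc <- di %% 10
  expect_true(all(mr %/% 2 == dr %/% 2 & mc %/% 2 == dc %/% 2)) # same window
  expect_true(all(mr %% 2 + dr %% 2 == 1))
  expect_true(all(mc %% 2 + dc %% 2 == 1))
})

test_that("window normalisation divides by the stabilised window sum", {
  w <- window_normalize(4, 3, 1, 2, eps = 1e-6)
  expect_equal(w$m, 4 / (10 + 1e-6))
  expect_equal(w$m + w$d + w$l1 + w$l2, (w$c - 1e-6) / w$c)
  # arithmetic example (1, 2, 3, 4)
  v <- window_normalize(1, 2, 3, 4, eps = 1e-6)
  expect_equal(c(v$m, v$d, v$l1, v$l2), c(0.1, 0.2, 0.3, 0.4),
               tolerance = 1e-6)
  # all-zero windows stay finite and zero
  z <- window_normalize(0, 0, 0, 0)
  expect_equal(c(z$m, z$d, z$l1, z$l2), c(0, 0, 0, 0))
  # ratios are scale invariant as eps -> 0
  a <- window_normalize(1, 2, 3, 4, eps = 1e-12)
  b <- window_normalize(10, 20, 30, 40, eps = 1e-12)
  expect_equal(a$m, b$m, tolerance = 1e-9)
})

test_that("unpool writes pooled values back to their recorded cells", {
  set.seed(3)
  x <- matrix(rnorm(64), 8, 8) # continuous values: no ties
  p <- max_diagonal_pool(x)
  u <- max_diagonal_unpool(pool = p)
  for (idx_name in c("max_idx", "diag_idx")) {
    idx <- as.integer(p[[idx_name]])
    map <- as.numeric(p[[sub("idx", "map", idx_name)]])
    r <- idx %/% 8 + 1; cc <- idx %% 8 + 1
    expect_identical(u[cbind(r, cc)], map)
    expect_identical(x[cbind(r, cc)], map) # round trip to the source cells
  }
})

test_that("constant 1x1 input unpools to a constant 2x2 field", {
  u <- max_diagonal_unpool(matrix(3.5, 1, 1), matrix(3.5, 1, 1),
                           matrix(0L, 1, 1), matrix(3L, 1, 1), 2, 2)
  expect_equal(u, matrix(3.5, 2, 2))
  z <- max_diagonal_unpool(matrix(0, 1, 1), matrix(0, 1, 1),
                           matrix(0L, 1, 1), matrix(3L, 1, 1), 2, 2)
  expect_equal(z, matrix(0, 2, 2))
})

test_that("invalid inputs are rejected", {
  expect_error(max_diagonal_pool(matrix(1, 4, 4), eps = 0), "positive")
  expect_error(max_diagonal_pool(matrix(1, 4, 4), eps = -1), "positive")
  expect_error(max_diagonal_pool(array(0, c(0, 4))), "empty")
  expect_error(max_diagonal_pool(1:4), "matrix or array")
  p <- max_diagonal_pool(matrix(rnorm(16), 4, 4))
  expect_error(
    max_diagonal_unpool(p$max_map, matrix(0, 1, 1), p$max_idx, p$diag_idx, 4, 4),
    "identical shapes")
  bad <- p$max_idx; bad[1] <- 99L
  expect_error(
    max_diagonal_unpool(p$max_map, p$diag_map, bad, p$diag_idx, 4, 4),
    "out of output bounds")
})

test_that("odd inputs are reflect-padded and cropped back on unpooling", {
  set.seed(4)
  x <- matrix(rnorm(49), 7, 7)
  p <- max_diagonal_pool(x)
  expect_equal(dim(p$max_map), c(4, 4))
  expect_equal(p$pad, c(1L, 1L))
  u <- max_diagonal_unpool(pool = p)
  expect_equal(dim(u), c(7, 7))
})

test_that("both retained cells per window carry gradient", {
  set.seed(5)
  x <- matrix(rnorm(16), 4, 4) # distinct values
  xt <- hssamnet:::ag_param(array(x, c(4, 4, 1, 1)))
  p <- hssamnet:::ag_maxdiag_pool(xt)
  loss <- hssamnet:::ag_mean(hssamnet:::ag_add(p$max, p$diag))
  hssamnet:::ag_backward(loss)
  sens <- matrix(xt$grad[, , 1, 1] != 0, 4, 4)
  expect_equal(sum(sens), 8) # 2 of 4 cells in each of the 4 windows
  for (i in 1:2) for (j in 1:2) {
    expect_equal(sum(sens[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)]), 2)
  }
  # finite-difference agreement at one indexed and one dropped cell
  f <- function(v) {
    xx <- x; xx[2, 3] <- v
    pp <- max_diagonal_pool(xx)
    mean(pp$max_map + pp$diag_map)
  }
  fd <- (f(x[2, 3] + 1e-6) - f(x[2, 3] - 1e-6)) / 2e-6
  expect_equal(fd, xt$grad[2, 3, 1, 1], tolerance = 1e-5)
})

test_that("bilinear resize is the identity at the same size and constant-preserving", {
  x <- matrix(rnorm(36), 6, 6)
  expect_equal(bilinear_resize(x, 6, 6), x)
  expect_equal(bilinear_resize(matrix(2, 3, 3), 7, 5), matrix(2, 7, 5))
})
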
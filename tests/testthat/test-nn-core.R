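# Differentiation correctness of the layer backend: every operator's
# analytic gradient is checked against central finite differences.

fd_check <- function(make_loss, param, n_probe = 6, tol = 1e-4, eps = 1e-5) {
  loss <- make_loss()
  hssamnet:::ag_zero_grad(list(param))
  hssamnet:::ag_backward(loss)
  g <- param$grad
  set.seed(1234)
  for (k in seq_len(n_probe)) {
    j <- sample(length(param$value), 1)
    old <- param$value[j]
    param$value[j] <- old + eps
    lp <- make_loss()$value
    param$value[j] <- old - eps
    lm <- make_loss()$value
    param$value[j] <- old
    fd <- (lp - lm) / (2 * eps)
    expect_equal(g[j], fd, tolerance = tol,
                 info = paste("probe", k, "index", j))
  }
}

test_that("convolution matches a naive loop and differentiates correctly", {
  set.seed(40)
  conv <- hssamnet:::hn_conv2d(2, 3, kernel = 3, stride = 2, dilation = 2,
                               pad = 2)
  x <- array(rnorm(9 * 9 * 2 * 2), c(9, 9, 2, 2))
  out <- conv$forward(hssamnet:::ag_const(x))$value
  w <- conv$params$weight$value
  b <- conv$params$bias$value
  # naive correlation with stride 2, dilation 2, pad 2
  oh <- dim(out)[1]
  for (n in 1:2) for (co in 1:3) for (i in 1:oh) for (j in 1:oh) {
    acc <- b[co]
    for (ci in 1:2) for (kr in 1:3) for (kc in 1:3) {
      r <- (i - 1) * 2 - 2 + (kr - 1) * 2 + 1
      cc <- (j - 1) * 2 - 2 + (kc - 1) * 2 + 1
      if (r >= 1 && r <= 9 && cc >= 1 && cc <= 9)
        acc <- acc + x[r, cc, ci, n] * w[kr, kc, ci, co]
    }
    expect_equal(out[i, j, co, n], acc, tolerance = 1e-12)
  }
  xp <- hssamnet:::ag_param(x)
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_relu(conv$forward(xp))), xp)
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_relu(conv$forward(xp))), conv$params$weight)
})

test_that("depthwise convolution agrees with the grouped im2col path", {
  set.seed(41)
  dw <- hssamnet:::hn_conv2d(4, 4, kernel = 3, groups = 4, dilation = 2)
  x <- array(rnorm(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  got <- dw$forward(hssamnet:::ag_const(x))$value
  want <- hssamnet:::cpp_conv2d(x, dw$params$weight$value, dw$params$bias$value,
                                1L, 1L, 2L, 2L, 2L, 2L, 4L)
  expect_equal(got, want, tolerance = 1e-12)
  xp <- hssamnet:::ag_param(x)
  fd_check(function() hssamnet:::ag_mean(dw$forward(xp)), xp)
  fd_check(function() hssamnet:::ag_mean(dw$forward(xp)), dw$params$weight)
})

test_that("batch normalisation normalises and differentiates through the stats", {
  set.seed(42)
  bn <- hssamnet:::hn_batchnorm(3)
  x <- array(rnorm(6 * 6 * 3 * 4, mean = 2, sd = 3), c(6, 6, 3, 4))
  xp <- hssamnet:::ag_param(x)
  out <- bn$forward(xp, training = TRUE)
  for (c in 1:3) {
    v <- out$value[, , c, ]
    expect_equal(mean(v), 0, tolerance = 1e-8)
    expect_equal(mean(v^2), 1, tolerance = 1e-3) # eps-shifted unit variance
  }
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_sigmoid(bn$forward(xp, training = TRUE))), xp, tol = 1e-3)
  # eval mode uses the running statistics
  out_eval <- bn$forward(xp, training = FALSE)
  expect_false(isTRUE(all.equal(out$value, out_eval$value)))
})

test_that("resize, pooling and unpooling operators differentiate correctly", {
  set.seed(43)
  x <- array(rnorm(8 * 8 * 2 * 2), c(8, 8, 2, 2))
  xp <- hssamnet:::ag_param(x)
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_bilinear(xp, 5, 11)), xp)
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_adaptive_avg(xp, 3, 3)), xp)
  fd_check(function() hssamnet:::ag_mean(
    hssamnet:::ag_scalar_mul(hssamnet:::ag_adaptive_max(xp, 3, 3), 2)), xp)
  fd_check(function() hssamnet:::ag_mean(hssamnet:::ag_maxpool2(xp)), xp)
  fd_check(function() {
    p <- hssamnet:::ag_maxdiag_pool(xp)
    u <- hssamnet:::ag_maxdiag_unpool(p$max, p$diag, p$max_idx, p$diag_idx, 8, 8)
    hssamnet:::ag_mean(hssamnet:::ag_sigmoid(u))
  }, xp, tol = 1e-3)
})

test_that("the segmentation loss gradient matches finite differences", {
  set.seed(44)
  v <- array(rnorm(6 * 6 * 1 * 2), c(6, 6, 1, 2))
  y <- array((runif(72) > 0.5) * 1, c(6, 6, 1, 2))
  vp <- hssamnet:::ag_param(v)
  fd_check(function() hssamnet:::ag_seg_loss(vp, y), vp, tol = 1e-5)
  # degenerate all-background target stays finite
  l0 <- hssamnet:::ag_seg_loss(hssamnet:::ag_const(v), array(0, dim(v)))
  expect_true(is.finite(l0$value))
})

test_that("the optimisers apply their update rules", {
  p <- hssamnet:::ag_param(array(1, c(2, 1, 1, 1)))
  p$grad <- array(c(0.5, -0.5), c(2, 1, 1, 1))
  opt <- hssamnet:::hn_optimizer(list(p), type = "sgd", lr = 0.1, momentum = 0)
  opt$step()
  expect_equal(as.numeric(p$value), c(1 - 0.05, 1 + 0.05))
  q <- hssamnet:::ag_param(array(0, c(1, 1, 1, 1)))
  q$grad <- array(2, c(1, 1, 1, 1))
  ad <- hssamnet:::hn_optimizer(list(q), type = "adam", lr = 0.1)
  ad$step()
  # first Adam step moves by ~lr regardless of gradient scale
  expect_equal(as.numeric(q$value), -0.1, tolerance = 1e-6)
})
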
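small_cfg <- function(variant = "M4", ...) {
  network_config(variant = variant, stage_channels = c(4L, 6L, 8L, 10L, 12L),
                 seed = 11L, ...)
}

test_that("variant presets force the module flag combinations", {
  flags <- function(cfg) c(cfg$enable_maxdp, cfg$enable_maxdup,
                           cfg$enable_lab, cfg$enable_pra)
  expect_equal(flags(network_config(variant = "M1")), rep(FALSE, 4))
  expect_equal(flags(network_config(variant = "M2")), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(flags(network_config(variant = "M3")), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(flags(network_config(variant = "M4")), rep(TRUE, 4))
  expect_error(network_config(variant = NULL, enable_maxdup = TRUE,
                              enable_maxdp = FALSE), "configuration error")
})

test_that("forward produces probabilities of the input size, batched or not", {
  m <- build_network(small_cfg())
  out <- net_forward(m, array(runif(64 * 64 * 3), c(64, 64, 3)))
  expect_equal(dim(out$probabilities), c(64, 64))
  expect_true(all(out$probabilities >= 0 & out$probabilities <= 1))
  expect_identical(out$binary_mask, out$probabilities >= 0.5)
  ns <- net_forward(m, array(runif(96 * 64 * 3), c(96, 64, 3)))
  expect_equal(dim(ns$probabilities), c(96, 64))
  odd <- net_forward(m, array(runif(50 * 70 * 3), c(50, 70, 3))) # pad-and-crop
  expect_equal(dim(odd$probabilities), c(50, 70))
  expect_error(net_forward(m, array(0, c(64, 64, 4))), "3 channels")
})

test_that("builds are seeded: same seed, bit-identical parameters and output", {
  a <- build_network(small_cfg())
  b <- build_network(small_cfg())
  pa <- hssamnet:::hn_params(a$root)
  pb <- hssamnet:::hn_params(b$root)
  expect_identical(names(pa), names(pb))
  for (nm in names(pa)) expect_identical(pa[[nm]]$value, pb[[nm]]$value)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(net_forward(a, x)$probabilities,
                   net_forward(b, x)$probabilities)
  expect_identical(net_forward(a, x)$probabilities,
                   net_forward(a, x)$probabilities) # inference determinism
})

test_that("parameter counting is exact and monotone across ablation variants", {
  conv1 <- hssamnet:::hn_conv2d(1, 1, kernel = 1)
  expect_equal(param_count(conv1), 2L) # 1 weight + 1 bias
  conv3 <- hssamnet:::hn_conv2d(128, 128, kernel = 3)
  expect_equal(param_count(conv3), 147584L) # 3*3*128*128 + 128
  counts <- vapply(c("M1", "M2", "M3", "M4"), function(v)
    param_count(build_network(small_cfg(variant = v))), numeric(1))
  expect_true(all(diff(counts) >= 0))
  bd <- param_breakdown(build_network(small_cfg()))
  expect_equal(bd$total, unname(counts["M4"]))
})

test_that("the default full network stays under the lightweight budget", {
  n <- param_count(build_network(network_config()))
  expect_lt(n, 2e6)
})

test_that("wiring: dual sampling layers are paired and the deepest stage is direct", {
  m <- build_network(small_cfg())
  expect_equal(m$wiring$n_maxdp, 4L)
  expect_equal(m$wiring$n_maxdup, 4L)
  expect_true(m$wiring$deepest_stage_direct)
  expect_length(m$hssam, 4L) # no aggregation module for the deepest stage
  m1 <- build_network(small_cfg(variant = "M1"))
  expect_equal(m1$wiring$n_maxdp, 0L)
  expect_equal(m1$wiring$n_pra, 0L)
  expect_true(all(vapply(m1$hssam, is.null, logical(1))))
  # each unpooling consumes the indices of the matching stage's pooling:
  # corrupting a stage's pooled indices must change the output
  x <- hssamnet:::ag_const(array(runif(32 * 32 * 3), c(32, 32, 3, 1)))
  ref <- hssamnet:::network_forward(m, x, collect = TRUE)
  expect_length(ref$pools, 4L)
  for (i in 1:4)
    expect_equal(dim(ref$pools[[i]]$max$value)[1], 32 / 2^i)
})

test_that("gradient reaches essentially every parameter in one backward pass", {
  # default widths: at toy widths the tiny descriptor grids of the channel
  # attention can have fully blocked ReLU paths
  m <- build_network(network_config(variant = "M4", seed = 11L))
  x <- hssamnet:::ag_const(array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2)))
  y <- array((runif(64 * 64 * 2) > 0.6) * 1, c(64, 64, 1, 2))
  params <- hssamnet:::hn_params(m$root)
  logits <- hssamnet:::network_forward(m, x, training = TRUE)
  loss <- hssamnet:::ag_seg_loss(logits, y)
  hssamnet:::ag_backward(loss)
  total <- sum(vapply(params, function(p) length(p$value), numeric(1)))
  nonzero <- sum(vapply(params, function(p)
    if (is.null(p$grad)) 0 else sum(p$grad != 0), numeric(1)))
  expect_gte(nonzero / total, 0.99)
})

test_that("the attention gate modulates the combined skip feature", {
  set.seed(50)
  af <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  f <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  gate <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  # zero-initialised projections: coefficients are exactly sigmoid(0) = 0.5
  zmod <- attention_gate_module(4, 6, zero_init = TRUE)
  out0 <- attention_gate(af, f, gate, zmod)
  expect_equal(out0, (af + f) * 0.5)
  mod <- attention_gate_module(4, 6, seed = 2)
  out <- attention_gate(af, f, gate, mod)
  expect_equal(dim(out), dim(f))
  # coefficients lie in (0, 1): the gated feature never exceeds the skip
  expect_true(all(abs(out) <= abs(af + f) + 1e-12))
  expect_true(all(sign(out) == sign(af + f) | out == 0))
  expect_error(attention_gate(af, array(0, c(6, 6, 4)), gate), "aligned")
})

test_that("checkpoints restore configuration, parameters and statistics", {
  m <- build_network(small_cfg(variant = "M3"))
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  expect_equal(m2$cfg$variant, "M3")
  expect_identical(net_forward(m, x)$probabilities,
                   net_forward(m2, x)$probabilities)
  unlink(ck)
})
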
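test_that("shift ratio is exactly 1/2^z and halves as z increments", {
  expect_equal(shift_ratio(1), 0.5)
  expect_equal(shift_ratio(3), 0.125)
  for (z in 1:6) expect_equal(shift_ratio(z + 1), shift_ratio(z) / 2)
  expect_error(shift_ratio(0), "integer")
  expect_error(shift_ratio(1.5), "integer")
})

test_that("receptive field matches the impulse-influence oracle", {
  expect_equal(receptive_field(list(conv_layer_spec(3))), 3L)
  expect_equal(receptive_field(list(conv_layer_spec(3), conv_layer_spec(3))), 5L)
  expect_equal(receptive_field(list(conv_layer_spec(3, stride = 2),
                                    conv_layer_spec(3))), 7L)
  expect_error(receptive_field(list()), "non-empty")
  set.seed(10)
  for (k in 1:50) {
    depth <- sample(1:4, 1)
    layers <- lapply(seq_len(depth), function(i)
      conv_layer_spec(sample(c(1, 3, 5), 1), sample(1:2, 1), sample(1:3, 1)))
    expect_identical(receptive_field(layers), oracle_receptive_field(layers),
                     info = paste("stack", k))
  }
})

test_that("the literal recursion disagrees with the oracle when strides > 1", {
  layers <- list(conv_layer_spec(3, stride = 2), conv_layer_spec(3))
  expect_equal(receptive_field(layers), 7L)
  expect_false(receptive_field(layers, literal = TRUE) ==
                 oracle_receptive_field(layers))
})

test_that("shift feasibility follows the stated inequality", {
  expect_true(shift_feasible(3, shift_spec(L = 32, z = 1, L_rm = 0)))
  expect_false(shift_feasible(0, shift_spec(L = 32, z = 1, L_rm = 4)))
  # monotone non-increasing in z for fixed everything else
  vals <- vapply(1:6, function(z)
    shift_feasible(2, shift_spec(L = 16, z = z, L_rm = 8, psi = 4)), logical(1))
  expect_true(all(diff(as.integer(vals)) <= 0))
})

test_that("narrow crops have the stated geometry and jointly cover the map", {
  f <- matrix(seq_len(64), 8, 8)
  ul <- narrow(f, 0.5, "up-left")
  expect_equal(dim(ul), c(4, 4))
  expect_equal(ul, f[1:4, 1:4])
  expect_equal(narrow(f, 0.5, "down-right"), f[5:8, 5:8])
  expect_equal(narrow(f, 0, "center"), f) # degenerate zero shift
  expect_error(narrow(matrix(1, 1, 1), 0.5), "smaller than one pixel")
  # the five submaps are complementary: their footprints cover every cell
  for (z in 1:3) {
    theta <- shift_ratio(z)
    for (n in c(8L, 16L)) {
      cov <- matrix(FALSE, n, n)
      for (v in hssamnet:::.narrow_variants) {
        wnd <- hssamnet:::narrow_window(n, n, theta, v)
        cov[wnd$row0:wnd$row1, wnd$col0:wnd$col1] <- TRUE
      }
      expect_true(all(cov), info = paste("z =", z, "n =", n))
    }
  }
})

test_that("msea pre-bottleneck sum equals the adaptive-max oracle", {
  set.seed(11)
  a <- matrix(rnorm(64 * 64), 64, 64)
  b <- matrix(rnorm(32 * 32), 32, 32)
  got <- msea(list(a, b), 16, 16)
  want <- oracle_adaptive_max(a, 16, 16) + oracle_adaptive_max(b, 16, 16)
  expect_equal(got, want)
  # summation is permutation invariant
  expect_equal(msea(list(b, a), 16, 16), got)
  expect_error(msea(list(), 4, 4), "non-empty")
  expect_error(msea(list(array(0, c(8, 8, 2)), array(0, c(8, 8, 3))), 4, 4),
               "channel count")
})

test_that("ssam sums the five averaged submaps and falls back when infeasible", {
  f <- matrix(4, 16, 16)
  spec <- shift_spec(16, z = 1)
  out <- ssam(f, spec, 8, 8)
  expect_equal(out, matrix(20, 8, 8)) # constant input: 5 * v everywhere
  bad <- shift_spec(16, z = 1, L_rm = 16, psi = 1e6)
  expect_warning(out2 <- ssam(f, bad, 8, 8), "infeasible")
  expect_equal(out2, matrix(4, 8, 8)) # center submap only
})

test_that("hssam aggregation has the stage size, shares one bottleneck and is deterministic", {
  set.seed(12)
  feats <- list(array(rnorm(32 * 32 * 4), c(32, 32, 4)),
                array(rnorm(16 * 16 * 8), c(16, 16, 8)),
                array(rnorm(8 * 8 * 16), c(8, 8, 16)))
  mod <- hssam_module(4, 8, seed = 3)
  af1 <- hssam_forward(1, feats, mod)
  expect_equal(dim(af1), c(32, 32, 4))
  expect_identical(af1, hssam_forward(1, feats, mod)) # bit-identical repeat
  expect_error(hssam_forward(3, feats), "decoder directly")
  # exactly one shared bottleneck parameter set regardless of five submaps
  nconv <- sum(vapply(hssamnet:::hn_params(mod), function(p)
    length(dim(p$value)) == 4L, logical(1)))
  expect_equal(nconv, 2L) # stage projection + the shared bottleneck
})

test_that("disabling the shifted-submap path reduces hssam to the MSEA path", {
  set.seed(13)
  feats <- list(array(rnorm(16 * 16 * 3), c(16, 16, 3)),
                array(rnorm(8 * 8 * 5), c(8, 8, 5)))
  on <- hssam_module(3, 5, seed = 9, enable_ssam = TRUE)
  off <- hssam_module(3, 5, seed = 9, enable_ssam = FALSE)
  a_on <- hssam_forward(1, feats, on)
  a_off <- hssam_forward(1, feats, off)
  expect_false(isTRUE(all.equal(a_on, a_off)))
  # the MSEA-only output equals bottleneck(maxpool(f1) + maxpool(proj(f2)))
  ag_const <- hssamnet:::ag_const
  f1 <- ag_const(array(feats[[1]], c(16, 16, 3, 1)))
  f2 <- ag_const(array(feats[[2]], c(8, 8, 5, 1)))
  pn <- off$children$proj_next$forward(f2)
  pre <- hssamnet:::ag_add(hssamnet:::ag_adaptive_max(f1, 16, 16),
                           hssamnet:::ag_adaptive_max(pn, 16, 16))
  want <- off$children$bottleneck$forward(pre)$value[, , , 1]
  expect_equal(a_off, want)
})
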
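mk <- function(v, h = 4, w = 4) matrix(as.logical(v), h, w, byrow = TRUE)

test_that("dice follows the overlap formula and its conventions", {
  a <- mk(c(1, 1, 0, 0, rep(0, 12)))
  expect_equal(dice(a, a), 1)
  b <- mk(c(0, 0, 1, 1, rep(0, 12)))
  expect_equal(dice(a, b), 0)
  # |pred| = 3, |gt| = 3, intersection 2 -> 2*2/6
  p <- mk(c(1, 1, 1, 0, rep(0, 12)))
  g <- mk(c(1, 1, 0, 1, rep(0, 12)))
  expect_equal(dice(p, g), 2 / 3)
  expect_equal(dice(mk(rep(0, 16)), mk(rep(0, 16))), 1) # both empty
  expect_error(dice(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "match")
})

test_that("hd95 measures boundary distances symmetrically", {
  m <- matrix(FALSE, 9, 9); m[4:6, 4:6] <- TRUE
  expect_equal(hd95(m, m), 0)
  a <- matrix(FALSE, 3, 11); a[2, 2] <- TRUE
  b <- matrix(FALSE, 3, 11); b[2, 7] <- TRUE
  expect_equal(hd95(a, b), 5)
  expect_equal(hd95(b, a), 5) # symmetric by the outer max
  # empty-mask conventions
  e <- matrix(FALSE, 3, 11)
  expect_equal(hd95(e, e), 0)
  expect_equal(hd95(e, b), sqrt(3^2 + 11^2))
  expect_equal(hd95(e, b, empty_penalty = 42), 42)
})

test_that("miou averages foreground and background IoU", {
  p <- mk(c(1, 1, 0, 0, rep(0, 12)))
  g <- mk(c(1, 0, 1, 0, rep(0, 12)))
  # tp=1 fp=1 fn=1 tn=13: fg 1/3, bg 13/15
  expect_equal(miou(p, g), (1 / 3 + 13 / 15) / 2)
  expect_equal(miou(p, p), 1)
  # complement prediction on a half-filled mask: foreground IoU is 0
  h <- matrix(FALSE, 4, 4); h[, 1:2] <- TRUE
  expect_equal(miou(!h, h), 0 / 2) # bg IoU is 0 too: mean 0
})

test_that("mae is the mean absolute per-pixel difference", {
  g <- mk(c(rep(1, 4), rep(0, 12)))
  expect_equal(mae(g, g), 0)
  p <- mk(c(rep(1, 3), rep(0, 13)))
  expect_equal(mae(p, g), 1 / 16) # differs in one of 16 pixels
  expect_equal(mae(matrix(0.5, 4, 4), g), 0.5)
})

test_that("confusion metrics match the hand-counted toy table", {
  # tp=2 fp=1 fn=1 tn=12
  p <- mk(c(1, 1, 1, 0, rep(0, 12)))
  g <- mk(c(1, 1, 0, 1, rep(0, 12)))
  cm <- confusion_metrics(p, g)
  expect_equal(cm$ppv, 2 / 3)
  expect_equal(cm$tpr, 2 / 3)
  expect_equal(cm$acc, 14 / 16)
  expect_equal(cm$tnr, 12 / 13)
  ident <- confusion_metrics(g, g)
  expect_equal(unlist(ident), c(acc = 1, ppv = 1, tpr = 1, tnr = 1))
  # all-background prediction
  none <- mk(rep(0, 16))
  cm2 <- confusion_metrics(none, g)
  expect_equal(cm2$acc, 13 / 16)
  expect_equal(cm2$tpr, 0)
  expect_equal(cm2$tnr, 1)
})

test_that("metrics agree with the set-arithmetic oracle on random pairs", {
  set.seed(30)
  for (k in 1:30) {
    p <- matrix(runif(256) > runif(1, 0.3, 0.7), 16, 16)
    g <- matrix(runif(256) > runif(1, 0.3, 0.7), 16, 16)
    o <- oracle_metrics(p, g)
    expect_equal(dice(p, g), o$dice, tolerance = 1e-12)
    expect_equal(miou(p, g), o$miou, tolerance = 1e-12)
    expect_equal(mae(p, g), o$mae, tolerance = 1e-12)
    cm <- confusion_metrics(p, g)
    expect_equal(cm$acc, o$acc, tolerance = 1e-12)
    expect_equal(cm$ppv, o$ppv, tolerance = 1e-12)
    expect_equal(cm$tpr, o$tpr, tolerance = 1e-12)
    expect_equal(cm$tnr, o$tnr, tolerance = 1e-12)
    # Dice and foreground IoU satisfy dice = 2 iou / (1 + iou)
    iou_fg <- unname(o$counts["tp"]) / sum(o$counts[c("tp", "fp", "fn")])
    if (is.finite(iou_fg))
      expect_equal(o$dice, 2 * iou_fg / (1 + iou_fg), tolerance = 1e-12)
    if (sum(p) > 0 && sum(g) > 0)
      expect_equal(hd95(p, g), oracle_hd95(p, g), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to a common translation", {
  set.seed(31)
  p <- matrix(FALSE, 16, 16); p[4:8, 5:9] <- matrix(runif(25) > 0.4, 5, 5)
  g <- matrix(FALSE, 16, 16); g[4:9, 4:9] <- matrix(runif(36) > 0.5, 6, 6)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    out[(1 + dr):16, (1 + dc):16] <- m[1:(16 - dr), 1:(16 - dc)]
    out
  }
  ps <- shift(p, 3, 2); gs <- shift(g, 3, 2)
  expect_equal(dice(ps, gs), dice(p, g))
  expect_equal(miou(ps, gs), miou(p, g))
  expect_equal(hd95(ps, gs), hd95(p, g))
  expect_equal(unlist(confusion_metrics(ps, gs)), unlist(confusion_metrics(p, g)))
})

test_that("seg_metrics thresholds probabilities and reports all eight values", {
  set.seed(32)
  g <- matrix(FALSE, 8, 8); g[3:6, 3:6] <- TRUE
  prob <- ifelse(g, 0.9, 0.1) + rnorm(64, 0, 0.02)
  row <- seg_metrics(prob, g)
  expect_named(row, c("dice", "miou", "hd95", "mae", "acc", "ppv", "tpr", "tnr"))
  expect_equal(row$dice, 1)
  expect_true(row$mae > 0 && row$mae < 0.2)
  rep <- metrics_report(rbind(row, row))
  expect_equal(nrow(rep), 4) # two images + mean + sd rows
  expect_equal(rep$dice[rep$id == "mean"], 1)
  expect_equal(rep$dice[rep$id == "sd"], 0)
  tmp <- tempfile(fileext = ".csv")
  write_metrics(rep, csv = tmp)
  expect_true(file.exists(tmp))
  expect_equal(nrow(utils::read.csv(tmp)), 4)
})
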
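test_that("warmup ramps linearly from lr/steps to lr exactly", {
  expect_equal(warmup_schedule(0, 10, 0.5), 0.05)
  expect_equal(warmup_schedule(4, 10, 0.5), 0.25)
  expect_equal(warmup_schedule(9, 10, 0.5), 0.5)
  expect_equal(warmup_schedule(50, 10, 0.5), 0.5)
  expect_equal(warmup_schedule(0, 0, 0.5), 0.5) # no warmup configured
})

test_that("training runs, logs and is reproducible under a fixed seed", {
  ds <- tiny_dataset()
  cfg <- tiny_cfg(seed = 5L)
  r1 <- train(cfg, ds)
  expect_s3_class(r1, "train_result")
  expect_named(r1$log, c("epoch", "lr", "train_loss", "val_loss", "val_dice"))
  expect_equal(nrow(r1$log), 2)
  expect_true(all(is.finite(r1$log$train_loss)))
  r2 <- train(cfg, ds)
  p1 <- hssamnet:::hn_params(r1$model$root)
  p2 <- hssamnet:::hn_params(r2$model$root)
  for (nm in names(p1)) expect_identical(p1[[nm]]$value, p2[[nm]]$value)
  expect_identical(r1$log, r2$log)
})

test_that("a zero learning rate exhausts early-stopping patience unchanged", {
  ds <- tiny_dataset()
  cfg <- tiny_cfg(learning_rate = 0, epochs = 10L, patience = 2L, seed = 3L)
  init <- build_network(network_config(variant = cfg$variant,
                                       stage_channels = cfg$stage_channels,
                                       seed = cfg$seed))
  ref <- lapply(hssamnet:::hn_params(init$root), function(p) p$value)
  res <- train(cfg, ds)
  # patience is exhausted before the epoch budget (batch-norm statistics
  # still drift between epochs, so the best epoch need not be the first)
  expect_lt(nrow(res$log), 10)
  got <- lapply(hssamnet:::hn_params(res$model$root), function(p) p$value)
  expect_identical(got, ref)
})

test_that("evaluation reports per-image rows whose mean matches the summary", {
  ds <- tiny_dataset()
  res <- train(tiny_cfg(seed = 2L), ds)
  rep <- evaluate(res, ds, split = "test")
  per_image <- rep[!(rep$id %in% c("mean", "sd")), ]
  expect_equal(mean(per_image$dice), rep$dice[rep$id == "mean"])
  expect_equal(mean(per_image$hd95), rep$hd95[rep$id == "mean"])
  expect_error(evaluate(res, list(samples = ds$samples,
                                  split = rep("train", length(ds$samples))),
                        split = "test"), "empty")
})

test_that("protocols partition and aggregate correctly", {
  ds <- tiny_dataset()
  cfg <- tiny_cfg(seed = 4L, n_runs = 2L, k_folds = 3L, epochs = 1L)
  pr <- run_protocol(cfg, "repeat", ds)
  expect_equal(nrow(pr$runs), 2)
  expect_true(all(is.finite(pr$mean)))
  kf <- run_protocol(cfg, "kfold", ds)
  expect_equal(nrow(kf$runs), 3)
  expect_equal(length(kf$folds), length(ds$samples))
  expect_equal(sort(unique(kf$folds)), 1:3) # disjoint cover of all samples
  cd <- run_protocol(cfg, "cross_dataset", ds, data_b = ds)
  expect_equal(nrow(cd$runs), 1)
  # training on A and testing on B = A equals a plain evaluation on all of A
  res <- train(cfg, ds)
  rep <- evaluate(res, ds, split = "all")
  expect_equal(unname(unlist(cd$runs[1, ])),
               unname(unlist(rep[rep$id == "mean",
                                 c("dice", "miou", "hd95", "mae",
                                   "acc", "ppv", "tpr", "tnr")])))
})

test_that("run configurations round-trip through YAML and reject unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("batch_size: 2", "learning_rate: 0.002", "epochs: 3",
               "variant: M2", "image_size: [32, 32]"), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$batch_size, 2L)
  expect_equal(cfg$learning_rate, 0.002)
  expect_equal(cfg$variant, "M2")
  writeLines("nonsense_key: 1", path)
  expect_error(load_run_config(path), "unknown configuration keys")
  unlink(path)
})

test_that("overlays follow the white/pink/red convention", {
  img <- array(0.3, c(4, 4, 3))
  gt <- matrix(FALSE, 4, 4); gt[2:3, 2:3] <- TRUE
  # perfect prediction: no red anywhere
  ov <- render_overlay(img, gt, gt)
  areas <- attr(ov, "areas")
  expect_equal(unname(areas["wrong"]), 0)
  expect_equal(unname(areas["tp"]), 4)
  red <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 0
  expect_false(any(red))
  # missing prediction: the whole ground truth is painted red
  ov2 <- render_overlay(img, gt, matrix(FALSE, 4, 4))
  expect_equal(unname(attr(ov2, "areas")["wrong"]), sum(gt))
  red2 <- ov2[, , 1] == 1 & ov2[, , 2] == 0 & ov2[, , 3] == 0
  expect_equal(sum(red2), sum(gt))
  # toy confusion: pink pixels = TP, red pixels = FP + FN
  pred <- matrix(FALSE, 4, 4); pred[2, 2:4] <- TRUE # tp=2, fp=1, fn=2
  ov3 <- render_overlay(img, gt, pred)
  a3 <- attr(ov3, "areas")
  expect_equal(unname(a3["tp"]), 2)
  expect_equal(unname(a3["wrong"]), 3)
  pink <- ov3[, , 1] == 1 & ov3[, , 2] == 0.6 & ov3[, , 3] == 0.8
  expect_equal(sum(pink), 2)
  expect_error(render_overlay(img, gt, matrix(FALSE, 5, 5)), "match")
})
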
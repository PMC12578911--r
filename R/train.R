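# Configuration-driven training, evaluation, experiment protocols
# (repeated runs, k-fold cross-validation, cross-dataset transfer) and the
# ground-truth/prediction overlay renderer.

#' Run configuration
#'
#' @param manifest path to a dataset manifest CSV (optional when in-memory
#'   data is passed to [train()]).
#' @param image_size `(H, W)` the images and masks are resized to.
#' @param batch_size minibatch size.
#' @param learning_rate base learning rate.
#' @param epochs maximum number of epochs.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param early_stop stop when validation Dice stops improving.
#' @param patience epochs without improvement tolerated by early stopping.
#' @param min_delta minimum Dice improvement that counts.
#' @param warmup linearly ramp the learning rate over the first
#'   `warmup_frac` of all steps.
#' @param warmup_frac fraction of total steps used for warmup.
#' @param loss `"bce_dice"` (equally weighted, default), `"bce"` or
#'   `"dice"`.
#' @param seed run seed; all randomness (parameter init, shuffling) flows
#'   from it.
#' @param n_runs number of repetitions for the `repeat` protocol.
#' @param k_folds number of folds for the `kfold` protocol.
#' @param variant network ablation variant (see [network_config()]).
#' @param stage_channels network stage widths.
#' @param threshold binarisation threshold for predictions.
#' @param checkpoint optional path where the best checkpoint is written.
#' @export
run_config <- function(manifest = NULL, image_size = c(64L, 64L),
                       batch_size = 4L, learning_rate = 1e-3, epochs = 30L,
                       optimizer = c("adam", "sgd"), early_stop = TRUE,
                       patience = 10L, min_delta = 1e-4, warmup = TRUE,
                       warmup_frac = 0.05, loss = c("bce_dice", "bce", "dice"),
                       seed = 1L, n_runs = 1L, k_folds = NULL,
                       variant = "M4", stage_channels = c(6L, 12L, 24L, 48L, 96L),
                       threshold = 0.5, checkpoint = NULL) {
  optimizer <- match.arg(optimizer)
  loss <- match.arg(loss)
  stopifnot(learning_rate >= 0, batch_size >= 1L, epochs >= 1L)
  structure(list(manifest = manifest, image_size = as.integer(image_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, early_stop = early_stop,
                 patience = as.integer(patience), min_delta = min_delta,
                 warmup = warmup, warmup_frac = warmup_frac, loss = loss,
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 k_folds = if (is.null(k_folds)) NULL else as.integer(k_folds),
                 variant = variant, stage_channels = as.integer(stage_channels),
                 threshold = threshold, checkpoint = checkpoint),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [run_config()] defaults.
#'
#' @param path YAML file path.
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Warmup learning-rate schedule
#'
#' Linear ramp: at 0-based step `s` during warmup the learning rate is
#' `lr * (s + 1) / warmup_steps`; it reaches `lr` exactly at the end of
#' warmup and stays there.
#'
#' @param step 0-based optimisation step.
#' @param warmup_steps number of warmup steps.
#' @param lr target learning rate.
#' @export
warmup_schedule <- function(step, warmup_steps, lr) {
  if (warmup_steps <= 0L) return(lr)
  lr * pmin(1, (step + 1) / warmup_steps)
}

# nearest-neighbour resize for masks (and integer maps)
.nearest_resize <- function(m, oh, ow) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(h, pmax(1L, floor((seq_len(oh) - 0.5) * h / oh) + 1L))
  ci <- pmin(w, pmax(1L, floor((seq_len(ow) - 0.5) * w / ow) + 1L))
  m[ri, ci, drop = FALSE]
}

# stack samples into (H, W, 3, N) images and (H, W, 1, N) targets at the
# configured size
.prepare_batchable <- function(samples, image_size) {
  n <- length(samples)
  h <- image_size[1]; w <- image_size[2]
  x <- array(0, dim = c(h, w, 3L, n))
  y <- array(0, dim = c(h, w, 1L, n))
  for (i in seq_len(n)) {
    img <- samples[[i]]$image
    if (!identical(dim(img)[1:2], c(h, w)))
      img <- bilinear_resize(img, h, w)
    x[, , , i] <- img
    msk <- samples[[i]]$mask
    if (!identical(dim(msk), c(h, w)))
      msk <- .nearest_resize(msk, h, w)
    y[, , 1, i] <- msk
  }
  list(x = x, y = y)
}

.loss_weights <- function(loss) {
  switch(loss,
         bce_dice = c(0.5, 0.5),
         bce = c(1, 0),
         dice = c(0, 1))
}

#' Train a segmentation network
#'
#' Trains the configured ablation variant with the configured optimiser and
#' learning-rate schedule (linear warmup, optional early stopping on
#' validation Dice), keeping the parameters of the best validation epoch.
#' All randomness flows from `cfg$seed`.
#'
#' @param cfg a [run_config()].
#' @param data in-memory dataset from [generate_samples()] /
#'   [load_manifest()]; when `NULL`, `cfg$manifest` is loaded.
#' @param verbose print per-epoch progress.
#' @return a list of class `train_result`: the trained `model`, the per-epoch
#'   `log` data frame (epoch, lr, train_loss, val_loss, val_dice), and
#'   `best_epoch`.
#' @export
train <- function(cfg, data = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(data)) {
    if (is.null(cfg$manifest)) stop("no data: provide 'data' or cfg$manifest")
    data <- load_manifest(cfg$manifest)
  }
  tr_idx <- which(data$split == "train")
  va_idx <- which(data$split == "val")
  if (!length(tr_idx)) stop("empty training split")
  if (!length(va_idx)) stop("empty validation split")
  tr <- .prepare_batchable(data$samples[tr_idx], cfg$image_size)
  va <- .prepare_batchable(data$samples[va_idx], cfg$image_size)
  net_cfg <- network_config(variant = cfg$variant,
                            stage_channels = cfg$stage_channels,
                            threshold = cfg$threshold, seed = cfg$seed)
  model <- build_network(net_cfg)
  params <- hn_params(model$root)
  opt <- hn_optimizer(params, type = cfg$optimizer, lr = cfg$learning_rate)
  lw <- .loss_weights(cfg$loss)
  n_tr <- length(tr_idx)
  steps_per_epoch <- ceiling(n_tr / cfg$batch_size)
  total_steps <- cfg$epochs * steps_per_epoch
  wsteps <- if (cfg$warmup) max(1L, round(cfg$warmup_frac * total_steps)) else 0L
  set.seed(cfg$seed + 1L)
  log <- data.frame()
  best <- list(dice = -Inf, epoch = 0L, values = NULL, bn = NULL)
  wait <- 0L
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr, n_tr)
    ep_loss <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1L) * cfg$batch_size + 1L):min(b * cfg$batch_size, n_tr)]
      xb <- ag_const(tr$x[, , , idx, drop = FALSE])
      yb <- tr$y[, , , idx, drop = FALSE]
      logits <- network_forward(model, xb, training = TRUE)
      loss_t <- ag_seg_loss(logits, yb, w_bce = lw[1], w_dice = lw[2])
      if (!is.finite(loss_t$value))
        stop("non-finite loss at epoch ", epoch, ", step ", b,
             " (learning rate ", cfg$learning_rate, "); aborting")
      ag_zero_grad(params)
      ag_backward(loss_t)
      opt$step(warmup_schedule(step, wsteps, cfg$learning_rate))
      step <- step + 1L
      ep_loss <- ep_loss + loss_t$value * length(idx)
    }
    ep_loss <- ep_loss / n_tr
    vl <- .validate(model, va, lw)
    log <- rbind(log, data.frame(epoch = epoch,
                                 lr = warmup_schedule(step - 1L, wsteps,
                                                      cfg$learning_rate),
                                 train_loss = ep_loss, val_loss = vl$loss,
                                 val_dice = vl$dice))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  dice %.4f",
                      epoch, ep_loss, vl$loss, vl$dice))
    if (vl$dice > best$dice + cfg$min_delta) {
      best$dice <- vl$dice
      best$epoch <- epoch
      best$values <- lapply(params, function(p) p$value)
      best$bn <- lapply(hn_bn_states(model$root), function(s)
        list(running_mean = s$running_mean, running_var = s$running_var))
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (cfg$early_stop && wait >= cfg$patience) break
    }
  }
  if (!is.null(best$values)) {
    for (nm in names(params)) params[[nm]]$value <- best$values[[nm]]
    states <- hn_bn_states(model$root)
    for (nm in names(states)) {
      states[[nm]]$running_mean <- best$bn[[nm]]$running_mean
      states[[nm]]$running_var <- best$bn[[nm]]$running_var
    }
  }
  if (!is.null(cfg$checkpoint)) save_checkpoint(model, cfg$checkpoint)
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 best_val_dice = best$dice, cfg = cfg),
            class = "train_result")
}

.validate <- function(model, va, lw) {
  logits <- network_forward(model, ag_const(va$x), training = FALSE)
  loss <- ag_seg_loss(logits, va$y, w_bce = lw[1], w_dice = lw[2])$value
  probs <- 1 / (1 + exp(-logits$value))
  n <- dim(va$x)[4]
  dices <- vapply(seq_len(n), function(i)
    dice(probs[, , 1, i] >= 0.5, va$y[, , 1, i] > 0.5), numeric(1))
  list(loss = loss, dice = mean(dices))
}

#' Evaluate a model on one split of a dataset
#'
#' Computes the full metric suite per image plus mean and standard-deviation
#' summary rows.
#'
#' @param model an `hn_network`, a `train_result`, or a checkpoint path.
#' @param data in-memory dataset or manifest path.
#' @param split which split to evaluate (`"test"`, `"val"`, `"train"` or
#'   `"all"`).
#' @param image_size size images are resized to before the forward pass;
#'   metrics are computed at this prediction resolution.
#' @param csv,json optional output paths for the report.
#' @return the report data frame from [metrics_report()].
#' @export
evaluate <- function(model, data, split = "test", image_size = c(64L, 64L),
                     csv = NULL, json = NULL) {
  if (inherits(model, "train_result")) {
    image_size <- model$cfg$image_size
    model <- model$model
  }
  if (is.character(model)) model <- load_checkpoint(model)
  if (is.character(data)) data <- load_manifest(data)
  idx <- if (identical(split, "all")) seq_along(data$samples)
         else which(data$split == split)
  if (!length(idx)) stop("split '", split, "' is empty")
  pb <- .prepare_batchable(data$samples[idx], image_size)
  rows <- data.frame()
  for (i in seq_along(idx)) {
    out <- net_forward(model, pb$x[, , , i, drop = FALSE])
    rows <- rbind(rows, seg_metrics(out$probabilities, pb$y[, , 1, i] > 0.5,
                                    threshold = model$cfg$threshold))
  }
  rep <- metrics_report(rows, id = as.character(idx))
  write_metrics(rep, csv = csv, json = json)
  rep
}

#' Run an experiment protocol
#'
#' * `repeat`: `cfg$n_runs` independent seeded runs on the same train/val/
#'   test split; reports per-run test means and their mean and sd.
#' * `kfold`: seeded disjoint partition into `cfg$k_folds` folds; each fold
#'   serves once as the test set (one tenth of the remaining samples is held
#'   out for validation).
#' * `cross_dataset`: train on `data`'s training split, evaluate on the
#'   whole of `data_b`.
#'
#' @param cfg a [run_config()].
#' @param mode `"repeat"`, `"kfold"` or `"cross_dataset"`.
#' @param data primary dataset (in-memory or manifest path); defaults to
#'   `cfg$manifest`.
#' @param data_b transfer target dataset for `cross_dataset`.
#' @param verbose forwarded to [train()].
#' @return a list of class `protocol_result` with `runs` (per-run metric
#'   means), `mean`, `sd`, and fold assignments when applicable.
#' @export
run_protocol <- function(cfg, mode = c("repeat", "kfold", "cross_dataset"),
                         data = NULL, data_b = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(data)) {
    if (is.null(cfg$manifest)) stop("no data: provide 'data' or cfg$manifest")
    data <- load_manifest(cfg$manifest)
  }
  if (is.character(data)) data <- load_manifest(data)
  metric_cols <- c("dice", "miou", "hd95", "mae", "acc", "ppv", "tpr", "tnr")
  run_means <- list()
  folds <- NULL
  if (mode == "repeat") {
    for (r in seq_len(cfg$n_runs)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + (r - 1L)
      res <- train(cfg_r, data, verbose = verbose)
      rep <- evaluate(res, data, split = "test")
      run_means[[r]] <- rep[rep$id == "mean", metric_cols]
    }
  } else if (mode == "kfold") {
    k <- cfg$k_folds %||% 5L
    n <- length(data$samples)
    if (k > n) stop("more folds than samples")
    set.seed(cfg$seed)
    folds <- sample(rep(seq_len(k), length.out = n))
    for (f in seq_len(k)) {
      split <- ifelse(folds == f, "test", "train")
      tr_pool <- which(split == "train")
      n_val <- max(1L, floor(length(tr_pool) * 0.1))
      split[tr_pool[seq_len(n_val)]] <- "val"
      dat_f <- list(samples = data$samples, split = split)
      res <- train(cfg, dat_f, verbose = verbose)
      rep <- evaluate(res, dat_f, split = "test")
      run_means[[f]] <- rep[rep$id == "mean", metric_cols]
    }
  } else {
    if (is.null(data_b)) stop("cross_dataset requires 'data_b'")
    if (is.character(data_b)) data_b <- load_manifest(data_b)
    res <- train(cfg, data, verbose = verbose)
    rep <- evaluate(res, data_b, split = "all")
    run_means[[1]] <- rep[rep$id == "mean", metric_cols]
  }
  runs <- do.call(rbind, run_means)
  rownames(runs) <- NULL
  structure(list(mode = mode, runs = runs,
                 mean = colMeans(runs),
                 sd = vapply(runs, stats::sd, numeric(1)),
                 folds = folds, cfg = cfg),
            class = "protocol_result")
}

#' Render a ground-truth / prediction overlay
#'
#' Composites the segmentation outcome onto the image using the standard
#' colour convention: the ground-truth outline is drawn in white, correctly
#' predicted polyp pixels (true positives) in pink, and incorrect
#' predictions (false positives and false negatives) in red.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param gt,pred binary masks matching the image size.
#' @return `H x W x 3` RGB array; attribute `areas` holds the pixel counts
#'   of the pink (TP) and red (FP + FN) regions.
#' @export
render_overlay <- function(image, gt, pred) {
  gt <- .as_mask(gt, "gt"); pred <- .as_mask(pred, "pred")
  .check_shapes(gt, pred)
  if (!identical(dim(image)[1:2], dim(gt)))
    stop("image and masks must share spatial size")
  out <- image
  tp <- pred & gt
  wrong <- xor(pred, gt) # false positives and false negatives
  # GT reference outline: background pixels adjacent to the GT region, so it
  # stays visible around the coloured prediction regions
  outline <- .dilate8(gt) & !gt
  cols <- list(white = c(1, 1, 1), pink = c(1, 0.6, 0.8), red = c(1, 0, 0))
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[outline] <- cols$white[ch]
    plane[tp] <- cols$pink[ch]
    plane[wrong] <- cols$red[ch]
    out[, , ch] <- plane
  }
  attr(out, "areas") <- c(tp = sum(tp), wrong = sum(wrong),
                          outline = sum(outline & !wrong & !tp))
  out
}

# 8-connected dilation by one pixel
.dilate8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  out <- matrix(FALSE, h, w)
  for (dr in -1:1)
    for (dc in -1:1)
      out <- out | pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
  out
}
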
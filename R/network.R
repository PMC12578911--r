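# Five-stage encoder-decoder assembly: local-aware + residual encoder
# blocks, max-diagonal pooling transitions fused by an M2D block, hyper-scale
# shifted aggregation + progressive reusing attention skip connections
# modulated by attention gates, dual-bottleneck decoder blocks feeding
# max-diagonal unpooling, and a single-channel probability head.

.variants <- c("M1", "M2", "M3", "M4", "full")

#' Network configuration
#'
#' Ablation variant presets force the module flags: `M1` is the plain
#' baseline (max pooling + bilinear upsampling, no local-aware block, no
#' attention skip aggregation), `M2` adds max-diagonal pooling and the
#' local-aware block, `M3` adds index-guided max-diagonal unpooling, and
#' `M4` (= `full`) additionally enables the hyper-scale aggregation skip
#' connections with progressive reusing attention.
#'
#' @param stages number of encoder/decoder stages (default 5).
#' @param stage_channels channel widths per stage. The default
#'   `(6, 12, 24, 48, 96)` puts the full network at roughly 0.9 million
#'   learnable parameters, matching the architecture's lightweight design
#'   intent; widths are freely configurable.
#' @param in_channels expected image channels (default 3, RGB).
#' @param variant one of `"M1" .. "M4"`, `"full"`, or `NULL` to use the
#'   individual flags as given.
#' @param enable_maxdp,enable_maxdup,enable_lab,enable_pra,enable_hssam
#'   individual module flags (overridden by `variant`).
#' @param normalize_windows divide the pooled dual-branch maps by their
#'   stabilised window sums before the M2D fusion.
#' @param skip_combine combine the aggregated and stage features by
#'   elementwise `"add"` (default) or `"concat"` + 1x1 fusion.
#' @param threshold probability threshold used to binarise predictions.
#' @param seed seed fixing all parameter initialisation.
#' @export
network_config <- function(stages = 5L, stage_channels = c(6L, 12L, 24L, 48L, 96L),
                           in_channels = 3L, variant = "full",
                           enable_maxdp = TRUE, enable_maxdup = TRUE,
                           enable_lab = TRUE, enable_pra = TRUE,
                           enable_hssam = TRUE, normalize_windows = FALSE,
                           skip_combine = c("add", "concat"), threshold = 0.5,
                           seed = 42L) {
  skip_combine <- match.arg(skip_combine)
  stopifnot(stages >= 2L, length(stage_channels) == stages)
  if (!is.null(variant)) {
    variant <- match.arg(variant, .variants)
    flags <- switch(variant,
      M1 = c(FALSE, FALSE, FALSE, FALSE, FALSE),
      M2 = c(TRUE, FALSE, TRUE, FALSE, FALSE),
      M3 = c(TRUE, TRUE, TRUE, FALSE, FALSE),
      M4 = c(TRUE, TRUE, TRUE, TRUE, TRUE),
      full = c(TRUE, TRUE, TRUE, TRUE, TRUE)
    )
    enable_maxdp <- flags[1]; enable_maxdup <- flags[2]; enable_lab <- flags[3]
    enable_pra <- flags[4]; enable_hssam <- flags[5]
  }
  if (enable_maxdup && !enable_maxdp)
    stop("configuration error: max-diagonal unpooling requires the matching ",
         "pooling indices (enable_maxdp)")
  structure(list(stages = as.integer(stages),
                 stage_channels = as.integer(stage_channels),
                 in_channels = as.integer(in_channels),
                 variant = variant %||% "custom",
                 enable_maxdp = enable_maxdp, enable_maxdup = enable_maxdup,
                 enable_lab = enable_lab, enable_pra = enable_pra,
                 enable_hssam = enable_hssam,
                 normalize_windows = normalize_windows,
                 skip_combine = skip_combine, threshold = threshold,
                 seed = as.integer(seed)),
            class = "network_config")
}

# attention gate: additive attention over the combined skip feature, gated
# by the deeper decoder state
hn_attention_gate <- function(c_skip, c_gate, att_c = NULL, zero_init = FALSE) {
  att_c <- att_c %||% max(4L, c_skip %/% 2L)
  wx <- hn_conv2d(c_skip, att_c, kernel = 1L, zero_init = zero_init)
  wg <- hn_conv2d(c_gate, att_c, kernel = 1L, zero_init = zero_init)
  psi <- hn_conv2d(att_c, 1L, kernel = 1L, zero_init = zero_init)
  m <- hn_module(forward = NULL, children = list(wx = wx, wg = wg, psi = psi),
                 type = "attention_gate")
  m$forward <- function(skip, gate, training = FALSE) {
    d <- dim(skip$value)
    if (!identical(dim(gate$value)[4], d[4]))
      stop("skip and gate batch sizes do not match")
    gup <- ag_bilinear(gate, d[1], d[2])
    a <- ag_relu(ag_add(wx$forward(skip, training), wg$forward(gup, training)))
    coef <- ag_sigmoid(psi$forward(a, training))
    ag_scale_spatial(skip, coef)
  }
  m
}

#' Additive attention gate over a skip connection
#'
#' Combines the aggregated skip feature `af` with the stage feature `f`
#' (elementwise sum), projects the combination and the deeper gate signal to
#' a common width, sums, applies ReLU, reduces to a single coefficient map
#' through a 1x1 convolution and sigmoid, and multiplies the coefficients
#' onto the combined skip feature.
#'
#' @param af aggregated skip feature `(H, W, C)` or `(H, W, C, N)`.
#' @param f stage encoder feature, spatially aligned with `af`.
#' @param gate deeper decoder state (any spatial size; it is resized).
#' @param params module built by [attention_gate_module()]; built on the fly
#'   when `NULL`.
#' @param seed seed used when building on the fly.
#' @return the gated skip feature, same shape as `f`.
#' @export
attention_gate <- function(af, f, gate, params = NULL, seed = 42L) {
  la <- .lift4(af); lf <- .lift4(f); lg <- .lift4(gate)
  if (!identical(dim(la$x)[1:2], dim(lf$x)[1:2]))
    stop("'af' and 'f' must be spatially aligned")
  if (is.null(params))
    params <- attention_gate_module(dim(lf$x)[3], dim(lg$x)[3], seed = seed)
  comb <- ag_add(ag_const(la$x), ag_const(lf$x))
  out <- params$forward(comb, ag_const(lg$x))
  .drop4(out$value, lf$rank)
}

#' Build a standalone attention-gate module
#'
#' @param c_skip,c_gate channel counts of the skip feature and gate signal.
#' @param att_c internal attention width (default `max(4, c_skip / 2)`).
#' @param zero_init zero-initialise all projections; the coefficient map is
#'   then exactly 0.5 everywhere (`sigmoid(0)`).
#' @param seed RNG seed.
#' @export
attention_gate_module <- function(c_skip, c_gate, att_c = NULL,
                                  zero_init = FALSE, seed = 42L) {
  set.seed(seed)
  hn_attention_gate(c_skip, c_gate, att_c = att_c, zero_init = zero_init)
}

#' Build the segmentation network
#'
#' Assembles the five-stage encoder-decoder described by the configuration.
#' Each encoder stage is a local-aware block (when enabled) followed by two
#' residual blocks; stages 1-4 are followed by a max-diagonal pooling
#' transition whose two branches are fused by the M2D block (1x1
#' bottleneck). Skip connections aggregate the stage feature with its deeper
#' neighbour (hyper-scale shifted aggregation), refine the aggregate with
#' progressive reusing attention, and are modulated by an additive attention
#' gate. Each decoder stage holds two residual blocks and two parallel
#' bottlenecks producing the max- and diagonal-branch inputs of the
#' index-guided unpooling. The deepest stage feature feeds the decoder
#' directly, without aggregation or sampling. The head is a 1x1 convolution
#' followed by a sigmoid.
#'
#' @param cfg a [network_config()].
#' @return a model object of class `hn_network`.
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  S <- cfg$stages
  ch <- cfg$stage_channels
  children <- list()
  stem <- hn_sequential(conv = hn_conv2d(cfg$in_channels, ch[1], kernel = 3L),
                        bn = hn_batchnorm(ch[1]), relu = hn_relu_mod())
  children$stem <- stem
  enc <- vector("list", S)
  m2d <- vector("list", S)
  for (i in seq_len(S)) {
    cin <- if (i == 1L) ch[1] else ch[i - 1L]
    blocks <- list()
    if (cfg$enable_lab) blocks$lab <- hn_lab(cin)
    blocks$res1 <- hn_residual_block(cin, ch[i])
    blocks$res2 <- hn_residual_block(ch[i], ch[i])
    enc[[i]] <- hn_sequential(blocks)
    children[[paste0("enc", i)]] <- enc[[i]]
    if (i < S && cfg$enable_maxdp) {
      m2d[[i]] <- hn_bottleneck(2L * ch[i], ch[i])
      children[[paste0("m2d", i)]] <- m2d[[i]]
    }
  }
  hss <- vector("list", S - 1L)
  pra <- vector("list", S - 1L)
  gates <- vector("list", S - 1L)
  skipfuse <- vector("list", S - 1L)
  for (i in seq_len(S - 1L)) {
    if (cfg$enable_hssam) {
      hss[[i]] <- hn_hssam(ch[i], ch[i + 1L])
      children[[paste0("hssam", i)]] <- hss[[i]]
      if (cfg$enable_pra) {
        pra[[i]] <- hn_pra(ch[i])
        children[[paste0("pra", i)]] <- pra[[i]]
      }
      if (cfg$skip_combine == "concat") {
        skipfuse[[i]] <- hn_conv2d(2L * ch[i], ch[i], kernel = 1L)
        children[[paste0("skipfuse", i)]] <- skipfuse[[i]]
      }
    }
    gates[[i]] <- hn_attention_gate(ch[i], ch[i + 1L])
    children[[paste0("gate", i)]] <- gates[[i]]
  }
  dec <- vector("list", S)
  bott_m <- vector("list", S - 1L)
  bott_d <- vector("list", S - 1L)
  dec[[S]] <- hn_sequential(res1 = hn_residual_block(ch[S], ch[S]),
                            res2 = hn_residual_block(ch[S], ch[S]))
  children[[paste0("dec", S)]] <- dec[[S]]
  for (i in seq_len(S - 1L)) {
    bott_m[[i]] <- hn_bottleneck(ch[i + 1L], ch[i])
    children[[paste0("bott_m", i)]] <- bott_m[[i]]
    if (cfg$enable_maxdup) {
      bott_d[[i]] <- hn_bottleneck(ch[i + 1L], ch[i])
      children[[paste0("bott_d", i)]] <- bott_d[[i]]
    }
    dec[[i]] <- hn_sequential(res1 = hn_residual_block(ch[i], ch[i]),
                              res2 = hn_residual_block(ch[i], ch[i]))
    children[[paste0("dec", i)]] <- dec[[i]]
  }
  head <- hn_conv2d(ch[1], 1L, kernel = 1L)
  children$head <- head
  root <- hn_module(forward = NULL, children = children, type = "network")
  model <- list(cfg = cfg, root = root, stem = stem, enc = enc, m2d = m2d,
                hssam = hss, pra = pra, gates = gates, skipfuse = skipfuse,
                dec = dec, bott_m = bott_m, bott_d = bott_d, head = head)
  model$wiring <- list(
    n_maxdp = if (cfg$enable_maxdp) S - 1L else 0L,
    n_maxdup = if (cfg$enable_maxdup) S - 1L else 0L,
    n_pra = if (cfg$enable_hssam && cfg$enable_pra) S - 1L else 0L,
    n_lab = if (cfg$enable_lab) S else 0L,
    deepest_stage_direct = TRUE
  )
  class(model) <- "hn_network"
  model
}

# full forward pass on an autograd tensor (H, W, C, N); returns the logits
# tensor; when collect = TRUE also returns intermediates for introspection
network_forward <- function(model, x, training = FALSE, collect = FALSE) {
  cfg <- model$cfg
  S <- cfg$stages
  feats <- vector("list", S)
  pools <- vector("list", S - 1L)
  cur <- model$stem$forward(x, training)
  for (i in seq_len(S)) {
    feats[[i]] <- model$enc[[i]]$forward(cur, training)
    if (i < S) {
      if (cfg$enable_maxdp) {
        p <- ag_maxdiag_pool(feats[[i]])
        pools[[i]] <- p
        mx <- p$max; dg <- p$diag
        if (cfg$normalize_windows) {
          od <- dim(mx$value)
          ws <- ag_scalar_add(
            ag_scalar_mul(ag_adaptive_avg(feats[[i]], od[1], od[2]), 4), 1e-6)
          mx <- ag_div(mx, ws)
          dg <- ag_div(dg, ws)
        }
        cur <- model$m2d[[i]]$forward(ag_concat_channels(list(mx, dg)), training)
      } else {
        cur <- ag_maxpool2(feats[[i]])
      }
    }
  }
  d <- model$dec[[S]]$forward(feats[[S]], training) # f_5 feeds De5 directly
  for (i in rev(seq_len(S - 1L))) {
    skip <- feats[[i]]
    if (cfg$enable_hssam) {
      af <- model$hssam[[i]]$forward(list(f_i = feats[[i]],
                                          f_next = feats[[i + 1L]]), training)
      if (cfg$enable_pra) af <- model$pra[[i]]$forward(af, training)
      skip <- if (cfg$skip_combine == "concat") {
        model$skipfuse[[i]]$forward(ag_concat_channels(list(af, feats[[i]])),
                                    training)
      } else {
        ag_add(af, feats[[i]])
      }
    }
    gated <- model$gates[[i]]$forward(skip, d, training)
    fd <- dim(feats[[i]]$value)
    if (cfg$enable_maxdup) {
      mu <- model$bott_m[[i]]$forward(d, training)
      du <- model$bott_d[[i]]$forward(d, training)
      up <- ag_maxdiag_unpool(mu, du, pools[[i]]$max_idx, pools[[i]]$diag_idx,
                              fd[1], fd[2])
    } else {
      up <- ag_bilinear(model$bott_m[[i]]$forward(d, training), fd[1], fd[2])
    }
    d <- model$dec[[i]]$forward(ag_add(up, gated), training)
  }
  logits <- model$head$forward(d, training)
  if (collect) list(logits = logits, feats = feats, pools = pools) else logits
}

#' Number of learnable parameters of a model
#'
#' @param model an `hn_network` (or any internal module).
#' @return integer count of learnable scalars.
#' @export
param_count <- function(model) {
  m <- if (inherits(model, "hn_network")) model$root else model
  as.integer(hn_param_count(m))
}

#' Per-module parameter breakdown
#'
#' @param model an `hn_network`.
#' @param json optional path; when given, the breakdown is also written as
#'   JSON.
#' @return named list of per-module parameter counts plus the total.
#' @export
param_breakdown <- function(model, json = NULL) {
  stopifnot(inherits(model, "hn_network"))
  counts <- lapply(model$root$children, hn_param_count)
  counts$total <- param_count(model)
  if (!is.null(json))
    jsonlite::write_json(counts, json, auto_unbox = TRUE, digits = NA)
  counts
}

#' Run the network on an image
#'
#' @param model an `hn_network` from [build_network()].
#' @param image numeric array `(H, W, 3)` in `[0, 1]`, or a batch
#'   `(H, W, 3, N)`. Sizes not divisible by `2^(stages - 1)` are zero-padded
#'   on the bottom/right and the output is cropped back.
#' @param threshold binarisation threshold; defaults to the configured one.
#' @return a list of class `segmentation_output` with `probabilities`
#'   (`H x W` matrix, or `(H, W, N)` for batches) in `[0, 1]` and
#'   `binary_mask` (`probabilities >= threshold`).
#' @export
net_forward <- function(model, image, threshold = NULL) {
  stopifnot(inherits(model, "hn_network"))
  cfg <- model$cfg
  lf <- .lift4(image)
  d <- dim(lf$x)
  if (d[3] != cfg$in_channels)
    stop("expected ", cfg$in_channels, " channels, got ", d[3])
  div <- 2L^(cfg$stages - 1L)
  ph <- ceiling(d[1] / div) * div
  pw <- ceiling(d[2] / div) * div
  xi <- lf$x
  if (ph != d[1] || pw != d[2]) {
    xp <- array(0, dim = c(ph, pw, d[3], d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- xi
    xi <- xp
  }
  logits <- network_forward(model, ag_const(xi), training = FALSE)
  pr <- 1 / (1 + exp(-logits$value))
  pr <- pr[seq_len(d[1]), seq_len(d[2]), 1, , drop = FALSE]
  probs <- if (d[4] == 1L) matrix(pr[, , 1, 1], d[1], d[2]) else
    array(pr[, , 1, ], dim = c(d[1], d[2], d[4]))
  thr <- threshold %||% cfg$threshold
  structure(list(probabilities = probs, binary_mask = probs >= thr,
                 threshold = thr),
            class = "segmentation_output")
}

# --- checkpointing ----------------------------------------------------------

# collect batch-norm state environments, named like the parameters
hn_bn_states <- function(m, prefix = "") {
  out <- list()
  if (identical(m$type, "batchnorm")) out[[paste0(prefix, "state")]] <- m$meta$state
  for (nm in names(m$children))
    out <- c(out, hn_bn_states(m$children[[nm]], paste0(prefix, nm, ".")))
  out
}

#' Save a model checkpoint
#'
#' Serialises the configuration, every parameter tensor and the batch-norm
#' running statistics into a single file.
#'
#' @param model an `hn_network`.
#' @param path output file path.
#' @export
save_checkpoint <- function(model, path) {
  params <- hn_params(model$root)
  values <- lapply(params, function(p) p$value)
  bn <- lapply(hn_bn_states(model$root), function(s)
    list(running_mean = s$running_mean, running_var = s$running_var))
  saveRDS(list(cfg = model$cfg, params = values, bn = bn,
               package_version = as.character(utils::packageVersion("hssamnet"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_checkpoint()].
#' @return the restored `hn_network`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg)
  params <- hn_params(model$root)
  stopifnot(identical(sort(names(params)), sort(names(ck$params))))
  for (nm in names(params)) params[[nm]]$value <- ck$params[[nm]]
  states <- hn_bn_states(model$root)
  for (nm in names(states)) {
    states[[nm]]$running_mean <- ck$bn[[nm]]$running_mean
    states[[nm]]$running_var <- ck$bn[[nm]]$running_var
  }
  model
}
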
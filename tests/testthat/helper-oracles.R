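# Independent brute-force oracles used to validate the package operators.
# These deliberately share no code with the implementation: plain loops and
# set arithmetic over coordinate lists.

# per-window loop oracle for dual-branch 2x2 pooling on a matrix;
# row-major scan of the window, first maximal cell wins ties
oracle_maxdiag_pool <- function(x) {
  h <- nrow(x) %/% 2L; w <- ncol(x) %/% 2L
  mx <- matrix(0, h, w); dg <- matrix(0, h, w)
  mi <- matrix(0L, h, w); di <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      rows <- (2L * i - 1L):(2L * i)
      cols <- (2L * j - 1L):(2L * j)
      win <- x[rows, cols]
      best <- -Inf; br <- 1L; bc <- 1L
      for (r in 1:2) for (cc in 1:2) {
        if (win[r, cc] > best) { best <- win[r, cc]; br <- r; bc <- cc }
      }
      mx[i, j] <- best
      dg[i, j] <- win[3L - br, 3L - bc]
      mi[i, j] <- (rows[br] - 1L) * ncol(x) + (cols[bc] - 1L)
      di[i, j] <- (rows[3L - br] - 1L) * ncol(x) + (cols[3L - bc] - 1L)
    }
  }
  list(max_map = mx, diag_map = dg, max_idx = mi, diag_idx = di)
}

# impulse-influence oracle for the receptive field of a conv stack: track
# which input cells influence output cell 1, layer by layer (no padding)
oracle_receptive_field <- function(layers) {
  cells <- 1L # 1-based positions in the current layer's output
  for (ly in rev(layers)) {
    nxt <- integer(0)
    for (p in cells) {
      start <- (p - 1L) * ly$stride + 1L
      taps <- start + (seq_len(ly$kernel_size) - 1L) * ly$expansion
      nxt <- c(nxt, taps)
    }
    cells <- sort(unique(nxt))
  }
  max(cells) - min(cells) + 1L
}

# set-arithmetic reimplementation of the mask metrics over coordinate lists
oracle_metrics <- function(pred, gt, prob = NULL) {
  key <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    paste(idx[, 1], idx[, 2])
  }
  P <- key(pred); G <- key(gt)
  n <- length(pred)
  tp <- length(intersect(P, G))
  fp <- length(setdiff(P, G))
  fn <- length(setdiff(G, P))
  tn <- n - tp - fp - fn
  dice <- if (length(P) + length(G) == 0) 1 else 2 * tp / (length(P) + length(G))
  iou_fg <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  iou_bg <- if (tn + fp + fn == 0) 1 else tn / (tn + fp + fn)
  pv <- if (is.null(prob)) as.numeric(pred) else as.numeric(prob)
  list(
    dice = dice,
    miou = (iou_fg + iou_bg) / 2,
    mae = mean(abs(pv - as.numeric(gt))),
    acc = (tp + tn) / n,
    ppv = if (tp + fp == 0) 1 else tp / (tp + fp),
    tpr = if (tp + fn == 0) 1 else tp / (tp + fn),
    tnr = if (tn + fp == 0) 1 else tn / (tn + fp),
    counts = c(tp = tp, fp = fp, fn = fn, tn = tn)
  )
}

# boundary + percentile Hausdorff oracle (independent loops)
oracle_hd95 <- function(pred, gt) {
  bound <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(FALSE, h, w)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (!m[i, j]) next
      edge <- FALSE
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- i + dr; cc <- j + dc
        if (r < 1 || r > h || cc < 1 || cc > w || !m[r, cc]) edge <- TRUE
      }
      out[i, j] <- edge
    }
    out
  }
  A <- which(bound(pred), arr.ind = TRUE)
  B <- which(bound(gt), arr.ind = TRUE)
  dir <- function(S, T) {
    vapply(seq_len(nrow(S)), function(k)
      min(sqrt((S[k, 1] - T[, 1])^2 + (S[k, 2] - T[, 2])^2)), numeric(1))
  }
  max(stats::quantile(dir(A, B), 0.95, names = FALSE),
      stats::quantile(dir(B, A), 0.95, names = FALSE))
}

# adaptive max pooling oracle by window enumeration
oracle_adaptive_max <- function(x, oh, ow) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    r0 <- floor((i - 1) * h / oh) + 1L; r1 <- ceiling(i * h / oh)
    c0 <- floor((j - 1) * w / ow) + 1L; c1 <- ceiling(j * w / ow)
    out[i, j] <- max(x[r0:r1, c0:c1])
  }
  out
}

# 4-connected component count of a logical mask (BFS labelling)
oracle_n_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0L
  for (si in seq_len(h)) for (sj in seq_len(w)) {
    if (!mask[si, sj] || seen[si, sj]) next
    ncomp <- ncomp + 1L
    queue <- list(c(si, sj))
    seen[si, sj] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- p[1] + d[1]; cc <- p[2] + d[2]
        if (r >= 1 && r <= h && cc >= 1 && cc <= w &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  ncomp
}

# tiny dataset + config used by the training-harness tests
tiny_dataset <- function(n = 12L, size = 32L, seed = 7L) {
  generate_samples(n, synth_params(height = size, width = size,
                                   polyp_area_fraction = c(0.08, 0.3)),
                   split = c(0.6, 0.2, 0.2), seed = seed)
}

tiny_cfg <- function(epochs = 2L, ...) {
  run_config(image_size = c(32L, 32L), batch_size = 4L, epochs = epochs,
             stage_channels = c(4L, 6L, 8L, 10L, 12L), variant = "M3",
             warmup_frac = 0.1, ...)
}
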
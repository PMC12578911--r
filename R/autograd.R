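# Minimal reverse-mode automatic differentiation over 4-d feature arrays.
#
# A tensor is an environment carrying a value, an accumulated gradient, the
# parent tensors it was computed from and a vector-Jacobian product closure.
# Backward runs over the reverse topological order of the recorded tape.

.ag_counter <- local({
  i <- 0L
  function() {
    i <<- i + 1L
    i
  }
})

#' @keywords internal
ag_tensor <- function(value, parents = list(), vjp = NULL, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$id <- .ag_counter()
  t$value <- value
  t$grad <- NULL
  t$parents <- parents
  t$vjp <- vjp
  rg <- requires_grad
  if (!rg) for (p in parents) if (p$requires_grad) { rg <- TRUE; break }
  t$requires_grad <- rg
  class(t) <- "ag_tensor"
  t
}

ag_const <- function(value) ag_tensor(value)

ag_param <- function(value) {
  t <- ag_tensor(value, requires_grad = TRUE)
  t$is_param <- TRUE
  t
}

ag_accum <- function(t, g) {
  if (is.null(t$grad)) t$grad <- g else t$grad <- t$grad + g
  invisible(t)
}

#' Backpropagate from a scalar loss tensor
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  # iterative DFS topological sort (recursion depth can exceed R's limit)
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = loss, stage = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents)
        if (p$requires_grad && is.null(seen[[as.character(p$id)]]))
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  loss$grad <- array(1, dim = dim(loss$value) %||% 1L)
  for (node in rev(order)) {
    if (is.null(node$vjp) || is.null(node$grad)) next
    grads <- node$vjp(node$grad)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      if (p$requires_grad && !is.null(grads[[k]])) ag_accum(p, grads[[k]])
    }
  }
  invisible(loss)
}

ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- elementwise and structural ops ---------------------------------------

ag_add <- function(a, b) {
  ag_tensor(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_tensor(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_tensor(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_scalar_mul <- function(a, s) {
  ag_tensor(a$value * s, list(a), function(g) list(g * s))
}

ag_scalar_add <- function(a, s) {
  ag_tensor(a$value + s, list(a), function(g) list(g))
}

ag_div <- function(a, b) {
  av <- a$value; bv <- b$value
  ag_tensor(av / bv, list(a, b), function(g) list(g / bv, -g * av / bv^2))
}

ag_relu <- function(a) {
  m <- a$value > 0
  ag_tensor(a$value * m, list(a), function(g) list(g * m))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ag_tensor(s, list(a), function(g) list(g * s * (1 - s)))
}

# per-(channel, sample) sums, returned as a (1, 1, C, N) array
.cn_sum <- function(x, d = dim(x)) {
  dim(x) <- c(d[1] * d[2], d[3] * d[4])
  array(.colSums(x, d[1] * d[2], d[3] * d[4]), dim = c(1L, 1L, d[3], d[4]))
}

# channel-wise scale: w has dim (1, 1, C, N) matching x's channels and batch
ag_scale_channels <- function(x, w) {
  d <- dim(x$value)
  wfull <- array(rep(w$value, each = d[1] * d[2]), dim = d)
  ag_tensor(x$value * wfull, list(x, w), function(g) {
    list(g * wfull, .cn_sum(g * x$value, d))
  })
}

# spatial scale: s has dim (H, W, 1, N), broadcast across channels
ag_scale_spatial <- function(x, s) {
  d <- dim(x$value)
  sfull <- x$value
  sfull[] <- s$value[, , rep(1L, d[3]), , drop = FALSE]
  ag_tensor(x$value * sfull, list(x, s), function(g) {
    prod_ <- g * x$value
    dim(prod_) <- c(d[1] * d[2], d[3], d[4])
    gs <- array(0, dim = dim(s$value))
    for (n in seq_len(d[4])) {
      mm <- prod_[, , n, drop = FALSE]
      dim(mm) <- c(d[1] * d[2], d[3])
      gs[, , 1, n] <- .rowSums(mm, d[1] * d[2], d[3])
    }
    list(g * sfull, gs)
  })
}

ag_concat_channels <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  dims <- lapply(vals, dim)
  cs <- vapply(dims, function(d) d[3], numeric(1))
  d1 <- dims[[1]]
  out <- array(0, dim = c(d1[1], d1[2], sum(cs), d1[4]))
  at <- 0L
  for (k in seq_along(vals)) {
    out[, , at + seq_len(cs[k]), ] <- vals[[k]]
    at <- at + cs[k]
  }
  ag_tensor(out, tensors, function(g) {
    at <- 0L
    res <- vector("list", length(tensors))
    for (k in seq_along(tensors)) {
      res[[k]] <- g[, , at + seq_len(cs[k]), , drop = FALSE]
      at <- at + cs[k]
    }
    res
  })
}

ag_crop <- function(x, r0, r1, c0, c1) {
  d <- dim(x$value)
  ag_tensor(x$value[r0:r1, c0:c1, , , drop = FALSE], list(x), function(g) {
    gx <- array(0, dim = d)
    gx[r0:r1, c0:c1, , ] <- g
    list(gx)
  })
}

ag_mean <- function(x) {
  n <- length(x$value)
  ag_tensor(mean(x$value), list(x), function(g) {
    list(array(as.numeric(g) / n, dim = dim(x$value)))
  })
}

# --- backend-op wrappers ----------------------------------------------------

ag_conv2d <- function(x, w, b, stride = 1L, pad = 0L, dilation = 1L, groups = 1L) {
  stride <- rep(as.integer(stride), length.out = 2L)
  pad <- rep(as.integer(pad), length.out = 2L)
  dilation <- rep(as.integer(dilation), length.out = 2L)
  out <- cpp_conv2d(x$value, w$value, b$value, stride[1], stride[2],
                    pad[1], pad[2], dilation[1], dilation[2], as.integer(groups))
  xv <- x$value; wv <- w$value
  ag_tensor(out, list(x, w, b), function(g) {
    bk <- cpp_conv2d_backward(xv, wv, g, stride[1], stride[2],
                              pad[1], pad[2], dilation[1], dilation[2],
                              as.integer(groups))
    list(bk$gx, bk$gw, as.numeric(bk$gb))
  })
}

ag_maxdiag_pool <- function(x) {
  res <- cpp_maxdiag_pool(x$value)
  d <- dim(x$value)
  vjp_shared <- function(gm, gd) {
    cpp_scatter_add_plane(gm, gd, res$max_idx, res$diag_idx, d[1], d[2])
  }
  zero <- function(t) array(0, dim = dim(t))
  max_t <- ag_tensor(res$max_map, list(x), function(g) {
    list(vjp_shared(g, zero(res$diag_map)))
  })
  diag_t <- ag_tensor(res$diag_map, list(x), function(g) {
    list(vjp_shared(zero(res$max_map), g))
  })
  list(max = max_t, diag = diag_t, max_idx = res$max_idx, diag_idx = res$diag_idx)
}

ag_maxdiag_unpool <- function(max_t, diag_t, max_idx, diag_idx, oh, ow) {
  out <- cpp_maxdiag_unpool(max_t$value, diag_t$value, max_idx, diag_idx,
                            as.integer(oh), as.integer(ow))
  d <- dim(max_t$value)
  ag_tensor(out, list(max_t, diag_t), function(g) {
    bk <- cpp_maxdiag_unpool_backward(g, max_idx, diag_idx, d[1], d[2])
    list(bk$gmax, bk$gdiag)
  })
}

ag_maxpool2 <- function(x) {
  res <- cpp_maxpool2(x$value)
  d <- dim(x$value)
  ag_tensor(res$out, list(x), function(g) {
    list(cpp_scatter_add_single(g, res$idx, d[1], d[2]))
  })
}

ag_bilinear <- function(x, oh, ow) {
  d <- dim(x$value)
  if (d[1] == oh && d[2] == ow) return(x)
  out <- cpp_bilinear(x$value, as.integer(oh), as.integer(ow))
  ag_tensor(out, list(x), function(g) {
    list(cpp_bilinear_backward(g, d[1], d[2]))
  })
}

ag_adaptive_max <- function(x, oh, ow) {
  res <- cpp_adaptive_pool(x$value, as.integer(oh), as.integer(ow), 0L)
  d <- dim(x$value)
  ag_tensor(res$out, list(x), function(g) {
    list(cpp_scatter_add_single(g, res$idx, d[1], d[2]))
  })
}

ag_adaptive_avg <- function(x, oh, ow) {
  res <- cpp_adaptive_pool(x$value, as.integer(oh), as.integer(ow), 1L)
  d <- dim(x$value)
  ag_tensor(res$out, list(x), function(g) {
    list(cpp_adaptive_avg_backward(g, d[1], d[2]))
  })
}

ag_global_avg <- function(x) {
  d <- dim(x$value)
  m <- .cn_sum(x$value, d) / (d[1] * d[2])
  ag_tensor(m, list(x), function(g) {
    gx <- array(rep(g / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
    list(gx)
  })
}

# channel descriptor (1,1,C,N) -> zero-padded square grid (S,S,1,N);
# channel c (1-based) fills grid cell row (c-1) %/% S, col (c-1) %% S
ag_chan_to_grid <- function(x, S) {
  d <- dim(x$value)
  C <- d[3]; N <- d[4]
  out <- array(0, dim = c(S, S, 1L, N))
  rows <- ((seq_len(C) - 1L) %/% S) + 1L
  cols <- ((seq_len(C) - 1L) %% S) + 1L
  for (n in seq_len(N))
    out[cbind(rows, cols, 1L, n)] <- x$value[1, 1, , n]
  ag_tensor(out, list(x), function(g) {
    gx <- array(0, dim = d)
    for (n in seq_len(N)) gx[1, 1, , n] <- g[cbind(rows, cols, 1L, n)]
    list(gx)
  })
}

# inverse of ag_chan_to_grid: drop padded cells, return (1,1,C,N)
ag_grid_to_chan <- function(y, C) {
  d <- dim(y$value)
  S <- d[1]; N <- d[4]
  rows <- ((seq_len(C) - 1L) %/% S) + 1L
  cols <- ((seq_len(C) - 1L) %% S) + 1L
  out <- array(0, dim = c(1L, 1L, C, N))
  for (n in seq_len(N)) out[1, 1, , n] <- y$value[cbind(rows, cols, 1L, n)]
  ag_tensor(out, list(y), function(g) {
    gy <- array(0, dim = d)
    for (n in seq_len(N)) gy[cbind(rows, cols, 1L, n)] <- g[1, 1, , n]
    list(gy)
  })
}

# broadcast a (1,1,C,N) context tensor to (H,W,C,N)
ag_broadcast_spatial <- function(x, H, W) {
  d <- dim(x$value)
  out <- array(rep(x$value, each = H * W), dim = c(H, W, d[3], d[4]))
  ag_tensor(out, list(x), function(g) {
    list(.cn_sum(g))
  })
}

# --- segmentation loss ------------------------------------------------------

# binary cross-entropy with logits plus soft Dice, equally weighted;
# gradient is computed analytically with respect to the logits
ag_seg_loss <- function(logits, target, w_bce = 0.5, w_dice = 0.5, smooth = 1.0) {
  v <- logits$value
  y <- target
  n <- length(v)
  p <- 1 / (1 + exp(-v))
  bce <- mean(pmax(v, 0) - v * y + log1p(exp(-abs(v))))
  sp <- sum(p); sy <- sum(y); spy <- sum(p * y)
  den <- sp + sy + smooth
  dice_loss <- 1 - (2 * spy + smooth) / den
  val <- w_bce * bce + w_dice * dice_loss
  ag_tensor(val, list(logits), function(g) {
    g <- as.numeric(g)
    gb <- (p - y) / n
    gd_p <- -(2 * y * den - (2 * spy + smooth)) / den^2
    gd <- gd_p * p * (1 - p)
    list(array(g * (w_bce * gb + w_dice * gd), dim = dim(v)))
  })
}
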
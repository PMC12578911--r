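# Lightweight layer-module system on top of the autograd tape.
#
# A module is a list with class "hn_module": $params (named list of ag_param
# tensors), $children (named list of sub-modules), $forward(x, training),
# plus free-form metadata fields. Parameters are collected recursively.

hn_module <- function(forward, params = list(), children = list(), type = "module",
                      ...) {
  structure(
    list(forward = forward, params = params, children = children, type = type,
         meta = list(...)),
    class = "hn_module"
  )
}

#' Collect all parameter tensors of a module tree
#' @keywords internal
hn_params <- function(m, prefix = "") {
  out <- list()
  if (length(m$params)) {
    names_ <- paste0(prefix, names(m$params))
    out <- stats::setNames(m$params, names_)
  }
  for (nm in names(m$children)) {
    out <- c(out, hn_params(m$children[[nm]], paste0(prefix, nm, ".")))
  }
  out
}

hn_param_count <- function(m) {
  sum(vapply(hn_params(m), function(p) length(p$value), numeric(1)))
}

# He-normal initialisation; draws come from the R RNG so that a single
# set.seed() before construction fixes every parameter
init_conv_weight <- function(kh, kw, cin_g, cout) {
  fan_in <- kh * kw * cin_g
  array(stats::rnorm(kh * kw * cin_g * cout, sd = sqrt(2 / fan_in)),
        dim = c(kh, kw, cin_g, cout))
}

#' 2-d convolution module ("same" padding by default)
#' @keywords internal
hn_conv2d <- function(cin, cout, kernel = 3L, stride = 1L, dilation = 1L,
                      groups = 1L, pad = NULL, bias = TRUE, zero_init = FALSE) {
  kernel <- as.integer(kernel)
  if (is.null(pad)) pad <- dilation * (kernel - 1L) %/% 2L
  w <- if (zero_init) array(0, dim = c(kernel, kernel, cin %/% groups, cout))
       else init_conv_weight(kernel, kernel, cin %/% groups, cout)
  b <- if (bias && !zero_init) stats::rnorm(cout, sd = 0.01) else numeric(cout)
  wp <- ag_param(w)
  bp <- ag_param(b)
  m <- hn_module(
    forward = NULL,
    params = list(weight = wp, bias = bp),
    type = "conv2d",
    kernel = kernel, stride = stride, dilation = dilation, groups = groups,
    pad = pad, cin = cin, cout = cout
  )
  depthwise <- groups == cin && cin == cout && stride == 1L &&
    pad == dilation * (kernel - 1L) %/% 2L # direct kernel needs "same" output
  m$forward <- function(x, training = FALSE) {
    if (depthwise) {
      out <- cpp_dwconv2d(x$value, wp$value, bp$value, as.integer(pad),
                          as.integer(dilation))
      xv <- x$value
      ag_tensor(out, list(x, wp, bp), function(g) {
        bk <- cpp_dwconv2d_backward(xv, wp$value, g, as.integer(pad),
                                    as.integer(dilation))
        list(bk$gx, bk$gw, as.numeric(bk$gb))
      })
    } else {
      ag_conv2d(x, wp, bp, stride = stride, pad = pad, dilation = dilation,
                groups = groups)
    }
  }
  m
}

#' Batch normalisation over (H, W, N) per channel
#' @keywords internal
hn_batchnorm <- function(C, momentum = 0.1, eps = 1e-5) {
  gamma <- ag_param(rep(1, C))
  beta <- ag_param(rep(0, C))
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, C)
  state$running_var <- rep(1, C)
  m <- hn_module(
    forward = NULL,
    params = list(gamma = gamma, beta = beta),
    type = "batchnorm", state = state, C = C
  )
  m$forward <- function(x, training = FALSE) {
    if (training) {
      st <- cpp_bn_stats(x$value)
      mu <- st$mu; va <- st$va
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * va
    } else {
      mu <- state$running_mean
      va <- state$running_var
    }
    fw <- cpp_bn_forward(x$value, gamma$value, beta$value, mu, va, eps)
    ag_tensor(fw$out, list(x, gamma, beta), function(g) {
      bk <- cpp_bn_backward(g, fw$xhat, gamma$value, va, eps, training)
      list(bk$gx, as.numeric(bk$ggam), as.numeric(bk$gbet))
    })
  }
  m
}

#' Sequential composition of modules
#' @keywords internal
hn_sequential <- function(...) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1]]) && !inherits(mods[[1]], "hn_module"))
    mods <- mods[[1]]
  names(mods) <- names(mods) %||% paste0("m", seq_along(mods))
  m <- hn_module(forward = NULL, children = mods, type = "sequential")
  m$forward <- function(x, training = FALSE) {
    for (sub in mods) x <- sub$forward(x, training)
    x
  }
  m
}

hn_relu_mod <- function() hn_module(forward = function(x, training = FALSE) ag_relu(x),
                                    type = "relu")

# 1x1 convolution + batch norm + ReLU ("bottleneck" in the network's sense)
hn_bottleneck <- function(cin, cout) {
  hn_sequential(
    conv = hn_conv2d(cin, cout, kernel = 1L),
    bn = hn_batchnorm(cout),
    relu = hn_relu_mod()
  )
}

# 3x3 conv + BN + ReLU twice, with identity shortcut (1x1 projection when
# widths differ)
hn_residual_block <- function(cin, cout) {
  c1 <- hn_conv2d(cin, cout, kernel = 3L)
  b1 <- hn_batchnorm(cout)
  c2 <- hn_conv2d(cout, cout, kernel = 3L)
  b2 <- hn_batchnorm(cout)
  proj <- if (cin != cout) hn_conv2d(cin, cout, kernel = 1L) else NULL
  children <- list(conv1 = c1, bn1 = b1, conv2 = c2, bn2 = b2)
  if (!is.null(proj)) children$proj <- proj
  m <- hn_module(forward = NULL, children = children, type = "residual")
  m$forward <- function(x, training = FALSE) {
    h <- ag_relu(b1$forward(c1$forward(x, training), training))
    h <- b2$forward(c2$forward(h, training), training)
    sc <- if (is.null(proj)) x else proj$forward(x, training)
    ag_relu(ag_add(h, sc))
  }
  m
}

# Local-aware block: 3x3 conv + BN + ReLU, then a 3x3 depthwise convolution
# whose sigmoid output gates the features locally, with a residual add
hn_lab <- function(C) {
  conv <- hn_conv2d(C, C, kernel = 3L)
  bn <- hn_batchnorm(C)
  dw <- hn_conv2d(C, C, kernel = 3L, groups = C)
  m <- hn_module(forward = NULL, children = list(conv = conv, bn = bn, dw = dw),
                 type = "lab")
  m$forward <- function(x, training = FALSE) {
    h <- ag_relu(bn$forward(conv$forward(x, training), training))
    gate <- ag_sigmoid(dw$forward(h, training))
    ag_add(x, ag_mul(h, gate))
  }
  m
}

# --- optimisers -------------------------------------------------------------

#' @keywords internal
hn_optimizer <- function(params, type = c("adam", "sgd"), lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, momentum = 0.9) {
  type <- match.arg(type)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(params, function(p) p$value * 0) # zeros, same shape class
  st$v <- lapply(params, function(p) p$value * 0)
  step <- function(lr_now = lr) {
    st$t <- st$t + 1L
    for (k in seq_along(params)) {
      p <- params[[k]]
      g <- p$grad
      if (is.null(g)) next
      if (type == "adam") {
        st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
        st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g^2
        mhat <- st$m[[k]] / (1 - beta1^st$t)
        vhat <- st$v[[k]] / (1 - beta2^st$t)
        p$value <- p$value - lr_now * mhat / (sqrt(vhat) + eps)
      } else {
        st$m[[k]] <- momentum * st$m[[k]] + g
        p$value <- p$value - lr_now * st$m[[k]]
      }
    }
  }
  list(step = step, params = params, state = st, lr = lr, type = type)
}
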
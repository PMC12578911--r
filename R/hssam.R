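# Hyper-scale shifted aggregation: multi-stage encoding aggregation (MSEA)
# over adaptively max-pooled encoder features, and shifted-submap aggregation
# (SSAM) over five complementary crops of the relatively high-resolution
# feature, governed by the shift-ratio calculus.

#' Shift ratio of the shifted-submap aggregation
#'
#' The shift ratio halves at each successive stage and is therefore
#' parameterised as `theta = 1 / 2^z` for a positive integer `z`.
#'
#' @param z positive integer exponent.
#' @return `2^(-z)`, a real number in `(0, 1/2]`.
#' @examples
#' shift_ratio(1) # 0.5
#' shift_ratio(3) # 0.125
#' @export
shift_ratio <- function(z) {
  if (!is.numeric(z) || length(z) != 1L || z < 1 || z != round(z))
    stop("'z' must be a single integer >= 1")
  2^(-z)
}

#' Specification of a convolution layer for receptive-field analysis
#'
#' @param kernel_size positive odd kernel size.
#' @param stride positive integer stride.
#' @param expansion dilation (expansion) factor.
#' @export
conv_layer_spec <- function(kernel_size, stride = 1L, expansion = 1L) {
  stopifnot(kernel_size >= 1, stride >= 1, expansion >= 1)
  structure(list(kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 expansion = as.integer(expansion)),
            class = "conv_layer_spec")
}

#' Receptive field of a convolution stack
#'
#' Computes the one-dimensional input span that influences a single output
#' cell of a sequence of (possibly strided, dilated) convolutions, using the
#' standard recursion: the span grows by `(kernel - 1) * dilation` times the
#' cumulative stride of all preceding layers.
#'
#' `literal = TRUE` switches to an alternative recursion in which the whole
#' bracket is multiplied by the cumulative stride at every step; this form
#' disagrees with an impulse-influence count whenever strides exceed 1 and is
#' retained only for comparison.
#'
#' @param layers a list of [conv_layer_spec()] objects, ordered input to
#'   output.
#' @param literal use the non-standard recursion (default `FALSE`).
#' @return positive integer receptive-field span in input cells.
#' @examples
#' receptive_field(list(conv_layer_spec(3), conv_layer_spec(3))) # 5
#' @export
receptive_field <- function(layers, literal = FALSE) {
  if (!length(layers)) stop("'layers' must be a non-empty list")
  if (inherits(layers, "conv_layer_spec")) layers <- list(layers)
  if (literal) {
    r <- 1
    for (ly in layers) {
      r <- (r + ly$expansion * (ly$kernel_size - 1)) * ly$stride
    }
    return(r)
  }
  r <- 1
  jump <- 1
  for (ly in layers) {
    r <- r + ly$expansion * (ly$kernel_size - 1) * jump
    jump <- jump * ly$stride
  }
  as.integer(r)
}

#' Shift specification for shifted-submap aggregation
#'
#' @param L maximum of the source map's height and width.
#' @param z positive integer; the shift ratio is `theta = 1 / 2^z`.
#' @param L_rm length of the missing margin; defaults to `theta * L` (the
#'   margin lost to a single shift).
#' @param psi positive scaling factor of the feasibility condition
#'   (default 1).
#' @export
shift_spec <- function(L, z = 1L, L_rm = NULL, psi = 1) {
  stopifnot(L >= 1, psi > 0)
  theta <- shift_ratio(z)
  if (is.null(L_rm)) L_rm <- theta * L
  if (L_rm < 0 || L_rm > L) stop("'L_rm' must lie in [0, L]")
  structure(list(L = L, L_rm = L_rm, z = as.integer(z), theta = theta, psi = psi),
            class = "shift_spec")
}

#' Feasibility of a shifted-submap configuration
#'
#' The five shifted submaps are complementary and the central shift stays
#' within the receptive field whenever
#' `rf * L / (2^(z+1) * psi) >= L_rm / L`.
#'
#' @param rf receptive-field span of the first decoder kernel relative to the
#'   source feature (see [receptive_field()]).
#' @param spec a [shift_spec()].
#' @return `TRUE` when the condition holds.
#' @export
shift_feasible <- function(rf, spec) {
  stopifnot(inherits(spec, "shift_spec"), rf >= 0)
  lhs <- rf * spec$L / (2^(spec$z + 1) * spec$psi)
  rhs <- spec$L_rm / spec$L
  lhs >= rhs
}

#' Collect a shifted submap
#'
#' Crops a contiguous submap of side `round((1 - theta) * dim)` per spatial
#' dimension. The four corner variants are anchored at the four corners of
#' the source map; the `center` variant is offset by `floor(theta * dim / 2)`.
#' For `theta <= 1/2` the five crops jointly cover every cell of the source.
#'
#' @param f feature map `(H, W)`, `(H, W, C)` or `(H, W, C, N)`.
#' @param theta shift ratio in `[0, 1/2]`; `0` returns the identity crop.
#' @param which one of `"center"`, `"up-left"`, `"up-right"`, `"down-left"`,
#'   `"down-right"`.
#' @return the cropped feature map.
#' @export
narrow <- function(f, theta,
                   which = c("center", "up-left", "up-right",
                             "down-left", "down-right")) {
  which <- match.arg(which)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta > 0.5)
    stop("'theta' must lie in [0, 1/2]")
  lf <- .lift4(f)
  d <- dim(lf$x)
  ch <- round((1 - theta) * d[1])
  cw <- round((1 - theta) * d[2])
  if (ch < 1 || cw < 1) stop("crop smaller than one pixel")
  off <- switch(which,
    "up-left" = c(0L, 0L),
    "up-right" = c(0L, d[2] - cw),
    "down-left" = c(d[1] - ch, 0L),
    "down-right" = c(d[1] - ch, d[2] - cw),
    "center" = c(floor(theta * d[1] / 2), floor(theta * d[2] / 2))
  )
  out <- lf$x[off[1] + seq_len(ch), off[2] + seq_len(cw), , , drop = FALSE]
  .drop4(out, lf$rank)
}

.narrow_variants <- c("center", "up-left", "up-right", "down-left", "down-right")

#' Offsets and size of a narrow crop (without materialising it)
#' @keywords internal
narrow_window <- function(h, w, theta, which) {
  ch <- round((1 - theta) * h); cw <- round((1 - theta) * w)
  off <- switch(which,
    "up-left" = c(0L, 0L),
    "up-right" = c(0L, w - cw),
    "down-left" = c(h - ch, 0L),
    "down-right" = c(h - ch, w - cw),
    "center" = c(floor(theta * h / 2), floor(theta * w / 2))
  )
  list(row0 = off[1] + 1L, row1 = off[1] + ch, col0 = off[2] + 1L, col1 = off[2] + cw)
}

#' Multi-stage encoding aggregation (MSEA)
#'
#' Adaptively max-pools each contributing encoder feature to a common target
#' size, sums them elementwise and applies a learned bottleneck (1x1
#' convolution, batch normalisation, ReLU).
#'
#' @param contributing list of feature maps sharing a channel count.
#' @param target_h,target_w target spatial size.
#' @param bottleneck an internal bottleneck module (e.g. from
#'   [hssam_module()]); `NULL` returns the pre-bottleneck sum, which is
#'   useful for testing the aggregation in isolation.
#' @param pool `"adaptive"` (adaptive max pooling, default) or `"maxdp"`
#'   (max-diagonal pooling max branch when the size ratio is exactly two).
#' @return the aggregated feature map as a plain array.
#' @export
msea <- function(contributing, target_h, target_w, bottleneck = NULL,
                 pool = c("adaptive", "maxdp")) {
  pool <- match.arg(pool)
  if (!length(contributing)) stop("'contributing' must be a non-empty list")
  lifted <- lapply(contributing, function(f) .lift4(f)$x)
  cs <- vapply(lifted, function(x) dim(x)[3], numeric(1))
  if (length(unique(cs)) != 1L)
    stop("contributing maps must share a channel count (project first)")
  acc <- NULL
  for (x in lifted) {
    d <- dim(x)
    if (pool == "maxdp" && d[1] == 2L * target_h && d[2] == 2L * target_w) {
      p <- cpp_maxdiag_pool(x)$max_map
    } else {
      p <- cpp_adaptive_pool(x, as.integer(target_h), as.integer(target_w), 0L)$out
    }
    acc <- if (is.null(acc)) p else acc + p
  }
  if (!is.null(bottleneck)) acc <- bottleneck$forward(ag_const(acc))$value
  .drop4(acc, .lift4(contributing[[1]])$rank)
}

#' Shifted-submap aggregation (SSAM)
#'
#' Collects the five complementary shifted submaps of a high-resolution
#' feature, adaptively average-pools each to the target size, sums them and
#' applies a parameter-shared bottleneck. If the shift configuration is
#' infeasible (see [shift_feasible()]) a warning is raised and only the
#' center submap is used.
#'
#' @param f the source feature map.
#' @param spec a [shift_spec()].
#' @param target_h,target_w target spatial size.
#' @param shared_bottleneck internal bottleneck module; `NULL` returns the
#'   pre-bottleneck sum.
#' @param rf receptive-field span used for the feasibility check (default 3,
#'   a single 3x3 decoder kernel).
#' @return the aggregated feature map as a plain array.
#' @export
ssam <- function(f, spec, target_h, target_w, shared_bottleneck = NULL, rf = 3L) {
  stopifnot(inherits(spec, "shift_spec"))
  variants <- .narrow_variants
  if (!shift_feasible(rf, spec)) {
    warning("infeasible shift specification; falling back to the center submap")
    variants <- "center"
  }
  lf <- .lift4(f)
  acc <- NULL
  for (v in variants) {
    sub <- narrow(lf$x, spec$theta, v)
    p <- cpp_adaptive_pool(sub, as.integer(target_h), as.integer(target_w), 1L)$out
    acc <- if (is.null(acc)) p else acc + p
  }
  if (!is.null(shared_bottleneck)) acc <- shared_bottleneck$forward(ag_const(acc))$value
  .drop4(acc, lf$rank)
}

# --- network-facing module --------------------------------------------------

# HSSAM block for stage i: aggregates f_i with the projected f_{i+1} (MSEA,
# adaptive max pooling) and the five shifted submaps of f_i (SSAM, adaptive
# average pooling), then fuses pre-bottleneck sums through one shared
# bottleneck. Operates on autograd tensors.
hn_hssam <- function(c_i, c_next, z = 1L, psi = 1, enable_ssam = TRUE,
                     msea_pool = "adaptive") {
  proj <- hn_bottleneck(c_next, c_i)
  bott <- hn_bottleneck(c_i, c_i)
  theta <- shift_ratio(z)
  m <- hn_module(forward = NULL,
                 children = list(proj_next = proj, bottleneck = bott),
                 type = "hssam", theta = theta, z = z, psi = psi,
                 enable_ssam = enable_ssam)
  m$forward <- function(inputs, training = FALSE) {
    f_i <- inputs$f_i
    f_next <- inputs$f_next
    d <- dim(f_i$value)
    th <- d[1]; tw <- d[2]
    pn <- proj$forward(f_next, training)
    acc <- ag_add(ag_adaptive_max(f_i, th, tw), ag_adaptive_max(pn, th, tw))
    if (enable_ssam) {
      spec <- shift_spec(max(th, tw), z = z, psi = psi)
      variants <- if (shift_feasible(3L, spec)) .narrow_variants else "center"
      for (v in variants) {
        wnd <- narrow_window(th, tw, theta, v)
        sub <- ag_crop(f_i, wnd$row0, wnd$row1, wnd$col0, wnd$col1)
        acc <- ag_add(acc, ag_adaptive_avg(sub, th, tw))
      }
    }
    bott$forward(acc, training)
  }
  m
}

#' Build a standalone HSSAM aggregation module
#'
#' Constructs the learned projections and bottleneck for one skip-connection
#' stage, seeded for reproducibility.
#'
#' @param c_i channel count of the stage feature `f_i`.
#' @param c_next channel count of the deeper feature `f_(i+1)`.
#' @param z shift exponent (`theta = 1/2^z`).
#' @param psi feasibility scaling factor.
#' @param enable_ssam include the shifted-submap path.
#' @param seed RNG seed fixing the parameter initialisation.
#' @export
hssam_module <- function(c_i, c_next, z = 1L, psi = 1, enable_ssam = TRUE,
                         seed = 42L) {
  set.seed(seed)
  hn_hssam(c_i, c_next, z = z, psi = psi, enable_ssam = enable_ssam)
}

#' Aggregated skip feature for one stage
#'
#' Runs the hyper-scale shifted aggregation for stage `stage_i` of a 5-stage
#' encoder pyramid: the stage feature and its deeper neighbour are aggregated
#' by MSEA, the stage feature additionally by SSAM, and the fused sum passes
#' through the shared bottleneck. Stage 5 has no aggregation (its feature
#' feeds the decoder directly).
#'
#' @param stage_i stage index in 1..4.
#' @param features list of stage feature maps `f_1 .. f_5`, spatial size
#'   halving per stage.
#' @param params module built by [hssam_module()]; built on the fly (seeded)
#'   when `NULL`.
#' @param training propagate batch statistics updates.
#' @return the aggregated feature `af_i` as a plain array at `f_i`'s size.
#' @export
hssam_forward <- function(stage_i, features, params = NULL, training = FALSE) {
  if (stage_i < 1 || stage_i > length(features) - 1L)
    stop("'stage_i' must be between 1 and ", length(features) - 1L,
         " (the deepest feature feeds the decoder directly)")
  f_i <- .lift4(features[[stage_i]])
  f_next <- .lift4(features[[stage_i + 1L]])
  if (is.null(params))
    params <- hssam_module(dim(f_i$x)[3], dim(f_next$x)[3])
  out <- params$forward(list(f_i = ag_const(f_i$x), f_next = ag_const(f_next$x)),
                        training)
  .drop4(out$value, f_i$rank)
}
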
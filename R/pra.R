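# Progressive reusing attention: progressive partial-to-global channel
# attention (PGCA) with weights in [0, 2], and multiscale reusing spatial
# attention (MRSA) with five branches of perceptible ranges 1 / 3 / 7 / 15 /
# global, each branch reusing the previous branch's output.

# --- PGCA -------------------------------------------------------------------

# Channel descriptor grid side: smallest S with S^2 >= C
pgca_grid_side <- function(C) as.integer(ceiling(sqrt(C)))

hn_pgca <- function(C, dilations = c(1L, 2L, 4L), zero_init = FALSE) {
  convs <- lapply(dilations, function(d)
    hn_conv2d(1L, 1L, kernel = 3L, dilation = d, zero_init = zero_init))
  names(convs) <- paste0("atrous", seq_along(convs))
  S <- pgca_grid_side(C)
  m <- hn_module(forward = NULL, children = convs, type = "pgca",
                 C = C, S = S, dilations = dilations)
  m$forward <- function(x, training = FALSE) {
    desc <- ag_global_avg(x)           # (1,1,C,N)
    grid <- ag_chan_to_grid(desc, S)   # zero-padded (S,S,1,N)
    h <- grid
    for (k in seq_along(convs)) {
      h <- convs[[k]]$forward(h, training)
      if (k < length(convs)) h <- ag_relu(h)
    }
    w <- ag_grid_to_chan(h, C)         # drop padded entries
    ag_scalar_mul(ag_sigmoid(w), 2)    # weights in [0, 2]
  }
  m
}

#' Progressive global channel attention (PGCA)
#'
#' Globally average-pools each channel into a 1-d descriptor, zero-pads it to
#' the smallest perfect square, reshapes it to a square grid to shorten
#' interaction distances, applies a progressive stack of dilated 3x3
#' convolutions (partial to global), drops the padded entries and maps the
#' result through `2 * sigmoid` so every channel weight lies in `[0, 2]` -
#' weights above 1 enhance a channel, weights below 1 suppress it.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param params module from [pgca_module()]; built on the fly when `NULL`.
#' @param seed seed used when building a module on the fly.
#' @return channel weights: a length-`C` vector (or `C x N` matrix).
#' @export
pgca <- function(x, params = NULL, seed = 42L) {
  lf <- .lift4(x)
  C <- dim(lf$x)[3]
  if (is.null(params)) params <- pgca_module(C, seed = seed)
  if (params$meta$C != C) stop("module was built for a different channel count")
  w <- params$forward(ag_const(lf$x))$value
  w <- matrix(w, nrow = C)
  if (ncol(w) == 1L) as.numeric(w) else w
}

#' Build a PGCA module
#'
#' @param C channel count the module operates on.
#' @param dilations dilation sequence of the progressive atrous stack.
#' @param zero_init zero-initialise all convolutions; every emitted weight is
#'   then exactly 1 (`2 * sigmoid(0)`), the identity scaling.
#' @param seed RNG seed fixing the parameter initialisation.
#' @export
pgca_module <- function(C, dilations = c(1L, 2L, 4L), zero_init = FALSE,
                        seed = 42L) {
  set.seed(seed)
  hn_pgca(C, dilations = dilations, zero_init = zero_init)
}

# --- MRSA -------------------------------------------------------------------

#' Branch layout of the multiscale reusing spatial attention
#'
#' @return a data frame with one row per branch: its kind, kernel size,
#'   dilation and perceptible range (kernel span `2 * dilation + 1` for the
#'   dilated branches).
#' @export
mrsa_branch_specs <- function() {
  data.frame(
    branch = 1:5,
    kind = c("pointwise", "dilated3x3", "dilated3x3", "dilated3x3", "global"),
    kernel = c(1L, 3L, 3L, 3L, NA),
    dilation = c(NA, 1L, 3L, 7L, NA),
    range = c(1, 3, 7, 15, Inf)
  )
}

hn_mrsa <- function(C, compress = NULL, activation = c("sigmoid", "sigmoid2"),
                    zero_init = FALSE) {
  activation <- match.arg(activation)
  k <- compress %||% max(4L, C %/% 4L)
  comp <- hn_conv2d(C, k, kernel = 1L, zero_init = zero_init)
  b1 <- hn_conv2d(k, k, kernel = 1L, zero_init = zero_init)
  b2 <- hn_conv2d(k, k, kernel = 3L, dilation = 1L, zero_init = zero_init)
  b3 <- hn_conv2d(k, k, kernel = 3L, dilation = 3L, zero_init = zero_init)
  b4 <- hn_conv2d(k, k, kernel = 3L, dilation = 7L, zero_init = zero_init)
  b5 <- hn_conv2d(k, k, kernel = 1L, zero_init = zero_init)
  fuse <- hn_conv2d(5L * k, 1L, kernel = 1L, zero_init = zero_init)
  m <- hn_module(forward = NULL,
                 children = list(compress = comp, branch1 = b1, branch2 = b2,
                                 branch3 = b3, branch4 = b4, branch5 = b5,
                                 fuse = fuse),
                 type = "mrsa", C = C, k = k, activation = activation,
                 reuse = TRUE)
  m$forward <- function(x, training = FALSE, reuse = m$meta$reuse %||% TRUE) {
    d <- dim(x$value)
    xc <- comp$forward(x, training)
    nxt <- function(prev) if (reuse && !is.null(prev)) ag_add(xc, prev) else xc
    o1 <- b1$forward(xc, training)
    o2 <- b2$forward(nxt(o1), training)
    o3 <- b3$forward(nxt(o2), training)
    o4 <- b4$forward(nxt(o3), training)
    ctx <- ag_global_avg(nxt(o4))
    o5 <- ag_broadcast_spatial(b5$forward(ctx, training), d[1], d[2])
    cat5 <- ag_concat_channels(list(o1, o2, o3, o4, o5))
    s <- ag_sigmoid(fuse$forward(cat5, training))
    if (activation == "sigmoid2") s <- ag_scalar_mul(s, 2)
    s
  }
  m
}

#' Multiscale reusing spatial attention (MRSA)
#'
#' Compresses the input channels, then runs five parallel branches with
#' perceptible ranges 1 (pointwise), 3 / 7 / 15 (3x3 kernels with dilations
#' 1, 3, 7) and global (pooled context, broadcast). Each branch reuses the
#' previous branch's output by adding it to the compressed input, so
#' large-scale awareness is built on top of the small-scale branches. The
#' five outputs are concatenated, fused by a 1x1 convolution and mapped
#' through a sigmoid; no batch normalisation is used anywhere in the module.
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param params module from [mrsa_module()]; built on the fly when `NULL`.
#' @param seed seed used when building a module on the fly.
#' @return spatial weight map `(H, W)` (or `(H, W, 1, N)`) with values in
#'   `[0, 1]`.
#' @export
mrsa <- function(x, params = NULL, seed = 42L) {
  lf <- .lift4(x)
  C <- dim(lf$x)[3]
  if (is.null(params)) params <- mrsa_module(C, seed = seed)
  s <- params$forward(ag_const(lf$x))$value
  if (lf$rank <= 3L) s <- matrix(s[, , 1, 1], dim(s)[1], dim(s)[2])
  s
}

#' Build an MRSA module
#'
#' @param C input channel count.
#' @param compress width of the compressed representation each branch works
#'   on; default `max(4, C / 4)`.
#' @param activation `"sigmoid"` (range `[0, 1]`, default) or `"sigmoid2"`
#'   (range `[0, 2]`).
#' @param zero_init zero-initialise all convolutions (identity-weight
#'   configuration: every spatial weight is `sigmoid(0) = 0.5`).
#' @param seed RNG seed fixing the parameter initialisation.
#' @export
mrsa_module <- function(C, compress = NULL, activation = "sigmoid",
                        zero_init = FALSE, seed = 42L) {
  set.seed(seed)
  hn_mrsa(C, compress = compress, activation = activation, zero_init = zero_init)
}

#' Impulse-response support of a dilated convolution branch
#'
#' Builds a single-channel convolution with all weights set to one and zero
#' bias, feeds a zero image with a single central impulse, and measures the
#' spatial width of the nonzero response - the perceptible range of the
#' branch. For a 3x3 kernel with dilation `d` this equals `2 * d + 1`.
#'
#' @param kernel_size kernel size of the branch convolution.
#' @param dilation dilation (expansion) factor.
#' @param size side length of the probe image (default 41).
#' @return integer support width in pixels.
#' @export
impulse_response_span <- function(kernel_size = 3L, dilation = 1L, size = 41L) {
  conv <- hn_conv2d(1L, 1L, kernel = kernel_size, dilation = dilation,
                    zero_init = TRUE)
  conv$params$weight$value[] <- 1
  x <- array(0, dim = c(size, size, 1L, 1L))
  ctr <- (size + 1L) %/% 2L
  x[ctr, ctr, 1, 1] <- 1
  y <- conv$forward(ag_const(x))$value
  nz <- which(y[, , 1, 1] != 0, arr.ind = TRUE)
  as.integer(max(nz[, 1]) - min(nz[, 1]) + 1L)
}

# --- combined attention -----------------------------------------------------

hn_pra <- function(C, pgca_dilations = c(1L, 2L, 4L), mrsa_compress = NULL,
                   mrsa_activation = "sigmoid", zero_init = FALSE) {
  pg <- hn_pgca(C, dilations = pgca_dilations, zero_init = zero_init)
  ms <- hn_mrsa(C, compress = mrsa_compress, activation = mrsa_activation,
                zero_init = zero_init)
  m <- hn_module(forward = NULL, children = list(pgca = pg, mrsa = ms),
                 type = "pra", C = C)
  m$forward <- function(x, training = FALSE) {
    w <- pg$forward(x, training)
    xc <- ag_scale_channels(x, w)
    s <- ms$forward(xc, training)
    ag_scale_spatial(xc, s)
  }
  m
}

#' Apply progressive reusing attention to a feature map
#'
#' Scales the input per channel by the PGCA weights, then per pixel by the
#' MRSA map of the channel-scaled feature (channel-then-spatial order).
#'
#' @param x feature map `(H, W, C)` or `(H, W, C, N)`.
#' @param params module from [pra_module()]; built on the fly when `NULL`.
#' @param seed seed used when building a module on the fly.
#' @return the attended feature map, same shape as `x`.
#' @export
pra_apply <- function(x, params = NULL, seed = 42L) {
  lf <- .lift4(x)
  C <- dim(lf$x)[3]
  if (is.null(params)) params <- pra_module(C, seed = seed)
  out <- params$forward(ag_const(lf$x))$value
  .drop4(out, lf$rank)
}

#' Build a combined PRA module (PGCA followed by MRSA)
#'
#' @inheritParams pgca_module
#' @param mrsa_compress,mrsa_activation forwarded to [mrsa_module()].
#' @param pgca_dilations forwarded to [pgca_module()].
#' @export
pra_module <- function(C, pgca_dilations = c(1L, 2L, 4L), mrsa_compress = NULL,
                       mrsa_activation = "sigmoid", zero_init = FALSE,
                       seed = 42L) {
  set.seed(seed)
  hn_pra(C, pgca_dilations = pgca_dilations, mrsa_compress = mrsa_compress,
         mrsa_activation = mrsa_activation, zero_init = zero_init)
}
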
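# Dual-branch max-diagonal pooling (Max-DP) and index-guided dual-input
# unpooling (Max-DUP).
#
# Feature maps are numeric arrays indexed (height, width) with optional
# trailing channel and batch dimensions: (H, W), (H, W, C) or (H, W, C, N).
# Both operators are parameter free and act independently per channel.

# lift an input to (H, W, C, N), remembering the original rank
.lift4 <- function(x) {
  if (is.null(dim(x))) stop("input must be a matrix or array, not a bare vector")
  d <- dim(x)
  if (length(d) < 2L || length(d) > 4L) stop("input must have 2 to 4 dimensions")
  if (any(d == 0L)) stop("input feature map is empty")
  rank <- length(d)
  dim(x) <- c(d, rep(1L, 4L - rank))
  list(x = x, rank = rank, dim = d)
}

.drop4 <- function(x, rank) {
  d <- dim(x)
  dim(x) <- d[seq_len(rank)]
  x
}

#' Max-diagonal pooling (Max-DP)
#'
#' Downsamples a feature map by a factor of two in each spatial dimension
#' while retaining, for every non-overlapping 2x2 window, both the window
#' maximum and the value in the diagonally opposite cell, together with the
#' positions both values came from. Keeping the diagonal partner halves the
#' maximum sampling interval of plain max pooling (from three cells to one)
#' and lets twice as many cells carry gradient.
#'
#' Ties are broken towards the first maximal cell in row-major order. Odd
#' spatial dimensions are reflect-padded by one row/column on the bottom/right
#' before pooling; the padding is recorded in the result so that
#' [max_diagonal_unpool()] can crop back to the original size.
#'
#' @param x numeric array `(H, W)`, `(H, W, C)` or `(H, W, C, N)`.
#' @param eps small positive stabiliser used by the optional window
#'   normalisation (default `1e-6`).
#' @param normalize if `TRUE`, each retained value is divided by the sum of
#'   its 2x2 window plus `eps` (see [window_normalize()]).
#' @return an object of class `hn_dual_pool`: a list with half-resolution
#'   `max_map` and `diag_map`, integer `max_idx` / `diag_idx` (0-based
#'   row-major positions in the padded input plane), the original `input_dim`,
#'   the `pad` applied on (bottom, right), and `eps`.
#' @examples
#' x <- matrix(c(5, 2, 1, 3), 2, 2, byrow = TRUE)
#' p <- max_diagonal_pool(x)
#' p$max_map  # 5
#' p$diag_map # 3
#' @export
max_diagonal_pool <- function(x, eps = 1e-6, normalize = FALSE) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a single positive number")
  lf <- .lift4(x)
  xi <- lf$x
  d <- dim(xi)
  pad <- c(d[1] %% 2L, d[2] %% 2L)
  if (any(pad > 0L)) {
    hp <- d[1] + pad[1]; wp <- d[2] + pad[2]
    xp <- array(0, dim = c(hp, wp, d[3], d[4]))
    xp[seq_len(d[1]), seq_len(d[2]), , ] <- xi
    rr <- max(d[1] - 1L, 1L); rc <- max(d[2] - 1L, 1L) # reflect (edge if size 1)
    if (pad[1]) xp[hp, seq_len(d[2]), , ] <- xi[rr, seq_len(d[2]), , ]
    if (pad[2]) xp[seq_len(d[1]), wp, , ] <- xi[seq_len(d[1]), rc, , ]
    if (pad[1] && pad[2]) xp[hp, wp, , ] <- xi[rr, rc, , ]
    xi <- xp
  }
  res <- cpp_maxdiag_pool(xi)
  if (normalize) {
    dd <- dim(xi)
    win_sum <- cpp_adaptive_pool(xi, dd[1] %/% 2L, dd[2] %/% 2L, 1L)$out * 4
    res$max_map <- res$max_map / (win_sum + eps)
    res$diag_map <- res$diag_map / (win_sum + eps)
  }
  rank <- lf$rank
  structure(
    list(
      max_map = .drop4(res$max_map, rank),
      diag_map = .drop4(res$diag_map, rank),
      max_idx = .drop4(res$max_idx, rank),
      diag_idx = .drop4(res$diag_idx, rank),
      input_dim = lf$dim,
      padded_dim = dim(xi)[1:2],
      pad = pad,
      eps = eps,
      normalized = normalize
    ),
    class = "hn_dual_pool"
  )
}

#' Normalise a 2x2 pooling window
#'
#' Divides each of the four window features by the stabilised window sum
#' `c = m + d + l1 + l2 + eps`. For non-negative features the four outputs sum
#' to `(c - eps) / c`, so the weights behave like a local soft occupancy that
#' adapts to the activation level of the window.
#'
#' @param m,d,l1,l2 the window maximum, its diagonal partner, and the two
#'   remaining features; vectors are normalised elementwise.
#' @param eps small positive stabiliser guarding against all-zero windows.
#' @return a list with normalised `m`, `d`, `l1`, `l2` and the divisor `c`.
#' @examples
#' window_normalize(4, 3, 1, 2)
#' @export
window_normalize <- function(m, d, l1, l2, eps = 1e-6) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("'eps' must be a single positive number")
  cc <- m + d + l1 + l2 + eps
  list(m = m / cc, d = d / cc, l1 = l1 / cc, l2 = l2 / cc, c = cc)
}

#' Max-diagonal unpooling (Max-DUP)
#'
#' Doubles the spatial resolution of a pooled feature map by combining a
#' dense "many-to-many" bilinear interpolation of the max branch with a
#' sparse "one-to-one" index-guided correction: the max-branch and
#' diagonal-branch values are written back to the exact cells they were
#' sampled from, overwriting the interpolated base there. This restores
#' high-frequency content at the recorded positions while keeping the
#' upsampled map spatially continuous elsewhere.
#'
#' @param max_in,diag_in pooled feature maps of identical shape (the max and
#'   diagonal branches).
#' @param max_idx,diag_idx integer index grids as produced by
#'   [max_diagonal_pool()] (0-based row-major positions in the output plane).
#' @param out_height,out_width the output spatial size; defaults to twice the
#'   input size. May be one less than twice the input size per dimension when
#'   the matching pooling step padded an odd input.
#' @param pool alternatively, an `hn_dual_pool` object; branches, indices and
#'   output size are then taken from it.
#' @return a feature map of size `(out_height, out_width)` with the channel
#'   and batch dimensions of the inputs.
#' @export
max_diagonal_unpool <- function(max_in = NULL, diag_in = NULL, max_idx = NULL,
                                diag_idx = NULL, out_height = NULL,
                                out_width = NULL, pool = NULL) {
  if (inherits(max_in, "hn_dual_pool")) pool <- max_in
  if (is.null(max_in) && is.null(pool)) stop("provide 'max_in' or 'pool'")
  if (!is.null(pool)) {
    max_in <- pool$max_map; diag_in <- pool$diag_map
    max_idx <- pool$max_idx; diag_idx <- pool$diag_idx
    out_height <- pool$input_dim[1]; out_width <- pool$input_dim[2]
    if (pool$normalized)
      warning("unpooling window-normalized maps does not invert the pooling")
  }
  lm <- .lift4(max_in); ld <- .lift4(diag_in)
  if (!identical(dim(lm$x), dim(ld$x)))
    stop("'max_in' and 'diag_in' must have identical shapes")
  d <- dim(lm$x)
  ph <- 2L * d[1]; pw <- 2L * d[2]
  if (is.null(out_height)) out_height <- ph
  if (is.null(out_width)) out_width <- pw
  if (!(out_height %in% c(ph - 1L, ph)) || !(out_width %in% c(pw - 1L, pw)))
    stop("output size must be twice the input size (minus recorded padding)")
  mi <- as.integer(max_idx); di <- as.integer(diag_idx)
  if (any(mi < 0L) || any(mi >= ph * pw) || any(di < 0L) || any(di >= ph * pw))
    stop("sampling index out of output bounds")
  dim(mi) <- dim(lm$x); dim(di) <- dim(lm$x)
  out <- cpp_maxdiag_unpool(lm$x, ld$x, mi, di, ph, pw)
  out <- out[seq_len(out_height), seq_len(out_width), , , drop = FALSE]
  .drop4(out, max(lm$rank, 2L))
}

#' Bilinear resize of a feature map
#'
#' Half-pixel-centre bilinear interpolation to an arbitrary spatial size,
#' applied independently per channel.
#'
#' @param x numeric array `(H, W)`, `(H, W, C)` or `(H, W, C, N)`.
#' @param out_height,out_width target spatial size.
#' @export
bilinear_resize <- function(x, out_height, out_width) {
  lf <- .lift4(x)
  out <- cpp_bilinear(lf$x, as.integer(out_height), as.integer(out_width))
  .drop4(out, lf$rank)
}
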
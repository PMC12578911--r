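# Seeded generator of endoscopy-like image/mask pairs. The generator
# emulates the challenges that make polyp segmentation hard - variable
# polyp sizes, irregular boundaries, poor contrast against the mucosa and
# specular highlight artifacts - without claiming photographic realism.

#' Parameters of the synthetic endoscopy generator
#'
#' @param height,width image size in pixels.
#' @param n_polyps number of polyps per image (0 gives an all-background
#'   image with an empty mask).
#' @param polyp_area_fraction range `(min, max)` of the mask area as a
#'   fraction of the image; each polyp's target size is drawn uniformly from
#'   this range.
#' @param boundary_irregularity amplitude of the random radial harmonics
#'   (orders 2-8) modulating the polyp ellipse; 0 gives smooth ellipses.
#' @param contrast mean luminance offset of polyp tissue against the
#'   surrounding mucosa, in `(0, 1]`; small values emulate poor contrast.
#' @param n_highlights number of saturated specular blobs placed on and off
#'   the polyp.
#' @param noise_sd standard deviation of the fine per-pixel texture noise.
#' @param seed integer seed; the sample is fully determined by it.
#' @export
synth_params <- function(height = 64L, width = 64L, n_polyps = 1L,
                         polyp_area_fraction = c(0.05, 0.30),
                         boundary_irregularity = 0.3, contrast = 0.18,
                         n_highlights = 3L, noise_sd = 0.03, seed = 1L) {
  stopifnot(height >= 8L, width >= 8L, n_polyps >= 0L,
            length(polyp_area_fraction) == 2L,
            polyp_area_fraction[1] > 0, polyp_area_fraction[2] <= 0.9,
            polyp_area_fraction[1] <= polyp_area_fraction[2],
            boundary_irregularity >= 0, contrast > 0, contrast <= 1,
            n_highlights >= 0L, noise_sd >= 0)
  if (polyp_area_fraction[1] * height * width < 4)
    stop("minimum polyp area is below 4 pixels at this resolution")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_polyps = as.integer(n_polyps),
                 polyp_area_fraction = polyp_area_fraction,
                 boundary_irregularity = boundary_irregularity,
                 contrast = contrast, n_highlights = as.integer(n_highlights),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_params")
}

# smooth low-frequency field: coarse random grid upsampled bilinearly
.smooth_field <- function(h, w, mean, sd, coarse = 6L) {
  g <- array(stats::rnorm(coarse * coarse, mean, sd), dim = c(coarse, coarse, 1L))
  bilinear_resize(g, h, w)[, , 1]
}

# one radially perturbed ellipse mask; returns logical (h, w)
.polyp_mask <- function(h, w, target_frac, irregularity) {
  r0 <- sqrt(target_frac * h * w / pi)
  aspect <- stats::runif(1, 0.7, 1.4)
  rot <- stats::runif(1, 0, pi)
  orders <- 2:8
  amp_c <- stats::rnorm(length(orders), 0, 1) / orders
  amp_s <- stats::rnorm(length(orders), 0, 1) / orders
  norm <- max(1, sqrt(sum(amp_c^2 + amp_s^2)))
  amp_c <- amp_c / norm; amp_s <- amp_s / norm
  margin <- r0 * max(aspect, 1 / aspect) * (1 + irregularity) + 1
  cy <- stats::runif(1, min(margin, h / 2), max(h - margin, h / 2))
  cx <- stats::runif(1, min(margin, w / 2), max(w - margin, w / 2))
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  # rotate into ellipse frame
  u <- (yy * cos(rot) + xx * sin(rot)) / sqrt(aspect)
  v <- (-yy * sin(rot) + xx * cos(rot)) * sqrt(aspect)
  rho <- sqrt(u^2 + v^2)
  phi <- atan2(v, u)
  rboundary <- r0
  for (k in seq_along(orders))
    rboundary <- rboundary + r0 * irregularity *
      (amp_c[k] * cos(orders[k] * phi) + amp_s[k] * sin(orders[k] * phi))
  mask <- rho <= rboundary
  # star-convex in the ellipse frame, hence one connected component;
  # rescale the radius until the realised area lands in a band around target
  frac <- mean(mask)
  tries <- 0L
  while (tries < 5L && frac > 0 && abs(frac - target_frac) / target_frac > 0.15) {
    s <- sqrt(target_frac / frac)
    rboundary <- rboundary * s
    mask <- rho <= rboundary
    frac <- mean(mask)
    tries <- tries + 1L
  }
  mask
}

#' Generate one synthetic endoscopy-like sample
#'
#' Produces a mucosa-like textured background (smooth low-frequency reddish
#' field plus fine noise), `n_polyps` radially perturbed ellipses filled with
#' contrast-shifted tissue texture, saturated specular highlights, and the
#' exact binary polyp mask. Fully determined by the seed in `params`.
#'
#' @param params a [synth_params()] object.
#' @return a list of class `synth_sample` with `image` (`H x W x 3` array in
#'   `[0, 1]`), `mask` (logical `H x W`) and `params`.
#' @export
generate_sample <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  h <- params$height; w <- params$width
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- .smooth_field(h, w, 0.55, 0.08)
  img[, , 2] <- .smooth_field(h, w, 0.26, 0.05)
  img[, , 3] <- .smooth_field(h, w, 0.24, 0.05)
  mask <- matrix(FALSE, h, w)
  if (params$n_polyps > 0) {
    for (k in seq_len(params$n_polyps)) {
      frac <- stats::runif(1, params$polyp_area_fraction[1],
                           params$polyp_area_fraction[2])
      mask <- mask | .polyp_mask(h, w, frac, params$boundary_irregularity)
    }
  }
  # polyp tissue: luminance lifted by the configured contrast, slightly
  # redder, with its own low-frequency texture
  shift <- params$contrast * c(1.15, 0.95, 0.9)
  tex <- .smooth_field(h, w, 0, params$contrast * 0.25)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- plane[mask] + shift[ch] + tex[mask]
    img[, , ch] <- plane
  }
  # fine per-pixel noise everywhere
  img <- img + array(stats::rnorm(h * w * 3, 0, params$noise_sd), dim = dim(img))
  # specular highlights: small saturated blobs, some centred on the polyp
  if (params$n_highlights > 0) {
    on_polyp_pool <- which(mask)
    for (k in seq_len(params$n_highlights)) {
      on_polyp <- length(on_polyp_pool) > 0 && stats::runif(1) < 0.5
      if (on_polyp) {
        pos <- on_polyp_pool[sample.int(length(on_polyp_pool), 1L)]
        cy <- (pos - 1L) %% h + 1L
        cx <- (pos - 1L) %/% h + 1L
      } else {
        cy <- sample.int(h, 1L); cx <- sample.int(w, 1L)
      }
      rad <- stats::runif(1, 1, 2.5)
      yy <- matrix(seq_len(h), h, w) - cy
      xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
      blob <- exp(-(yy^2 + xx^2) / (2 * (rad / 2)^2))
      core <- blob > 0.4
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane <- pmax(plane, blob)
        plane[core] <- 1
        img[, , ch] <- plane
      }
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(list(image = img, mask = mask, params = params),
            class = "synth_sample")
}

#' Generate a list of synthetic samples with a split assignment
#'
#' In-memory counterpart of [generate_dataset()]; per-sample seeds are drawn
#' from the dataset seed so the whole collection is reproducible.
#'
#' @param n number of samples (at least 10).
#' @param params template [synth_params()]; its seed field is replaced per
#'   sample.
#' @param split train/validation/test fractions summing to 1.
#' @param seed dataset-level seed.
#' @return list with `samples` (list of `synth_sample`) and `split`
#'   (character vector of assignments).
#' @export
generate_samples <- function(n, params = synth_params(),
                             split = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(n >= 10L, abs(sum(split) - 1) < 1e-8)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    p <- params
    p$seed <- seeds[i]
    samples[[i]] <- generate_sample(p)
  }
  n_val <- floor(n * split[2])
  n_test <- floor(n * split[3])
  n_train <- n - n_val - n_test # train absorbs the rounding remainder
  assign <- c(rep("train", n_train), rep("val", n_val), rep("test", n_test))
  assign <- assign[sample.int(n, n)] # seeded shuffle
  list(samples = samples, split = assign, seed = seed)
}

#' Generate a synthetic dataset on disk with a manifest
#'
#' Writes `images/<id>.png` (RGB) and `masks/<id>.png` (single channel,
#' 0/255), a `manifest.csv` with columns `id, image_path, mask_path, split`,
#' and a `metadata.json` recording the generation parameters and seed.
#'
#' @inheritParams generate_samples
#' @param dir output directory (created if missing).
#' @return the manifest as a data frame (invisibly, with attribute `dir`).
#' @export
generate_dataset <- function(n, dir, params = synth_params(),
                             split = c(0.8, 0.1, 0.1), seed = 1L) {
  ds <- generate_samples(n, params, split, seed)
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  ids <- sprintf("sample_%04d", seq_len(n))
  img_paths <- file.path("images", paste0(ids, ".png"))
  mask_paths <- file.path("masks", paste0(ids, ".png"))
  for (i in seq_len(n)) {
    png::writePNG(ds$samples[[i]]$image, file.path(dir, img_paths[i]))
    png::writePNG(ds$samples[[i]]$mask * 1.0, file.path(dir, mask_paths[i]))
  }
  manifest <- data.frame(id = ids, image_path = img_paths,
                         mask_path = mask_paths, split = ds$split,
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  meta <- c(unclass(params), list(n = n, split = split, dataset_seed = seed))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"), auto_unbox = TRUE)
  attr(manifest, "dir") <- dir
  invisible(manifest)
}

#' Load a dataset manifest and its samples
#'
#' @param manifest path to a `manifest.csv` written by [generate_dataset()]
#'   (or following the same layout for real datasets).
#' @return list with `samples` and `split` in the in-memory layout of
#'   [generate_samples()].
#' @export
load_manifest <- function(manifest) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  dir <- dirname(manifest)
  tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  needed <- c("id", "image_path", "mask_path", "split")
  if (!all(needed %in% names(tab)))
    stop("manifest must have columns: ", paste(needed, collapse = ", "))
  samples <- lapply(seq_len(nrow(tab)), function(i) {
    img <- png::readPNG(file.path(dir, tab$image_path[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    msk <- png::readPNG(file.path(dir, tab$mask_path[i]))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    structure(list(image = img[, , 1:3], mask = msk > 0.5, params = NULL),
              class = "synth_sample")
  })
  list(samples = samples, split = tab$split, manifest = tab)
}
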
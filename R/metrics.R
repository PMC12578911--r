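# Boundary-aware evaluation suite for binary segmentation masks:
# Dice, HD95, mIoU, MAE, plus accuracy / precision / sensitivity /
# specificity. All operate on logical matrices (TRUE = polyp).

.as_mask <- function(m, arg = "mask") {
  if (is.null(dim(m)) || length(dim(m)) != 2L)
    stop("'", arg, "' must be a 2-d matrix")
  if (!is.logical(m)) {
    if (!all(m %in% c(0, 1))) stop("'", arg, "' must be logical or 0/1")
    m <- m > 0.5
  }
  m
}

.check_shapes <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes do not match: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
}

#' Threshold a probability map into a binary mask
#'
#' @param prob numeric matrix of foreground probabilities in `[0, 1]`.
#' @param threshold decision threshold (default 0.5); a pixel is foreground
#'   when its probability is greater than or equal to the threshold.
#' @export
binarize <- function(prob, threshold = 0.5) {
  prob >= threshold
}

#' Dice similarity coefficient
#'
#' `2 |P intersect G| / (|P| + |G|)` between the thresholded prediction and
#' the ground truth. Two empty masks are in perfect agreement and return 1.
#'
#' @param pred,gt binary masks of identical shape.
#' @return a value in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  pred <- .as_mask(pred, "pred"); gt <- .as_mask(gt, "gt")
  .check_shapes(pred, gt)
  sp <- sum(pred); sg <- sum(gt)
  if (sp + sg == 0) return(1)
  2 * sum(pred & gt) / (sp + sg)
}

#' 8-connected boundary of a binary mask
#'
#' A foreground pixel belongs to the boundary when any of its 8 neighbours
#' (with outside-image cells counting as background) is background.
#'
#' @param mask logical matrix.
#' @return logical matrix marking boundary pixels.
#' @export
mask_boundary <- function(mask) {
  mask <- .as_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  interior <- matrix(TRUE, h, w)
  for (dr in -1:1)
    for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      interior <- interior & pad[(2:(h + 1L)) + dr, (2:(w + 1L)) + dc]
    }
  mask & !interior
}

# directed distances: for each point of A (n x 2), distance to nearest of B
.directed_dists <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

#' 95th-percentile symmetric Hausdorff distance (HD95)
#'
#' Computed over the 8-connected boundary point sets of the two masks (the
#' standard convention in medical segmentation), in Euclidean pixel units.
#' For each direction the 95th percentile (linear interpolation) of the
#' point-to-set distances is taken; the symmetric value is the maximum of
#' the two directions. If exactly one mask is empty the configured penalty
#' (image diagonal by default) is returned; two empty masks give 0.
#'
#' @param pred,gt binary masks of identical shape.
#' @param boundary measure distances between boundary point sets (default)
#'   rather than full mask point sets.
#' @param empty_penalty distance returned when exactly one mask is empty;
#'   defaults to the image diagonal.
#' @return a non-negative distance in pixels.
#' @export
hd95 <- function(pred, gt, boundary = TRUE, empty_penalty = NULL) {
  pred <- .as_mask(pred, "pred"); gt <- .as_mask(gt, "gt")
  .check_shapes(pred, gt)
  if (sum(pred) == 0 && sum(gt) == 0) return(0)
  if (xor(sum(pred) == 0, sum(gt) == 0)) {
    return(empty_penalty %||% sqrt(nrow(pred)^2 + ncol(pred)^2))
  }
  pset <- if (boundary) mask_boundary(pred) else pred
  gset <- if (boundary) mask_boundary(gt) else gt
  P <- which(pset, arr.ind = TRUE)
  G <- which(gset, arr.ind = TRUE)
  hpg <- stats::quantile(.directed_dists(P, G), 0.95, names = FALSE, type = 7)
  hgp <- stats::quantile(.directed_dists(G, P), 0.95, names = FALSE, type = 7)
  max(hpg, hgp)
}

#' Confusion counts between two masks
#' @keywords internal
confusion_counts <- function(pred, gt) {
  pred <- .as_mask(pred, "pred"); gt <- .as_mask(gt, "gt")
  .check_shapes(pred, gt)
  list(tp = sum(pred & gt), fp = sum(pred & !gt),
       fn = sum(!pred & gt), tn = sum(!pred & !gt))
}

#' Mean intersection over union (mIoU)
#'
#' Mean over the foreground (polyp) and background classes of
#' `TP / (TP + FP + FN)`. A class absent from both masks scores 1.
#'
#' @param pred,gt binary masks of identical shape.
#' @return a value in `[0, 1]`.
#' @export
miou <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  iou_fg <- if (cc$tp + cc$fp + cc$fn == 0) 1 else cc$tp / (cc$tp + cc$fp + cc$fn)
  iou_bg <- if (cc$tn + cc$fp + cc$fn == 0) 1 else cc$tn / (cc$tn + cc$fp + cc$fn)
  (iou_fg + iou_bg) / 2
}

#' Mean absolute error between a prediction and a binary ground truth
#'
#' @param pred numeric matrix in `[0, 1]` (probabilities or a binary mask).
#' @param gt binary mask of the same shape.
#' @export
mae <- function(pred, gt) {
  gt <- .as_mask(gt, "gt")
  if (!identical(dim(pred), dim(gt)))
    stop("mask shapes do not match")
  mean(abs(as.numeric(pred) - as.numeric(gt)))
}

#' Pixel classification metrics: ACC, PPV, TPR, TNR
#'
#' Accuracy `(TP+TN)/N`, positive predictive value (precision) `TP/(TP+FP)`,
#' true positive rate (sensitivity) `TP/(TP+FN)` and true negative rate
#' (specificity) `TN/(TN+FP)`. A ratio with zero denominator returns 1 when
#' the corresponding reference set is empty (nothing to find, nothing
#' missed), matching the empty-mask convention of [dice()].
#'
#' @param pred,gt binary masks of identical shape.
#' @return named list with `acc`, `ppv`, `tpr`, `tnr`.
#' @export
confusion_metrics <- function(pred, gt) {
  cc <- confusion_counts(pred, gt)
  n <- cc$tp + cc$fp + cc$fn + cc$tn
  safe <- function(num, den) if (den == 0) 1 else num / den
  list(acc = (cc$tp + cc$tn) / n,
       ppv = safe(cc$tp, cc$tp + cc$fp),
       tpr = safe(cc$tp, cc$tp + cc$fn),
       tnr = safe(cc$tn, cc$tn + cc$fp))
}

#' Full metrics report for one prediction
#'
#' Computes Dice, HD95, mIoU, MAE, ACC, PPV, TPR and TNR for a predicted
#' probability map (or mask) against a ground-truth mask.
#'
#' @param prob numeric probability matrix in `[0, 1]`, or a binary mask.
#' @param gt binary ground-truth mask.
#' @param threshold binarisation threshold applied to `prob`.
#' @param boundary_hd95 compute HD95 on boundary point sets (default).
#' @return a one-row data frame with all eight metrics.
#' @export
seg_metrics <- function(prob, gt, threshold = 0.5, boundary_hd95 = TRUE) {
  gt <- .as_mask(gt, "gt")
  pred <- if (is.logical(prob)) prob else binarize(prob, threshold)
  cm <- confusion_metrics(pred, gt)
  data.frame(
    dice = dice(pred, gt),
    miou = miou(pred, gt),
    hd95 = hd95(pred, gt, boundary = boundary_hd95),
    mae = mae(prob, gt),
    acc = cm$acc, ppv = cm$ppv, tpr = cm$tpr, tnr = cm$tnr
  )
}

#' Aggregate per-image metric rows into a report with summary rows
#'
#' @param rows a data frame of per-image metric rows (e.g. from
#'   [seg_metrics()]), one row per image.
#' @param id optional identifiers for the rows.
#' @return a data frame with one row per image plus `mean` and `sd` summary
#'   rows, in the style of multi-run reporting tables.
#' @export
metrics_report <- function(rows, id = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  id <- id %||% as.character(seq_len(nrow(rows)))
  out <- cbind(data.frame(id = id, stringsAsFactors = FALSE), rows)
  means <- vapply(rows, mean, numeric(1))
  sds <- vapply(rows, stats::sd, numeric(1))
  summary_rows <- rbind(as.data.frame(as.list(means)), as.data.frame(as.list(sds)))
  summary_rows <- cbind(data.frame(id = c("mean", "sd")), summary_rows)
  rbind(out, summary_rows)
}

#' Write a metrics report to CSV and/or JSON
#'
#' @param report data frame from [metrics_report()].
#' @param csv,json output paths (skipped when `NULL`).
#' @export
write_metrics <- function(report, csv = NULL, json = NULL) {
  if (!is.null(csv)) utils::write.csv(report, csv, row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(report, json, dataframe = "rows", digits = NA)
  invisible(report)
}
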
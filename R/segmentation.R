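#' Classical gland-segmentation baseline
#'
#' A deterministic desk-scale stand-in for the learned segmentation stage:
#' Gaussian smoothing, local-mean adaptive thresholding, morphological
#' opening, and removal of small components. The stage is a pluggable
#' contract — any function mapping a grayscale image to a binary mask (e.g. a
#' trained network's predictions loaded from disk) can replace it upstream of
#' the morphometry.
#'
#' @param image grayscale matrix with values in `[0, 1]`.
#' @param config named list overriding defaults: `blur_sigma` (1),
#'   `window` (adaptive-threshold half-window, 15), `offset` (threshold
#'   offset above the local mean, 0.15), `opening_radius` (2),
#'   `min_area` (30). Defaults were calibrated on the synthetic generator's
#'   scenes.
#' @return 0/1 integer mask of the same dimensions.
#' @export
segment_baseline <- function(image, config = list()) {
  if (length(image) == 0) stop("empty image", call. = FALSE)
  stopifnot(is.matrix(image))
  cfg <- utils::modifyList(list(blur_sigma = 1, window = 15, offset = 0.15,
                                opening_radius = 2, min_area = 30), config)
  sm <- EBImage::imageData(EBImage::gblur(image, sigma = cfg$blur_sigma))
  bw <- EBImage::imageData(EBImage::thresh(sm, w = cfg$window, h = cfg$window,
                                           offset = cfg$offset))
  if (cfg$opening_radius > 0) {
    brush <- EBImage::makeBrush(2 * cfg$opening_radius + 1, shape = "disc")
    bw <- EBImage::imageData(EBImage::opening(bw, brush))
  }
  bw <- matrix(as.integer(bw > 0), nrow(image), ncol(image))
  if (is.finite(cfg$min_area) && cfg$min_area > 0) {
    comps <- label_glands(bw, min_area = 1)
    bw[] <- 0L
    for (cc in comps)
      if (cc$area >= cfg$min_area) bw[cbind(cc$rows, cc$cols)] <- 1L
  } else if (is.infinite(cfg$min_area)) {
    bw[] <- 0L
  }
  bw
}

#' Segmentation-quality metrics
#'
#' Pixel-wise confusion-matrix metrics of a predicted mask against a ground
#' truth: accuracy `(TP+TN)/all`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)` and intersection-over-union `TP/(TP+FP+FN)`. Empty
#' denominators use the conventions: sensitivity 1 when the truth has no
#' foreground, specificity 1 when it has no background, IoU 1 when both masks
#' are empty.
#'
#' @param pred,truth 0/1 matrices of identical dimensions.
#' @return A list of class `seg_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `iou`, and the raw counts `tp`, `tn`, `fp`, `fn`.
#' @export
evaluate_segmentation <- function(pred, truth) {
  assert_same_dim(pred, truth, "pred and truth masks")
  stopifnot(is_binary_mask(pred), is_binary_mask(truth))
  tp <- sum(pred == 1 & truth == 1)
  tn <- sum(pred == 0 & truth == 0)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  structure(list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 1 else tn / (tn + fp),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    tp = tp, tn = tn, fp = fp, fn = fn), class = "seg_metrics")
}

#' Aggregate segmentation metrics over a set of image pairs
#'
#' @param preds,truths lists of masks.
#' @param method `"mean"` (default): mean of per-image metrics, the reading
#'   used for the published "average intersection ratio"; `"pooled"`: metrics
#'   of the pooled pixel-level confusion matrix.
#' @return A `seg_metrics` list (without counts for `method = "mean"`).
#' @export
evaluate_segmentation_set <- function(preds, truths,
                                      method = c("mean", "pooled")) {
  method <- match.arg(method)
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  ms <- Map(evaluate_segmentation, preds, truths)
  if (method == "mean") {
    out <- lapply(c("accuracy", "sensitivity", "specificity", "iou"),
                  function(k) mean(vapply(ms, `[[`, 0, k)))
    return(structure(setNames(out, c("accuracy", "sensitivity",
                                     "specificity", "iou")),
                     class = "seg_metrics"))
  }
  counts <- lapply(c("tp", "tn", "fp", "fn"),
                   function(k) sum(vapply(ms, `[[`, 0, k)))
  names(counts) <- c("tp", "tn", "fp", "fn")
  with(counts, structure(list(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn == 0) 1 else tp / (tp + fn),
    specificity = if (tn + fp == 0) 1 else tn / (tn + fp),
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    tp = tp, tn = tn, fp = fp, fn = fn), class = "seg_metrics"))
}

#' Merge manual mask edits
#'
#' Applies the manual-correction step of the analysis workflow: regions
#' missed by the segmenter are added, spurious regions removed; removal has
#' precedence where an add and a remove region overlap.
#'
#' @param mask 0/1 matrix.
#' @param add_regions,remove_regions lists of 0/1 matrices of the same
#'   dimensions.
#' @return The edited 0/1 mask, `(mask | adds) & !removes`.
#' @export
apply_manual_edits <- function(mask, add_regions = list(),
                               remove_regions = list()) {
  stopifnot(is_binary_mask(mask))
  out <- mask == 1
  for (a in add_regions) {
    assert_same_dim(mask, a, "mask and add region")
    out <- out | (a == 1)
  }
  for (r in remove_regions) {
    assert_same_dim(mask, r, "mask and remove region")
    out <- out & (r != 1)
  }
  matrix(as.integer(out), nrow(mask), ncol(mask))
}
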
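# Counting metrics (DiC, absolute DiC, MSE, R-squared, percentage
# agreement) and segmentation metrics (pixel accuracy, IoU, Dice), plus
# report assembly over manifests and JSON serialization.

check_count_vectors <- function(pred, gt) {
  if (!is.numeric(pred) || !is.numeric(gt)) {
    stop_config("pred and gt must be numeric vectors")
  }
  if (length(pred) != length(gt)) {
    stop_config("pred (%d) and gt (%d) lengths differ",
                length(pred), length(gt))
  }
  if (!length(pred)) stop_config("empty prediction vector")
  invisible(TRUE)
}

#' Counting metrics
#'
#' `dic()` is the mean signed difference `pred - gt` (0 is unbiased);
#' `abs_dic()` the mean absolute difference; `mse_count()` the mean
#' squared difference; `r2_count()` the coefficient of determination
#' `1 - SS_res / SS_tot` of the ground truth; `percentage_agreement()`
#' the percentage of exact matches.
#'
#' @param pred,gt Equal-length numeric vectors of predicted and true leaf
#'   counts.
#' @return A scalar. `r2_count()` errors on constant ground truth, where
#'   the statistic is undefined.
#' @export
dic <- function(pred, gt) {
  check_count_vectors(pred, gt)
  mean(pred - gt)
}

#' @rdname dic
#' @export
abs_dic <- function(pred, gt) {
  check_count_vectors(pred, gt)
  mean(abs(pred - gt))
}

#' @rdname dic
#' @export
mse_count <- function(pred, gt) {
  check_count_vectors(pred, gt)
  mean((pred - gt)^2)
}

#' @rdname dic
#' @export
r2_count <- function(pred, gt) {
  check_count_vectors(pred, gt)
  ss_tot <- sum((gt - mean(gt))^2)
  if (ss_tot == 0) {
    stop_config("R^2 is undefined for constant ground truth")
  }
  1 - sum((gt - pred)^2) / ss_tot
}

#' @rdname dic
#' @export
percentage_agreement <- function(pred, gt) {
  check_count_vectors(pred, gt)
  100 * mean(pred == gt)
}

check_mask_pair <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask))) {
    stop_config("mask shapes differ")
  }
  if (!all(pred_mask %in% c(0, 1)) || !all(gt_mask %in% c(0, 1))) {
    stop_config("masks must be binary; threshold probability masks first")
  }
  invisible(TRUE)
}

#' Segmentation metrics
#'
#' `pixel_accuracy()` is the fraction of pixels on which the two binary
#' masks agree; `iou()` is intersection over union and `dice()` the Dice
#' coefficient `2|A n B| / (|A| + |B|)`. When both masks are empty, IoU
#' and Dice are defined as 1 (perfect agreement on "no leaf"); when
#' exactly one is empty they are 0. Probability masks must be thresholded
#' (see [normalize_mask()]) before calling.
#'
#' @param pred_mask,gt_mask Binary matrices/arrays of identical shape.
#' @return A scalar in `[0, 1]`.
#' @export
pixel_accuracy <- function(pred_mask, gt_mask) {
  check_mask_pair(pred_mask, gt_mask)
  mean(pred_mask == gt_mask)
}

#' @rdname pixel_accuracy
#' @export
iou <- function(pred_mask, gt_mask) {
  check_mask_pair(pred_mask, gt_mask)
  inter <- sum(pred_mask * gt_mask)
  union <- sum(pmax(pred_mask, gt_mask))
  if (union == 0) return(1)
  inter / union
}

#' @rdname pixel_accuracy
#' @export
dice <- function(pred_mask, gt_mask) {
  check_mask_pair(pred_mask, gt_mask)
  s <- sum(pred_mask) + sum(gt_mask)
  if (s == 0) return(1)
  2 * sum(pred_mask * gt_mask) / s
}

#' Assemble a counting-metrics report
#'
#' @param pred,gt Predicted and true counts (predictions are expected to
#'   be rounded integers; see [round_count()]).
#' @param raw Optional raw (unrounded) predictions; when given, raw-value
#'   MSE and R-squared are reported alongside for sensitivity analysis.
#' @return A `count_metrics_report` list with fields `dic`, `abs_dic`,
#'   `mse`, `r2`, `percentage_agreement`, `n`.
#' @export
count_metrics <- function(pred, gt, raw = NULL) {
  report <- list(dic = dic(pred, gt), abs_dic = abs_dic(pred, gt),
                 mse = mse_count(pred, gt), r2 = r2_count(pred, gt),
                 percentage_agreement = percentage_agreement(pred, gt),
                 n = length(pred))
  if (!is.null(raw)) {
    report$mse_raw <- mse_count(raw, gt)
    report$r2_raw <- r2_count(raw, gt)
  }
  structure(report, class = "count_metrics_report")
}

#' Assemble a segmentation-metrics report
#'
#' Pixels are pooled over all mask pairs, matching accuracy/IoU/Dice
#' computed over the whole evaluation set.
#'
#' @param pred_masks,gt_masks Lists of binary masks of equal length and
#'   per-pair equal shape.
#' @return A `seg_metrics_report` list with `accuracy`, `iou`, `dice`,
#'   `n_pixels`.
#' @export
seg_metrics <- function(pred_masks, gt_masks) {
  if (length(pred_masks) != length(gt_masks) || !length(pred_masks)) {
    stop_config("need equal, non-zero numbers of predicted and true masks")
  }
  tp <- fp <- fn <- agree <- total <- 0
  for (i in seq_along(pred_masks)) {
    p <- pred_masks[[i]]; g <- gt_masks[[i]]
    check_mask_pair(p, g)
    tp <- tp + sum(p * g)
    fp <- fp + sum(p * (1 - g))
    fn <- fn + sum((1 - p) * g)
    agree <- agree + sum(p == g)
    total <- total + length(p)
  }
  structure(list(
    accuracy = agree / total,
    iou = if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn),
    dice = if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn),
    n_pixels = total
  ), class = "seg_metrics_report")
}

#' Evaluate a predictions CSV against a manifest
#'
#' The predictions CSV must have columns
#' `image_path,raw_prediction,rounded_count` (the format written by
#' [cmd_predict()]); every manifest record of the chosen split must have
#' exactly one prediction row and a ground-truth count. Unmatched records
#' are an error listing the offending paths.
#'
#' @param predictions_csv Path to the predictions CSV.
#' @param manifest Manifest data frame.
#' @param split Split to evaluate (default `"test"`).
#' @return A `count_metrics_report`.
#' @export
evaluate_counts <- function(predictions_csv, manifest, split = "test") {
  preds <- utils::read.csv(predictions_csv, stringsAsFactors = FALSE)
  need <- c("image_path", "raw_prediction", "rounded_count")
  if (!all(need %in% names(preds))) {
    stop_config("predictions CSV must have columns %s",
                paste(need, collapse = ", "))
  }
  manifest <- validate_manifest(manifest)
  recs <- manifest[manifest$split == split, ]
  missing <- setdiff(recs$image_path, preds$image_path)
  if (length(missing)) {
    stop_config("no prediction for: %s", paste(missing, collapse = ", "))
  }
  if (any(is.na(recs$count))) {
    stop_config("manifest records lack ground-truth counts")
  }
  m <- match(recs$image_path, preds$image_path)
  count_metrics(preds$rounded_count[m], recs$count,
                raw = preds$raw_prediction[m])
}

#' Evaluate predicted mask files against a manifest
#'
#' Reads predicted masks named like the ground-truth mask files from
#' `mask_dir`, thresholds them at 0.5, and pools segmentation metrics
#' over the chosen split.
#'
#' @param mask_dir Directory of predicted mask PNGs (basenames matching
#'   the manifest's `mask_path` basenames).
#' @param manifest Manifest data frame.
#' @param root Directory the manifest's ground-truth paths are relative
#'   to.
#' @param split Split to evaluate.
#' @return A `seg_metrics_report`.
#' @export
evaluate_masks <- function(mask_dir, manifest, root, split = "test") {
  manifest <- validate_manifest(manifest)
  recs <- manifest[manifest$split == split, ]
  if (!nrow(recs)) stop_config("no records in split '%s'", split)
  pred_files <- file.path(mask_dir, basename(recs$mask_path))
  missing <- pred_files[!file.exists(pred_files)]
  if (length(missing)) {
    stop_config("missing predicted masks: %s",
                paste(missing, collapse = ", "))
  }
  preds <- lapply(pred_files, read_mask)
  gts <- lapply(file.path(root, recs$mask_path), read_mask)
  seg_metrics(preds, gts)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `count_metrics_report` or `seg_metrics_report`.
#' @param path Output JSON path.
#' @param extra Named list of run metadata (split, seed, config hash, ...)
#'   embedded alongside the metrics.
#' @return The path, invisibly.
#' @export
write_metrics_report <- function(report, path, extra = list()) {
  task <- if (inherits(report, "seg_metrics_report")) {
    "segmentation"
  } else "counting"
  payload <- c(list(task = task), extra, list(metrics = unclass(report)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.count_metrics_report <- function(x, ...) {
  cat(sprintf(
    "Counting metrics (n = %d)\n  DiC %.4f | AbsDiC %.4f | MSE %.4f | R^2 %.4f | agreement %.2f%%\n",
    x$n, x$dic, x$abs_dic, x$mse, x$r2, x$percentage_agreement))
  invisible(x)
}

#' @export
print.seg_metrics_report <- function(x, ...) {
  cat(sprintf(
    "Segmentation metrics (%d pixels)\n  accuracy %.4f | IoU %.4f | Dice %.4f\n",
    x$n_pixels, x$accuracy, x$iou, x$dice))
  invisible(x)
}
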
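# Confusion-count segmentation metrics and small-lesion component analysis.
#
# All metrics are reported as percentages in [0, 100]. For binary
# segmentation, mIoU averages the foreground and background IoU. When a
# class is absent from both the ground truth and the prediction its IoU (or
# Dice) is conventionally 100% so that lesion-free slices predicted clean
# are not penalized; this is configurable via `empty_value`.

#' Pixel confusion counts
#'
#' @param pred_mask,gt_mask binary matrices/arrays of equal shape.
#' @return object of class `confusion_counts`: list with integer `tp`, `fp`,
#'   `fn`, `tn` summing to the pixel count.
#' @export
confusion_counts <- function(pred_mask, gt_mask) {
  p <- as.array(pred_mask); g <- as.array(gt_mask)
  if (!identical(dim(p), dim(g))) {
    stop("shape mismatch: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(g), collapse = "x"))
  }
  .check_binary(p, "pred_mask"); .check_binary(g, "gt_mask")
  structure(list(tp = sum(p == 1 & g == 1), fp = sum(p == 1 & g == 0),
                 fn = sum(p == 0 & g == 1), tn = sum(p == 0 & g == 0)),
            class = "confusion_counts")
}

# counts for the background class (complemented masks)
.counts_bg <- function(counts) {
  structure(list(tp = counts$tn, fp = counts$fn, fn = counts$fp,
                 tn = counts$tp), class = "confusion_counts")
}

.iou_one <- function(counts, empty_value = 100) {
  den <- counts$tp + counts$fp + counts$fn
  if (den == 0) return(empty_value)
  100 * counts$tp / den
}

#' Mean intersection-over-union (percent)
#'
#' Averages per-class IoU `TP / (TP + FP + FN)`. For binary masks pass a
#' single foreground `confusion_counts`; the background class is derived by
#' complementation. A list of per-class counts is also accepted.
#'
#' @param counts a `confusion_counts` (binary case) or list of per-class
#'   `confusion_counts`.
#' @param empty_value IoU assigned to a class absent from both masks
#'   (default 100; set to 0 or `NA` to change the convention).
#' @return mIoU in percent.
#' @export
miou <- function(counts, empty_value = 100) {
  per_class <- if (inherits(counts, "confusion_counts")) {
    list(fg = counts, bg = .counts_bg(counts))
  } else counts
  ious <- vapply(per_class, .iou_one, numeric(1), empty_value = empty_value)
  mean(ious, na.rm = is.na(empty_value))
}

#' Dice coefficient (percent)
#'
#' `2 TP / (2 TP + FP + FN)`; equals `2 IoU / (1 + IoU)` on the foreground.
#'
#' @param counts a `confusion_counts`.
#' @param empty_value value when gt and prediction are both empty.
#' @return Dice in percent.
#' @export
dice <- function(counts, empty_value = 100) {
  den <- 2 * counts$tp + counts$fp + counts$fn
  if (den == 0) return(empty_value)
  100 * 2 * counts$tp / den
}

#' F1 score (percent)
#'
#' The pixel-level (micro) F1 of the foreground class is algebraically
#' identical to the Dice coefficient; `variant = "macro"` instead averages
#' the per-class F1 over foreground and background, which differs whenever
#' the two classes are imbalanced.
#'
#' @param counts a `confusion_counts`.
#' @param variant `"micro"` (= Dice) or `"macro"` (mean over classes).
#' @param empty_value value for a class absent from both masks.
#' @return F1 in percent.
#' @export
f1 <- function(counts, variant = c("micro", "macro"), empty_value = 100) {
  variant <- match.arg(variant)
  if (variant == "micro") return(dice(counts, empty_value))
  mean(c(dice(counts, empty_value),
         dice(.counts_bg(counts), empty_value)),
       na.rm = is.na(empty_value))
}

#' Pixel accuracy (percent)
#'
#' @param counts a `confusion_counts`.
#' @return `(TP + TN) / total` in percent.
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$fp + counts$fn + counts$tn
  100 * (counts$tp + counts$tn) / total
}

#' Connected lesion components
#'
#' Labels foreground components (8-connectivity by default, the blob-lesion
#' convention) and returns their pixel areas in descending order.
#'
#' @param mask binary matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer vector of component areas, largest first, with attribute
#'   `labels` (the label matrix).
#' @export
lesion_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), connectivity %in% c(4L, 8L))
  .check_binary(mask)
  lab <- label_components_cpp(as.integer(mask), nrow(mask), ncol(mask),
                              connectivity == 8L)
  if (max(lab) == 0L) {
    return(structure(integer(0), labels = lab))
  }
  areas <- sort(tabulate(lab[lab > 0L]), decreasing = TRUE)
  structure(as.integer(areas), labels = lab)
}

#' Count small lesion components
#'
#' @param mask binary matrix.
#' @param threshold area threshold in pixels (components strictly below it
#'   count as small; default 100).
#' @return integer count of small components.
#' @export
count_small_lesions <- function(mask, threshold = 100L) {
  sum(lesion_components(mask) < threshold)
}

#' Per-image metric row
#'
#' @param pred_mask,gt_mask binary matrices.
#' @param id image identifier.
#' @param small_threshold area below which a gt component counts as small.
#' @return one-row data.frame: id, miou, dice, f1, acc, n_lesions,
#'   n_small_lesions, n_small_detected (small gt components overlapped by
#'   the prediction).
#' @export
image_metrics <- function(pred_mask, gt_mask, id = "",
                          small_threshold = 100L) {
  cc <- confusion_counts(pred_mask, gt_mask)
  comp <- lesion_components(gt_mask)
  lab <- attr(comp, "labels")
  small_ids <- which(tabulate(lab[lab > 0L]) < small_threshold)
  detected <- sum(vapply(small_ids, function(k) {
    any(pred_mask[lab == k] == 1)
  }, logical(1)))
  data.frame(id = id, miou = miou(cc), dice = dice(cc), f1 = f1(cc),
             acc = accuracy(cc), n_lesions = length(comp),
             n_small_lesions = length(small_ids),
             n_small_detected = detected)
}

#' Aggregate per-image confusion counts
#'
#' Micro aggregation sums the counts over images before computing metrics;
#' macro aggregation averages the per-image metric values. The two coincide
#' when all images are identical.
#'
#' @param counts_list list of `confusion_counts`.
#' @return data.frame with micro and macro mIoU/Dice/F1/accuracy.
#' @export
aggregate_metrics <- function(counts_list) {
  tot <- structure(list(tp = sum(vapply(counts_list, `[[`, 0, "tp")),
                        fp = sum(vapply(counts_list, `[[`, 0, "fp")),
                        fn = sum(vapply(counts_list, `[[`, 0, "fn")),
                        tn = sum(vapply(counts_list, `[[`, 0, "tn"))),
                   class = "confusion_counts")
  per <- function(f) vapply(counts_list, f, numeric(1))
  data.frame(
    aggregation = c("micro", "macro"),
    miou = c(miou(tot), mean(per(miou))),
    dice = c(dice(tot), mean(per(dice))),
    f1 = c(f1(tot), mean(per(f1))),
    acc = c(accuracy(tot), mean(per(accuracy))))
}
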
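#' Voxelwise confusion counts
#'
#' @param pred,truth 0/1 arrays or matrices of identical shape.
#' @return An object of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn` (their sum is the voxel count).
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  p <- pred == 1; t <- truth == 1
  structure(list(tp = sum(p & t), fp = sum(p & !t),
                 tn = sum(!p & !t), fn = sum(!p & t)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

.safe_ratio <- function(num, den, what, empty_is_one = FALSE) {
  if (den > 0) return(num / den)
  if (empty_is_one) return(1)
  warning(sprintf("%s undefined (zero denominator); returning 0", what))
  0
}

#' Overlap and voxel-classification scores
#'
#' Dice `2TP/(FP+2TP+FN)`, Jaccard `TP/(FP+TP+FN)`, recall `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)` and precision `TP/(TP+FP)`. A zero denominator
#' yields 0 with a warning, except that two empty masks are in perfect
#' agreement: DSC and JSC are then 1.
#'
#' @param c a `confusion_counts`.
#' @return score in [0, 1].
#' @rdname overlap_scores
#' @export
dsc <- function(c) {
  if (c$tp + c$fp + c$fn == 0) return(1) # both masks empty
  .safe_ratio(2 * c$tp, c$fp + 2 * c$tp + c$fn, "DSC")
}

#' @rdname overlap_scores
#' @export
jsc <- function(c) {
  if (c$tp + c$fp + c$fn == 0) return(1)
  .safe_ratio(c$tp, c$fp + c$tp + c$fn, "JSC")
}

#' @rdname overlap_scores
#' @export
recall <- function(c) .safe_ratio(c$tp, c$tp + c$fn, "recall")

#' @rdname overlap_scores
#' @export
specificity <- function(c) .safe_ratio(c$tn, c$tn + c$fp, "specificity")

#' @rdname overlap_scores
#' @export
precision <- function(c) .safe_ratio(c$tp, c$tp + c$fp, "precision")

.as_mask3d <- function(mask, spacing) {
  if (is.matrix(mask)) {
    mask <- array(as.integer(mask), c(1L, dim(mask)))
    spacing <- c(1, spacing)
  }
  list(mask = array(as.integer(mask), dim(mask)), spacing = spacing)
}

#' 95th-percentile Hausdorff distance between mask boundaries
#'
#' Boundary voxels are mask voxels with at least one off-mask face-neighbor
#' (the array border counts as off-mask). For every boundary point of each
#' mask the Euclidean distance (scaled by voxel spacing) to the nearest
#' boundary point of the other mask is computed; HD95 is the maximum of the
#' two directed 95th percentiles (linear-interpolation percentile). The
#' `"pooled"` method takes one 95th percentile over both directed sets.
#'
#' @param pred,truth nonempty 0/1 arrays (2D or 3D) of identical shape.
#' @param spacing physical voxel size per axis (mm); length 2 for matrices,
#'   3 for 3D arrays.
#' @param method `"directed"` (default) or `"pooled"`.
#' @return distance in units of `spacing`.
#' @export
hd95 <- function(pred, truth, spacing = NULL,
                 method = c("directed", "pooled")) {
  method <- match.arg(method)
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ")
  if (sum(pred) == 0 || sum(truth) == 0)
    stop("undefined distance: empty mask")
  if (is.null(spacing)) spacing <- rep(1, length(dim(pred)))
  p <- .as_mask3d(pred, spacing)
  t <- .as_mask3d(truth, spacing)
  bx <- cpp_boundary3d(p$mask, as.integer(dim(p$mask)))
  by <- cpp_boundary3d(t$mask, as.integer(dim(t$mask)))
  X <- sweep(bx, 2, p$spacing, "*")
  Y <- sweep(by, 2, t$spacing, "*")
  dxy <- cpp_nn_dists(X, Y)
  dyx <- cpp_nn_dists(Y, X)
  if (method == "directed")
    max(quantile(dxy, 0.95, type = 7), quantile(dyx, 0.95, type = 7))
  else
    as.numeric(quantile(c(dxy, dyx), 0.95, type = 7))
}

#' Full metric row for one prediction/truth pair
#'
#' @param pred,truth 0/1 arrays of identical shape.
#' @param spacing voxel spacing (mm) for HD95.
#' @return one-row data frame with dsc, jsc, recall, specificity, precision,
#'   hd95 (NA with a warning when a mask is empty).
#' @export
evaluate_masks <- function(pred, truth, spacing = NULL) {
  cc <- confusion(pred, truth)
  h <- if (sum(pred) == 0 || sum(truth) == 0) {
    warning("HD95 undefined for an empty mask; reporting NA")
    NA_real_
  } else hd95(pred, truth, spacing)
  data.frame(dsc = dsc(cc), jsc = jsc(cc), recall = recall(cc),
             specificity = specificity(cc), precision = precision(cc),
             hd95 = h)
}
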
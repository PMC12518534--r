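# Evaluation metrics: Dice similarity, Hausdorff distances (maximum and
# percentile variants) on 2D slices or stacked 3D volumes, and the binary
# confusion-matrix panel (accuracy, precision, sensitivity, specificity, IoU).

#' Dice similarity coefficient for one class
#'
#' \eqn{2|P \cap L| / (|P| + |L|)} on the binarized class masks. When both
#' masks are empty the class is counted as perfectly segmented (DSC 1);
#' when exactly one is empty the DSC is 0.
#'
#' @param pred integer label mask (any shape).
#' @param truth integer label mask, same shape as `pred`.
#' @param cls class index to binarize on (default 1).
#' @return DSC in `[0, 1]`.
#' @export
dsc_metric <- function(pred, truth, cls = 1L) {
  stopifnot(length(pred) == length(truth))
  p <- pred == cls
  l <- truth == cls
  sp <- sum(p); sl <- sum(l)
  if (sp == 0 && sl == 0) return(1)
  2 * sum(p & l) / (sp + sl)
}

#' Boundary extraction for a binary mask
#'
#' A mask voxel is a boundary voxel if at least one orthogonal neighbour
#' (4-neighbourhood in 2D, 6 in 3D) is background; voxels on the array edge
#' count the outside as background.
#'
#' @param mask logical or 0/1 array, 2D or 3D.
#' @return integer matrix of boundary voxel coordinates (one row per voxel).
#' @export
boundary_points <- function(mask) {
  m <- mask != 0
  d <- dim(m)
  nd <- length(d)
  pad_shift <- function(ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq_len(d[ax] - by) + by; idx_src[[ax]] <- seq_len(d[ax] - by) }
    else { idx_dst[[ax]] <- seq_len(d[ax] + by); idx_src[[ax]] <- seq_len(d[ax] + by) - by }
    out <- do.call(`[<-`, c(list(out), idx_dst, list(do.call(`[`, c(list(m), idx_src)))))
    out
  }
  has_bg_neighbour <- array(FALSE, d)
  for (ax in seq_len(nd)) {
    for (by in c(-1L, 1L)) {
      nb <- pad_shift(ax, by) # neighbour's mask value, FALSE outside
      has_bg_neighbour <- has_bg_neighbour | (!nb)
    }
  }
  which(m & has_bg_neighbour, arr.ind = TRUE)
}

directed_boundary_distances <- function(a, b, spacing) {
  # all nearest-neighbour distances from points a to set b (rows = points)
  as_ <- sweep(a, 2, spacing, "*")
  bs <- sweep(b, 2, spacing, "*")
  d2 <- outer(rowSums(as_^2), rep(1, nrow(bs))) +
    outer(rep(1, nrow(as_)), rowSums(bs^2)) - 2 * as_ %*% t(bs)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Hausdorff distance between two mask boundaries
#'
#' The symmetric maximum (or, for `percentile < 100`, the maximum of the two
#' directed percentile statistics) of Euclidean nearest-boundary distances
#' between the class boundaries of two masks. Works on 2D slices and stacked
#' 3D volumes; distances are in voxel units unless a physical `spacing`
#' vector is given.
#'
#' @param pred integer label mask (2D or 3D array).
#' @param truth integer label mask, same shape.
#' @param percentile percentile of the directed distance distributions,
#'   100 for the classical Hausdorff distance, 95 for HD95.
#' @param cls class index to binarize on (default 1).
#' @param spacing numeric vector of per-axis voxel spacings (default 1).
#' @return distance, or `NA` (with a warning) if either boundary is empty.
#' @export
hausdorff <- function(pred, truth, percentile = 100, cls = 1L, spacing = NULL) {
  stopifnot(identical(dim(pred), dim(truth)))
  pa <- boundary_points(pred == cls)
  pb <- boundary_points(truth == cls)
  if (nrow(pa) == 0 || nrow(pb) == 0) {
    warning("empty boundary: Hausdorff distance undefined, returning NA")
    return(NA_real_)
  }
  if (is.null(spacing)) spacing <- rep(1, ncol(pa))
  dab <- directed_boundary_distances(pa, pb, spacing)
  dba <- directed_boundary_distances(pb, pa, spacing)
  if (percentile >= 100) {
    max(max(dab), max(dba))
  } else {
    max(stats::quantile(dab, percentile / 100, names = FALSE),
        stats::quantile(dba, percentile / 100, names = FALSE))
  }
}

#' Binary confusion-matrix metrics
#'
#' Accuracy, precision, sensitivity, specificity and intersection-over-union
#' from the TP/FP/FN/TN counts of two binary masks. A metric whose
#' denominator is zero (e.g. precision with no predicted positives) is
#' reported as `NA`.
#'
#' @param pred binary (or binarizable) mask.
#' @param truth binary mask, same shape.
#' @param cls class index treated as positive (default 1).
#' @return one-row `data.frame` with columns `tp, fp, fn, tn, ac, pr, se,
#'   sp, iou`.
#' @export
confusion_metrics <- function(pred, truth, cls = 1L) {
  stopifnot(length(pred) == length(truth))
  p <- pred == cls
  l <- truth == cls
  tp <- sum(p & l); fp <- sum(p & !l); fn <- sum(!p & l); tn <- sum(!p & !l)
  sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
  data.frame(
    tp = tp, fp = fp, fn = fn, tn = tn,
    ac = sdiv(tp + tn, tp + fp + fn + tn),
    pr = sdiv(tp, tp + fp),
    se = sdiv(tp, tp + fn),
    sp = sdiv(tn, tn + fp),
    iou = sdiv(tp, tp + fp + fn)
  )
}

#' Per-class segmentation report
#'
#' Computes per-foreground-class DSC, HD and HD95 between predicted and
#' ground-truth label masks, either per slice or with slices of one case
#' stacked into a volume first (the multi-organ/cardiac evaluation
#' convention). Binary problems additionally get the confusion-matrix panel.
#'
#' @param pred list of predicted masks (or a single mask).
#' @param truth list of ground-truth masks aligned with `pred`.
#' @param num_classes total class count including background (class 0).
#' @param mode `"slice"` (each mask evaluated separately) or `"volume"`
#'   (masks stacked along a third axis per case before evaluation).
#' @param case_ids case identifier per mask for `mode = "volume"`; a single
#'   case is assumed when missing.
#' @param spacing optional physical spacing vector passed to [hausdorff()].
#' @return `data.frame` with one row per (case, class) plus `mean_dsc`
#'   obtainable via [summarize_report()].
#' @export
segmentation_report <- function(pred, truth, num_classes,
                                mode = c("slice", "volume"),
                                case_ids = NULL, spacing = NULL) {
  mode <- match.arg(mode)
  if (!is.list(pred)) pred <- list(pred)
  if (!is.list(truth)) truth <- list(truth)
  stopifnot(length(pred) == length(truth))
  if (mode == "volume") {
    if (is.null(case_ids)) case_ids <- rep(1L, length(pred))
    groups <- split(seq_along(pred), case_ids)
    pred <- lapply(groups, function(ix) {
      if (length(ix) == 1) pred[[ix]] else
        array(unlist(pred[ix]), c(dim(pred[[ix[1]]]), length(ix)))
    })
    truth <- lapply(groups, function(ix) {
      if (length(ix) == 1) truth[[ix]] else
        array(unlist(truth[ix]), c(dim(truth[[ix[1]]]), length(ix)))
    })
    units <- names(groups)
  } else {
    units <- as.character(seq_along(pred))
  }
  rows <- list()
  for (i in seq_along(pred)) {
    for (cls in seq_len(num_classes - 1L)) {
      dsc <- dsc_metric(pred[[i]], truth[[i]], cls)
      hd <- suppressWarnings(hausdorff(pred[[i]], truth[[i]], 100, cls, spacing))
      hd95 <- suppressWarnings(hausdorff(pred[[i]], truth[[i]], 95, cls, spacing))
      row <- data.frame(case = units[i], class = cls, dsc = dsc,
                        hd = hd, hd95 = hd95)
      if (num_classes == 2L) {
        row <- cbind(row, confusion_metrics(pred[[i]], truth[[i]], cls))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Aggregate a segmentation report
#'
#' Mean per-class DSC/HD/HD95 across cases plus the grand means (the
#' mean DSC is the arithmetic mean of the per-class means, foreground
#' classes only).
#'
#' @param report output of [segmentation_report()].
#' @return list with `per_class` data.frame and scalars `mean_dsc`,
#'   `mean_hd`, `mean_hd95`.
#' @export
summarize_report <- function(report) {
  agg <- stats::aggregate(report[c("dsc", "hd", "hd95")],
                          by = list(class = report$class),
                          FUN = function(x) mean(x, na.rm = TRUE))
  list(per_class = agg,
       mean_dsc = mean(agg$dsc),
       mean_hd = mean(agg$hd, na.rm = TRUE),
       mean_hd95 = mean(agg$hd95, na.rm = TRUE))
}
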
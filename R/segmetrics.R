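#' Per-class confusion counts for semantic segmentation
#'
#' For each class c in `[0, C)`: `TP_c` = points predicted c whose ground
#' truth is c, `FP_c` = points predicted c with another ground truth,
#' `FN_c` = ground-truth-c points predicted otherwise.  Totals are
#' conserved: `TP_c + FN_c` is the ground-truth size of class c, and both
#' `sum(TP + FP)` and `sum(TP + FN)` equal the number of points.
#'
#' @param pred_sem,gt_sem integer vectors of equal length, labels in
#'   `[0, C)`.
#' @param C number of semantic classes.
#' @return an object of class `confusion_table`: data frame with columns
#'   `class`, `TP`, `FP`, `FN`.
#' @export
confusion <- function(pred_sem, gt_sem, C) {
  pred_sem <- as.integer(pred_sem); gt_sem <- as.integer(gt_sem)
  C <- as.integer(C)
  if (length(pred_sem) != length(gt_sem))
    stop_data("pred and gt label vectors differ in length")
  if (anyNA(pred_sem) || anyNA(gt_sem) ||
      any(pred_sem < 0L | pred_sem >= C) || any(gt_sem < 0L | gt_sem >= C))
    stop_data("labels must lie in [0, C)")
  lv <- 0:(C - 1L)
  tab <- table(factor(gt_sem, levels = lv), factor(pred_sem, levels = lv))
  tp <- diag(tab)
  structure(data.frame(class = lv, TP = as.integer(tp),
                       FP = as.integer(colSums(tab) - tp),
                       FN = as.integer(rowSums(tab) - tp)),
            class = c("confusion_table", "data.frame"))
}

#' Semantic segmentation metrics from confusion counts
#'
#' Per class: `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`, `F1` the
#' harmonic mean of the two, and `IoU = TP/(TP+FP+FN)`.  A class absent
#' from both prediction and ground truth (`TP+FP+FN = 0`) is excluded;
#' the summary row is the unweighted (macro) mean over the included
#' classes, the convention used when organ metrics are averaged over
#' semantic classes.  `average = "micro"` instead pools counts over
#' classes first.  Note the algebraic identity `F1 = 2*IoU/(1+IoU)`.
#'
#' @param table a [confusion] table.
#' @param average `"macro"` (default) or `"micro"`.
#' @return an object of class `semantic_report`: data frame with one row
#'   per included class plus a `"mean"` row, columns `Precision`,
#'   `Recall`, `F1`, `IoU`, all in `[0, 1]`.
#' @examples
#' ct <- confusion(c(0,0,0,0,1,1,1,1,1,0), c(0,0,0,0,0,1,1,1,1,1), 2)
#' semantic_report(ct)
#' @export
semantic_report <- function(table, average = c("macro", "micro")) {
  stopifnot(inherits(table, "confusion_table"))
  average <- match.arg(average)
  keep <- table$TP + table$FP + table$FN > 0L
  t <- table[keep, , drop = FALSE]
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  prec <- safe(t$TP, t$TP + t$FP)
  rec <- safe(t$TP, t$TP + t$FN)
  f1 <- safe(2 * prec * rec, prec + rec)
  iou <- safe(t$TP, t$TP + t$FP + t$FN)
  if (average == "macro") {
    m <- c(mean(prec), mean(rec), mean(f1), mean(iou))
  } else {
    TP <- sum(t$TP); FP <- sum(t$FP); FN <- sum(t$FN)
    mp <- safe(TP, TP + FP); mr <- safe(TP, TP + FN)
    m <- c(mp, mr, safe(2 * mp * mr, mp + mr), safe(TP, TP + FP + FN))
  }
  out <- data.frame(class = c(as.character(t$class), "mean"),
                    Precision = c(prec, m[1]), Recall = c(rec, m[2]),
                    F1 = c(f1, m[3]), IoU = c(iou, m[4]))
  structure(out, class = c("semantic_report", "data.frame"),
            average = average)
}

#' @export
print.semantic_report <- function(x, digits = 4, ...) {
  cat(sprintf("semantic_report (%s average), values in [0, 1]:\n",
              attr(x, "average")))
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Intersection over union of two point-index sets
#'
#' @param a,b integer vectors of point indices (treated as sets).
#' @return `|a .. b| / |a u b|` in `[0, 1]`; both sets empty is an error.
#' @export
instance_iou <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) stop_data("IoU of two empty sets is undefined")
  length(intersect(a, b)) / u
}

#' Group labeled points into instances
#'
#' Builds the instance partition used by the instance metrics: one group of
#' point indices per instance id `>= 0` (id `-1` marks points, such as the
#' stem system, that belong to no instance).  Each instance's semantic
#' class is the majority semantic label of its points (ties: smallest
#' class id); instances arriving without semantic context get class 0.
#'
#' @param ins integer instance labels (`-1` = none).
#' @param sem optional integer semantic labels of the same length.
#' @return an object of class `instance_partition`: list with `groups`
#'   (named list of point-index vectors) and `class_of` (integer class per
#'   group).
#' @export
instance_partition <- function(ins, sem = NULL) {
  ins <- as.integer(ins)
  ids <- sort(unique(ins[ins >= 0L]))
  groups <- lapply(ids, function(i) which(ins == i))
  names(groups) <- ids
  class_of <- if (is.null(sem)) rep(0L, length(ids)) else
    vapply(groups, function(g) {
      tab <- table(factor(sem[g], levels = sort(unique(sem[g]))))
      as.integer(names(tab))[which.max(tab)]
    }, 1L)
  structure(list(groups = groups, class_of = class_of),
            class = "instance_partition")
}

#' @export
print.instance_partition <- function(x, ...) {
  cat(sprintf("instance_partition: %d instances over %d classes\n",
              length(x$groups), length(unique(x$class_of))))
  invisible(x)
}

# per-class split of an instance partition
.split_by_class <- function(part) {
  split(part$groups, part$class_of)
}

#' Coverage metrics for instance segmentation (mCov, mWCov)
#'
#' Within each instance-bearing class, every ground-truth instance is
#' credited with its best IoU against the predicted instances of that
#' class (0 if none overlaps).  `mCov` averages these best-IoUs uniformly
#' over the ground-truth instances; `mWCov` weights each instance by its
#' share of the class's points, so large leaves count more.  Class values
#' are then macro-averaged over the classes present in the ground truth.
#'
#' @param gt,pred [instance_partition]s for ground truth and prediction.
#' @return named numeric vector `c(mCov, mWCov)` in `[0, 1]`.
#' @export
coverage <- function(gt, pred) {
  stopifnot(inherits(gt, "instance_partition"),
            inherits(pred, "instance_partition"))
  if (length(gt$groups) == 0L)
    stop_data("ground truth has no instances")
  by_cls_gt <- .split_by_class(gt)
  by_cls_pr <- .split_by_class(pred)
  cov <- wcov <- numeric(length(by_cls_gt))
  for (i in seq_along(by_cls_gt)) {
    gg <- by_cls_gt[[i]]
    pp <- by_cls_pr[[names(by_cls_gt)[i]]]
    best <- vapply(gg, function(g) {
      if (is.null(pp) || length(pp) == 0L) return(0)
      max(vapply(pp, function(p) instance_iou(g, p), 1))
    }, 1)
    sizes <- lengths(gg)
    cov[i] <- mean(best)
    wcov[i] <- sum(sizes / sum(sizes) * best)
  }
  c(mCov = mean(cov), mWCov = mean(wcov))
}

#' Instance precision and recall at an IoU threshold
#'
#' A predicted instance counts as a true positive when its IoU with some
#' ground-truth instance of the same class exceeds `iou_threshold`
#' (threshold above 0.5 makes such matches mutually exclusive, so no
#' explicit assignment is needed).  Per instance-bearing class, precision
#' is TP over predicted instances of the class (0 when there are none) and
#' recall is TP over ground-truth instances; both are macro-averaged over
#' the classes present in the ground truth.
#'
#' @param gt,pred [instance_partition]s.
#' @param iou_threshold matching threshold in `(0, 1)`; default 0.5.
#' @return named numeric vector `c(mPrec, mRec)` in `[0, 1]`.
#' @export
prec_rec_instances <- function(gt, pred, iou_threshold = 0.5) {
  stopifnot(inherits(gt, "instance_partition"),
            inherits(pred, "instance_partition"))
  if (length(gt$groups) == 0L)
    stop_data("ground truth has no instances")
  if (!is.numeric(iou_threshold) || iou_threshold <= 0 || iou_threshold >= 1)
    stop_data("iou_threshold must lie in (0, 1)")
  by_cls_gt <- .split_by_class(gt)
  by_cls_pr <- .split_by_class(pred)
  prec <- rec <- numeric(length(by_cls_gt))
  for (i in seq_along(by_cls_gt)) {
    gg <- by_cls_gt[[i]]
    pp <- by_cls_pr[[names(by_cls_gt)[i]]]
    if (is.null(pp) || length(pp) == 0L) {
      prec[i] <- 0; rec[i] <- 0
      next
    }
    matched <- vapply(pp, function(p)
      any(vapply(gg, function(g) instance_iou(g, p), 1) > iou_threshold),
      TRUE)
    prec[i] <- sum(matched) / length(pp)
    rec[i] <- sum(matched) / length(gg)
  }
  c(mPrec = mean(prec), mRec = mean(rec))
}

#' Discard undersized predicted instance clusters
#'
#' Clustering the instance-embedding space tends to over-segment: tiny
#' spurious clusters appear next to real leaves.  Following the standard
#' inference post-process, any predicted instance whose point count is
#' below `fraction` of the average instance size (mean computed before any
#' removal) is discarded.
#'
#' @param pred an [instance_partition].
#' @param fraction size cutoff as a fraction of the mean instance size;
#'   default 0.01 (1 percent).
#' @return the filtered [instance_partition].
#' @export
filter_small_clusters <- function(pred, fraction = 0.01) {
  stopifnot(inherits(pred, "instance_partition"))
  if (length(pred$groups) == 0L) stop_data("empty instance partition")
  sizes <- lengths(pred$groups)
  keep <- sizes >= fraction * mean(sizes)
  structure(list(groups = pred$groups[keep],
                 class_of = pred$class_of[keep]),
            class = "instance_partition")
}

#' Full evaluation of a predicted labeling against ground truth
#'
#' Convenience wrapper: semantic metrics from the label vectors, and (when
#' instance labels are supplied) instance metrics after the small-cluster
#' filter.
#'
#' @param gt_sem,pred_sem semantic label vectors in `[0, C)`.
#' @param C number of semantic classes.
#' @param gt_ins,pred_ins optional instance label vectors (`-1` = none).
#' @param filter_fraction small-cluster cutoff passed to
#'   [filter_small_clusters]; `NULL` disables the filter.
#' @return a list with elements `semantic` (a [semantic_report]) and, when
#'   instances are given, `instance` (named vector mCov, mWCov, mPrec,
#'   mRec).
#' @export
evaluate_labels <- function(gt_sem, pred_sem, C, gt_ins = NULL,
                            pred_ins = NULL, filter_fraction = 0.01) {
  out <- list(semantic = semantic_report(confusion(pred_sem, gt_sem, C)))
  if (!is.null(gt_ins) && !is.null(pred_ins)) {
    gt_part <- instance_partition(gt_ins, gt_sem)
    pr_part <- instance_partition(pred_ins, pred_sem)
    if (length(pr_part$groups) > 0L && !is.null(filter_fraction))
      pr_part <- filter_small_clusters(pr_part, filter_fraction)
    out$instance <- c(coverage(gt_part, pr_part),
                      prec_rec_instances(gt_part, pr_part))
  }
  out
}
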
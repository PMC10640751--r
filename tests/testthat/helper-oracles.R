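# Fixture builders and brute-force oracles, independent of the package's
# implementation paths.

rand_cloud <- function(n, labeled = TRUE, seed = 1) {
  set.seed(seed)
  xyz <- matrix(runif(3 * n), ncol = 3)
  if (labeled) {
    sem <- sample(0:1, n, replace = TRUE)
    ins <- ifelse(sem == 1L, sample(0:2, n, replace = TRUE), -1L)
    plant_cloud(xyz, sem = sem, ins = ins, C = 2L)
  } else plant_cloud(xyz)
}

# exhaustive greedy max-min FPS on a full distance matrix
oracle_fps <- function(coords, n, start) {
  d <- as.matrix(dist(coords))
  sel <- start
  while (length(sel) < n) {
    mind <- apply(d[, sel, drop = FALSE], 1L, min)
    mind[sel] <- -Inf
    sel <- c(sel, which.max(mind))
  }
  sel
}

oracle_iou <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# all-pairs-IoU instance metrics, computed per class the slow way
oracle_instance <- function(gt_ins, gt_sem, pred_ins, pred_sem, thr = 0.5) {
  gt_ids <- sort(unique(gt_ins[gt_ins >= 0]))
  pr_ids <- sort(unique(pred_ins[pred_ins >= 0]))
  cls_of <- function(ids, ins, sem) vapply(ids, function(i) {
    tab <- table(sem[ins == i])
    as.integer(names(tab)[which.max(tab)])
  }, 1L)
  gt_cls <- cls_of(gt_ids, gt_ins, gt_sem)
  pr_cls <- if (length(pr_ids)) cls_of(pr_ids, pred_ins, pred_sem) else integer()
  classes <- sort(unique(gt_cls))
  cov <- wcov <- prec <- rec <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    g <- gt_ids[gt_cls == classes[ci]]
    p <- pr_ids[pr_cls == classes[ci]]
    ious <- matrix(0, length(g), max(1L, length(p)))
    for (i in seq_along(g)) for (j in seq_along(p))
      ious[i, j] <- oracle_iou(which(gt_ins == g[i]), which(pred_ins == p[j]))
    best <- apply(ious, 1L, max)
    sizes <- vapply(g, function(i) sum(gt_ins == i), 1L)
    cov[ci] <- mean(best)
    wcov[ci] <- sum(sizes / sum(sizes) * best)
    if (length(p) == 0L) { prec[ci] <- 0; rec[ci] <- 0 } else {
      tp <- sum(apply(ious, 2L, max) > thr)
      prec[ci] <- tp / length(p)
      rec[ci] <- tp / length(g)
    }
  }
  c(mCov = mean(cov), mWCov = mean(wcov),
    mPrec = mean(prec), mRec = mean(rec))
}

# a random instance-labeled fixture with <= 6 instances per class
rand_partition_labels <- function(n = 60, seed = 1) {
  set.seed(seed)
  sem <- sample(0:1, n, replace = TRUE)
  ins <- ifelse(sem >= 0, sample(c(-1L, 0:5), n, replace = TRUE), -1L)
  list(sem = sem, ins = ins)
}
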
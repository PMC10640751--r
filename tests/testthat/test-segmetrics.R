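test_that("confusion counts match hand tallies and conserve totals", {
  gt <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  pr <- c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0)
  ct <- confusion(pr, gt, 2)
  expect_identical(ct$TP, c(4L, 4L))
  expect_identical(ct$FP, c(1L, 1L))
  expect_identical(ct$FN, c(1L, 1L))

  perfect <- confusion(gt, gt, 2)
  expect_identical(perfect$FP, c(0L, 0L))
  expect_identical(perfect$FN, c(0L, 0L))

  for (seed in 1:5) {
    set.seed(seed)
    g <- sample(0:3, 200, replace = TRUE)
    p <- sample(0:3, 200, replace = TRUE)
    tab <- confusion(p, g, 4)
    expect_identical(tab$TP + tab$FN, as.integer(tabulate(g + 1L, 4L)))
    expect_identical(sum(tab$TP + tab$FP), 200L)
    expect_identical(sum(tab$TP + tab$FN), 200L)
  }
  expect_error(confusion(c(0, 1), c(0, 1, 1), 2), "length")
  expect_error(confusion(c(0, 2), c(0, 1), 2), "\\[0, C\\)")
})

test_that("semantic_report implements the four metrics and their identity", {
  ct <- confusion(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0),
                  c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1), 2)
  rep <- semantic_report(ct)
  r0 <- rep[rep$class == "0", ]
  expect_equal(r0$Precision, 0.8)
  expect_equal(r0$Recall, 0.8)
  expect_equal(r0$F1, 0.8)
  expect_equal(r0$IoU, 2 / 3)

  perfect <- semantic_report(confusion(0:3, 0:3, 4))
  expect_true(all(as.matrix(perfect[, -1]) == 1))

  # F1 = 2 IoU / (1 + IoU) per class, and IoU <= min(P, R), on random tables
  for (seed in 1:10) {
    set.seed(seed)
    g <- sample(0:4, 300, replace = TRUE)
    p <- sample(0:4, 300, replace = TRUE)
    r <- semantic_report(confusion(p, g, 5))
    cls <- r[r$class != "mean", ]
    expect_equal(cls$F1, 2 * cls$IoU / (1 + cls$IoU))
    expect_true(all(cls$IoU <= pmin(cls$Precision, cls$Recall) + 1e-12))
  }
})

test_that("empty classes drop out of the macro mean; micro pools counts", {
  # class 2 never occurs: excluded rather than scored 0
  r <- semantic_report(confusion(c(0, 1), c(0, 1), 3))
  expect_identical(nrow(r), 3L)
  expect_identical(r$class, c("0", "1", "mean"))
  expect_equal(r$IoU[r$class == "mean"], 1)
  mi <- semantic_report(confusion(c(0, 0, 1), c(0, 1, 1), 2),
                        average = "micro")
  expect_equal(mi$Precision[mi$class == "mean"], 2 / 3)
})

test_that("instance_iou is set IoU with the empty-empty case an error", {
  expect_equal(instance_iou(1:5, 1:5), 1)
  expect_equal(instance_iou(1:3, 4:6), 0)
  expect_equal(instance_iou(1:6, c(1:5, 7)), 5 / 7)
  expect_error(instance_iou(integer(0), integer(0)), "empty")
})

test_that("coverage reproduces the two-instance hand calculation", {
  # GT leaves A = {1..6}, B = {7..10}; predictions P1 = {1..5, 7}, P2 = {8,9,10}
  gt <- instance_partition(c(rep(0L, 6), rep(1L, 4)), sem = rep(1L, 10))
  pr <- instance_partition(c(rep(0L, 5), -1L, 0L, rep(1L, 3)),
                           sem = rep(1L, 10))
  cv <- coverage(gt, pr)
  expect_equal(unname(cv["mCov"]), (5 / 7 + 3 / 4) / 2)
  expect_equal(unname(cv["mWCov"]), 0.6 * (5 / 7) + 0.4 * (3 / 4))
  pm <- prec_rec_instances(gt, pr)
  expect_equal(unname(pm), c(1, 1))                  # both IoUs exceed 0.5

  ident <- coverage(gt, gt)
  expect_equal(unname(ident), c(1, 1))
  # equal-sized GT instances make the weights uniform: mWCov = mCov
  gt_eq <- instance_partition(rep(0:1, each = 5), sem = rep(1L, 10))
  cv_eq <- coverage(gt_eq, pr)
  expect_equal(cv_eq[["mCov"]], cv_eq[["mWCov"]])
  # empty prediction: zero coverage, not an error
  none <- instance_partition(rep(-1L, 10), sem = rep(1L, 10))
  expect_equal(unname(coverage(gt, none)), c(0, 0))
  expect_error(coverage(none, gt), "no instances")
})

test_that("IoU > 0.5 matching needs no assignment and handles split misses", {
  # one GT instance split into two halves: neither prediction exceeds 0.5
  gt <- instance_partition(rep(0L, 10), sem = rep(1L, 10))
  pr <- instance_partition(rep(0:1, each = 5), sem = rep(1L, 10))
  pm <- prec_rec_instances(gt, pr)
  expect_equal(unname(pm), c(0, 0))
  expect_error(prec_rec_instances(gt, pr, iou_threshold = 1.2), "\\(0, 1\\)")

  # each predicted instance can exceed 0.5 with at most one GT instance
  for (seed in 1:10) {
    lab <- rand_partition_labels(seed = seed)
    pred <- rand_partition_labels(seed = seed + 100)
    gt_groups <- split(seq_along(lab$ins), lab$ins)[-1]
    for (p in split(seq_along(pred$ins), pred$ins)[-1]) {
      hits <- sum(vapply(gt_groups, function(g) oracle_iou(g, p), 1) > 0.5)
      expect_lte(hits, 1L)
    }
  }
})

test_that("coverage and prec/rec agree with the all-pairs-IoU oracle", {
  for (seed in 1:12) {
    lab <- rand_partition_labels(n = 80, seed = seed)
    pred <- rand_partition_labels(n = 80, seed = seed + 500)
    gt <- instance_partition(lab$ins, lab$sem)
    pr <- instance_partition(pred$ins, pred$sem)
    if (length(gt$groups) == 0L || length(pr$groups) == 0L) next
    got <- c(coverage(gt, pr), prec_rec_instances(gt, pr))
    want <- oracle_instance(lab$ins, lab$sem, pred$ins, pred$sem)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("small-cluster filter discards below 1% of the pre-removal mean", {
  part <- function(sizes) {
    ins <- rep.int(seq_along(sizes) - 1L, sizes)
    instance_partition(ins, sem = rep(1L, sum(sizes)))
  }
  expect_length(filter_small_clusters(part(c(100, 100, 100)))$groups, 3L)
  expect_length(filter_small_clusters(part(c(300, 300, 3)))$groups, 3L)
  kept <- filter_small_clusters(part(c(300, 300, 1)))
  expect_length(kept$groups, 2L)
  expect_setequal(names(kept$groups), c("0", "1"))
})

test_that("flipping more labels never improves the semantic metrics", {
  set.seed(42)
  gt <- sample(0:1, 2000, replace = TRUE, prob = c(0.4, 0.6))
  flip_order <- sample.int(2000)
  prev <- NULL
  for (frac in c(0, 0.1, 0.2, 0.3, 0.4)) {
    pred <- gt
    idx <- flip_order[seq_len(frac * 2000)]
    pred[idx] <- 1L - pred[idx]
    m <- semantic_report(confusion(pred, gt, 2))
    m <- as.numeric(m[m$class == "mean", -1])
    if (!is.null(prev)) expect_true(all(m <= prev + 0.01))
    prev <- m
  }
})
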
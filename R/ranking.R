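# Rank-based comparison of down-sampling strategies over a strategies x
# metrics table.  Comprehensive metrics (F1, IoU, Cov, WCov) carry "major"
# weights 6/4/2 for the top three ranks; the one-sided metrics (Precision,
# Recall, mPrec, mRec) carry "minor" weights 3/2/1.  Score is the sum of a
# strategy's rank points over all columns; AveDiff is its mean shortfall
# from the per-column best, in percentage points.

.semantic_metrics <- c("Precision", "Recall", "F1", "IoU")
.instance_metrics <- c("Cov", "WCov", "mPrec", "mRec")
.minor_metrics <- c("Precision", "Recall", "mPrec", "mRec")

.metric_weight_class <- function(metric) {
  ifelse(metric %in% .minor_metrics, "minor", "major")
}

#' Strategy-by-metric value table
#'
#' The input of the scoring harness: one row per down-sampling strategy,
#' one column per metric, values in percent.  Two modes are meaningful:
#' `semantic` (exactly Precision, Recall, F1, IoU, as produced by
#' semantic-only networks) and `dual` (those four plus Cov, WCov, mPrec,
#' mRec from networks that also segment instances).
#'
#' @param values data frame with a `strategy` character column and numeric
#'   metric columns.
#' @return an object of class `metric_table` (a data frame) with a
#'   `"mode"` attribute.
#' @export
metric_table <- function(values) {
  values <- as.data.frame(values)
  if (!"strategy" %in% names(values) || names(values)[1] != "strategy")
    stop_data("first column must be 'strategy'")
  metrics <- setdiff(names(values), "strategy")
  mode <- if (identical(metrics, .semantic_metrics)) "semantic"
    else if (identical(metrics, c(.semantic_metrics, .instance_metrics)))
      "dual"
    else stop_data("metric columns must be exactly ",
                   paste(.semantic_metrics, collapse = ","),
                   " (semantic mode), optionally followed by ",
                   paste(.instance_metrics, collapse = ","),
                   " (dual mode); got: ", paste(metrics, collapse = ","))
  if (anyDuplicated(values$strategy))
    stop_data("duplicate strategy names")
  for (m in metrics) {
    if (!is.numeric(values[[m]]) || !all(is.finite(values[[m]])))
      stop_data("non-numeric or non-finite value in column ", m)
  }
  structure(values, class = c("metric_table", "data.frame"), mode = mode)
}

#' Rank points for one metric column
#'
#' Strategies are ranked descending (all supported metrics are
#' higher-is-better); the top three ranks earn 3/2/1 points for minor
#' metrics (Precision, Recall, mPrec, mRec) or 6/4/2 for major ones (F1,
#' IoU, Cov, WCov), everyone else 0.  Tied values share the arithmetic
#' mean of the points of the positions they span (`ties = "average"`,
#' default) or are resolved in row order (`ties = "first"`).
#'
#' @param column numeric metric values, one per strategy.
#' @param weight_class `"minor"` or `"major"`.
#' @param ties tie policy, `"average"` or `"first"`.
#' @return numeric vector of points, aligned with `column`.
#' @examples
#' rank_points(c(85.38, 85.29, 86.07, 85.55, 85.64), "minor") # 0 0 3 1 2
#' @export
rank_points <- function(column, weight_class = c("minor", "major"),
                        ties = c("average", "first")) {
  weight_class <- match.arg(weight_class)
  ties <- match.arg(ties)
  if (length(column) < 1L) stop_data("empty metric column")
  pts <- c(if (weight_class == "minor") c(3, 2, 1) else c(6, 4, 2),
           rep(0, max(0L, length(column) - 3L)))[seq_along(column)]
  if (ties == "first") {
    r <- rank(-column, ties.method = "first")
    return(pts[r])
  }
  rmin <- rank(-column, ties.method = "min")
  vapply(seq_along(column), function(i) {
    span <- rmin == rmin[i]
    mean(pts[rmin[i]:(rmin[i] + sum(span) - 1L)])
  }, 1)
}

#' Total rank score of every strategy
#'
#' Sums [rank_points] over all metric columns of the table: the maximum is
#' 18 in semantic mode (2 x 3 + 2 x 6) and 36 in dual mode.  Absent ties,
#' the points handed out per column sum to 6 (minor) or 12 (major).
#'
#' @param table a [metric_table].
#' @param ties tie policy passed to [rank_points].
#' @return a `score_card`: data frame with columns `strategy`, `Score`,
#'   `AveDiff`.
#' @export
score_table <- function(table, ties = c("average", "first")) {
  stopifnot(inherits(table, "metric_table"))
  ties <- match.arg(ties)
  metrics <- setdiff(names(table), "strategy")
  score <- rep(0, nrow(table))
  for (m in metrics)
    score <- score + rank_points(table[[m]], .metric_weight_class(m),
                                 ties = ties)
  structure(data.frame(strategy = table$strategy, Score = score,
                       AveDiff = avediff(table)),
            class = c("score_card", "data.frame"), mode = attr(table, "mode"))
}

#' Mean shortfall from the per-metric best (AveDiff)
#'
#' For each metric the difference between the column best and the
#' strategy's value (>= 0, percentage points); AveDiff is the mean over
#' the table's metrics, rounded half-to-even to two decimals.  The
#' strategy that is best in every metric has AveDiff 0.
#'
#' @param table a [metric_table].
#' @return numeric vector of AveDiff values, aligned with the table rows.
#' @export
avediff <- function(table) {
  stopifnot(inherits(table, "metric_table"))
  metrics <- setdiff(names(table), "strategy")
  vals <- as.matrix(table[metrics])
  diffs <- sweep(-vals, 2L, apply(vals, 2L, max), "+")
  unname(round(rowMeans(diffs), 2L))
}

#' @export
print.score_card <- function(x, ...) {
  cat(sprintf("score_card (%s mode, max %d points):\n", attr(x, "mode"),
              if (identical(attr(x, "mode"), "dual")) 36L else 18L))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read and write scoring-harness CSV files
#'
#' `read_metrics_csv` expects the exact header
#' `strategy,Precision,Recall,F1,IoU` optionally followed by
#' `,Cov,WCov,mPrec,mRec`; unknown or reordered columns are rejected so
#' that scorecards are comparable across runs.  `write_scorecard_csv`
#' emits `strategy,Score,AveDiff` rows.
#'
#' @param path CSV file path.
#' @return [read_metrics_csv]: a [metric_table].
#' @export
read_metrics_csv <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- tryCatch(read.csv(path, check.names = FALSE, strip.white = TRUE),
                 error = function(e) stop_data("cannot parse ", path, ": ",
                                               conditionMessage(e)))
  for (m in setdiff(names(df), "strategy")) {
    if (!is.numeric(df[[m]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[m]]))))[1]
      stop_data("non-numeric cell in ", path, " at row ",
                if (is.na(bad)) "?" else bad, ", column '", m, "'")
    }
  }
  metric_table(df)
}

#' @param card a `score_card` from [score_table].
#' @rdname read_metrics_csv
#' @export
write_scorecard_csv <- function(card, path) {
  stopifnot(inherits(card, "score_card"))
  df <- as.data.frame(card)
  df$AveDiff <- sprintf("%.2f", df$AveDiff)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bundled benchmark metric tables
#'
#' Strategy-by-metric segmentation benchmark tables for the five
#' down-sampling strategies (FPS, RS, UVS, VFPS, 3DEPS) evaluated on five
#' point-level segmentation networks, shipped as CSVs under
#' `inst/extdata/`: `pointnetpp_semantic`, `dgcnn_semantic`, `asis_dual`,
#' `plantnet_dual`, `psegnet_dual` (tomato/tobacco/sorghum benchmark) and
#' `pointnetpp_soybean_semantic` (a multi-view-stereo soybean benchmark).
#' These are the canonical inputs of the scoring harness.
#'
#' @param name table name (see above); `NULL` lists the available names.
#' @return a [metric_table], or a character vector of names.
#' @examples
#' score_table(benchmark_table("pointnetpp_semantic"))
#' @export
benchmark_table <- function(name = NULL) {
  dir <- system.file("extdata", package = "plantcloud")
  avail <- sub("\\.csv$", "", list.files(dir, pattern = "\\.csv$"))
  if (is.null(name)) return(avail)
  if (!name %in% avail)
    stop_data("unknown table '", name, "'; available: ",
              paste(avail, collapse = ", "))
  read_metrics_csv(file.path(dir, paste0(name, ".csv")))
}
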
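#' Labeled plant point cloud
#'
#' The central container: an N x 3 coordinate matrix with optional
#' per-point semantic labels (`sem`, integers in `[0, C)`) and instance
#' labels (`ins`, integers with `-1` meaning "belongs to no instance", used
#' for the stem system, which is fully connected and carries no instance
#' concept).  Instance ids may only occur on points of instance-bearing
#' semantic classes (leaves); class ids are 0-based and contiguous, with the
#' class count `C` carried as metadata (inferred as `max(sem) + 1` when not
#' given).
#'
#' @param coords numeric N x 3 matrix of point coordinates (arbitrary
#'   length units, typically mm).
#' @param sem optional integer vector of length N, semantic class per point.
#' @param ins optional integer vector of length N, instance id per point
#'   (`-1` = no instance).
#' @param C number of semantic classes; default `max(sem) + 1`.
#' @param species optional free-text tag (e.g. `"tomato"`, `"sorghum"`).
#' @param instance_classes semantic classes allowed to carry instances;
#'   default: every class that has at least one `ins >= 0` point.
#' @return an object of class `plant_cloud`: a list with elements `coords`,
#'   `sem`, `ins`, `C`, `species`.
#' @examples
#' pc <- plant_cloud(matrix(rnorm(30), 10, 3),
#'                   sem = rep(0:1, 5), ins = rep(c(-1L, 0L), 5))
#' pc
#' @export
plant_cloud <- function(coords, sem = NULL, ins = NULL, C = NULL,
                        species = NULL, instance_classes = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop_data("coords must be a numeric N x 3 matrix")
  if (nrow(coords) < 1L) stop_data("a point cloud needs at least one point")
  if (!all(is.finite(coords))) stop_data("coords must be finite")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  n <- nrow(coords)
  if (!is.null(sem)) {
    sem <- as.integer(sem)
    if (length(sem) != n) stop_data("sem must have one label per point")
    if (anyNA(sem) || any(sem < 0L)) stop_data("sem labels must be >= 0")
    if (is.null(C)) C <- max(sem) + 1L
    C <- as.integer(C)
    if (C < 1L || any(sem >= C)) stop_data("sem labels must lie in [0, C)")
  } else {
    C <- if (is.null(C)) NULL else as.integer(C)
  }
  if (!is.null(ins)) {
    ins <- as.integer(ins)
    if (length(ins) != n) stop_data("ins must have one label per point")
    if (anyNA(ins) || any(ins < -1L)) stop_data("ins labels must be >= -1")
    if (!is.null(sem)) {
      if (is.null(instance_classes))
        instance_classes <- sort(unique(sem[ins >= 0L]))
      bad <- ins >= 0L & !(sem %in% instance_classes)
      if (any(bad))
        stop_data("instance labels occur on a semantic class declared ",
                  "instance-free (e.g. the stem system)")
    }
  }
  structure(list(coords = coords, sem = sem, ins = ins, C = C,
                 species = species),
            class = "plant_cloud")
}

#' @export
print.plant_cloud <- function(x, ...) {
  cat(sprintf("plant_cloud: %d points", nrow(x$coords)))
  if (!is.null(x$sem))
    cat(sprintf(", %d semantic classes", x$C))
  if (!is.null(x$ins))
    cat(sprintf(", %d instances", length(unique(x$ins[x$ins >= 0L]))))
  if (!is.null(x$species)) cat(sprintf(" [%s]", x$species))
  cat("\n")
  invisible(x)
}

#' @export
summary.plant_cloud <- function(object, ...) {
  cat(sprintf("plant_cloud with %d points\n", nrow(object$coords)))
  rng <- apply(object$coords, 2L, range)
  cat(sprintf("  bounding box: [%.3f, %.3f] x [%.3f, %.3f] x [%.3f, %.3f]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  if (!is.null(object$sem)) {
    tab <- table(object$sem)
    cat("  semantic classes:",
        paste(sprintf("%s (%d pts)", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(object$ins)) {
    k <- sum(unique(object$ins) >= 0L)
    cat(sprintf("  instances: %d (%d unassigned points)\n",
                k, sum(object$ins < 0L)))
  }
  invisible(object)
}

#' @export
plot.plant_cloud <- function(x, which = c("xz", "xy", "yz"), cex = 0.2, ...) {
  which <- match.arg(which)
  ax <- c(substr(which, 1, 1), substr(which, 2, 2))
  ij <- match(ax, c("x", "y", "z"))
  col <- if (!is.null(x$ins)) {
    ifelse(x$ins < 0L, "grey40", grDevices::hcl.colors(
      max(x$ins) + 1L, "Dark 3")[x$ins + 1L])
  } else if (!is.null(x$sem)) x$sem + 1L else "grey20"
  graphics::plot(x$coords[, ij[1]], x$coords[, ij[2]], col = col, pch = 16,
                 cex = cex, asp = 1, xlab = ax[1], ylab = ax[2], ...)
  invisible(x)
}

#' Number of points in a cloud
#'
#' @param cloud a [plant_cloud].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$coords)

#' Center and scale a point cloud
#'
#' Translates the cloud so its centroid is at the origin and scales it so
#' the maximum distance from the centroid is 1, making distance-based
#' parameters (voxel sizes, boundary-filter thresholds) comparable across
#' scans of different physical size.  Labels are untouched; a zero-extent
#' cloud is translated only.  Idempotent.
#'
#' @param cloud a [plant_cloud].
#' @return a [plant_cloud] with transformed coordinates.
#' @export
normalize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "plant_cloud"))
  xyz <- cloud$coords
  ctr <- colMeans(xyz)
  xyz <- sweep(xyz, 2L, ctr)
  r <- sqrt(max(rowSums(xyz^2)))
  if (r > 0) xyz <- xyz / r
  out <- cloud
  out$coords <- xyz
  out
}
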
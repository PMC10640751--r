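#' Fixed-size batches of point clouds
#'
#' Point-level segmentation networks consume batches of clouds that all
#' share one fixed point count (conventionally 4096).  `cloud_batch`
#' bundles a list of [plant_cloud]s and enforces that constraint; clouds of
#' other sizes must be down-sampled first (see [sample_cloud]).
#'
#' @param clouds list of [plant_cloud] objects, all with the same number of
#'   points.
#' @param n_fixed expected points per cloud; default: taken from the first
#'   cloud.
#' @return an object of class `cloud_batch`.
#' @export
cloud_batch <- function(clouds, n_fixed = NULL) {
  if (length(clouds) < 1L) stop_data("a batch needs at least one cloud")
  stopifnot(all(vapply(clouds, inherits, TRUE, "plant_cloud")))
  sizes <- vapply(clouds, n_points, 1L)
  if (is.null(n_fixed)) n_fixed <- sizes[1]
  if (any(sizes != n_fixed))
    stop_data("all clouds in a batch must have exactly ", n_fixed,
              " points (got ", paste(unique(sizes), collapse = ", "),
              "); down-sample first with sample_cloud()")
  structure(list(clouds = clouds, n_fixed = as.integer(n_fixed)),
            class = "cloud_batch")
}

#' @export
print.cloud_batch <- function(x, ...) {
  cat(sprintf("cloud_batch: %d clouds x %d points\n",
              length(x$clouds), x$n_fixed))
  invisible(x)
}

#' HDF5 batch I/O
#'
#' Stores a [cloud_batch] in the layout point-network training code
#' expects: dataset `data` of shape B x n x 3 (32-bit float), plus `sem`
#' and `ins` (integer, B x n) when the member clouds carry labels.  Label
#' datasets are written only when the labels are present on every cloud.
#'
#' @param batch a [cloud_batch].
#' @param path file path (`.h5`).
#' @return [read_h5_batch]: a [cloud_batch]. [write_h5_batch]: `path`,
#'   invisibly.
#' @export
write_h5_batch <- function(batch, path) {
  stopifnot(inherits(batch, "cloud_batch"))
  B <- length(batch$clouds)
  n <- batch$n_fixed
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  # rhdf5 stores arrays column-major; dim (3, n, B) on disk reads back in
  # the same orientation, so round-trips are transparent.
  arr <- array(0, dim = c(3L, n, B))
  for (b in seq_len(B)) arr[, , b] <- t(batch$clouds[[b]]$coords)
  rhdf5::h5createDataset(path, "data", dims = dim(arr),
                         storage.mode = "double", H5type = "H5T_IEEE_F32LE")
  rhdf5::h5write(arr, path, "data")
  has_sem <- all(vapply(batch$clouds, function(cl) !is.null(cl$sem), TRUE))
  has_ins <- all(vapply(batch$clouds, function(cl) !is.null(cl$ins), TRUE))
  if (has_sem)
    rhdf5::h5write(vapply(batch$clouds, function(cl) cl$sem, integer(n)),
                   path, "sem")
  if (has_ins)
    rhdf5::h5write(vapply(batch$clouds, function(cl) cl$ins, integer(n)),
                   path, "ins")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_h5_batch
#' @export
read_h5_batch <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  ls <- rhdf5::h5ls(path)
  if (!"data" %in% ls$name) stop_data("no 'data' dataset in ", path)
  arr <- rhdf5::h5read(path, "data")
  sem <- if ("sem" %in% ls$name) rhdf5::h5read(path, "sem")
  ins <- if ("ins" %in% ls$name) rhdf5::h5read(path, "ins")
  rhdf5::h5closeAll()
  if (length(dim(arr)) != 3L || dim(arr)[1] != 3L)
    stop_data("'data' in ", path, " is not a 3 x n x B coordinate array")
  n <- dim(arr)[2]; B <- dim(arr)[3]
  clouds <- lapply(seq_len(B), function(b)
    plant_cloud(t(arr[, , b]),
                sem = if (!is.null(sem)) as.integer(sem[, b]),
                ins = if (!is.null(ins)) as.integer(ins[, b])))
  cloud_batch(clouds, n_fixed = n)
}
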
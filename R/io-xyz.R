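#' Read and write labeled-XYZ text files
#'
#' The plain-text interchange format: one point per line, whitespace
#' separated, `x y z [sem [ins]]`, with `#` comment lines ignored.  Labels
#' are present in the returned cloud iff the corresponding column is present
#' on every line; `-1` in the instance column means "no instance".
#'
#' @param path file path.
#' @param C optional class count override; default inferred as
#'   `max(sem) + 1`.
#' @return [read_labeled_xyz]: a [plant_cloud]. [write_labeled_xyz]:
#'   `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' write_labeled_xyz(plant_cloud(diag(3), sem = c(0L, 1L, 1L)), f)
#' read_labeled_xyz(f)
#' @export
read_labeled_xyz <- function(path, C = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop_data("empty labeled-XYZ file: ", path)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nf <- lengths(toks)
  if (any(nf < 3L | nf > 5L))
    stop_data("malformed line ", keep[which(nf < 3L | nf > 5L)[1]],
              " in ", path, ": expected 3-5 fields, got ",
              nf[which(nf < 3L | nf > 5L)[1]])
  width <- nf[1]
  if (any(nf != width))
    stop_data("inconsistent field count at line ", keep[which(nf != width)[1]],
              " in ", path)
  m <- matrix(suppressWarnings(as.numeric(unlist(toks))),
              nrow = length(toks), ncol = width, byrow = TRUE)
  if (anyNA(m[, 1:3]))
    stop_data("non-numeric coordinate at line ",
              keep[which(rowSums(is.na(m[, 1:3, drop = FALSE])) > 0)[1]],
              " in ", path)
  sem <- ins <- NULL
  if (width >= 4L) {
    sem <- m[, 4]
    bad <- is.na(sem) | sem != floor(sem)
    if (any(bad))
      stop_data("non-integer semantic label at line ", keep[which(bad)[1]],
                " in ", path)
    sem <- as.integer(sem)
  }
  if (width == 5L) {
    ins <- m[, 5]
    bad <- is.na(ins) | ins != floor(ins)
    if (any(bad))
      stop_data("non-integer instance label at line ", keep[which(bad)[1]],
                " in ", path)
    ins <- as.integer(ins)
  }
  plant_cloud(m[, 1:3, drop = FALSE], sem = sem, ins = ins, C = C)
}

#' @param cloud a [plant_cloud].
#' @rdname read_labeled_xyz
#' @export
write_labeled_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "plant_cloud"))
  xyz <- sprintf("%.6f %.6f %.6f",
                 cloud$coords[, 1], cloud$coords[, 2], cloud$coords[, 3])
  if (!is.null(cloud$sem)) {
    xyz <- paste(xyz, cloud$sem)
    if (!is.null(cloud$ins)) xyz <- paste(xyz, cloud$ins)
  }
  writeLines(xyz, path)
  invisible(path)
}
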
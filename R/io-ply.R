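# PLY I/O.  Only the vertex element is interpreted: float properties
# x/y/z, optional integer properties "sem"/"label" and "ins"/"instance".
# Both the ascii and binary_little_endian dialects are read; the writer
# emits binary-little-endian unless ascii = TRUE.  List properties and
# big-endian files are not supported.

.ply_sizes <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_scalar <- function(raw_mat, offset, type, n) {
  sz <- .ply_sizes[[type]]
  bytes <- as.vector(raw_mat[offset + seq_len(sz), , drop = FALSE])
  what <- if (type %in% c("float", "float32", "double", "float64"))
    "double" else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16"))
  v <- readBin(bytes, what = what, n = n, size = sz,
               signed = if (what == "integer" && sz < 4L) signed else TRUE,
               endian = "little")
  v
}

#' Read and write PLY point clouds
#'
#' Reads the vertex element of an ASCII or binary-little-endian PLY file
#' into a [plant_cloud]; semantic labels are taken from an integer vertex
#' property named `sem` or `label`, instance labels from `ins` or
#' `instance`, when present.  The writer stores coordinates as `float32`
#' and labels as `int32`, in binary-little-endian by default.
#'
#' @param path file path.
#' @param C optional semantic class count override.
#' @return [read_ply]: a [plant_cloud]. [write_ply]: `path`, invisibly.
#' @export
read_ply <- function(path, C = NULL) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  # header, byte by byte so the binary payload is left untouched
  header <- character()
  line <- raw()
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop_data("unterminated PLY header in ", path)
    if (b == as.raw(10L)) {
      header <- c(header, rawToChar(line))
      line <- raw()
      if (trimws(header[length(header)]) == "end_header") break
    } else if (b != as.raw(13L)) line <- c(line, b)
  }
  if (length(header) == 0L || trimws(header[1]) != "ply")
    stop_data(path, " is not a PLY file")
  fmt_ln <- grep("^format ", header, value = TRUE)
  if (length(fmt_ln) != 1L) stop_data("missing PLY format line in ", path)
  fmt <- strsplit(trimws(fmt_ln), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop_data("unsupported PLY format '", fmt, "' in ", path)

  # element/property structure
  elems <- list(); cur <- NULL
  for (h in trimws(header)) {
    tk <- strsplit(h, "\\s+")[[1]]
    if (tk[1] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tk[2], count = as.integer(tk[3]),
                  ptype = character(), pname = character())
    } else if (tk[1] == "property" && !is.null(cur)) {
      if (tk[2] == "list")
        stop_data("PLY list properties are not supported (element '",
                  cur$name, "' in ", path, ")")
      cur$ptype <- c(cur$ptype, tk[2])
      cur$pname <- c(cur$pname, tk[3])
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  if (!"vertex" %in% names(elems))
    stop_data("PLY file ", path, " has no vertex element")

  vals <- NULL
  for (el in elems) {
    if (fmt == "ascii") {
      lns <- character(0)
      while (length(lns) < el$count) {
        ln <- readLines(con, n = 1L)
        if (length(ln) == 0L) stop_data("truncated PLY data in ", path)
        if (nzchar(trimws(ln))) lns <- c(lns, ln)
      }
      if (el$name == "vertex") {
        num <- suppressWarnings(
          matrix(as.numeric(unlist(strsplit(trimws(lns), "\\s+"))),
                 nrow = el$count, byrow = TRUE))
        if (ncol(num) != length(el$pname) || anyNA(num))
          stop_data("malformed PLY vertex data in ", path)
        vals <- as.data.frame(num)
        names(vals) <- el$pname
      }
    } else {
      sizes <- .ply_sizes[el$ptype]
      if (anyNA(sizes)) stop_data("unknown PLY property type in ", path)
      rowsize <- sum(sizes)
      buf <- readBin(con, "raw", rowsize * el$count)
      if (length(buf) < rowsize * el$count)
        stop_data("truncated PLY data in ", path)
      if (el$name == "vertex") {
        dim(buf) <- c(rowsize, el$count)
        offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
        vals <- as.data.frame(lapply(seq_along(el$pname), function(i)
          .ply_read_scalar(buf, offs[i], el$ptype[i], el$count)))
        names(vals) <- el$pname
      }
    }
    if (el$name == "vertex") break  # later elements irrelevant
  }
  if (!all(c("x", "y", "z") %in% names(vals)))
    stop_data("PLY vertex element in ", path, " lacks x/y/z properties")
  sem_col <- intersect(c("sem", "label"), names(vals))[1]
  ins_col <- intersect(c("ins", "instance"), names(vals))[1]
  plant_cloud(cbind(vals$x, vals$y, vals$z),
              sem = if (!is.na(sem_col)) as.integer(vals[[sem_col]]),
              ins = if (!is.na(ins_col)) as.integer(vals[[ins_col]]),
              C = C)
}

#' @param cloud a [plant_cloud].
#' @param ascii write the ASCII dialect instead of binary-little-endian.
#' @rdname read_ply
#' @export
write_ply <- function(cloud, path, ascii = FALSE) {
  stopifnot(inherits(cloud, "plant_cloud"))
  n <- n_points(cloud)
  has_sem <- !is.null(cloud$sem)
  has_ins <- !is.null(cloud$ins)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (ascii) "ascii" else "binary_little_endian"),
              sprintf("element vertex %d", n),
              "property float x", "property float y", "property float z",
              if (has_sem) "property int sem",
              if (has_ins) "property int ins",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (ascii) {
    lines <- sprintf("%.9g %.9g %.9g", cloud$coords[, 1], cloud$coords[, 2],
                     cloud$coords[, 3])
    if (has_sem) lines <- paste(lines, cloud$sem)
    if (has_ins) lines <- paste(lines, cloud$ins)
    writeLines(lines, con, sep = "\n")
  } else {
    # interleave per point: 12 bytes of float32 xyz + 4 bytes per label
    fraw <- writeBin(as.vector(t(cloud$coords)), raw(), size = 4L,
                     endian = "little")
    dim(fraw) <- c(12L, n)
    blocks <- list(fraw)
    if (has_sem) {
      sraw <- writeBin(cloud$sem, raw(), size = 4L, endian = "little")
      dim(sraw) <- c(4L, n)
      blocks <- c(blocks, list(sraw))
    }
    if (has_ins) {
      iraw <- writeBin(cloud$ins, raw(), size = 4L, endian = "little")
      dim(iraw) <- c(4L, n)
      blocks <- c(blocks, list(iraw))
    }
    writeBin(as.vector(do.call(rbind, blocks)), con)
  }
  invisible(path)
}
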
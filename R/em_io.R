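# MRC volume/stack I/O, EMAN-style .box coordinates, TSV tables.
#
# MRC files are written in the MRC2014 layout, mode 2 (32-bit float),
# little-endian, z slowest.  Only mode-2 files are read back: a single
# numeric path keeps round trips exact.

MRC_HEADER_BYTES <- 1024L

#' Write a volume or particle stack as an MRC file
#'
#' Mode 2 (32-bit IEEE float), little-endian, axis order x fastest / z
#' slowest.  The voxel size is stored in the cell dimensions.
#'
#' @param volume an [em_volume()] or [particle_stack()] (a stack is written
#'   as nz = number of images).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume)
  if (length(d) != 3L) stop("expected a 3D array")
  vx <- voxel_size(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  vals <- as.numeric(volume)
  wi(d)                    # nx ny nz
  wi(2L)                   # mode 2: float32
  wi(c(0L, 0L, 0L))        # nxstart
  wi(d)                    # mx my mz
  wf(d * vx)               # cella (A)
  wf(c(90, 90, 90))        # cellb
  wi(c(1L, 2L, 3L))        # mapc mapr maps
  wf(c(min(vals), max(vals), mean(vals)))
  wi(c(1L, 0L))            # ispg, nsymbt
  writeBin(raw(100L), con) # extra
  wf(c(0, 0, 0))           # origin
  writeChar("MAP ", con, 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(vals))
  wi(0L)                   # nlabl
  writeBin(raw(800L), con)
  writeBin(vals, con, size = 4L, endian = "little")
  invisible(path)
}

read_mrc_raw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.info(path)$size
  if (sz < MRC_HEADER_BYTES)
    stop(sprintf("truncated MRC file: %d bytes, need at least %d for the header",
                 sz, MRC_HEADER_BYTES))
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")
  d <- ri(3L)
  mode <- ri(1L)
  if (any(d <= 0L)) stop("malformed MRC header: non-positive dimensions")
  if (mode != 2L)
    stop(sprintf("unsupported MRC mode %d (only mode 2, 32-bit float, is supported)",
                 mode))
  ri(3L)                       # nxstart
  m <- ri(3L)
  cella <- rf(3L)
  vx <- if (m[1] > 0 && cella[1] > 0) cella[1] / m[1] else 1
  seek(con, MRC_HEADER_BYTES)
  n <- prod(d)
  expected <- MRC_HEADER_BYTES + 4 * n
  if (sz < expected)
    stop(sprintf("truncated MRC file: %d bytes, expected %d (%d voxels)",
                 sz, expected, n))
  vals <- rf(n)
  list(data = array(vals, dim = d), voxel_size = vx)
}

#' Read an MRC volume
#'
#' @param path MRC file (mode 2).
#' @return An [em_volume()]; voxel size from the header cell dimensions.
#' @export
read_volume <- function(path) {
  r <- read_mrc_raw(path)
  em_volume(r$data, r$voxel_size)
}

#' Read an MRC particle stack
#'
#' Interprets the z sections of the file as a stack of 2D images.
#' @param path MRC file (mode 2).
#' @return A [particle_stack()].
#' @export
read_stack <- function(path) {
  r <- read_mrc_raw(path)
  particle_stack(r$data, r$voxel_size)
}

#' Read EMAN-style .box particle coordinates
#'
#' Whitespace-separated rows `x y width height` where `(x, y)` is the
#' left-top corner in pixels (0-based).  Returns the particle centres,
#' `corner + box/2`.  The y origin is top-left by default; `flip_y = TRUE`
#' converts from a bottom-left origin using `image_height`.
#'
#' @param path .box file.
#' @param image_height image height in px; required when `flip_y = TRUE`.
#' @param flip_y apply the bottom-left-origin convention.
#' @return data.frame with columns `x`, `y` (0-based centre coordinates) and
#'   `box` (box size in px).  Empty file gives zero rows.
#' @export
read_box <- function(path, image_height = NULL, flip_y = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), box = numeric(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 4L))
    stop(sprintf("malformed .box row at line %d: %d column(s), need at least 4",
                 which(nf < 4L)[1], nf[nf < 4L][1]))
  num <- vapply(fields, function(f) as.numeric(f[1:4]), numeric(4))
  if (anyNA(num))
    stop(sprintf("non-numeric .box entry at line %d",
                 which(apply(num, 2, anyNA))[1]))
  w <- num[3, ]; h <- num[4, ]
  if (any(w != h))
    stop(sprintf("non-square box at line %d (width %g != height %g)",
                 which(w != h)[1], w[w != h][1], h[w != h][1]))
  if (any(num[1, ] < 0 | num[2, ] < 0))
    stop("negative .box corner coordinates")
  x <- num[1, ] + w / 2
  y <- num[2, ] + h / 2
  if (flip_y) {
    if (is.null(image_height))
      stop("'image_height' is required when flip_y = TRUE")
    y <- image_height - 1 - y
  }
  data.frame(x = x, y = y, box = w)
}

#' Write / read a tab-separated table
#'
#' UTF-8, header row, `\n` line endings; re-writing an unmodified table
#' reproduces an identical file body.
#'
#' @param df data.frame.
#' @param path file path.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: the data.frame.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             encoding = "UTF-8")
}
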
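# Reader/writer for the IDX (ubyte) dataset format used by common
# handwritten-digit benchmarks: a big-endian header (magic bytes giving the
# element type and dimension count, then one 4-byte size per dimension)
# followed by the raw data.

#' Read an IDX (ubyte) file
#'
#' @param path Path to an uncompressed IDX file.
#' @param scale Divide pixel values by 255 so intensities land in \[0, 1\]
#'   (ignored for 1-d label files, which are returned as integers).
#' @return For 1-d files an integer vector of labels; for n-d files a
#'   numeric array with the dimensions given in the header (first
#'   dimension: item index).
#' @export
read_idx <- function(path, scale = TRUE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4L, size = 1L, signed = FALSE)
  if (length(magic) < 4L || magic[1L] != 0L || magic[2L] != 0L) {
    stop("not an IDX file (bad magic): ", path)
  }
  if (magic[3L] != 0x08) {
    stop("unsupported IDX element type 0x", sprintf("%02x", magic[3L]))
  }
  ndim <- magic[4L]
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "big")
  n_total <- prod(dims)
  data <- readBin(con, "integer", n = n_total, size = 1L, signed = FALSE)
  if (length(data) < n_total) stop("truncated IDX file: ", path)
  if (ndim == 1L) return(as.integer(data))
  # row-major on disk -> fill the R array with reversed dims, then aperm
  arr <- array(data, dim = rev(dims))
  arr <- aperm(arr, rev(seq_len(ndim)))
  if (scale) arr / 255 else arr
}

#' Write an IDX (ubyte) file
#'
#' Inverse of [read_idx()]; intensities in \[0, 1\] are rescaled to 0-255.
#' Mainly used to build synthetic fixtures.
#'
#' @param x Integer vector (labels) or numeric array (images).
#' @param path Output path.
#' @param scale Multiply by 255 before truncation to bytes (for arrays).
#' @return `path`, invisibly.
#' @export
write_idx <- function(x, path, scale = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  ndim <- length(dims)
  writeBin(as.raw(c(0L, 0L, 0x08, ndim)), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  vals <- if (ndim == 1L) as.integer(x) else {
    v <- aperm(x, rev(seq_len(ndim)))
    if (scale) as.integer(round(as.vector(v) * 255)) else
      as.integer(as.vector(v))
  }
  if (any(vals < 0 | vals > 255)) stop("values outside the ubyte range")
  writeBin(as.raw(vals), con)
  invisible(path)
}
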
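#' Read and write 3D volumes (MRC and multi-page TIFF)
#'
#' Volumes are stored in canonical (X, Y, Z) axis order. MRC files use the
#' MRC2014 layout: intensity volumes are written as mode 2 (32-bit float)
#' and label volumes as mode 6 (unsigned 16-bit). Multi-page TIFF stores
#' one Z slice per page (rows = X, columns = Y) as unsigned 16-bit:
#' intensity volumes as fixed point over `[0, 1]` (LAC values above 1 are
#' not representable in TIFF here; use MRC, which stores 32-bit float),
#' label volumes as raw integers. Round trips are lossless at the stored
#' precision.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"mrc"` or `"tiff"`.
#' @param vol A volume (3D numeric array).
#' @param voxel_size µm/voxel recorded with the volume.
#' @return `read_volume()` returns an [sxt_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".tif")
#' write_volume(sxt_volume(array(0, c(2, 2, 2))), p)
#' read_volume(p)
#' @name volume_io
NULL

guess_format <- function(path, format) {
  format <- match.arg(format, c("auto", "mrc", "tiff"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("mrc", "rec", "map", "st")) return("mrc")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("cannot guess volume format from extension '.", ext,
       "'; pass format=", call. = FALSE)
}

#' @rdname volume_io
#' @export
read_volume <- function(path, format = c("auto", "mrc", "tiff")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- guess_format(path, match.arg(format))
  data <- switch(format, mrc = read_mrc(path),
                 tiff = read_tiff_stack(path, as_is = FALSE))
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume in ", path, " contains NA/NaN/Inf values", call. = FALSE)
  sxt_volume(data)
}

#' @rdname volume_io
#' @export
write_volume <- function(vol, path, format = c("auto", "mrc", "tiff"),
                         voxel_size = attr(vol, "voxel_size") %||% 1) {
  check_dim3(vol, "volume")
  if (anyNA(vol) || any(!is.finite(vol)))
    stop("refusing to write non-finite volume", call. = FALSE)
  format <- guess_format(path, match.arg(format))
  if (format == "tiff" && (min(vol) < 0 || max(vol) > 1))
    stop("TIFF intensity storage covers [0, 1]; write values outside ",
         "that range as MRC", call. = FALSE)
  switch(format,
         mrc = write_mrc(vol, path, mode = 2L, voxel_size = voxel_size),
         tiff = write_tiff_stack(vol, path))
  invisible(path)
}

#' Read and write 3D label volumes (masks, instance maps, scenes)
#'
#' Same containers as [read_volume()] but for non-negative integer data,
#' stored as unsigned 16-bit (MRC mode 6 or 16-bit TIFF). Labels above
#' 65535 are rejected.
#'
#' @param labels Integer 3D array (logical masks are written as 0/1).
#' @inheritParams volume_io
#' @return `read_labels()` returns an integer 3D array.
#' @export
read_labels <- function(path, format = c("auto", "mrc", "tiff")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- guess_format(path, match.arg(format))
  data <- switch(format, mrc = read_mrc(path), tiff = read_tiff_stack(path))
  storage.mode(data) <- "integer"
  data
}

#' @rdname read_labels
#' @export
write_labels <- function(labels, path, format = c("auto", "mrc", "tiff")) {
  if (is.logical(labels)) labels <- array(as.integer(labels), dim(labels))
  check_dim3(labels, "labels")
  if (any(labels < 0) || any(labels > 65535))
    stop("labels must be integers in 0..65535", call. = FALSE)
  format <- guess_format(path, match.arg(format))
  switch(format,
         mrc = write_mrc(labels, path, mode = 6L),
         tiff = write_tiff_stack(labels, path, scale = 65535))
  invisible(path)
}

# ---- minimal MRC2014 reader/writer --------------------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]; mode <- hdr_int[4]
  if (nx < 1 || ny < 1 || nz < 1)
    stop("not a 3D MRC volume: extents ", nx, "x", ny, "x", nz, call. = FALSE)
  readBin(con, "numeric", n = 6, size = 4, endian = "little")    # cell
  readBin(con, "integer", n = 3, size = 4, endian = "little")    # map order
  readBin(con, "numeric", n = 3, size = 4, endian = "little")    # dmin/max/mean
  isp <- readBin(con, "integer", n = 2, size = 4, endian = "little")
  nsymbt <- isp[2]
  seek(con, 1024 + nsymbt)
  n <- as.numeric(nx) * ny * nz
  data <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode ", mode, call. = FALSE))
  if (length(data) != n) stop("truncated MRC data in ", path, call. = FALSE)
  array(data, c(nx, ny, nz))
}

write_mrc <- function(data, path, mode = 2L, voxel_size = 1) {
  d <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(d, mode, 0L, 0L, 0L, d))                 # nx..nz, mode, nstart, m
  wf(c(d * voxel_size * 1e4, 90, 90, 90))       # cell (angstrom), angles
  wi(c(1L, 2L, 3L))                             # axis order
  wf(c(min(data), max(data), mean(data)))
  wi(c(1L, 0L))                                 # ispg, nsymbt
  wi(rep(0L, 25))                               # extra
  wf(c(0, 0, 0))                                # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(as.numeric(data)))
  wi(0L)                                        # nlabl
  writeBin(raw(800), con)
  x <- as.vector(data)
  switch(as.character(mode),
    "2" = writeBin(as.numeric(x), con, size = 4, endian = "little"),
    "1" = {
      if (any(x < -32768 | x > 32767)) stop("values exceed int16 range")
      writeBin(as.integer(x), con, size = 2, endian = "little")
    },
    "6" = {
      if (any(x < 0 | x > 65535)) stop("values exceed uint16 range")
      writeBin(as.integer(x), con, size = 2, endian = "little")
    },
    stop("unsupported MRC write mode ", mode, call. = FALSE))
  invisible(path)
}

# ---- multi-page TIFF via the tiff package -------------------------------

read_tiff_stack <- function(path, as_is = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L)
    stop("TIFF pages disagree in shape", call. = FALSE)
  d2 <- dims[[1]]
  if (length(d2) != 2L)
    stop("expected single-channel grayscale TIFF pages", call. = FALSE)
  arr <- array(0, c(d2[1], d2[2], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  arr
}

write_tiff_stack <- function(data, path, scale = 1) {
  d <- dim(data)
  pages <- vector("list", d[3])
  for (k in seq_len(d[3])) {
    pages[[k]] <- matrix(as.numeric(data[, , k]) / scale, d[1], d[2])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  invisible(path)
}

#' Write or read an instance record table as CSV
#'
#' @param records Tibble from [extract_instances()].
#' @param path CSV path.
#' @return `read_instance_table()` returns a tibble.
#' @export
write_instance_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_instance_table
#' @export
read_instance_table <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}
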
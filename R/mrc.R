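# MRC2014 raster I/O. Header is 1024 bytes of little-endian words; pixel
# size is cella/mx. Only the modes used by cryoEM pipelines are supported:
# 0 (int8), 1 (int16), 2 (float32), 6 (uint16).

mrcModeInfo <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    stop("unsupported MRC mode ", mode, " (supported: 0, 1, 2, 6)",
         call. = FALSE)
  )
}

#' Read an MRC2014 image or stack
#'
#' Reads modes 0 (int8), 1 (int16), 2 (float32) and 6 (uint16). A stack
#' (nz > 1) is either averaged into one frame or returned as a list of
#' frames. Non-square frames are centre-cropped to square with a warning.
#' The nominal pixel size comes from the header cell dimensions (cella/mx)
#' unless overridden.
#'
#' @param path path to an MRC2014 file.
#' @param overridePixelSize optional pixel size (Angstrom) replacing the
#'   header value.
#' @param stack `"mean"` (default) averages stack frames into one
#'   [Micrograph-class]; `"list"` returns one Micrograph per frame.
#' @return a [Micrograph-class], or a list of them when `stack = "list"`.
#' @export
readMRC <- function(path, overridePixelSize = NULL, stack = c("mean", "list")) {
  stack <- match.arg(stack)
  if (!file.exists(path)) stop("MRC file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  mxyz <- hdr[8:10]
  cella <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")
  if (nx <= 0 || ny <= 0 || nz <= 0 || !mode %in% c(0L, 1L, 2L, 6L))
    stop("invalid or unsupported MRC header in ", path, call. = FALSE)
  px <- if (mxyz[1] > 0 && cella[1] > 0) cella[1] / mxyz[1] else NA_real_
  if (!is.null(overridePixelSize)) px <- overridePixelSize
  if (!is.finite(px) || px <= 0)
    stop("no valid pixel size in header of ", path,
         "; supply overridePixelSize", call. = FALSE)
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  info <- mrcModeInfo(mode)
  seek(con, 1024L + nsymbt)
  frames <- vector("list", nz)
  for (k in seq_len(nz)) {
    v <- readBin(con, info$what, n = nx * ny, size = info$size,
                 signed = info$signed, endian = "little")
    if (length(v) != nx * ny)
      stop("truncated MRC data in ", path, call. = FALSE)
    frames[[k]] <- matrix(as.numeric(v), nrow = nx, ncol = ny)
  }
  mk <- function(m, label) {
    m <- cropSquare(m, path)
    new("Micrograph", pixels = m, pixelSize = px, source = label)
  }
  if (nz == 1L) return(mk(frames[[1]], path))
  if (stack == "mean") {
    mk(Reduce(`+`, frames) / nz, path)
  } else {
    lapply(seq_len(nz), function(k) mk(frames[[k]], sprintf("%s@%d", path, k)))
  }
}

cropSquare <- function(m, label) {
  nx <- nrow(m); ny <- ncol(m)
  if (nx == ny) return(m)
  s <- min(nx, ny)
  warning("non-square image ", label, " (", nx, "x", ny,
          "): centre-cropping to ", s, "x", s, call. = FALSE)
  ox <- (nx - s) %/% 2
  oy <- (ny - s) %/% 2
  m[(ox + 1):(ox + s), (oy + 1):(oy + s), drop = FALSE]
}

#' Write a matrix or Micrograph stack as MRC2014
#'
#' @param x a numeric matrix, a [Micrograph-class], or a list of either
#'   (written as a stack).
#' @param path output path.
#' @param pixelSize pixel size (Angstrom) stored in the header cell; taken
#'   from the Micrograph when omitted.
#' @param mode MRC data mode: 0, 1, 2 (default) or 6.
#' @return `path`, invisibly.
#' @export
writeMRC <- function(x, path, pixelSize = NULL, mode = 2L) {
  if (is(x, "Micrograph")) {
    if (is.null(pixelSize)) pixelSize <- x@pixelSize
    x <- list(x@pixels)
  } else if (is.matrix(x)) {
    x <- list(x)
  } else if (is.list(x)) {
    x <- lapply(x, function(f) if (is(f, "Micrograph")) f@pixels else f)
  }
  if (is.null(pixelSize)) stop("pixelSize required", call. = FALSE)
  info <- mrcModeInfo(mode)
  nx <- nrow(x[[1]]); ny <- ncol(x[[1]]); nz <- length(x)
  all_v <- unlist(x, use.names = FALSE)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr_int <- integer(256)
  hdr_int[1:3] <- c(nx, ny, nz)
  hdr_int[4] <- as.integer(mode)
  hdr_int[8:10] <- c(nx, ny, nz)             # mx, my, mz
  writeBin(hdr_int[1:10], con, size = 4L, endian = "little")
  writeBin(as.numeric(c(nx, ny, nz) * pixelSize), con, size = 4L,
           endian = "little")               # cella
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4L, endian = "little")
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")  # mapc/r/s
  writeBin(as.numeric(c(min(all_v), max(all_v), mean(all_v))), con,
           size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")  # ispg, nsymbt
  writeBin(raw(100), con)                    # extra
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4L, endian = "little") # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(as.numeric(stats::sd(all_v)), con, size = 4L, endian = "little")
  writeBin(0L, con, size = 4L, endian = "little")    # nlabl
  writeBin(raw(800), con)
  for (f in x) {
    v <- as.vector(f)
    if (info$what == "integer") v <- as.integer(round(v))
    writeBin(if (info$what == "integer") v else as.numeric(v), con,
             size = info$size, endian = "little")
  }
  invisible(path)
}

#' Load micrographs matching a glob pattern
#'
#' @param pattern glob such as `"data/*.mrc"`, or a character vector of paths.
#' @param overridePixelSize optional pixel size (Angstrom) applied to all.
#' @return list of [Micrograph-class] objects.
#' @export
loadMicrographs <- function(pattern, overridePixelSize = NULL) {
  paths <- if (length(pattern) == 1L && grepl("[*?]", pattern))
    Sys.glob(pattern) else pattern
  if (length(paths) == 0L)
    stop("no files match ", pattern, call. = FALSE)
  lapply(paths, readMRC, overridePixelSize = overridePixelSize)
}
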
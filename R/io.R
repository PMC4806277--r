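#' Read an RGB image from PNG or BMP
#'
#' Reads an 8-bit PNG or an uncompressed BMP (24-bit RGB or 8-bit
#' greyscale) into an `rgb_image`: an `H x W x 3` integer array with
#' channel values in `[0, 255]`. Greyscale sources are replicated across
#' the three channels; an alpha channel, if present, is dropped.
#'
#' @param path Path to a `.png` or `.bmp` file.
#' @return An object of class `rgb_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  magic <- readBin(path, "raw", n = 8L)
  png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  if (length(magic) >= 8 && identical(magic[1:8], png_sig)) {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
    if (dim(arr)[3] == 1L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE]
    if (dim(arr)[3] >= 4L) arr <- arr[, , 1:3, drop = FALSE]
    if (dim(arr)[3] == 2L) arr <- arr[, , c(1L, 1L, 1L), drop = FALSE] # grey+alpha
    px <- array(as.integer(round(arr * 255)), dim(arr))
  } else if (length(magic) >= 2 && rawToChar(magic[1:2]) == "BM") {
    px <- read_bmp(path)
  } else {
    stop("unrecognised image format (expected PNG or BMP): ", path)
  }
  rgb_image(px)
}

#' Construct an rgb_image
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 255]`.
#' @return An `rgb_image` (integer array with class attribute).
#' @export
rgb_image <- function(pixels) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) stop("pixels must be an H x W x 3 array")
  if (d[1] < 1L || d[2] < 1L) stop("image must have positive dimensions")
  px <- array(as.integer(round(pixels)), d)
  if (anyNA(px) || min(px) < 0L || max(px) > 255L)
    stop("channel values must lie in [0, 255]")
  structure(px, class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d>\n", d[1], d[2]))
  invisible(x)
}

#' Write an RGB image or binary mask to PNG or BMP
#'
#' Masks (logical matrices) are written as 0/255 images, the dialect used
#' for ground-truth masks in this package.
#'
#' @param x An `rgb_image` or a logical matrix (mask).
#' @param path Output path; format chosen by extension (`.png` or `.bmp`).
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  if (is.logical(x) && is.matrix(x)) {
    v <- ifelse(x, 255L, 0L)
    x <- rgb_image(array(v, c(dim(v), 3L))[, , c(1L, 1L, 1L), drop = FALSE])
  }
  if (!inherits(x, "rgb_image")) stop("x must be an rgb_image or a logical mask")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(unclass(x) / 255, target = path)
  } else if (ext == "bmp") {
    write_bmp(unclass(x), path)
  } else {
    stop("unsupported output extension: ", ext)
  }
  invisible(path)
}

#' Read a binary 0/255 mask image
#'
#' @param path PNG or BMP mask file.
#' @param threshold Channel-mean value above which a pixel is foreground.
#' @return Logical matrix.
#' @export
read_mask <- function(path, threshold = 127) {
  img <- read_image(path)
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3 > threshold
}

# --- minimal uncompressed BMP codec -----------------------------------------
# Supports 24-bit BGR and 8-bit palette/greyscale, BITMAPINFOHEADER,
# bottom-up or top-down row order. Enough for the binary ground-truth
# mask dialect and ordinary photographic BMPs.

read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 14L)
  if (rawToChar(hdr[1:2]) != "BM") stop("not a BMP file: ", path)
  data_offset <- readBin(hdr[11:14], "integer", size = 4L, endian = "little")
  dib <- readBin(con, "raw", n = 40L)
  int_at <- function(r, i) readBin(r[i:(i + 3)], "integer", size = 4L, endian = "little")
  w <- int_at(dib, 5L)
  h_raw <- int_at(dib, 9L)
  topdown <- h_raw < 0
  h <- abs(h_raw)
  bpp <- readBin(dib[15:16], "integer", size = 2L, endian = "little")
  compression <- int_at(dib, 17L)
  if (compression != 0L) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("unsupported BMP bit depth: ", bpp)
  palette <- NULL
  if (bpp == 8L) {
    n_colors <- int_at(dib, 33L)
    if (n_colors == 0L) n_colors <- 256L
    pal_raw <- readBin(con, "raw", n = 4L * n_colors)
    palette <- matrix(as.integer(pal_raw), ncol = 4L, byrow = TRUE)[, 3:1, drop = FALSE]
  }
  seek(con, data_offset)
  row_bytes <- ((w * bpp / 8 + 3) %/% 4) * 4
  body <- readBin(con, "raw", n = row_bytes * h)
  px <- array(0L, c(h, w, 3L))
  for (r in seq_len(h)) {
    row <- as.integer(body[((r - 1) * row_bytes + 1):((r - 1) * row_bytes + w * bpp / 8)])
    i <- if (topdown) r else h - r + 1L
    if (bpp == 24L) {
      m <- matrix(row, nrow = 3L) # B,G,R triplets
      px[i, , 1] <- m[3, ]; px[i, , 2] <- m[2, ]; px[i, , 3] <- m[1, ]
    } else {
      px[i, , 1] <- palette[row + 1L, 1]
      px[i, , 2] <- palette[row + 1L, 2]
      px[i, , 3] <- palette[row + 1L, 3]
    }
  }
  px
}

write_bmp <- function(px, path) {
  h <- dim(px)[1]; w <- dim(px)[2]
  row_bytes <- ((w * 3 + 3) %/% 4) * 4
  body <- raw(row_bytes * h)
  for (r in seq_len(h)) {
    i <- h - r + 1L # bottom-up
    triplets <- as.integer(rbind(px[i, , 3], px[i, , 2], px[i, , 1]))
    body[((r - 1) * row_bytes + 1):((r - 1) * row_bytes + w * 3)] <- as.raw(triplets)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  int32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  int16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  writeBin(charToRaw("BM"), con)
  int32(14 + 40 + length(body)) # file size
  int16(0); int16(0)
  int32(14 + 40) # data offset
  int32(40); int32(w); int32(h)
  int16(1); int16(24)
  int32(0); int32(length(body))
  int32(2835); int32(2835); int32(0); int32(0)
  writeBin(body, con)
  invisible(path)
}
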
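# File formats: minimal NRRD volume reader/writer and 16-bit grayscale PNG
# export.  NRRD headers are plain text ("NRRD0004") followed by raw
# little-endian or ascii data; that subset is all the pipeline needs.

#' Write a volume to NRRD
#'
#' Writes a 2D or 3D numeric array as an NRRD0004 file.  `raw` encoding
#' stores IEEE doubles little-endian; `ascii` stores decimal text.
#'
#' @param x numeric matrix or 3D array.
#' @param path output file path.
#' @param encoding `"raw"` or `"ascii"`.
#' @return `path`, invisibly.
#' @seealso [read_nrrd()]
#' @export
write_nrrd <- function(x, path, encoding = c("raw", "ascii")) {
  encoding <- match.arg(encoding)
  if (!is.numeric(x) || is.null(dim(x))) stop("x must be a numeric array")
  d <- dim(x)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# generated by synthmri",
           "type: double",
           paste0("dimension: ", length(d)),
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("encoding: ", encoding),
           if (encoding == "raw") "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  if (encoding == "raw") {
    writeBin(as.double(x), con, size = 8, endian = "little")
  } else {
    writeLines(paste(format(as.double(x), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' Read an NRRD volume
#'
#' Reads the NRRD subset written by [write_nrrd()] (plus uchar/float/int
#' types): text header, then raw little-endian or ascii data.
#'
#' @param path NRRD file path.
#' @return numeric array with the dimensions declared in the header.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!startsWith(magic, "NRRD")) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (startsWith(line, "#")) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3) fields[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(fields$sizes), "\\s+")[[1]])
  n <- prod(sizes)
  type <- tolower(fields$type %||% "double")
  enc <- tolower(fields$encoding %||% "raw")
  if (enc %in% c("ascii", "text", "txt")) {
    vals <- scan(con, what = double(), n = n, quiet = TRUE)
  } else if (enc == "raw") {
    spec <- switch(type,
                   "double" = list(what = double(), size = 8),
                   "float"  = list(what = double(), size = 4),
                   "uchar"  = , "uint8" = list(what = integer(), size = 1),
                   "int"    = , "int32" = list(what = integer(), size = 4),
                   stop("unsupported NRRD type: ", type))
    vals <- readBin(con, what = spec$what, n = n, size = spec$size,
                    endian = "little", signed = spec$size > 1)
    vals <- as.double(vals)
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(vals) != n) stop("truncated NRRD data in ", path)
  array(vals, dim = sizes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

png_chunk <- function(con, type, data) {
  payload <- c(charToRaw(type), data)
  writeBin(length(data), con, size = 4, endian = "big")
  writeBin(payload, con)
  crc <- cpp_crc32(payload)
  writeBin(as.integer(crc - ifelse(crc > 2147483647, 4294967296, 0)), con,
           size = 4, endian = "big")
}

# Despite the type name, memCompress(type = "gzip") emits an RFC 1950 zlib
# stream (0x78 0x9c header + Adler-32 trailer), which is exactly the IDAT
# framing PNG requires.
zlib_compress <- function(bytes) {
  memCompress(bytes, type = "gzip")
}

#' Write a 16-bit grayscale PNG
#'
#' Stores intensity `x` in `[0, 1]` as `round(x * 65535)`.  The installed png
#' package reads but does not write 16-bit depth, so the encoder (IHDR/IDAT
#' chunks, zlib framing) is implemented here.
#'
#' @param img numeric matrix with values in `[0, 1]` (rows = image rows).
#' @param path output file path.
#' @return `path`, invisibly. Read back with [png::readPNG()].
#' @export
write_png16 <- function(img, path) {
  if (!is.matrix(img) || min(img) < 0 || max(img) > 1)
    stop("img must be a matrix with values in [0, 1]")
  v <- round(img * 65535)
  hi <- as.raw(v %/% 256)
  lo <- as.raw(v %% 256)
  h <- nrow(img); w <- ncol(img)
  scan <- raw(h * (1 + 2 * w))
  for (i in seq_len(h)) {
    row <- rbind(hi[seq(i, length(v), h)], lo[seq(i, length(v), h)])
    scan[((i - 1) * (1 + 2 * w) + 2):(i * (1 + 2 * w))] <- as.raw(row)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  ihdr <- c(writeBin(w, raw(), size = 4, endian = "big"),
            writeBin(h, raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0)))  # depth 16, grayscale
  png_chunk(con, "IHDR", ihdr)
  png_chunk(con, "IDAT", zlib_compress(scan))
  png_chunk(con, "IEND", raw(0))
  invisible(path)
}

#' Write a binary mask PNG
#'
#' 8-bit grayscale, foreground 255 / background 0.
#'
#' @param mask binary matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stop_if_not_mask(mask)
  png::writePNG(mask, path)
  invisible(path)
}
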
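# Minimal single-frame DICOM support (explicit VR little endian). This
# covers exactly what radiograph ingestion needs -- Rows/Columns, optional
# PixelSpacing, BitsAllocated, PixelData -- plus a matching writer used to
# build synthetic fixtures in code. It is not a general DICOM toolkit.

u16 <- function(raw, i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1])
u32 <- function(raw, i) u16(raw, i) + 65536 * u16(raw, i + 2)

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", n = 132)
  length(head) == 132 && rawToChar(head[129:132]) == "DICM"
}

#' Read a single-frame DICOM radiograph
#'
#' Parses an explicit-VR little-endian DICOM file and returns the pixel
#' array and pixel spacing. Multi-frame files are rejected; truncated or
#' non-DICOM files raise a read error.
#'
#' @param path file path.
#' @return List with `image` (numeric matrix in \[0, 1\], rows = y) and
#'   `pixel_spacing_mm` (first value of PixelSpacing, or `NULL`).
#' @export
read_dicom_image <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("unreadable DICOM file: missing DICM magic")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  i <- 133L
  tags <- list()
  while (i + 7 <= length(raw)) {
    group <- u16(raw, i); elem <- u16(raw, i + 2)
    vr <- rawToChar(raw[(i + 4):(i + 5)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unreadable DICOM file: not explicit-VR little endian")
    if (vr %in% long_vrs) {
      len <- u32(raw, i + 8); off <- 12L
    } else {
      len <- u16(raw, i + 6); off <- 8L
    }
    if (i + off + len - 1 > length(raw)) stop("unreadable DICOM file: truncated element")
    body <- raw[(i + off):(i + off + len - 1)]
    key <- sprintf("%04x%04x", group, elem)
    tags[[key]] <- list(vr = vr, body = body)
    i <- i + off + len
    if (key == "7fe00010") break
  }
  need <- function(key, what) {
    if (is.null(tags[[key]])) stop("unreadable DICOM file: missing ", what)
    tags[[key]]
  }
  as_us <- function(t) u16(t$body, 1)
  as_str <- function(t) trimws(rawToChar(t$body))
  if (!is.null(tags[["00280008"]])) {
    nf <- suppressWarnings(as.integer(as_str(tags[["00280008"]])))
    if (!is.na(nf) && nf > 1L) stop("multi-frame DICOM is not supported")
  }
  rows <- as_us(need("00280010", "Rows"))
  cols <- as_us(need("00280011", "Columns"))
  bits <- if (is.null(tags[["00280100"]])) 8L else as_us(tags[["00280100"]])
  if (!bits %in% c(8L, 16L)) stop("unsupported BitsAllocated: ", bits)
  spacing <- NULL
  if (!is.null(tags[["00280030"]])) {
    sp <- suppressWarnings(as.numeric(strsplit(as_str(tags[["00280030"]]), "\\\\")[[1]]))
    if (length(sp) >= 1 && is.finite(sp[1])) spacing <- sp[1]
  }
  pix <- need("7fe00010", "PixelData")$body
  vals <- if (bits == 8L) as.integer(pix)
          else u16(pix, seq(1, length(pix), by = 2))
  if (length(vals) < rows * cols) stop("unreadable DICOM file: short pixel data")
  img <- matrix(vals[seq_len(rows * cols)] / (2^bits - 1),
                nrow = rows, ncol = cols, byrow = TRUE)
  list(image = img, pixel_spacing_mm = spacing)
}

#' Write a minimal synthetic DICOM file
#'
#' Serializes a grayscale matrix as an 8-bit explicit-VR little-endian
#' DICOM file. Intended for building synthetic test fixtures in code; it
#' writes only the handful of attributes [read_dicom_image()] consumes.
#'
#' @param image numeric matrix in \[0, 1\] (rows = y).
#' @param path output path.
#' @param pixel_spacing_mm optional isotropic spacing written as
#'   PixelSpacing.
#' @param n_frames NumberOfFrames attribute; values above 1 produce a file
#'   the reader must reject (used to exercise that error path).
#' @return `path`, invisibly.
#' @export
write_synthetic_dicom <- function(image, path, pixel_spacing_mm = NULL, n_frames = 1L) {
  stopifnot(is.matrix(image))
  con <- file(path, "wb"); on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  element <- function(group, elem, vr, body) {
    w16(group); w16(elem)
    writeBin(charToRaw(vr), con)
    if (vr %in% c("OB", "OW")) {
      w16(0L); writeBin(as.integer(length(body)), con, size = 4, endian = "little")
    } else {
      if (length(body) %% 2 == 1) body <- c(body, charToRaw(" "))
      w16(length(body))
    }
    writeBin(body, con)
  }
  str_body <- function(s) charToRaw(s)
  us_body <- function(x) writeBin_raw16(x)
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  element(0x0002L, 0x0010L, "UI", str_body("1.2.840.10008.1.2.1"))
  if (n_frames != 1L) element(0x0028L, 0x0008L, "IS", str_body(as.character(n_frames)))
  element(0x0028L, 0x0010L, "US", us_body(nrow(image)))
  element(0x0028L, 0x0011L, "US", us_body(ncol(image)))
  if (!is.null(pixel_spacing_mm))
    element(0x0028L, 0x0030L, "DS",
            str_body(paste(pixel_spacing_mm, pixel_spacing_mm, sep = "\\")))
  element(0x0028L, 0x0100L, "US", us_body(8L))
  pix <- as.raw(round(pmin(pmax(t(image), 0), 1) * 255))  # row-major order
  if (length(pix) %% 2 == 1) pix <- c(pix, as.raw(0))
  element(0x7fe0L, 0x0010L, "OW", pix)
  invisible(path)
}

writeBin_raw16 <- function(x) {
  x <- as.integer(x)
  as.raw(c(x %% 256L, x %/% 256L))
}
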
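# Image ingestion and normalization. Images are plain numeric matrices with
# rows = y (top to bottom) and columns = x (left to right), intensities in
# [0, 1]. Geometry uses 0-based pixel coordinates: the center of matrix cell
# [i, j] is (x = j - 1, y = i - 1).

#' Canvas transform between original and model space
#'
#' Records the aspect-preserving resize-and-pad mapping so landmark
#' coordinates can be moved losslessly between the original radiograph and
#' the fixed-size model canvas: `canvas = original * scale + (pad_x, pad_y)`.
#'
#' @param scale isotropic scale factor (> 0).
#' @param pad_x,pad_y left/top zero-padding in canvas pixels.
#' @param original_size,canvas_size `(width, height)` in pixels.
#' @return Object of class `canvas_transform`.
#' @export
canvas_transform <- function(scale, pad_x, pad_y, original_size, canvas_size) {
  if (!is.finite(scale) || scale <= 0) stop("scale must be positive")
  structure(list(scale = scale, pad_x = pad_x, pad_y = pad_y,
                 original_size = as.numeric(original_size),
                 canvas_size = as.numeric(canvas_size)),
            class = "canvas_transform")
}

#' Load a radiograph from PNG or DICOM
#'
#' @param path file path.
#' @param format `"auto"` (by extension/magic), `"png"`, or `"dicom"`.
#' @return List with `image` (numeric matrix in \[0, 1\], rows = y) and
#'   `pixel_spacing_mm` (from DICOM metadata when available, else `NULL`).
#'   Color PNGs are converted to grayscale by channel averaging; multi-frame
#'   DICOM files are rejected.
#' @export
load_radiograph <- function(path, format = c("auto", "png", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
              else if (grepl("\\.dcm$", path, ignore.case = TRUE)) "dicom"
              else if (is_dicom_file(path)) "dicom" else "png"
  }
  if (format == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) stop("unreadable PNG file: ", conditionMessage(e)))
    if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                                             c(1, 2), mean)
    list(image = img, pixel_spacing_mm = NULL)
  } else {
    d <- read_dicom_image(path)
    list(image = d$image, pixel_spacing_mm = d$pixel_spacing_mm)
  }
}

#' Aspect-preserving resize onto a fixed canvas with zero padding
#'
#' Scales the image by `min(canvas_w / w, canvas_h / h)` (bilinear
#' interpolation) and centers it on a zero-valued canvas, splitting the
#' padding equally on the shorter dimension (extra pixel goes to the
#' right/bottom on odd remainders).
#'
#' @param image numeric matrix (rows = y).
#' @param canvas `(width, height)` of the target canvas; default 1333 x 800.
#' @return List with `image` (exactly canvas-sized) and `transform`
#'   (a `canvas_transform`).
#' @export
resize_pad <- function(image, canvas = c(1333, 800)) {
  if (!is.matrix(image) || any(dim(image) == 0L)) stop("image must be a nonempty matrix")
  h <- nrow(image); w <- ncol(image)
  cw <- canvas[1]; ch <- canvas[2]
  scale <- min(cw / w, ch / h)
  nw <- round(w * scale); nh <- round(h * scale)
  scaled <- if (nw == w && nh == h) image
            else EBImage::resize(image, w = nh, h = nw)  # EBImage dim1 = matrix rows
  pad_x <- floor((cw - nw) / 2); pad_y <- floor((ch - nh) / 2)
  out <- matrix(0, nrow = ch, ncol = cw)
  out[pad_y + seq_len(nh), pad_x + seq_len(nw)] <- scaled
  list(image = out,
       transform = canvas_transform(scale, pad_x, pad_y,
                                    original_size = c(w, h), canvas_size = c(cw, ch)))
}

#' Contrast-limited adaptive histogram equalization
#'
#' CLAHE on a grayscale image. The image is edge-padded to a multiple of the
#' tile grid for the equalizer and cropped back, so any image size is
#' accepted. A constant image is returned unchanged (it has no contrast to
#' amplify). Deterministic for fixed parameters.
#'
#' @param image numeric matrix in \[0, 1\].
#' @param clip_limit contrast clip limit (EBImage convention), default 2.
#' @param tile_grid `(nx, ny)` tile counts, default `c(8, 8)`.
#' @return Equalized matrix of the same shape, range within \[0, 1\].
#' @export
clahe_enhance <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  if (!is.matrix(image)) stop("image must be a 2D matrix")
  rng <- range(image)
  if (diff(rng) < .Machine$double.eps) return(image)
  nx <- tile_grid[1]; ny <- tile_grid[2]
  d <- dim(image)
  px <- (nx - d[1] %% nx) %% nx
  py <- (ny - d[2] %% ny) %% ny
  padded <- image
  if (px > 0) padded <- rbind(padded, padded[d[1] - seq_len(px) + 1, , drop = FALSE])
  if (py > 0) padded <- cbind(padded, padded[, d[2] - seq_len(py) + 1, drop = FALSE])
  eq <- EBImage::clahe(padded, nx = nx, ny = ny, limit = clip_limit, keep.range = TRUE)
  out <- as.matrix(eq)[seq_len(d[1]), seq_len(d[2]), drop = FALSE]
  pmin(pmax(out, 0), 1)
}

#' Map landmark coordinates through a canvas transform
#'
#' @param points length-2 point or n x 2 matrix of (x, y) coordinates.
#' @param transform a `canvas_transform`.
#' @param direction `"to_canvas"` (original to canvas) or `"to_original"`.
#'   Mapping back rejects points that fall in the zero-padded margin, where
#'   no original pixel exists.
#' @return Mapped coordinates in the same shape as the input.
#' @export
map_landmarks <- function(points, transform, direction = c("to_canvas", "to_original")) {
  stopifnot(inherits(transform, "canvas_transform"))
  direction <- match.arg(direction)
  one_row <- !is.matrix(points)
  p <- if (one_row) matrix(as.numeric(points), ncol = 2) else as.matrix(points)
  if (direction == "to_canvas") {
    q <- cbind(p[, 1] * transform$scale + transform$pad_x,
               p[, 2] * transform$scale + transform$pad_y)
  } else {
    nw <- round(transform$original_size[1] * transform$scale)
    nh <- round(transform$original_size[2] * transform$scale)
    tol <- 1e-9
    inside <- p[, 1] >= transform$pad_x - tol & p[, 1] <= transform$pad_x + nw + tol &
              p[, 2] >= transform$pad_y - tol & p[, 2] <= transform$pad_y + nh + tol
    if (!all(inside)) stop("point lies in the padded margin: no original coordinate exists")
    q <- cbind((p[, 1] - transform$pad_x) / transform$scale,
               (p[, 2] - transform$pad_y) / transform$scale)
  }
  if (one_row) c(x = q[1, 1], y = q[1, 2]) else q
}
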
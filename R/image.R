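#' Bilinear image resampling
#'
#' Resamples a 2-D matrix or H x W x C array to new spatial dimensions by
#' bilinear interpolation (half-pixel centre convention, edges clamped).
#' Used both to resize slides to grid-aligned dimensions before tiling and
#' to upsample low-resolution importance maps back to slide scale.
#'
#' @param img numeric matrix or 3-d array (height x width x channels).
#' @param out_h,out_w target dimensions in pixels, both >= 1.
#' @return object of the same rank as `img` with the requested dimensions.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  if (!is.numeric(img)) .duv_invalid("image must be numeric")
  nd <- length(dim(img))
  if (nd == 0L && is.vector(img)) .duv_invalid("image must be a matrix or array")
  if (nd == 2L) return(.resize_bilinear_2d(img, out_h, out_w))
  if (nd != 3L) .duv_invalid("image must have 2 or 3 dimensions")
  out <- array(0, dim = c(out_h, out_w, dim(img)[3]))
  for (k in seq_len(dim(img)[3])) {
    out[, , k] <- .resize_bilinear_2d(img[, , k], out_h, out_w)
  }
  out
}

.resize_bilinear_2d <- function(m, out_h, out_w) {
  if (out_h < 1L || out_w < 1L) .duv_invalid("output dimensions must be >= 1")
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  # source coordinate of each output pixel centre
  sy <- (seq_len(out_h) - 0.5) * (h / out_h) - 0.5
  sx <- (seq_len(out_w) - 0.5) * (w / out_w) - 0.5
  sy <- pmin(pmax(sy, 0), h - 1)
  sx <- pmin(pmax(sx, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(sx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  # separable: interpolate columns first, then rows
  tmp <- m[, x0 + 1, drop = FALSE] * rep(1 - fx, each = h) +
    m[, x1 + 1, drop = FALSE] * rep(fx, each = h)
  tmp[y0 + 1, , drop = FALSE] * (1 - fy) + tmp[y1 + 1, , drop = FALSE] * fy
}

#' Read an RGB slide image
#'
#' Reads a PNG image into the 8-bit H x W x 3 integer array used throughout
#' the package. Grayscale images are expanded to three identical channels;
#' an alpha channel, if present, is dropped.
#'
#' @param path path to a `.png` file.
#' @return integer array of dimension H x W x 3 with values in 0..255.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) .duv_invalid("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext != "png") .duv_invalid("unsupported image format '", ext, "' (PNG only)")
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  array(as.integer(round(x * 255)), dim = dim(x))
}

#' Write an RGB slide image
#'
#' @param pixels integer or numeric H x W x 3 array with values in 0..255.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(pixels, path) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    .duv_invalid("pixels must be an H x W x 3 array")
  png::writePNG(pmin(pmax(pixels / 255, 0), 1), target = path)
  invisible(path)
}

#' Export an importance map with its metadata sidecar
#'
#' Writes the map quantized to 16 bits (high byte in the red channel, low
#' byte in the green channel of an 8-bit PNG, since plain 16-bit grayscale
#' PNG output is unavailable) plus a JSON sidecar recording the target
#' class, layer tag, normalization bounds and the byte-split encoding.
#' [read_importance_map()] inverts the encoding.
#'
#' @param map an importance map as returned by [regional_importance()].
#' @param path output `.png` path; the sidecar is written as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_importance_map <- function(map, path) {
  stopifnot(inherits(map, "duv_importance_map"))
  q <- round(pmin(pmax(map$values, 0), 1) * 65535)
  img <- array(0, dim = c(nrow(q), ncol(q), 3L))
  img[, , 1] <- (q %/% 256) / 255
  img[, , 2] <- (q %% 256) / 255
  png::writePNG(img, target = path)
  meta <- list(
    class_index = map$class_index, layer = map$layer,
    norm_min = map$norm_min, norm_max = map$norm_max,
    all_zero = isTRUE(map$all_zero), method = map$method,
    encoding = "uint16 split: value = (255*R*256 + 255*G) / 65535"
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an importance map written by [write_importance_map()]
#'
#' @param path the `.png` path previously written.
#' @return an object of class `duv_importance_map`.
#' @export
read_importance_map <- function(path) {
  img <- png::readPNG(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  vals <- (round(img[, , 1] * 255) * 256 + round(img[, , 2] * 255)) / 65535
  structure(list(
    values = vals, class_index = meta$class_index, layer = meta$layer,
    norm_min = meta$norm_min, norm_max = meta$norm_max,
    all_zero = isTRUE(meta$all_zero), method = meta$method
  ), class = "duv_importance_map")
}
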
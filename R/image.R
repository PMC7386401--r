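# Image container conventions
#
# Images are numeric arrays dim c(H, W, 3) with intensities in [0, 255].
# Pixel coordinates are 0-based, x to the right (column), y down (row),
# pixel centers at integer coordinates; pixel (x, y) is img[y + 1, x + 1, ].

#' Read an 8-bit RGB PNG image
#'
#' @param path path to a PNG file.
#' @return numeric array `c(H, W, 3)` with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    ps_stop(sprintf("image file not found: %s", path), "io",
            class = "ps_validation_error")
  }
  a <- tryCatch(png::readPNG(path), error = function(e) {
    ps_stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
            "io", class = "ps_validation_error")
  })
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  a[, , 1:3, drop = FALSE] * 255
}

#' Write an RGB image array to PNG
#'
#' @param img numeric array `c(H, W, 3)` in `[0, 255]`.
#' @param path output path.
#' @export
write_image <- function(img, path) {
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

# Mean-of-channels brightness, (R + G + B) / 3, as an H x W matrix.
img_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

# 0-based coordinate grids for an H x W image: list(x = , y = ), each H x W.
pixel_grid <- function(h, w) {
  list(
    x = matrix(rep(seq_len(w) - 1, each = h), h, w),
    y = matrix(rep(seq_len(h) - 1, times = w), h, w)
  )
}

# Bilinear sampling at 0-based (x, y) positions; coordinates are clamped to
# the image. Returns an n x 3 matrix.
bilinear_sample <- function(img, x, y) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x <- clamp(x, 0, w - 1); y <- clamp(y, 0, h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  out <- matrix(0, length(x), 3L)
  for (ch in 1:3) {
    m <- img[, , ch]
    i00 <- m[cbind(y0 + 1, x0 + 1)]; i10 <- m[cbind(y0 + 1, x1 + 1)]
    i01 <- m[cbind(y1 + 1, x0 + 1)]; i11 <- m[cbind(y1 + 1, x1 + 1)]
    out[, ch] <- (1 - fy) * ((1 - fx) * i00 + fx * i10) +
      fy * ((1 - fx) * i01 + fx * i11)
  }
  out
}
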
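# Scale fiducial: a square matrix code of known physical edge length.
#
# A smartphone held at the examinee's forehead displays a machine-readable
# square tag whose physical edge length (mm) is encoded in its payload; the
# ratio of encoded edge length to detected edge length in pixels calibrates
# the frontal-plane scale alpha (mm per pixel). The symbol used here is a
# purpose-built matrix code (a synthetic stand-in for a QR symbol, with the
# same role and payload): a 1-module black border ring, a 1-module white
# margin, and a D x D data grid carrying a CRC-16 protected JSON payload
# {"id": ..., "edge_mm": ...}. Decoding assumes the tag is frontal and
# axis-aligned, consistent with the held-at-forehead protocol.

TAG_QUIET <- 2L  # quiet-zone width in modules

crc16_ccitt <- function(bytes) {
  crc <- 0xFFFFL
  for (b in bytes) {
    crc <- bitwXor(crc, bitwShiftL(as.integer(b), 8L))
    for (i in 1:8) {
      crc <- if (bitwAnd(crc, 0x8000L) != 0L) {
        bitwAnd(bitwXor(bitwShiftL(crc, 1L), 0x1021L), 0xFFFFL)
      } else {
        bitwAnd(bitwShiftL(crc, 1L), 0xFFFFL)
      }
    }
  }
  crc
}

int_to_bits <- function(x, nbits) {
  rev(as.integer(bitwAnd(bitwShiftR(as.integer(x), 0:(nbits - 1L)), 1L)))
}

bits_to_int <- function(bits) {
  sum(bits * 2^rev(seq_along(bits) - 1L))
}

payload_to_bits <- function(json) {
  bytes <- utf8ToInt(json)
  ps_validate(all(bytes < 256), "fiducial payload must be 8-bit text", "fiducial")
  c(int_to_bits(length(bytes), 16L),
    unlist(lapply(bytes, int_to_bits, nbits = 8L), use.names = FALSE),
    int_to_bits(crc16_ccitt(bytes), 16L))
}

# Module matrix (TRUE = black) for a payload: border ring + margin + data.
tag_modules <- function(json) {
  bits <- payload_to_bits(json)
  D <- ceiling(sqrt(length(bits)))
  grid <- matrix(0L, D, D)
  grid[cbind(rep(seq_len(D), each = D), rep(seq_len(D), times = D))[seq_along(bits), , drop = FALSE]] <- bits
  M <- D + 4L
  mod <- matrix(FALSE, M, M)
  mod[1, ] <- TRUE; mod[M, ] <- TRUE; mod[, 1] <- TRUE; mod[, M] <- TRUE
  mod[3:(M - 2L), 3:(M - 2L)] <- grid == 1L
  mod
}

#' Render a scale fiducial of known physical size
#'
#' Draws the square matrix-code tag encoding `{"id", "edge_mm"}` as JSON at
#' `edge_mm * ppmm` pixels on a side (the outer black square), surrounded by
#' a white quiet zone. The true frontal-plane scale of the rendering is
#' `1 / ppmm` mm per pixel.
#'
#' @param id examinee identifier string (may be empty).
#' @param edge_mm physical edge length of the symbol in mm (> 0).
#' @param ppmm rendering scale in pixels per mm (> 0).
#' @return list with `image` (RGB array), `alpha` (true mm/px), `side_px`
#'   (physical edge in pixels), `payload` (the encoded JSON string).
#' @export
render_scale_fiducial <- function(id, edge_mm, ppmm) {
  ps_validate(is.numeric(edge_mm) && length(edge_mm) == 1 && edge_mm > 0,
              "fiducial edge_mm must be a positive number", "fiducial")
  ps_validate(is.numeric(ppmm) && ppmm > 0, "ppmm must be positive", "fiducial")
  json <- as.character(jsonlite::toJSON(
    list(id = as.character(id), edge_mm = edge_mm), auto_unbox = TRUE))
  mod <- tag_modules(json)
  M <- nrow(mod)
  side_px <- edge_mm * ppmm
  mod_px <- side_px / M
  if (mod_px < 2) {
    ps_stop(sprintf(
      "fiducial payload too large: %d modules at %.2f px/module (need >= 2)",
      M, mod_px), "fiducial", class = "ps_validation_error")
  }
  qpx <- TAG_QUIET * mod_px
  size <- as.integer(ceiling(side_px + 2 * qpx))
  g <- pixel_grid(size, size)
  i <- floor((g$y - qpx) / mod_px)
  j <- floor((g$x - qpx) / mod_px)
  black <- i >= 0 & i < M & j >= 0 & j < M
  black[black] <- mod[cbind(i[black] + 1L, j[black] + 1L)]
  img <- array(255, dim = c(size, size, 3L))
  for (ch in 1:3) img[, , ch][black] <- 0
  list(image = img, alpha = 1 / ppmm, side_px = side_px, payload = json)
}

# Attempt to decode one candidate component as a tag. Returns NULL on
# failure, else list(payload_chr, parsed).
decode_tag_candidate <- function(gray, xmin, xmax, ymin, ymax) {
  wpx <- xmax - xmin + 1; hpx <- ymax - ymin + 1
  if (abs(wpx - hpx) > max(3, 0.04 * wpx)) return(NULL)
  side <- (wpx + hpx) / 2
  # The module count is not encoded; scan all counts that leave >= 2 px per
  # module. The CRC check rejects every wrong reading.
  for (M in 7:floor(side / 2)) {
    mpx <- side / M
    D <- M - 4L
    ii <- rep(seq_len(D) - 1L, each = D)
    jj <- rep(seq_len(D) - 1L, times = D)
    cx <- round(xmin + (jj + 2L + 0.5) * mpx)
    cy <- round(ymin + (ii + 2L + 0.5) * mpx)
    ok <- cx >= 0 & cx < ncol(gray) & cy >= 0 & cy < nrow(gray)
    if (!all(ok)) next
    bits <- as.integer(gray[cbind(cy + 1L, cx + 1L)] < 128)
    if (length(bits) < 40L) next
    nbytes <- bits_to_int(bits[1:16])
    if (nbytes < 1 || 16 + 8 * nbytes + 16 > length(bits)) next
    byte_bits <- matrix(bits[17:(16 + 8 * nbytes)], nrow = 8L)
    bytes <- apply(byte_bits, 2, bits_to_int)
    crc <- bits_to_int(bits[(16 + 8 * nbytes + 1):(16 + 8 * nbytes + 16)])
    if (crc != crc16_ccitt(bytes)) next
    payload <- intToUtf8(bytes)
    parsed <- tryCatch(jsonlite::fromJSON(payload), error = function(e) NULL)
    if (is.null(parsed)) next
    return(list(payload = payload, parsed = parsed))
  }
  NULL
}

#' Decode the scale fiducial and calibrate the frontal-plane scale
#'
#' Locates the single matrix-code symbol in the image, decodes its JSON
#' payload, and derives the scale `alpha = edge_mm / side length in px`,
#' where the pixel side length is the mean of the four side lengths of the
#' symbol's corner quadrilateral.
#'
#' @param image RGB array (full frame or a region containing the tag).
#' @return object of class `scale_calibration`: `alpha` (mm/px), `id`,
#'   `edge_mm`, `corners` (4 x 2 matrix, 0-based pixel coords), `side_px`.
#' @export
decode_scale <- function(image) {
  gray <- img_gray(image)
  mask <- gray < 128
  lab <- cpp_label_components(mask, 4L)
  nlab <- max(lab)
  if (nlab == 0) ps_stop("no fiducial symbol found", "scale",
                         class = "ps_detection_error")
  sizes <- tabulate(lab[lab > 0], nbins = nlab)
  hits <- list()
  for (k in which(sizes >= 64)) {
    idx <- which(lab == k, arr.ind = TRUE)
    xmin <- min(idx[, 2]) - 1L; xmax <- max(idx[, 2]) - 1L
    ymin <- min(idx[, 1]) - 1L; ymax <- max(idx[, 1]) - 1L
    dec <- decode_tag_candidate(gray, xmin, xmax, ymin, ymax)
    if (!is.null(dec)) {
      dec$bbox <- c(xmin, xmax, ymin, ymax)
      hits[[length(hits) + 1L]] <- dec
    }
  }
  if (length(hits) == 0) {
    ps_stop("no decodable fiducial symbol found", "scale",
            class = "ps_detection_error")
  }
  if (length(hits) > 1) {
    ps_stop(sprintf("multiple (%d) fiducial symbols found", length(hits)),
            "scale", class = "ps_detection_error")
  }
  hit <- hits[[1]]
  if (is.null(hit$parsed$edge_mm) || !is.numeric(hit$parsed$edge_mm)) {
    ps_stop("fiducial payload missing edge_mm", "scale",
            class = "ps_validation_error")
  }
  bb <- hit$bbox
  corners <- rbind(c(bb[1], bb[3]), c(bb[2], bb[3]), c(bb[2], bb[4]),
                   c(bb[1], bb[4]))
  w <- bb[2] - bb[1] + 1; h <- bb[4] - bb[3] + 1
  side <- mean(c(w, h, w, h))
  structure(
    list(alpha = hit$parsed$edge_mm / side,
         id = as.character(hit$parsed$id %||% ""),
         edge_mm = hit$parsed$edge_mm, corners = corners, side_px = side,
         payload = hit$payload),
    class = "scale_calibration"
  )
}
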
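# Landmark ingestion, closed-eye rejection, head-tilt correction and per-eye
# patch extraction.
#
# Landmark JSON schema (one record per image):
# {
#   "image_size": [W, H],
#   "head_tilt_deg": <number>,
#   "source": "external-detector" | "synthetic-truth",
#   "eyes": {
#     "left":  {"inner_corner": [x, y], "outer_corner": [x, y],
#               "upper_lid": [[x, y], ...], "lower_lid": [[x, y], ...]},
#     "right": {...}
#   }
# }
# "left"/"right" are anatomical (the examinee's left eye sits in the image's
# right half of a frontal photo). Coordinates are 0-based pixels, x right,
# y down. Each lid needs at least 3 contour points.

#' Write a facial-landmark record to JSON
#' @param landmarks a `face_landmarks` object.
#' @param path output path.
#' @export
write_landmarks <- function(landmarks, path) {
  to_xy <- function(p) as.numeric(p)
  out <- list(
    image_size = as.integer(landmarks$image_size),
    head_tilt_deg = landmarks$head_tilt_deg,
    source = landmarks$source,
    eyes = lapply(landmarks$eyes, function(e) list(
      inner_corner = to_xy(e$inner_corner),
      outer_corner = to_xy(e$outer_corner),
      upper_lid = unname(apply(e$upper_lid, 1, to_xy, simplify = FALSE)),
      lower_lid = unname(apply(e$lower_lid, 1, to_xy, simplify = FALSE))
    ))
  )
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10)),
             path)
  invisible(path)
}

#' Load and validate a facial-landmark record
#'
#' @param record path to a landmark JSON file, or an already-parsed list
#'   following the documented schema.
#' @return object of class `face_landmarks`.
#' @export
load_landmarks <- function(record) {
  if (is.character(record)) {
    if (!file.exists(record)) {
      ps_stop(sprintf("landmark record not found: %s", record), "landmarks",
              class = "ps_validation_error")
    }
    record <- tryCatch(jsonlite::fromJSON(record, simplifyVector = TRUE),
                       error = function(e) {
      ps_stop(sprintf("malformed landmark JSON: %s", conditionMessage(e)),
              "landmarks", class = "ps_validation_error")
    })
  }
  fail <- function(msg) ps_stop(paste0("landmark record: ", msg), "landmarks",
                                class = "ps_validation_error")
  if (is.null(record$image_size) || length(record$image_size) != 2) {
    fail("missing image_size")
  }
  W <- record$image_size[1]; H <- record$image_size[2]
  if (is.null(record$head_tilt_deg) || !is.finite(record$head_tilt_deg)) {
    fail("missing head_tilt_deg")
  }
  as_pts <- function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.numeric))
    matrix(as.numeric(x), ncol = 2)
  }
  eyes <- list()
  for (e in EYE_NAMES) {
    ey <- record$eyes[[e]]
    if (is.null(ey)) fail(sprintf("missing %s eye", e))
    for (f in c("inner_corner", "outer_corner", "upper_lid", "lower_lid")) {
      if (is.null(ey[[f]])) fail(sprintf("%s eye: missing %s", e, f))
    }
    ic <- as.numeric(ey$inner_corner); oc <- as.numeric(ey$outer_corner)
    ul <- as_pts(ey$upper_lid); ll <- as_pts(ey$lower_lid)
    if (nrow(ul) < 3 || nrow(ll) < 3) {
      fail(sprintf("%s eye: each lid needs >= 3 contour points", e))
    }
    if (sqrt(sum((ic - oc)^2)) <= 0) fail(sprintf("%s eye: corner distance is 0", e))
    all_pts <- rbind(ic, oc, ul, ll)
    if (any(all_pts[, 1] < 0 | all_pts[, 1] > W - 1 |
            all_pts[, 2] < 0 | all_pts[, 2] > H - 1)) {
      fail(sprintf("%s eye: landmark outside image bounds", e))
    }
    eyes[[e]] <- list(inner_corner = ic, outer_corner = oc,
                      upper_lid = ul, lower_lid = ll)
  }
  structure(list(image_size = c(W, H),
                 head_tilt_deg = record$head_tilt_deg,
                 source = record$source %||% "external-detector",
                 eyes = eyes),
            class = "face_landmarks")
}

#' Eye openness ratio and closed-eye flag
#'
#' The height-to-width ratio of the eye opening: the maximum gap between the
#' upper and lower eyelid contours, measured perpendicular to the
#' corner-to-corner axis (so the ratio is invariant to head tilt and to
#' uniform scaling), divided by the corner distance. An eye is flagged
#' closed when the ratio falls strictly below `eta` ("below the threshold",
#' so a ratio of exactly `eta` passes).
#'
#' @param eye one entry of `face_landmarks$eyes`.
#' @param eta closed-eye threshold (default 0.25).
#' @return list with `ratio` and `closed`.
#' @export
eye_openness <- function(eye, eta = 0.25) {
  u <- eye$outer_corner - eye$inner_corner
  cd <- sqrt(sum(u^2))
  if (cd == 0) ps_stop("eye corner distance is zero", "openness",
                       class = "ps_validation_error")
  dirv <- u / cd
  nrm <- c(-dirv[2], dirv[1])
  if (nrm[2] < 0) nrm <- -nrm           # normal pointing image-down
  up <- as.vector(eye$upper_lid %*% nrm)
  lo <- as.vector(eye$lower_lid %*% nrm)
  gap <- max(lo) - min(up)
  list(ratio = max(gap, 0) / cd, closed = max(gap, 0) / cd < eta)
}

#' Extract tilt-corrected per-eye patches
#'
#' Rejects closed eyes, rotates the image by minus the head tilt about the
#' midpoint between the two eye-corner centroids (bilinear interpolation;
#' zero tilt is an exact crop), and cuts one axis-aligned patch per eye
#' covering the landmark bounding box padded by `pad_frac` of the corner
#' distance on each side. The coordinate mapping between patch and original
#' image is recorded and invertible via [patch_to_image()].
#'
#' @param image RGB image array.
#' @param landmarks a [load_landmarks()] record for that image.
#' @param pad_frac padding per side as a fraction of the corner distance.
#' @param eta closed-eye threshold.
#' @return list with elements `left` and `right`, each an `eye_patch`:
#'   `img`, `origin` (patch origin in tilt-corrected coordinates),
#'   `rotation_deg` (the tilt that was corrected), `pivot`, `eye`,
#'   `corner_distance`, `openness`.
#' @export
extract_eye_patches <- function(image, landmarks, pad_frac = 0.25, eta = 0.25) {
  open_info <- lapply(landmarks$eyes, eye_openness, eta = eta)
  for (e in EYE_NAMES) {
    if (open_info[[e]]$closed) {
      ps_stop(sprintf("%s eye closed (openness ratio %.3f < %.2f)",
                      e, open_info[[e]]$ratio, eta),
              "openness", class = "ps_closed_eye_error",
              data = list(eye = e, ratio = open_info[[e]]$ratio))
    }
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  tilt <- landmarks$head_tilt_deg
  corner_centroid <- function(e) {
    (landmarks$eyes[[e]]$inner_corner + landmarks$eyes[[e]]$outer_corner) / 2
  }
  pivot <- (corner_centroid("left") + corner_centroid("right")) / 2

  out <- list()
  for (e in EYE_NAMES) {
    ey <- landmarks$eyes[[e]]
    cd <- sqrt(sum((ey$inner_corner - ey$outer_corner)^2))
    pts <- rbind(ey$inner_corner, ey$outer_corner, ey$upper_lid, ey$lower_lid)
    cpts <- rotate_points(pts, -tilt, pivot)
    pad <- pad_frac * cd
    x0 <- floor(min(cpts[, 1]) - pad); x1 <- ceiling(max(cpts[, 1]) + pad)
    y0 <- floor(min(cpts[, 2]) - pad); y1 <- ceiling(max(cpts[, 2]) + pad)
    pw <- x1 - x0 + 1; ph <- y1 - y0 + 1

    if (tilt == 0) {
      if (x0 < 0 || y0 < 0 || x1 > W - 1 || y1 > H - 1) {
        ps_stop(sprintf("%s eye patch clipped by the image border", e),
                "patch", class = "ps_validation_error")
      }
      patch <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), , drop = FALSE]
    } else {
      g <- pixel_grid(ph, pw)
      src <- rotate_points(cbind(as.vector(g$x) + x0, as.vector(g$y) + y0),
                           tilt, pivot)
      if (any(src[, 1] < 0 | src[, 1] > W - 1 | src[, 2] < 0 | src[, 2] > H - 1)) {
        ps_stop(sprintf("%s eye patch clipped by the image border", e),
                "patch", class = "ps_validation_error")
      }
      vals <- bilinear_sample(image, src[, 1], src[, 2])
      patch <- array(0, dim = c(ph, pw, 3L))
      for (ch in 1:3) patch[, , ch] <- matrix(vals[, ch], ph, pw)
    }
    out[[e]] <- structure(
      list(img = patch, origin = c(x0, y0), rotation_deg = tilt,
           pivot = pivot, eye = e, corner_distance = cd,
           openness = open_info[[e]]$ratio),
      class = "eye_patch"
    )
  }
  out
}

#' Map patch coordinates back to original-image coordinates
#'
#' @param patch an `eye_patch`.
#' @param xy length-2 vector or n x 2 matrix of 0-based patch coordinates.
#' @return coordinates in the original (uncorrected) image.
#' @export
patch_to_image <- function(patch, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  corrected <- sweep(xy, 2, patch$origin, "+")
  out <- rotate_points(corrected, patch$rotation_deg, patch$pivot)
  if (nrow(out) == 1) as.vector(out) else out
}

#' Map patch coordinates to the tilt-corrected image frame
#'
#' @inheritParams patch_to_image
#' @export
patch_to_corrected <- function(patch, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  out <- sweep(xy, 2, patch$origin, "+")
  if (nrow(out) == 1) as.vector(out) else out
}
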
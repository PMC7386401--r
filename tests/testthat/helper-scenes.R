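# Shared synthetic scenes and a cached full segmentation run, so expensive
# renders happen once per test session.

.scene_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.scene_cache[[key]])) .scene_cache[[key]] <- builder()
  .scene_cache[[key]]
}

default_exam <- function() {
  cached("default", function() {
    spec <- eye_scene_spec(clr_offset_left = c(12, -4),
                           clr_offset_right = c(-6, 3),
                           crescent_mm_left = 1.5,
                           tilt_deg = 6, occlusion_deg = 20)
    c(list(spec = spec), render_exam(spec))
  })
}

# Truth limbus center of one eye in the tilt-corrected patch frame.
truth_center_in_patch <- function(spec, patch, eye) {
  rotate_points(matrix(spec$eyes[[eye]]$center, 1), -spec$tilt_deg,
                patch$pivot)[1, ] - patch$origin
}

# Full Hirschberg + red-reflex segmentation of one eye of a rendered exam.
segment_eye <- function(spec, ex, eye, scale = NULL) {
  key <- paste0("seg-", spec$seed, "-", eye, "-", substr(digest_num(spec), 1, 8))
  ph <- extract_eye_patches(ex$hirschberg, ex$landmarks)[[eye]]
  pr <- extract_eye_patches(ex$redreflex, ex$landmarks)[[eye]]
  if (is.null(scale)) scale <- decode_scale(ex$hirschberg)
  mask <- build_roi_mask(ph)
  lim <- detect_limbus_hirschberg(ph, mask)
  clr <- detect_clr(ph, lim)
  limr <- refine_limbus_photorefraction(pr, lim)
  cres <- detect_crescent(pr, limr, clr, scale, spec$flash_side)
  list(patch_h = ph, patch_r = pr, scale = scale, mask = mask,
       limbus = lim, clr = clr, limbus_refined = limr, crescent = cres)
}

digest_num <- function(x) paste(unlist(x$eyes$left), collapse = "")

# Flat single-eye patch (no tilt machinery) for operator-level tests: a
# bare RGB array wrapped as an eye_patch with a given corner distance.
flat_patch <- function(img, corner_distance = 150) {
  structure(list(img = img, origin = c(0, 0), rotation_deg = 0,
                 pivot = c(0, 0), eye = "left",
                 corner_distance = corner_distance, openness = 1),
            class = "eye_patch")
}

# Simple rendered single eye on skin, centered in a small patch.
simple_eye_patch <- function(w = 220, h = 180, cx = 110, cy = 90, rl = 55,
                             rp = 30, spot = c(0, 0), skin = c(184, 134, 100),
                             sclera = c(245, 242, 238), iris = c(40, 52, 70)) {
  img <- array(0, dim = c(h, w, 3))
  g <- photoscreen:::pixel_grid(h, w)
  dist <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  cov <- function(r, d) pmin(pmax(0.5 + (r - d), 0), 1)
  for (ch in 1:3) img[, , ch] <- skin[ch]
  for (lay in list(list(r = 1.45 * rl, col = sclera),
                   list(r = rl, col = iris),
                   list(r = rp, col = c(25, 22, 20)))) {
    a <- cov(lay$r, dist)
    for (ch in 1:3) img[, , ch] <- a * lay$col[ch] + (1 - a) * img[, , ch]
  }
  ds <- sqrt((g$x - cx - spot[1])^2 + (g$y - cy - spot[2])^2)
  a <- cov(0.08 * rl, ds)
  for (ch in 1:3) img[, , ch] <- a * 255 + (1 - a) * img[, , ch]
  flat_patch(img, corner_distance = 2.8 * rl)
}

rotate_points <- photoscreen:::rotate_points
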
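# Image operators: ROI masking, limbus detection, corneal reflection spot,
# crescent extraction.

test_that("ROI mask isolates the eye from skin and is idempotent", {
  p <- simple_eye_patch()
  mask <- build_roi_mask(p)
  g <- photoscreen:::pixel_grid(dim(p$img)[1], dim(p$img)[2])
  dist <- sqrt((g$x - 110)^2 + (g$y - 90)^2)
  # covers sclera+iris disk...
  expect_gt(mean(mask[dist < 1.3 * 55]), 0.99)
  # ...and excludes nearly all rendered skin
  expect_lt(mean(mask[dist > 1.6 * 55]), 0.01)

  # idempotence under explicit stats: masking a masked patch changes nothing
  stats <- attr(mask, "skin_stats")
  p2 <- p
  for (ch in 1:3) {
    m <- p2$img[, , ch]
    m[!mask] <- c(184, 134, 100)[ch]
    p2$img[, , ch] <- m
  }
  mask2 <- build_roi_mask(p2, stats = stats)
  expect_identical(unname(mask2), unname(mask))

  # an all-skin patch has no region of interest
  skin_only <- p
  for (ch in 1:3) skin_only$img[, , ch] <- c(184, 134, 100)[ch]
  expect_error(build_roi_mask(skin_only, stats = stats),
               class = "ps_detection_error")
})

test_that("arc-restricted Hough recovers the limbus on a clean eye", {
  p <- simple_eye_patch(w = 280, h = 240, cx = 142.3, cy = 118.6, rl = 60)
  mask <- build_roi_mask(p)
  lim <- detect_limbus_hirschberg(p, mask)
  expect_lt(sqrt(sum((lim$center - c(142.3, 118.6))^2)), 1)
  expect_lt(abs(lim$radius - 60) / 60, 0.02)
})

test_that("occluded arcs carry no votes: recovery unharmed by eyelids", {
  spec_open <- eye_scene_spec(occlusion_deg = 0, tilt_deg = 0)
  spec_occl <- eye_scene_spec(occlusion_deg = 40, tilt_deg = 0)
  for (spec in list(spec_open, spec_occl)) {
    ex <- render_exam(spec)
    p <- extract_eye_patches(ex$hirschberg, ex$landmarks)
    for (e in c("left", "right")) {
      mask <- build_roi_mask(p[[e]])
      lim <- detect_limbus_hirschberg(p[[e]], mask)
      tc <- truth_center_in_patch(spec, p[[e]], e)
      expect_lt(sqrt(sum((lim$center - tc)^2)), 1)
      expect_lt(abs(lim$radius - spec$eyes[[e]]$limbus_r) / spec$eyes[[e]]$limbus_r,
                0.02)
    }
  }
})

test_that("blank or featureless patches yield detection-failed errors", {
  blank <- flat_patch(array(120, dim = c(80, 80, 3)))
  full_mask <- matrix(TRUE, 80, 80)
  expect_error(detect_limbus_hirschberg(blank, full_mask),
               class = "ps_detection_error")
  expect_error(detect_limbus_hirschberg(blank, matrix(FALSE, 80, 80)),
               class = "ps_detection_error")
})

test_that("limbus and spot detection are translation equivariant", {
  base <- simple_eye_patch(w = 260, h = 220, cx = 100, cy = 90, spot = c(10, -6))
  run <- function(p) {
    mask <- build_roi_mask(p)
    lim <- detect_limbus_hirschberg(p, mask)
    clr <- detect_clr(p, lim)
    list(lim = lim$center, clr = clr$center, r = lim$radius)
  }
  r0 <- run(base)
  for (shift in list(c(17, 9), c(-5, 12))) {
    h <- dim(base$img)[1]; w <- dim(base$img)[2]
    sy <- shift[2]; sx <- shift[1]
    src_y <- (1 - min(sy, 0)):(h - max(sy, 0))
    src_x <- (1 - min(sx, 0)):(w - max(sx, 0))
    img <- base$img * 0
    for (ch in 1:3) img[, , ch] <- c(184, 134, 100)[ch]
    img[src_y + sy, src_x + sx, ] <- base$img[src_y, src_x, ]
    r1 <- run(flat_patch(img, corner_distance = base$corner_distance))
    expect_equal(r1$lim, r0$lim + shift, tolerance = 1e-6)
    expect_equal(r1$clr, r0$clr + shift, tolerance = 1e-6)
    expect_equal(r1$r, r0$r, tolerance = 1e-6)
  }
})

test_that("photorefraction refinement maximizes the true-circle contrast", {
  ex <- default_exam()
  spec <- ex$spec
  pr <- extract_eye_patches(ex$redreflex, ex$landmarks)$left
  ph <- extract_eye_patches(ex$hirschberg, ex$landmarks)$left
  mask <- build_roi_mask(ph)
  lim <- detect_limbus_hirschberg(ph, mask)
  # shift the prior center by 3 px: refinement must come back within 1 px
  prior <- lim
  prior$center <- lim$center + c(3, -3)
  ref <- refine_limbus_photorefraction(pr, prior)
  tc <- truth_center_in_patch(spec, pr, "left")
  expect_lt(sqrt(sum((ref$center - tc)^2)), 1)
  expect_gt(ref$score, 0)

  # the C++ contrast map agrees with a direct R computation
  gray <- photoscreen:::img_gray(pr$img)
  cx <- round(tc[1]); cy <- round(tc[2])
  cm <- photoscreen:::cpp_contrast_map(gray, cx, cy, lim$radius, 2L)
  expect_equal(cm[3, 3], bf_contrast(gray, cx, cy, lim$radius), tolerance = 1e-9)
  # contrast at the true center beats centers >= 5 px away (exhaustive scan)
  cm_wide <- photoscreen:::cpp_contrast_map(gray, cx, cy, lim$radius, 9L)
  g <- photoscreen:::pixel_grid(19, 19)
  far <- sqrt((g$x - 9)^2 + (g$y - 9)^2) >= 5
  expect_gt(cm_wide[10, 10], max(cm_wide[far], na.rm = TRUE))

  # a uniform patch has no contour contrast anywhere
  flat <- flat_patch(array(90, dim = c(120, 120, 3)))
  expect_error(refine_limbus_photorefraction(flat, lim),
               class = "ps_detection_error")
})

test_that("corneal reflection spot recovers its rendered offset", {
  for (off in list(c(0, 0), c(12, -4), c(-15, 8))) {
    p <- simple_eye_patch(spot = off)
    mask <- build_roi_mask(p)
    lim <- detect_limbus_hirschberg(p, mask)
    clr <- detect_clr(p, lim)
    expect_lt(max(abs(clr$center - lim$center - off)), 1)
    expect_true(all(photoscreen:::ellipse_contains(
      list(A = diag(2) / lim$radius^2, center = lim$center),
      matrix(clr$center, 1))))
  }
})

test_that("spot component selection prefers size then topmost-leftmost", {
  img <- array(20, dim = c(60, 60, 3))
  paint <- function(img, ys, xs) { img[ys, xs, ] <- 255; img }
  # larger cluster wins
  img1 <- paint(paint(img, 20:24, 20:24), 40:41, 40:41)
  p <- flat_patch(img1)
  lim <- structure(list(center = c(30, 30), radius = 28, score = 1,
                        source = "hirschberg"), class = "limbus_circle")
  clr <- detect_clr(p, lim)
  expect_equal(clr$center, c(21, 21), tolerance = 1e-9)
  # equal sizes: topmost (then leftmost) centroid wins
  img2 <- paint(paint(img, 40:42, 14:16), 14:16, 40:42)
  clr2 <- detect_clr(flat_patch(img2), lim)
  expect_equal(clr2$center, c(40, 14), tolerance = 1e-9)  # (x, y): top cluster
  # dark disk: no flash reflection
  expect_error(detect_clr(flat_patch(img), lim), class = "ps_detection_error")
})

test_that("crescent width, side and ellipse match the rendered truth", {
  scale <- list(alpha = 0.1)
  spec <- eye_scene_spec(crescent_mm_left = 1.5, crescent_mm_right = 0,
                         tilt_deg = 0, occlusion_deg = 10)
  ex <- render_exam(spec)
  seg <- segment_eye(spec, ex, "left")
  expect_lt(abs(seg$crescent$width_mm - 1.5), 0.1)
  expect_equal(seg$crescent$side, "toward_flash")
  expect_false(seg$crescent$full_pupil)
  # all crescent pixels inside the circumscribed oval
  expect_true(all(photoscreen:::ellipse_contains(seg$crescent$ellipse,
                                                 seg$crescent$pixels)))
  # right eye rendered without a crescent: empty result
  segR <- segment_eye(spec, ex, "right")
  expect_equal(segR$crescent$width_mm, 0)
  expect_equal(segR$crescent$side, "none")
  expect_equal(segR$crescent$n, 0)
})

test_that("away-from-flash crescents are lateralized correctly", {
  spec <- eye_scene_spec(crescent_mm_left = 1.8,
                         crescent_side_left = "away_from_flash",
                         tilt_deg = 0)
  ex <- render_exam(spec)
  seg <- segment_eye(spec, ex, "left")
  expect_equal(seg$crescent$side, "away_from_flash")
})

test_that("measured crescent width is monotone in the rendered width", {
  widths <- seq(0, 3, by = 0.5)
  got <- vapply(widths, function(w) {
    spec <- eye_scene_spec(crescent_mm_left = w, pupil_frac = 0.8,
                           tilt_deg = 0, occlusion_deg = 5)
    ex <- render_exam(spec)
    segment_eye(spec, ex, "left")$crescent$width_mm
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  expect_equal(got[1], 0)
})

test_that("a fully lit pupil is flagged and reported as the limbus width", {
  # dilated pupil nearly filling the limbus, crescent covering it entirely
  spec <- eye_scene_spec(pupil_frac = 0.9, crescent_mm_left = 10.5,
                         tilt_deg = 0, occlusion_deg = 0)
  ex <- render_exam(spec)
  seg <- segment_eye(spec, ex, "left")
  expect_true(seg$crescent$full_pupil)
  expect_equal(seg$crescent$width_mm, 2 * spec$eyes$left$limbus_r * 0.1,
               tolerance = 0.02)  # relative tolerance ~2%: alpha and radius errors
  # the synthetic truth applies the same rule
  expect_true(ex$truth$crescents$left$full_pupil)
})
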
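# Synthetic scene generator: validation, identity cases, ground truth
# self-consistency, cohort properties.

test_that("scene specifications validate their invariants by field", {
  expect_error(eye_scene_spec(pupil_frac = 1.2), "pupil",
               class = "ps_validation_error")
  expect_error(eye_scene_spec(occlusion_deg = 95), "occlusion",
               class = "ps_validation_error")
  expect_error(eye_scene_spec(crescent_mm_left = -0.5), "crescent",
               class = "ps_validation_error")
  expect_error(eye_scene_spec(crescent_mm_left = 8), "pupil radius",
               class = "ps_validation_error")
  expect_error(eye_scene_spec(clr_offset_left = c(70, 0)), "CLR offset",
               class = "ps_validation_error")
})

test_that("a centered spot renders at the limbus center", {
  spec <- eye_scene_spec(clr_offset_left = c(0, 0), tilt_deg = 0,
                         noise_sd = 0)
  ex <- render_exam(spec)
  seg <- segment_eye(spec, ex, "left")
  expect_lt(sqrt(sum((seg$clr$center - truth_center_in_patch(spec, seg$patch_h,
                                                             "left"))^2)),
            0.5)
})

test_that("zero-width crescents leave no crescent pixels in the pupil", {
  spec <- eye_scene_spec(crescent_mm_left = 0, crescent_mm_right = 0,
                         tilt_deg = 0)
  ex <- render_exam(spec)
  for (e in c("left", "right")) {
    seg <- segment_eye(spec, ex, e)
    expect_equal(seg$crescent$n, 0)
    expect_equal(seg$crescent$width_mm, 0)
  }
})

test_that("ground-truth angles equal the closed form", {
  spec <- eye_scene_spec(clr_offset_left = c(10, 0), ppmm = 10)
  tr <- photoscreen:::scene_truth(spec)
  expect_equal(tr$gaze$theta_h_left, atan(2 * 0.1 * 10 / 20) * 180 / pi,
               tolerance = 1e-12)
  expect_equal(tr$gaze$theta_h_left, 5.7106, tolerance = 1e-4)
  # self-consistency with the screening module on arbitrary offsets
  spec2 <- eye_scene_spec(clr_offset_left = c(23, -11),
                          clr_offset_right = c(-7, 4))
  tr2 <- photoscreen:::scene_truth(spec2)
  ref <- binocular_deviation(tr2$offsets, tr2$alpha, 20)
  expect_identical(unclass(tr2$gaze), unclass(ref))
})

test_that("truth labels are the classifier applied to the noise-free truth", {
  set.seed(31)
  for (i in 1:20) {
    th <- runif(1, 0, 18)
    w <- runif(2, 0, 2.2)
    spec <- eye_scene_spec(
      clr_offset_left = c(100 * tan(photoscreen:::deg2rad(th)), 0),
      crescent_mm_left = w[1], crescent_mm_right = w[2])
    tr <- photoscreen:::scene_truth(spec)
    flags <- classify(tr$gaze, tr$crescents$left, tr$crescents$right,
                      screening_config(flash_side = spec$flash_side))
    expect_identical(tr$labels$strabismus, flags$strabismus)
    expect_identical(tr$labels$myopia_left, flags$myopia_left)
    expect_identical(tr$labels$myopia_right, flags$myopia_right)
    expect_identical(tr$labels$anisometropia, flags$anisometropia)
  }
})

test_that("rendering is deterministic for a fixed seed", {
  spec <- eye_scene_spec(noise_sd = 8, seed = 99)
  a <- render_exam(spec); b <- render_exam(spec)
  expect_identical(a$hirschberg, b$hirschberg)
  expect_identical(a$redreflex, b$redreflex)
  spec2 <- eye_scene_spec(noise_sd = 8, seed = 100)
  expect_false(identical(render_exam(spec2)$hirschberg, a$hirschberg))
})

test_that("the two frames share geometry but differ in pupil state", {
  spec <- eye_scene_spec(crescent_mm_left = 1.5, tilt_deg = 0)
  ex <- render_exam(spec)
  ph <- extract_eye_patches(ex$hirschberg, ex$landmarks)$left
  pr <- extract_eye_patches(ex$redreflex, ex$landmarks)$left
  expect_identical(ph$origin, pr$origin)
  mask <- build_roi_mask(ph)
  lim_h <- detect_limbus_hirschberg(ph, mask)
  lim_r <- refine_limbus_photorefraction(pr, lim_h)
  expect_lt(sqrt(sum((lim_h$center - lim_r$center)^2)), 1)
  # red reflex content appears only in the maximally exposed frame
  red_px <- function(img) sum(img[, , 1] > 200 & img[, , 2] < 140)
  expect_gt(red_px(ex$redreflex), 0)
  expect_equal(red_px(ex$hirschberg), 0)
})

test_that("cohort generation is reproducible and respects prevalences", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cs <- cohort_spec(6, seed = 5)
  m1 <- generate_cohort(cs, dir1)
  m2 <- generate_cohort(cs, dir2)
  expect_identical(readLines(m1), readLines(m2))
  # per-case artifacts byte-identical too
  f1 <- attr(m1, "manifest")
  for (col in c("hirschberg_path", "truth_path")) {
    for (f in unlist(strsplit(f1[[col]], ";"))) {
      expect_identical(readBin(file.path(dir1, f), "raw", 1e6),
                       readBin(file.path(dir2, f), "raw", 1e6))
    }
  }
  expect_error(cohort_spec(0), class = "ps_validation_error")
  expect_error(cohort_spec(5, prevalence = c(strabismus = 1.2, myopia = 0,
                                             anisometropia = 0)),
               class = "ps_validation_error")
})

test_that("zero prevalence yields an all-negative cohort", {
  dirn <- tempfile()
  cs <- cohort_spec(8, prevalence = c(strabismus = 0, myopia = 0,
                                      anisometropia = 0), seed = 2)
  mp <- generate_cohort(cs, dirn)
  man <- attr(mp, "manifest")
  for (i in seq_len(nrow(man))) {
    tr <- photoscreen:::read_truth(file.path(dirn, man$truth_path[i]))
    expect_false(any(unlist(tr$labels)))
  }
})

test_that("realized strabismus counts track the prevalence binomially", {
  dirn <- tempfile()
  cs <- cohort_spec(60, prevalence = c(strabismus = 0.2, myopia = 0,
                                       anisometropia = 0), seed = 11)
  mp <- generate_cohort(cs, dirn)
  man <- attr(mp, "manifest")
  n_pos <- sum(vapply(seq_len(nrow(man)), function(i) {
    isTRUE(photoscreen:::read_truth(file.path(dirn, man$truth_path[i]))$labels$strabismus)
  }, logical(1)))
  # expectation 12; allow ~3 binomial standard deviations (sd ~ 3.1)
  expect_true(abs(n_pos - 12) <= 10)
})
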
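# Optics closed forms, classification rules and evaluation metrics.

test_that("axial deviation matches the closed form and its symmetries", {
  # independent evaluation of atan via acos
  atan_indep <- function(x) sign(x) * acos(1 / sqrt(1 + x^2)) * 180 / pi
  expect_equal(axial_deviation(0, 0.1), 0)
  expect_equal(axial_deviation(10, 0.1, 20), 5.7105931375, tolerance = 1e-9)
  set.seed(1)
  deltas <- runif(50, -60, 60)
  expect_equal(axial_deviation(deltas, 0.1, 20),
               atan_indep(2 * 0.1 * deltas / 20), tolerance = 1e-12)
  expect_equal(axial_deviation(-deltas, 0.1, 20),
               -axial_deviation(deltas, 0.1, 20))
  # monotone increasing
  expect_true(all(diff(axial_deviation(sort(deltas), 0.1, 20)) > 0))
  expect_error(axial_deviation(1, -0.1), class = "ps_validation_error")
  expect_error(axial_deviation(Inf, 0.1), class = "ps_validation_error")
})

test_that("small-angle limit of the deviation formula holds", {
  alpha <- 0.1; d <- 20
  deltas <- seq(0.01, 9.9, length.out = 40)   # 2*alpha*delta/d < 0.1
  lin <- (180 / pi) * 2 * alpha * deltas / d
  rel <- abs(axial_deviation(deltas, alpha, d) - lin) / lin
  expect_true(all(rel < 0.01))
})

test_that("binocular deviation combines eyes antisymmetrically", {
  off <- eye_offsets(15, 2, -15, 2)
  g <- binocular_deviation(off, 0.1, 20)
  expect_equal(g$theta_h, 2 * atan(0.15) * 180 / pi, tolerance = 1e-9)
  expect_equal(g$theta_v, 0)
  # identical offsets: zero binocular deviation
  g0 <- binocular_deviation(eye_offsets(7, -3, 7, -3), 0.1)
  expect_equal(g0$theta_h, 0)
  expect_equal(g0$theta_v, 0)
  # swapping eyes negates both axes
  gs <- binocular_deviation(eye_offsets(-15, 2, 15, 2), 0.1, 20)
  expect_equal(gs$theta_h, -g$theta_h)
  expect_equal(gs$theta_v, -g$theta_v)
})

test_that("interpupillary distance scales with alpha and rejects degeneracy", {
  expect_equal(interpupillary_distance(c(0, 0), c(600, 0), 0.1), 60)
  expect_equal(interpupillary_distance(c(0, 0), c(600, 0), 0.2), 120)
  expect_error(interpupillary_distance(c(5, 5), c(5, 5), 0.1),
               class = "ps_validation_error")
})

test_that("classification applies the screening-positive thresholds", {
  cfg <- screening_config()
  gz <- function(th, tv = 0) {
    structure(list(theta_h = th, theta_v = tv), class = "gaze_deviation")
  }
  cr <- function(w, side = "toward_flash", full = FALSE) {
    photoscreen:::new_crescent(w, if (w > 0) side else "none", full)
  }
  # 12 degrees horizontal, no crescents: strabismus only
  f <- classify(gz(12), cr(0), cr(0), cfg)
  expect_true(f$strabismus)
  expect_false(f$refractive_left$risk || f$refractive_right$risk || f$anisometropia)
  # widths 1.2 vs 0.1 mm: refractive risk left + anisometropia
  f <- classify(gz(0), cr(1.2), cr(0.1), cfg)
  expect_false(f$strabismus)
  expect_true(f$refractive_left$risk)
  expect_equal(f$refractive_left$direction, "myopic")
  expect_false(f$refractive_right$risk)
  expect_true(f$anisometropia)
  expect_true(f$myopia_left)
  # all-zero measurements: everything negative
  f <- classify(gz(0), cr(0), cr(0), cfg)
  expect_false(any(f$strabismus, f$refractive_left$risk, f$refractive_right$risk,
                   f$myopia_left, f$myopia_right, f$anisometropia))
  # thresholds are inclusive ("at least")
  f <- classify(gz(10), cr(1), cr(0), cfg)
  expect_true(f$strabismus)
  expect_true(f$refractive_left$risk)
  expect_true(f$anisometropia)
  # vertical axis alone can trigger strabismus risk
  expect_true(classify(gz(0, -11), cr(0), cr(0), cfg)$strabismus)
  # away-from-flash crescent reads hyperopic, full pupil indeterminate
  f <- classify(gz(0), cr(1.4, "away_from_flash"), cr(11.8, full = TRUE), cfg)
  expect_equal(f$refractive_left$direction, "hyperopic")
  expect_equal(f$refractive_right$direction, "indeterminate")
  expect_false(f$myopia_left || f$myopia_right)
})

test_that("classification is invariant to the pixel/scale trade-off", {
  cfg <- screening_config()
  for (k in c(0.5, 2, 3.7)) {
    g1 <- binocular_deviation(eye_offsets(30, 4, -8, 0), 0.1)
    g2 <- binocular_deviation(eye_offsets(30 / k, 4 / k, -8 / k, 0), 0.1 * k)
    cl <- photoscreen:::new_crescent(1.3, "toward_flash")
    crn <- photoscreen:::new_crescent(0.2, "toward_flash")
    f1 <- classify(g1, cl, crn, cfg); f2 <- classify(g2, cl, crn, cfg)
    expect_identical(f1[c("strabismus", "myopia_left", "anisometropia")],
                     f2[c("strabismus", "myopia_left", "anisometropia")])
  }
})

test_that("confusion metrics reproduce the screening-study arithmetic", {
  m <- confusion_metrics(confusion_matrix(tp = 16, fn = 4, fp = 2, tn = 78))
  expect_equal(m$sensitivity, 0.80)
  expect_equal(m$accuracy, 0.94)
  expect_equal(m$specificity, 0.975)
  expect_equal(round(m$specificity, 2), 0.98)
  m1 <- confusion_metrics(confusion_matrix(tp = 5, tn = 7))
  expect_equal(unlist(m1[c("accuracy", "sensitivity", "specificity")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1))
  expect_error(confusion_metrics(confusion_matrix(tp = 0, fn = 0, fp = 1, tn = 9)),
               "sensitivity", class = "ps_validation_error")
  expect_error(confusion_metrics(confusion_matrix(tp = 3, fn = 1, fp = 0, tn = 0)),
               "specificity", class = "ps_validation_error")
})

test_that("metrics are bounded and accuracy interpolates sens/spec", {
  set.seed(7)
  for (i in 1:25) {
    cm <- confusion_matrix(tp = sample(1:50, 1), fp = sample(1:50, 1),
                           tn = sample(1:50, 1), fn = sample(1:50, 1))
    m <- confusion_metrics(cm)
    v <- unlist(m[c("accuracy", "sensitivity", "specificity")])
    expect_true(all(v >= 0 & v <= 1))
    # accuracy is the prevalence-weighted mean of sensitivity and specificity
    npos <- cm$tp + cm$fn; nneg <- cm$tn + cm$fp
    expect_equal(m$accuracy,
                 (npos * m$sensitivity + nneg * m$specificity) / (npos + nneg))
  }
})

test_that("screening config validates inputs and reads YAML", {
  expect_error(screening_config(d = -1), class = "ps_validation_error")
  expect_error(screening_config(crescent_mm = 0), class = "ps_validation_error")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("strabismus_deg: 8.5", "flash_side: right"), path)
  cfg <- read_screening_config(path)
  expect_equal(cfg$strabismus_deg, 8.5)
  expect_equal(cfg$flash_side, "right")
  expect_equal(cfg$d, 20)
  writeLines("not_a_key: 1", path)
  expect_error(read_screening_config(path), "unknown config keys")
})
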
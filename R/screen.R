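# Optics and decision layer: corneal-reflection offsets to visual-axis
# angles, binocular deviation, interpupillary distance, risk classification
# and evaluation metrics.

#' Screening configuration
#'
#' Thresholds and optical constants of the screening decision rules.
#'
#' @param d assumed eyeball diameter in mm. The true diameter is not
#'   measurable from a single photo, so a population average of 20 mm is
#'   used in the offset-to-angle conversion.
#' @param strabismus_deg screening-positive threshold on the relative visual
#'   angle, degrees (default 10).
#' @param crescent_mm per-eye refractive-error threshold on red reflex
#'   crescent width, mm (default 1).
#' @param anisometropia_mm threshold on the absolute between-eye crescent
#'   width difference, mm (default 1).
#' @param eta eye-openness (height-to-width) ratio below which an eye is
#'   rejected as closed (default 0.25).
#' @param flash_side side of the camera on which the flash sits, from the
#'   examiner's point of view: "left" or "right".
#' @return object of class `screening_config`.
#' @export
screening_config <- function(d = 20, strabismus_deg = 10, crescent_mm = 1,
                             anisometropia_mm = 1, eta = 0.25,
                             flash_side = c("left", "right")) {
  flash_side <- match.arg(flash_side)
  for (nm in c("d", "strabismus_deg", "crescent_mm", "anisometropia_mm", "eta")) {
    v <- get(nm)
    ps_validate(is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0,
                sprintf("screening_config: %s must be a positive number", nm))
  }
  structure(list(d = d, strabismus_deg = strabismus_deg,
                 crescent_mm = crescent_mm, anisometropia_mm = anisometropia_mm,
                 eta = eta, flash_side = flash_side),
            class = "screening_config")
}

#' Load a screening configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take their defaults.
#' @param path YAML file with any subset of the [screening_config()] fields.
#' @export
read_screening_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(screening_config))
  bad <- setdiff(names(vals), known)
  ps_validate(length(bad) == 0,
              sprintf("unknown config keys: %s", paste(bad, collapse = ", ")))
  do.call(screening_config, vals)
}

#' Axial deviation of one eye from the camera/flash axis
#'
#' Converts a corneal-reflection offset Delta (pixels, reflection center
#' minus limbus center) into the deviation angle of that eye's visual axis:
#' `theta = atan(2 * alpha * delta / d)` in degrees. The factor 2 accounts
#' for the specular reflection geometry of the cornea: the reflection moves
#' half as fast as the visual axis rotates.
#'
#' @param delta offset in pixels (vectorised).
#' @param alpha frontal-plane scale, mm per pixel (> 0).
#' @param d eyeball diameter in mm (> 0, default 20).
#' @return angle(s) in degrees; odd and monotone increasing in `delta`.
#' @export
axial_deviation <- function(delta, alpha, d = 20) {
  ps_validate(all(is.finite(delta)) && is.finite(alpha) && is.finite(d),
              "axial_deviation: inputs must be finite")
  ps_validate(alpha > 0 && d > 0, "axial_deviation: alpha and d must be > 0")
  rad2deg(atan(2 * alpha * delta / d))
}

#' Per-eye corneal-reflection offsets
#'
#' @param dx_left,dy_left,dx_right,dy_right offsets in pixels (x right,
#'   y down; corneal reflection center minus limbus center).
#' @export
eye_offsets <- function(dx_left, dy_left, dx_right, dy_right) {
  v <- unname(c(dx_left, dy_left, dx_right, dy_right))
  ps_validate(length(v) == 4 && all(is.finite(v)),
              "eye_offsets: four finite offsets required")
  structure(list(dx_left = v[1], dy_left = v[2],
                 dx_right = v[3], dy_right = v[4]),
            class = "eye_offsets")
}

#' Binocular gaze deviation from per-eye offsets
#'
#' Per-eye axial deviations on each axis plus the binocular differences
#' `theta_h = theta_h_left - theta_h_right` (positive values indicate
#' exotropia, negative esotropia) and `theta_v` likewise (nonzero values
#' indicate vertical strabismus).
#'
#' @param offsets an [eye_offsets()] object.
#' @param alpha frontal-plane scale, mm/px.
#' @param d eyeball diameter, mm.
#' @return object of class `gaze_deviation` with fields `theta_h_left`,
#'   `theta_h_right`, `theta_v_left`, `theta_v_right`, `theta_h`, `theta_v`
#'   (all degrees).
#' @export
binocular_deviation <- function(offsets, alpha, d = 20) {
  hl <- axial_deviation(offsets$dx_left, alpha, d)
  hr <- axial_deviation(offsets$dx_right, alpha, d)
  vl <- axial_deviation(offsets$dy_left, alpha, d)
  vr <- axial_deviation(offsets$dy_right, alpha, d)
  structure(list(theta_h_left = hl, theta_h_right = hr,
                 theta_v_left = vl, theta_v_right = vr,
                 theta_h = hl - hr, theta_v = vl - vr),
            class = "gaze_deviation")
}

#' Interpupillary distance in millimetres
#'
#' @param center_left,center_right limbus centers (length-2, pixels, in the
#'   same tilt-corrected coordinate frame).
#' @param alpha frontal-plane scale, mm/px.
#' @export
interpupillary_distance <- function(center_left, center_right, alpha) {
  ps_validate(is.numeric(alpha) && alpha > 0, "alpha must be positive")
  d <- sqrt(sum((center_left - center_right)^2))
  if (d == 0) ps_stop("coincident limbus centers", "screen",
                      class = "ps_validation_error")
  alpha * d
}

# Minimal crescent record for classification (also used by the synthetic
# ground truth). `side` is one of "toward_flash", "away_from_flash", "none".
new_crescent <- function(width_mm, side, full_pupil = FALSE, n = NA_integer_,
                         ellipse = NULL, pixels = NULL) {
  structure(list(width_mm = width_mm, side = side, full_pupil = full_pupil,
                 n = n, ellipse = ellipse, pixels = pixels),
            class = "crescent")
}

#' Classify screening risk from measurements
#'
#' Applies the screening-positive rules: strabismus risk when
#' `max(|theta_h|, |theta_v|)` reaches the relative-angle threshold; per-eye
#' refractive-error risk when the crescent width reaches the width threshold
#' (direction myopic when the crescent rises on the flash side, hyperopic on
#' the far side, indeterminate for a fully lit pupil, where severe myopia and
#' hyperopia cannot be told apart); anisometropia risk when the unsigned
#' between-eye width difference reaches its threshold. All comparisons use
#' `>=` ("at least").
#'
#' @param gaze a [binocular_deviation()] result.
#' @param crescent_left,crescent_right crescent records for the left and
#'   right eye (see [detect_crescent()]).
#' @param config a [screening_config()].
#' @return list of flags: `strabismus`, `refractive_left`, `refractive_right`
#'   (each a list with `risk` and `direction`), `myopia_left`, `myopia_right`,
#'   `anisometropia`, and `notes` (character vector of quality remarks).
#' @export
classify <- function(gaze, crescent_left, crescent_right, config = screening_config()) {
  ps_validate(!is.null(crescent_left) && !is.null(crescent_right),
              "classify: measurements required for both eyes")
  strab <- max(abs(gaze$theta_h), abs(gaze$theta_v)) >= config$strabismus_deg
  eye_flag <- function(cr) {
    risk <- cr$width_mm >= config$crescent_mm
    direction <- if (!risk) "none"
      else if (isTRUE(cr$full_pupil)) "indeterminate"
      else if (cr$side == "toward_flash") "myopic"
      else if (cr$side == "away_from_flash") "hyperopic"
      else "indeterminate"
    list(risk = risk, direction = direction)
  }
  fl <- eye_flag(crescent_left); fr <- eye_flag(crescent_right)
  aniso <- abs(crescent_left$width_mm - crescent_right$width_mm) >=
    config$anisometropia_mm
  notes <- character(0)
  if (fl$risk && fr$risk && crescent_left$side != crescent_right$side &&
      crescent_left$side != "none" && crescent_right$side != "none") {
    notes <- c(notes, "opposite-side crescents")
  }
  list(strabismus = strab,
       refractive_left = fl, refractive_right = fr,
       myopia_left = fl$risk && fl$direction == "myopic",
       myopia_right = fr$risk && fr$direction == "myopic",
       anisometropia = aniso,
       notes = notes)
}

#' Confusion matrix from truth/prediction vectors or counts
#'
#' @param truth,pred logical vectors, or NULL when giving counts directly.
#' @param tp,fp,tn,fn direct counts (used when `truth` is NULL).
#' @export
confusion_matrix <- function(truth = NULL, pred = NULL,
                             tp = 0, fp = 0, tn = 0, fn = 0) {
  if (!is.null(truth)) {
    ps_validate(length(truth) == length(pred),
                "confusion_matrix: truth and pred lengths differ")
    truth <- as.logical(truth); pred <- as.logical(pred)
    tp <- sum(truth & pred); fp <- sum(!truth & pred)
    tn <- sum(!truth & !pred); fn <- sum(truth & !pred)
  }
  ps_validate(all(c(tp, fp, tn, fn) >= 0), "confusion_matrix: negative counts")
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' Accuracy, sensitivity and specificity of a confusion matrix
#'
#' `accuracy = (TP+TN)/(TP+TN+FP+FN)`, `sensitivity = TP/(TP+FN)`,
#' `specificity = TN/(TN+FP)`. A zero denominator raises an error naming the
#' undefined metric.
#'
#' @param cm a [confusion_matrix()].
#' @export
confusion_metrics <- function(cm) {
  with(cm, {
    if (tp + tn + fp + fn == 0) ps_stop("accuracy undefined: no cases",
                                        "metrics", class = "ps_validation_error")
    if (tp + fn == 0) ps_stop("sensitivity undefined: no positive cases",
                              "metrics", class = "ps_validation_error")
    if (tn + fp == 0) ps_stop("specificity undefined: no negative cases",
                              "metrics", class = "ps_validation_error")
    structure(list(accuracy = (tp + tn) / (tp + tn + fp + fn),
                   sensitivity = tp / (tp + fn),
                   specificity = tn / (tn + fp)),
              class = "screening_metrics")
  })
}
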
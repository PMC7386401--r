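# print methods for the user-facing records

#' @export
print.eye_scene_spec <- function(x, ...) {
  cat(sprintf("Synthetic eye scene: %dx%d px, %.1f px/mm, IPD %.1f mm, tilt %.1f deg\n",
              x$width, x$height, x$ppmm, x$ipd_mm, x$tilt_deg))
  for (e in EYE_NAMES) {
    ey <- x$eyes[[e]]
    cat(sprintf(
      "  %-5s center (%.1f, %.1f), limbus %.1f px, CLR offset (%+.1f, %+.1f), crescent %.2f mm %s\n",
      e, ey$center[1], ey$center[2], ey$limbus_r,
      ey$clr_offset[1], ey$clr_offset[2], ey$crescent_mm, ey$crescent_side))
  }
  cat(sprintf("  occlusion %.1f deg, noise sd %.1f, seed %d\n",
              x$eyes$left$occlusion_deg, x$noise_sd, x$seed))
  invisible(x)
}

#' @export
print.limbus_circle <- function(x, ...) {
  cat(sprintf("Limbus circle (%s): center (%.2f, %.2f), radius %.2f px, score %.1f\n",
              x$source, x$center[1], x$center[2], x$radius, x$score))
  invisible(x)
}

#' @export
print.clr_spot <- function(x, ...) {
  cat(sprintf("Corneal reflection spot: center (%.2f, %.2f), radius %.2f px, %d px\n",
              x$center[1], x$center[2], x$radius, x$n))
  invisible(x)
}

#' @export
print.crescent <- function(x, ...) {
  if (x$width_mm == 0) {
    cat("Red reflex crescent: none\n")
  } else {
    cat(sprintf("Red reflex crescent: width %.2f mm, side %s%s (%d px)\n",
                x$width_mm, x$side,
                if (isTRUE(x$full_pupil)) ", fully lit pupil" else "", x$n))
  }
  invisible(x)
}

#' @export
print.scale_calibration <- function(x, ...) {
  cat(sprintf("Scale calibration: alpha %.4f mm/px (id '%s', edge %.1f mm, side %.1f px)\n",
              x$alpha, x$id, x$edge_mm, x$side_px))
  invisible(x)
}

#' @export
print.gaze_deviation <- function(x, ...) {
  cat(sprintf("Gaze deviation (deg): theta_h %+.2f (L %+.2f, R %+.2f), theta_v %+.2f (L %+.2f, R %+.2f)\n",
              x$theta_h, x$theta_h_left, x$theta_h_right,
              x$theta_v, x$theta_v_left, x$theta_v_right))
  invisible(x)
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("Screening result for %s (attempt %d, alpha %.4f mm/px)\n",
              x$id, x$attempt, x$alpha))
  cat(sprintf("  theta_h %+.2f deg, theta_v %+.2f deg, IPD %.1f mm\n",
              x$gaze$theta_h, x$gaze$theta_v, x$ipd_mm))
  cat(sprintf("  crescent width L %.2f mm (%s), R %.2f mm (%s)\n",
              x$crescent_left$width_mm, x$crescent_left$side,
              x$crescent_right$width_mm, x$crescent_right$side))
  flag <- function(b) if (isTRUE(b)) "POSITIVE" else "negative"
  cat(sprintf("  strabismus %s | myopia L %s R %s | anisometropia %s\n",
              flag(x$flags$strabismus), flag(x$flags$myopia_left),
              flag(x$flags$myopia_right), flag(x$flags$anisometropia)))
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: TP %d, FP %d, TN %d, FN %d\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' @export
print.screening_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("Cohort report: %d cases, %d analysed, %d failed",
              x$n, length(x$results), length(x$failures)))
  if (is.finite(x$first_pass_rate)) {
    cat(sprintf(", first-pass rate %.0f%%", 100 * x$first_pass_rate))
  }
  cat("\n")
  if (length(x$failures)) {
    for (f in x$failures) {
      cat(sprintf("  failed %s at stage '%s': %s\n", f$id, f$stage, f$message))
    }
  }
  invisible(x)
}
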
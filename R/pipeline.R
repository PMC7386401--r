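# Exam orchestration: one-step analysis of an image pair, batch evaluation
# over manifests, and comparison against truth labels.

#' Define one exam case
#'
#' @param id examinee identifier.
#' @param hirschberg,redreflex,landmarks file paths. Each may be a vector
#'   (or a single ';'-separated string) listing alternate acquisition
#'   attempts in order; the pipeline uses the first attempt that passes all
#'   quality gates and records the attempt index.
#' @param truth optional path to a truth record.
#' @export
exam_case <- function(id, hirschberg, redreflex, landmarks, truth = NULL) {
  split_paths <- function(x) unlist(strsplit(x, ";", fixed = TRUE))
  h <- split_paths(hirschberg); r <- split_paths(redreflex)
  l <- split_paths(landmarks)
  ps_validate(length(h) == length(r),
              "exam_case: hirschberg and redreflex attempt counts differ")
  if (length(l) == 1) l <- rep(l, length(h))
  ps_validate(length(l) == length(h),
              "exam_case: landmarks attempt count mismatch")
  structure(list(id = id, hirschberg = h, redreflex = r, landmarks = l,
                 truth = truth),
            class = "exam_case")
}

# Analyse a single attempt (one Hirschberg still + one red-reflex frame +
# one landmark record). Returns a screening_result.
run_attempt <- function(id, hpath, rpath, lpath, config, scale = NULL,
                        log = NULL) {
  note <- function(stage, ...) {
    if (!is.null(log)) {
      rec <- c(list(id = id, stage = stage), list(...))
      cat(as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 6)),
          "\n", sep = "", file = log, append = TRUE)
    }
  }
  img_h <- read_image(hpath)
  img_r <- read_image(rpath)
  lms <- load_landmarks(lpath)
  note("load", tilt = lms$head_tilt_deg)

  if (is.null(scale)) scale <- decode_scale(img_h)
  note("scale", alpha = scale$alpha)

  patches_h <- extract_eye_patches(img_h, lms, eta = config$eta)
  patches_r <- extract_eye_patches(img_r, lms, eta = config$eta)

  eyes <- list()
  for (e in EYE_NAMES) {
    ph <- patches_h[[e]]
    mask <- build_roi_mask(ph)
    limbus <- detect_limbus_hirschberg(ph, mask)
    clr <- detect_clr(ph, limbus)
    note("hirschberg_eye", eye = e, center = limbus$center,
         radius = limbus$radius, votes = limbus$score)
    pr <- patches_r[[e]]
    limbus_r <- refine_limbus_photorefraction(pr, limbus)
    crescent <- detect_crescent(pr, limbus_r, clr, scale, config$flash_side)
    note("redreflex_eye", eye = e, center = limbus_r$center,
         contrast = limbus_r$score, width_mm = crescent$width_mm)
    eyes[[e]] <- list(patch_h = ph, patch_r = pr, limbus = limbus,
                      limbus_refined = limbus_r, clr = clr,
                      crescent = crescent,
                      offset = clr$center - limbus$center,
                      center_corrected = patch_to_corrected(ph, limbus$center))
  }

  offs <- eye_offsets(eyes$left$offset[1], eyes$left$offset[2],
                      eyes$right$offset[1], eyes$right$offset[2])
  gaze <- binocular_deviation(offs, scale$alpha, config$d)
  ipd <- interpupillary_distance(eyes$left$center_corrected,
                                 eyes$right$center_corrected, scale$alpha)
  flags <- classify(gaze, eyes$left$crescent, eyes$right$crescent, config)
  structure(list(
    id = id, alpha = scale$alpha, offsets = offs, gaze = gaze,
    crescent_left = eyes$left$crescent, crescent_right = eyes$right$crescent,
    ipd_mm = ipd, flags = flags, attempt = NA_integer_,
    limbus = list(left = eyes$left$limbus, right = eyes$right$limbus),
    notes = flags$notes
  ), class = "screening_result")
}

#' Run the one-step exam analysis for a single case
#'
#' Executes the full pipeline on an exam case: decode the scale fiducial,
#' localize and tilt-correct the eyes, detect the limbus and corneal
#' reflection on the Hirschberg still, refine the limbus and extract the
#' crescent on the red-reflex frame, then derive gaze deviation,
#' interpupillary distance and risk flags. When a case lists several
#' acquisition attempts, attempts are tried in order until one passes all
#' quality gates; the attempt index is recorded. Deterministic for fixed
#' inputs and configuration.
#'
#' @param case an [exam_case()].
#' @param config a [screening_config()].
#' @param scale optional pre-decoded `scale_calibration` (otherwise decoded
#'   from the Hirschberg image).
#' @param log optional path of a JSONL per-stage log.
#' @return object of class `screening_result`.
#' @export
run_exam <- function(case, config = screening_config(), scale = NULL,
                     log = NULL) {
  ps_validate(inherits(case, "exam_case"), "run_exam expects an exam_case")
  last <- NULL
  for (k in seq_along(case$hirschberg)) {
    res <- tryCatch(
      run_attempt(case$id, case$hirschberg[k], case$redreflex[k],
                  case$landmarks[k], config, scale, log),
      ps_error = function(e) e
    )
    if (!inherits(res, "condition")) {
      res$attempt <- k
      if (k > 1) res$notes <- c(res$notes, sprintf("retried: passed on attempt %d", k))
      return(res)
    }
    last <- res
  }
  ps_stop(sprintf("exam failed for %s at stage '%s' after %d attempt(s): %s",
                  case$id, last$stage %||% "?", length(case$hirschberg),
                  conditionMessage(last)),
          last$stage %||% "exam", class = class(last)[1],
          data = list(id = case$id, attempts = length(case$hirschberg)))
}

#' Serialize a screening result to JSON
#'
#' @param result a `screening_result`.
#' @param path optional output path; when NULL the JSON string is returned.
#' @export
result_to_json <- function(result, path = NULL) {
  out <- list(
    id = result$id, alpha = result$alpha,
    offsets = unclass(result$offsets),
    theta = unclass(result$gaze),
    crescent = list(
      left = list(width_mm = result$crescent_left$width_mm,
                  side = result$crescent_left$side,
                  full_pupil = result$crescent_left$full_pupil),
      right = list(width_mm = result$crescent_right$width_mm,
                   side = result$crescent_right$side,
                   full_pupil = result$crescent_right$full_pupil)
    ),
    ipd_mm = result$ipd_mm,
    flags = list(
      strabismus = result$flags$strabismus,
      refractive_left = result$flags$refractive_left,
      refractive_right = result$flags$refractive_right,
      myopia_left = result$flags$myopia_left,
      myopia_right = result$flags$myopia_right,
      anisometropia = result$flags$anisometropia
    ),
    attempt = result$attempt,
    notes = as.list(result$notes)
  )
  js <- as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 8))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    ps_validate(file.exists(manifest),
                sprintf("manifest not found: %s", manifest), "batch")
    df <- read.csv(manifest, stringsAsFactors = FALSE)
    attr(df, "dir") <- dirname(manifest)
    df
  } else {
    manifest
  }
}

#' Run the screening pipeline over a batch manifest
#'
#' Processes each manifest row in isolation: one failing case is recorded as
#' a structured failure and never aborts the batch.
#'
#' @param manifest path to a manifest CSV (columns `id`, `hirschberg_path`,
#'   `redreflex_path`, `landmarks_path`, optional `truth_path`; paths
#'   relative to the manifest, attempts ';'-separated), or an equivalent
#'   data frame (with attribute `"dir"` for relative paths).
#' @param config a [screening_config()].
#' @param out_dir optional directory for `results.json`, `summary.csv` and
#'   `log.jsonl`.
#' @return object of class `cohort_report`: `results` (list of
#'   `screening_result`), `failures` (list of id/stage/message records),
#'   `n`, `first_pass_rate` (fraction of successful cases that passed on
#'   attempt 1), `manifest`.
#' @export
run_batch <- function(manifest, config = screening_config(), out_dir = NULL) {
  df <- read_manifest(manifest)
  ps_validate(nrow(df) >= 1, "empty manifest", "batch")
  base <- attr(df, "dir") %||% "."
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "log.jsonl")
    if (file.exists(log)) file.remove(log)
  }
  results <- list(); failures <- list()
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rel <- function(p) file.path(base, unlist(strsplit(p, ";", fixed = TRUE)))
    res <- tryCatch({
      case <- exam_case(row$id, rel(row$hirschberg_path),
                        rel(row$redreflex_path), rel(row$landmarks_path),
                        truth = if (!is.null(row$truth_path)) file.path(base, row$truth_path))
      run_exam(case, config, log = log)
    }, ps_error = function(e) e, error = function(e) e)
    if (inherits(res, "condition")) {
      failures[[length(failures) + 1L]] <- list(
        id = row$id, stage = res$stage %||% "unknown",
        message = conditionMessage(res))
    } else {
      results[[length(results) + 1L]] <- res
    }
  }
  attempts <- vapply(results, function(r) r$attempt, integer(1))
  report <- structure(list(
    results = results, failures = failures, n = nrow(df),
    first_pass_rate = if (length(attempts)) mean(attempts == 1L) else NA_real_,
    manifest = df
  ), class = "cohort_report")
  if (!is.null(out_dir)) {
    writeLines(vapply(results, result_to_json, character(1)),
               file.path(out_dir, "results.json"))
    write.csv(summary_frame(report), file.path(out_dir, "summary.csv"),
              row.names = FALSE)
  }
  report
}

# Flat per-case summary of a cohort report.
summary_frame <- function(report) {
  rows <- lapply(report$results, function(r) data.frame(
    id = r$id, status = "ok", attempt = r$attempt,
    theta_h = r$gaze$theta_h, theta_v = r$gaze$theta_v,
    width_left_mm = r$crescent_left$width_mm,
    width_right_mm = r$crescent_right$width_mm,
    ipd_mm = r$ipd_mm,
    strabismus = r$flags$strabismus,
    myopia_left = r$flags$myopia_left, myopia_right = r$flags$myopia_right,
    anisometropia = r$flags$anisometropia,
    stringsAsFactors = FALSE))
  frows <- lapply(report$failures, function(f) data.frame(
    id = f$id, status = paste0("failed:", f$stage), attempt = NA_integer_,
    theta_h = NA_real_, theta_v = NA_real_, width_left_mm = NA_real_,
    width_right_mm = NA_real_, ipd_mm = NA_real_, strabismus = NA,
    myopia_left = NA, myopia_right = NA, anisometropia = NA,
    stringsAsFactors = FALSE))
  do.call(rbind, c(rows, frows))
}

#' Evaluate a cohort report against truth labels
#'
#' Builds one confusion matrix per condition. Myopia is counted per eye, so
#' its confusion-matrix total is twice the number of evaluated examinees;
#' strabismus and anisometropia are per examinee.
#'
#' @param report a [run_batch()] `cohort_report`.
#' @param truths named list of truth records (as read from the generator's
#'   truth JSON) keyed by case id, or NULL to load them from the manifest's
#'   `truth_path` column.
#' @return list with one entry per condition (`strabismus`, `myopia`,
#'   `anisometropia`), each holding `confusion` and `metrics`, plus
#'   `n_evaluated`.
#' @export
evaluate_cohort <- function(report, truths = NULL) {
  if (is.null(truths)) {
    df <- report$manifest
    ps_validate(!is.null(df$truth_path), "manifest has no truth_path column",
                "evaluate")
    base <- attr(df, "dir") %||% "."
    truths <- lapply(seq_len(nrow(df)), function(i) {
      read_truth(file.path(base, df$truth_path[i]))
    })
    names(truths) <- df$id
  }
  ids <- vapply(report$results, `[[`, character(1), "id")
  orphans <- setdiff(ids, names(truths))
  if (length(orphans) > 0) {
    ps_stop(sprintf("no truth record for: %s", paste(orphans, collapse = ", ")),
            "evaluate", class = "ps_validation_error")
  }
  tr <- truths[ids]
  pull <- function(lst, f) vapply(lst, f, logical(1))
  truth_strab <- pull(tr, function(t) isTRUE(t$labels$strabismus))
  truth_aniso <- pull(tr, function(t) isTRUE(t$labels$anisometropia))
  truth_myo <- c(pull(tr, function(t) isTRUE(t$labels$myopia_left)),
                 pull(tr, function(t) isTRUE(t$labels$myopia_right)))
  pred_strab <- pull(report$results, function(r) isTRUE(r$flags$strabismus))
  pred_aniso <- pull(report$results, function(r) isTRUE(r$flags$anisometropia))
  pred_myo <- c(pull(report$results, function(r) isTRUE(r$flags$myopia_left)),
                pull(report$results, function(r) isTRUE(r$flags$myopia_right)))
  out <- list(
    strabismus = confusion_matrix(truth_strab, pred_strab),
    myopia = confusion_matrix(truth_myo, pred_myo),
    anisometropia = confusion_matrix(truth_aniso, pred_aniso)
  )
  out <- lapply(out, function(cm) list(
    confusion = cm,
    metrics = tryCatch(confusion_metrics(cm), ps_validation_error = function(e) {
      structure(list(accuracy = NA_real_, sensitivity = NA_real_,
                     specificity = NA_real_, note = conditionMessage(e)),
                class = "screening_metrics")
    })))
  out$n_evaluated <- length(ids)
  out
}
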
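# Synthetic eye-scene renderer with exact ground truth.
#
# Renders the two-image exam pair that the pipeline consumes: a flash still
# with contracted pupils and a bright corneal reflection spot (automated
# Hirschberg test), and a maximally exposed frame with dilated pupils, a red
# fundus glow and an optional bright crescent (photorefraction). Geometry is
# flat-shaded disks with anti-aliased edges; eyelids are rendered as skin
# bands clipping the eye to `|dy| <= limbus_r * cos(occlusion)` so that an
# occlusion half-angle of beta hides the limbus arcs within beta of vertical,
# exercising the arc-restricted Hough transform downstream.

EYE_NAMES <- c("left", "right")  # anatomical; left eye = image right half

# Fixed rendering palette (see the methods vignette for the constraints the
# crescent/iris brightness ratios must satisfy).
PAL <- list(
  pupil_dark = c(25, 22, 20),     # Hirschberg (contracted) pupil
  pupil_glow = c(95, 28, 22),     # red-reflex fundus glow
  crescent   = c(255, 120, 105),  # saturated red crescent
  clr        = c(255, 255, 255)   # corneal reflection spot
)
HIRSCHBERG_PUPIL_FRAC <- 0.7      # contracted / dilated pupil radius ratio

#' Specify a synthetic two-eye exam scene
#'
#' Builds a validated parametric description of one exam scene. Eye centers
#' are placed `ipd_mm` apart on a line through the face center rotated by
#' `tilt_deg`; each eye's internal geometry (corneal-reflection offset,
#' crescent) is specified in tilt-corrected "face" coordinates and rotated
#' into the image.
#'
#' @param width,height image size in pixels.
#' @param ppmm true frontal-plane scale, pixels per mm (the ground-truth
#'   alpha is `1 / ppmm`).
#' @param ipd_mm true interpupillary distance, mm.
#' @param eye_y vertical position of the face center, px.
#' @param limbus_r_mm limbus radius in mm (default 5.9, a typical corneal
#'   radius for school-age children).
#' @param pupil_frac dilated pupil radius as a fraction of the limbus radius.
#' @param tilt_deg head tilt, degrees (counterclockwise positive in the
#'   package's rotation convention).
#' @param clr_offset_left,clr_offset_right corneal-reflection spot offset
#'   from the limbus center, px, in face coordinates `(dx, dy)`.
#' @param crescent_mm_left,crescent_mm_right red reflex crescent widths, mm
#'   (>= 0; 0 renders no crescent).
#' @param crescent_side_left,crescent_side_right `"toward_flash"` or
#'   `"away_from_flash"`.
#' @param occlusion_deg eyelid occlusion half-angle in degrees, `[0, 90)`:
#'   the arc of the limbus within this angle of vertical (top and bottom) is
#'   covered by skin. Length 1 (both eyes) or 2 (left, right).
#' @param noise_sd additive Gaussian noise standard deviation per channel
#'   (intensity units; images are clipped to `[0, 255]`).
#' @param seed integer seed controlling the noise.
#' @param flash_side flash position relative to the camera, examiner's view.
#' @param skin_rgb,sclera_rgb,iris_rgb palette, length-3 RGB in 0..255.
#' @param fiducial list with `id` and `edge_mm` for the embedded scale tag
#'   (drawn upright at the top of the frame, as if displayed on a phone held
#'   at the forehead), or NULL for no tag.
#' @return object of class `eye_scene_spec`.
#' @export
eye_scene_spec <- function(width = 880, height = 480, ppmm = 10, ipd_mm = 60,
                           eye_y = 320, limbus_r_mm = 5.9, pupil_frac = 0.55,
                           tilt_deg = 0,
                           clr_offset_left = c(0, 0), clr_offset_right = c(0, 0),
                           crescent_mm_left = 0, crescent_mm_right = 0,
                           crescent_side_left = "toward_flash",
                           crescent_side_right = "toward_flash",
                           occlusion_deg = 15, noise_sd = 0, seed = 1,
                           flash_side = c("left", "right"),
                           skin_rgb = c(184, 134, 100),
                           sclera_rgb = c(245, 242, 238),
                           iris_rgb = c(40, 52, 70),
                           fiducial = list(id = "anon", edge_mm = 18)) {
  flash_side <- match.arg(flash_side)
  chk <- function(ok, field) {
    if (!isTRUE(ok)) ps_stop(sprintf("invalid scene spec: %s", field),
                             "synthgen", class = "ps_validation_error")
  }
  chk(is.numeric(ppmm) && ppmm > 0, "ppmm")
  limbus_r <- limbus_r_mm * ppmm
  pupil_r <- pupil_frac * limbus_r
  chk(limbus_r > pupil_r && pupil_r > 0, "limbus radius > pupil radius > 0")
  occl <- rep_len(occlusion_deg, 2L)
  chk(all(occl >= 0 & occl < 90), "occlusion half-angle in [0, 90)")
  chk(all(c(crescent_mm_left, crescent_mm_right) >= 0), "crescent width >= 0")
  chk(crescent_mm_left * ppmm < 2 * pupil_r &&
        crescent_mm_right * ppmm < 2 * pupil_r,
      "crescent width x ppmm < 2 x pupil radius")
  chk(all(crescent_side_left %in% c("toward_flash", "away_from_flash")) &&
        all(crescent_side_right %in% c("toward_flash", "away_from_flash")),
      "crescent side")
  chk(noise_sd >= 0, "noise_sd")
  chk(abs(clr_offset_left[1]) < limbus_r && abs(clr_offset_left[2]) < limbus_r &&
        abs(clr_offset_right[1]) < limbus_r && abs(clr_offset_right[2]) < limbus_r,
      "|CLR offset| < limbus radius")

  face_mid <- c(width / 2, eye_y)
  sep <- ipd_mm * ppmm
  R <- rot_mat(tilt_deg)
  centers <- list(
    left  = as.vector(face_mid + R %*% c(sep / 2, 0)),   # examinee's left: image right
    right = as.vector(face_mid + R %*% c(-sep / 2, 0))
  )
  margin <- 1.6 * limbus_r
  for (e in EYE_NAMES) {
    chk(centers[[e]][1] > margin && centers[[e]][1] < width - margin &&
          centers[[e]][2] > margin && centers[[e]][2] < height - margin,
        sprintf("%s eye fits inside the image", e))
  }
  eyes <- list(
    left = list(center = centers$left, limbus_r = limbus_r, pupil_r = pupil_r,
                clr_offset = as.numeric(clr_offset_left),
                crescent_mm = crescent_mm_left,
                crescent_side = crescent_side_left, occlusion_deg = occl[1]),
    right = list(center = centers$right, limbus_r = limbus_r, pupil_r = pupil_r,
                 clr_offset = as.numeric(clr_offset_right),
                 crescent_mm = crescent_mm_right,
                 crescent_side = crescent_side_right, occlusion_deg = occl[2])
  )
  structure(list(width = width, height = height, ppmm = ppmm, ipd_mm = ipd_mm,
                 eye_y = eye_y, tilt_deg = tilt_deg, eyes = eyes,
                 face_mid = face_mid, noise_sd = noise_sd, seed = seed,
                 flash_side = flash_side, skin_rgb = skin_rgb,
                 sclera_rgb = sclera_rgb, iris_rgb = iris_rgb,
                 fiducial = fiducial),
            class = "eye_scene_spec")
}

# Is the crescent drawn on the image-left side of the pupil?
crescent_on_image_left <- function(side, flash_side) {
  (side == "toward_flash") == (flash_side == "left")
}

# Ground-truth facial landmark record for a scene (the synthetic-truth
# localizer): eye corners at +/-1.4 limbus radii along the tilted eye line,
# five points per eyelid along the occlusion band edges.
truth_landmarks <- function(spec) {
  lids_x <- seq(-1.1, 1.1, length.out = 5)
  eyes <- lapply(EYE_NAMES, function(e) {
    ey <- spec$eyes[[e]]
    r <- ey$limbus_r
    gap <- r * cos(deg2rad(ey$occlusion_deg))
    # inner corner faces the nose: image-left for the (anatomical) left eye
    inner_sign <- if (e == "left") -1 else 1
    local_pts <- rbind(
      c(inner_sign * 1.4 * r, 0),            # inner corner
      c(-inner_sign * 1.4 * r, 0),           # outer corner
      cbind(lids_x * r, -gap),               # upper lid
      cbind(lids_x * r, gap)                 # lower lid
    )
    pts <- rotate_points(local_pts, spec$tilt_deg) +
      matrix(ey$center, nrow(local_pts), 2, byrow = TRUE)
    list(inner_corner = pts[1, ], outer_corner = pts[2, ],
         upper_lid = pts[3:7, , drop = FALSE],
         lower_lid = pts[8:12, , drop = FALSE])
  })
  names(eyes) <- EYE_NAMES
  structure(list(image_size = c(spec$width, spec$height),
                 head_tilt_deg = spec$tilt_deg, source = "synthetic-truth",
                 eyes = eyes),
            class = "face_landmarks")
}

# Render one frame. mode = "hirschberg" (still: contracted pupil, no
# crescent) or "redreflex" (max-exposure frame: dilated pupil, fundus glow,
# crescent). Noise is NOT applied here (render_exam seeds it).
render_frame <- function(spec, mode = c("hirschberg", "redreflex")) {
  mode <- match.arg(mode)
  H <- spec$height; W <- spec$width
  chans <- lapply(1:3, function(ch) matrix(spec$skin_rgb[ch], H, W))

  for (e in EYE_NAMES) {
    ey <- spec$eyes[[e]]
    cx <- ey$center[1]; cy <- ey$center[2]
    rl <- ey$limbus_r
    rp <- if (mode == "hirschberg") HIRSCHBERG_PUPIL_FRAC * ey$pupil_r else ey$pupil_r
    box_r <- ceiling(1.6 * rl) + 2
    xs <- max(0, floor(cx - box_r)):min(W - 1, ceiling(cx + box_r))
    ys <- max(0, floor(cy - box_r)):min(H - 1, ceiling(cy + box_r))
    nx <- length(xs); ny <- length(ys)
    X <- matrix(rep(xs, each = ny), ny, nx)
    Y <- matrix(rep(ys, times = nx), ny, nx)
    dx <- X - cx; dy <- Y - cy
    t <- deg2rad(spec$tilt_deg)
    u <- cos(t) * dx + sin(t) * dy          # face-coordinate x
    v <- -sin(t) * dx + cos(t) * dy         # face-coordinate y
    dist <- sqrt(dx^2 + dy^2)
    cov <- function(r, d) clamp(0.5 + (r - d), 0, 1)
    vis <- cov(rl * cos(deg2rad(ey$occlusion_deg)), abs(v))  # eyelid band

    layers <- list(list(a = cov(1.45 * rl, dist), col = spec$sclera_rgb),
                   list(a = cov(rl, dist), col = spec$iris_rgb))
    pupil_col <- if (mode == "hirschberg") PAL$pupil_dark else PAL$pupil_glow
    layers <- c(layers, list(list(a = cov(rp, dist), col = pupil_col)))

    cres_a <- NULL
    if (mode == "redreflex" && ey$crescent_mm > 0) {
      w_px <- ey$crescent_mm * spec$ppmm
      on_left <- crescent_on_image_left(ey$crescent_side, spec$flash_side)
      # anti-aliased circular segment: pupil-disk coverage times the
      # coverage of the half-plane bounded by the flat chord edge
      a_flat <- if (on_left) clamp(0.5 + ((-rp + w_px) - u), 0, 1)
                else clamp(0.5 + (u - (rp - w_px)), 0, 1)
      cres_a <- cov(rp, dist) * a_flat
    }

    # corneal reflection spot (present in both frames)
    sp <- as.vector(rot_mat(spec$tilt_deg) %*% ey$clr_offset)
    ds <- sqrt((dx - sp[1])^2 + (dy - sp[2])^2)
    spot <- list(a = cov(0.08 * rl, ds), col = PAL$clr)

    sub <- lapply(chans, function(m) m[ys + 1, xs + 1])
    for (lay in layers) {
      a <- lay$a * vis
      for (ch in 1:3) sub[[ch]] <- a * lay$col[ch] + (1 - a) * sub[[ch]]
    }
    if (!is.null(cres_a)) {
      a <- cres_a * vis
      for (ch in 1:3) sub[[ch]] <- a * PAL$crescent[ch] + (1 - a) * sub[[ch]]
    }
    a <- spot$a * vis
    for (ch in 1:3) sub[[ch]] <- a * spot$col[ch] + (1 - a) * sub[[ch]]
    for (ch in 1:3) chans[[ch]][ys + 1, xs + 1] <- sub[[ch]]
  }

  if (!is.null(spec$fiducial)) {
    tag <- render_scale_fiducial(spec$fiducial$id, spec$fiducial$edge_mm,
                                 spec$ppmm)
    th <- dim(tag$image)[1]; tw <- dim(tag$image)[2]
    x0 <- round((W - tw) / 2); y0 <- 12
    ps_validate(x0 >= 0 && y0 + th <= H, "fiducial does not fit in the frame",
                "synthgen")
    for (ch in 1:3) {
      chans[[ch]][(y0 + 1):(y0 + th), (x0 + 1):(x0 + tw)] <- tag$image[, , ch]
    }
  }

  img <- array(0, dim = c(H, W, 3L))
  for (ch in 1:3) img[, , ch] <- chans[[ch]]
  img
}

# Ground-truth record for a scene: scale, offsets, closed-form angles,
# crescent widths/sides, landmarks, and condition labels produced by running
# the classifier on the noise-free truth measurements.
scene_truth <- function(spec, config = NULL) {
  config <- config %||% screening_config(flash_side = spec$flash_side)
  alpha <- 1 / spec$ppmm
  offs <- eye_offsets(spec$eyes$left$clr_offset[1], spec$eyes$left$clr_offset[2],
                      spec$eyes$right$clr_offset[1], spec$eyes$right$clr_offset[2])
  gaze <- binocular_deviation(offs, alpha, config$d)
  cres <- lapply(EYE_NAMES, function(e) {
    ey <- spec$eyes[[e]]
    w_px <- ey$crescent_mm * spec$ppmm
    area <- segment_area(ey$pupil_r, w_px)
    full <- area >= 0.7 * pi * ey$limbus_r^2
    new_crescent(
      width_mm = if (full) alpha * 2 * ey$limbus_r else ey$crescent_mm,
      side = if (ey$crescent_mm > 0) ey$crescent_side else "none",
      full_pupil = full
    )
  })
  names(cres) <- EYE_NAMES
  flags <- classify(gaze, cres$left, cres$right, config)
  structure(list(
    alpha = alpha,
    offsets = offs,
    gaze = gaze,
    crescents = cres,
    ipd_mm = spec$ipd_mm,
    centers = lapply(spec$eyes, `[[`, "center"),
    limbus_r = spec$eyes$left$limbus_r,
    pupil_r = spec$eyes$left$pupil_r,
    landmarks = truth_landmarks(spec),
    labels = list(strabismus = flags$strabismus,
                  myopia_left = flags$myopia_left,
                  myopia_right = flags$myopia_right,
                  anisometropia = flags$anisometropia)
  ), class = "scene_truth")
}

#' Render a synthetic exam image pair with ground truth
#'
#' @param spec an [eye_scene_spec()].
#' @param config optional [screening_config()] used to derive the truth
#'   condition labels (defaults to the standard thresholds with the spec's
#'   flash side).
#' @return list with `hirschberg` and `redreflex` RGB image arrays, `truth`
#'   (a `scene_truth` record) and `landmarks` (a `face_landmarks` record).
#' @export
render_exam <- function(spec, config = NULL) {
  ps_validate(inherits(spec, "eye_scene_spec"),
              "render_exam expects an eye_scene_spec", "synthgen")
  hir <- render_frame(spec, "hirschberg")
  red <- render_frame(spec, "redreflex")
  if (spec$noise_sd > 0) {
    with_seed(spec$seed, {
      hir <- clamp(hir + array(rnorm(length(hir), sd = spec$noise_sd), dim(hir)), 0, 255)
      red <- clamp(red + array(rnorm(length(red), sd = spec$noise_sd), dim(red)), 0, 255)
    })
  }
  list(hirschberg = hir, redreflex = red,
       truth = scene_truth(spec, config), landmarks = truth_landmarks(spec))
}

# Frame geometry large enough for the eyes (with patch padding), the head
# tilt and the top-of-frame fiducial at a given scale.
auto_scene_geometry <- function(ppmm, ipd_mm, tilt_deg, edge_mm = 18) {
  rl <- 5.9 * ppmm
  sep <- ipd_mm * ppmm
  margin <- 2.3 * rl + 8
  width <- ceiling(sep + 2 * margin)
  tag_bottom <- 12 + ceiling(edge_mm * ppmm * 1.25)
  vshift <- sep / 2 * abs(sin(deg2rad(tilt_deg)))
  eye_y <- ceiling(tag_bottom + vshift + margin + 8)
  height <- ceiling(eye_y + vshift + margin + 8)
  list(width = width, height = height, eye_y = eye_y)
}

#' Draw a random scene specification
#'
#' Samples a plausible exam scene for recovery experiments: scale 10-12
#' px/mm (the smartphone-at-arm's-length regime, alpha <= 0.1 mm/px; the
#' binary crescent filter quantizes widths to the pixel pitch, so coarser
#' sampling cannot resolve 0.1 mm), interpupillary distance 56-64 mm,
#' corneal-reflection offsets up to ~20 px on each axis, crescent width 0 or
#' 0.5-2.5 mm on either side, head tilt and eyelid occlusion within the
#' given ranges.
#'
#' @param seed integer seed (also becomes the scene's noise seed).
#' @param tilt_range,occlusion_range ranges (degrees) to sample uniformly.
#' @param noise_sd additive noise level passed through to the spec.
#' @export
random_scene_spec <- function(seed, tilt_range = c(-10, 10),
                              occlusion_range = c(0, 25), noise_sd = 0) {
  with_seed(seed, {
    ppmm <- runif(1, 10, 12)
    ipd <- runif(1, 56, 64)
    tilt <- runif(1, tilt_range[1], tilt_range[2])
    geom <- auto_scene_geometry(ppmm, ipd, tilt)
    has_cres <- runif(2) < 0.6
    w <- ifelse(has_cres, runif(2, 0.5, 2.5), 0)
    sides <- ifelse(runif(2) < 0.7, "toward_flash", "away_from_flash")
    eye_scene_spec(
      width = geom$width, height = geom$height, eye_y = geom$eye_y,
      ppmm = ppmm,
      ipd_mm = ipd,
      tilt_deg = tilt,
      clr_offset_left = round(runif(2, -20, 20)),
      clr_offset_right = round(runif(2, -20, 20)),
      crescent_mm_left = w[1], crescent_mm_right = w[2],
      crescent_side_left = sides[1], crescent_side_right = sides[2],
      occlusion_deg = runif(1, occlusion_range[1], occlusion_range[2]),
      noise_sd = noise_sd,
      seed = seed,
      fiducial = list(id = sprintf("rnd%06d", seed %% 1000000L), edge_mm = 18)
    )
  })
}

#' Specify a synthetic screening cohort
#'
#' Defines the population from which [generate_cohort()] samples exam cases.
#' Affected strata are separated from unaffected ones by a margin around the
#' screening thresholds so that condition labels are stable: strabismic eyes
#' deviate 12-20 degrees (vs at most 1.5 degrees per unaffected eye),
#' refractive-error eyes show 1.3-2.5 mm crescents (vs at most 0.5 mm), and
#' anisometropic examinees get one eye's width boosted by 1.5 mm.
#'
#' @param n number of examinees (>= 1).
#' @param prevalence named fractions in `[0, 1]` for `strabismus`, `myopia`
#'   and `anisometropia`.
#' @param noise_sd additive image noise level.
#' @param seed master seed; every case derives its own sub-seed from it.
#' @param blink_rate fraction of cases whose first image pair has closed
#'   eyes (a blink), forcing a retry with a second pair.
#' @export
cohort_spec <- function(n, prevalence = c(strabismus = 0.2, myopia = 0.3,
                                          anisometropia = 0.1),
                        noise_sd = 0, seed = 1, blink_rate = 0) {
  ps_validate(is.numeric(n) && length(n) == 1 && n >= 1,
              "cohort_spec: n must be >= 1", "synthgen")
  ps_validate(all(c("strabismus", "myopia", "anisometropia") %in% names(prevalence)),
              "cohort_spec: prevalence must name strabismus, myopia, anisometropia",
              "synthgen")
  ps_validate(all(prevalence >= 0 & prevalence <= 1),
              "cohort_spec: prevalences must be in [0, 1]", "synthgen")
  ps_validate(blink_rate >= 0 && blink_rate <= 1,
              "cohort_spec: blink_rate in [0, 1]", "synthgen")
  structure(list(n = as.integer(n), prevalence = prevalence,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 blink_rate = blink_rate,
                 strab_deg_affected = c(12, 20), strab_deg_normal = c(0, 1.5),
                 crescent_mm_affected = c(1.3, 2.5),
                 crescent_mm_normal = c(0, 0.5),
                 aniso_boost_mm = 1.5),
            class = "cohort_spec")
}

# Sample the scene spec for one cohort case (must be called inside the
# cohort's seeded RNG stream).
sample_case_spec <- function(cohort, case_seed, closed = FALSE) {
  p <- cohort$prevalence
  strab <- runif(1) < p[["strabismus"]]
  myo <- runif(1) < p[["myopia"]]
  aniso <- runif(1) < p[["anisometropia"]]

  th <- runif(2, cohort$strab_deg_normal[1], cohort$strab_deg_normal[2]) *
    sample(c(-1, 1), 2, replace = TRUE)
  if (strab) {
    e <- sample(1:2, 1)
    th[e] <- runif(1, cohort$strab_deg_affected[1], cohort$strab_deg_affected[2]) *
      sample(c(-1, 1), 1)
  }
  tv <- runif(2, 0, 1) * sample(c(-1, 1), 2, replace = TRUE)

  base <- if (myo) runif(1, cohort$crescent_mm_affected[1], cohort$crescent_mm_affected[2])
          else runif(1, cohort$crescent_mm_normal[1], cohort$crescent_mm_normal[2])
  w <- pmax(base + runif(2, -0.15, 0.15), 0)
  if (aniso) {
    e <- sample(1:2, 1)
    w[e] <- w[e] + cohort$aniso_boost_mm
  }

  ppmm <- 10
  alpha <- 1 / ppmm
  d <- 20
  delta_of <- function(theta) d * tan(deg2rad(theta)) / (2 * alpha)
  ipd <- runif(1, 56, 64)
  tilt <- runif(1, -8, 8)
  geom <- auto_scene_geometry(ppmm, ipd, tilt)
  eye_scene_spec(
    width = geom$width, height = geom$height, eye_y = geom$eye_y,
    ppmm = ppmm,
    ipd_mm = ipd,
    tilt_deg = tilt,
    clr_offset_left = c(delta_of(th[1]), delta_of(tv[1])),
    clr_offset_right = c(delta_of(th[2]), delta_of(tv[2])),
    crescent_mm_left = w[1], crescent_mm_right = w[2],
    crescent_side_left = "toward_flash", crescent_side_right = "toward_flash",
    occlusion_deg = if (closed) 75 else runif(1, 5, 25),
    noise_sd = cohort$noise_sd,
    seed = case_seed,
    fiducial = list(id = sprintf("c%06d", case_seed %% 1000000L), edge_mm = 18)
  )
}

#' Generate a synthetic screening cohort on disk
#'
#' Renders `n` exam cases (image pair + landmark record + truth record) into
#' `dir` and writes a manifest CSV with columns `id`, `hirschberg_path`,
#' `redreflex_path`, `landmarks_path`, `truth_path` (paths relative to the
#' manifest; retry image pairs are ';'-separated within a cell). The run is
#' fully reproducible under a fixed seed.
#'
#' @param cohort a [cohort_spec()].
#' @param dir output directory (created if needed).
#' @return path to the manifest CSV (invisibly, with the manifest data frame
#'   as attribute `"manifest"`).
#' @export
generate_cohort <- function(cohort, dir) {
  ps_validate(inherits(cohort, "cohort_spec"),
              "generate_cohort expects a cohort_spec", "synthgen")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- vector("list", cohort$n)
  with_seed(cohort$seed, {
    for (i in seq_len(cohort$n)) {
      id <- sprintf("case%04d", i)
      case_seed <- (cohort$seed * 10007L + i * 97L) %% 2147483647L
      blink <- runif(1) < cohort$blink_rate
      spec <- sample_case_spec(cohort, case_seed)
      attempts <- list()
      if (blink) {
        closed_spec <- spec
        closed_spec$eyes$left$occlusion_deg <- 75
        closed_spec$eyes$right$occlusion_deg <- 75
        attempts <- list(closed_spec)
      }
      attempts <- c(attempts, list(spec))

      hp <- character(0); rp <- character(0); lp <- character(0)
      for (k in seq_along(attempts)) {
        ex <- render_exam(attempts[[k]])
        hname <- sprintf("%s_a%d_hirschberg.png", id, k)
        rname <- sprintf("%s_a%d_redreflex.png", id, k)
        lname <- sprintf("%s_a%d_landmarks.json", id, k)
        write_image(ex$hirschberg, file.path(dir, hname))
        write_image(ex$redreflex, file.path(dir, rname))
        write_landmarks(ex$landmarks, file.path(dir, lname))
        hp <- c(hp, hname); rp <- c(rp, rname); lp <- c(lp, lname)
        if (k == length(attempts)) {
          tname <- sprintf("%s_truth.json", id)
          write_truth(ex$truth, file.path(dir, tname))
        }
      }
      rows[[i]] <- data.frame(
        id = id,
        hirschberg_path = paste(hp, collapse = ";"),
        redreflex_path = paste(rp, collapse = ";"),
        landmarks_path = paste(lp, collapse = ";"),
        truth_path = tname,
        stringsAsFactors = FALSE
      )
    }
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE, quote = TRUE)
  attr(mpath, "manifest") <- manifest
  invisible(mpath)
}

# Serialize a truth record (numbers kept at full precision for round-trips).
write_truth <- function(truth, path) {
  out <- list(
    alpha = truth$alpha,
    offsets = unclass(truth$offsets),
    theta = unclass(truth$gaze),
    crescent = list(
      left = list(width_mm = truth$crescents$left$width_mm,
                  side = truth$crescents$left$side,
                  full_pupil = truth$crescents$left$full_pupil),
      right = list(width_mm = truth$crescents$right$width_mm,
                   side = truth$crescents$right$side,
                   full_pupil = truth$crescents$right$full_pupil)
    ),
    ipd_mm = truth$ipd_mm,
    centers = truth$centers,
    limbus_r = truth$limbus_r,
    labels = truth$labels
  )
  writeLines(as.character(jsonlite::toJSON(out, auto_unbox = TRUE, digits = 10)),
             path)
  invisible(path)
}

read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
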
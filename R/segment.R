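# Bespoke image operators: skin-masked region of interest, IsoData
# thresholding, arc-restricted circle Hough limbus detection,
# contrast-maximizing refinement on the photorefraction frame, corneal
# reflection spot extraction and red reflex crescent extraction.

#' IsoData automatic threshold of an intensity histogram
#'
#' Iterative intermeans threshold selection: starting from the midpoint of
#' the occupied intensity range, repeatedly set
#' `t <- round((mean(levels <= t) + mean(levels > t)) / 2)` (round half up)
#' until a fixed point is reached. The update is clamped to keep both
#' classes non-empty, which guarantees termination; a cycle guard returns
#' the current value if the iteration ever revisits a state.
#'
#' @param counts integer vector of 256 bin counts for levels 0..255.
#' @return the threshold level `t`; "dark" pixels are those with level
#'   `<= t`.
#' @export
isodata_threshold <- function(counts) {
  ps_validate(length(counts) == 256 && all(counts >= 0),
              "isodata_threshold expects 256 non-negative bin counts",
              "threshold")
  lev <- 0:255
  occ <- lev[counts > 0]
  if (length(occ) < 2) {
    ps_stop("isodata threshold undefined: fewer than 2 occupied bins",
            "threshold", class = "ps_detection_error")
  }
  lo <- min(occ); hi <- max(occ)
  t <- floor((lo + hi) / 2)
  t <- clamp(t, lo, hi - 1)
  seen <- logical(256)
  repeat {
    below <- lev <= t
    m1 <- weighted.mean(lev[below], counts[below])
    m2 <- weighted.mean(lev[!below], counts[!below])
    tn <- clamp(floor((m1 + m2) / 2 + 0.5), lo, hi - 1)
    if (tn == t) break
    if (seen[tn + 1]) { t <- tn; break }
    seen[t + 1] <- TRUE
    t <- tn
  }
  as.integer(t)
}

# Circular hue distance in degrees.
hue_dist <- function(h1, h2) {
  d <- abs(h1 - h2) %% 360
  pmin(d, 360 - d)
}

#' Estimate skin color statistics from a patch border
#'
#' Mean hue (circular) and saturation of the outer 10% border frame of the
#' patch, which in a frontal eye patch is skin.
#'
#' @param patch an `eye_patch` (or any RGB array via `patch$img`).
#' @export
skin_stats <- function(patch) {
  img <- if (inherits(patch, "eye_patch")) patch$img else patch
  h <- dim(img)[1]; w <- dim(img)[2]
  fx <- max(1, round(0.1 * w)); fy <- max(1, round(0.1 * h))
  g <- pixel_grid(h, w)
  border <- g$x < fx | g$x >= w - fx | g$y < fy | g$y >= h - fy
  hsv <- rgb2hsv(r = as.vector(img[, , 1])[border],
                 g = as.vector(img[, , 2])[border],
                 b = as.vector(img[, , 3])[border], maxColorValue = 255)
  hue <- hsv[1, ] * 360
  mh <- rad2deg(atan2(mean(sin(deg2rad(hue))), mean(cos(deg2rad(hue))))) %% 360
  structure(list(hue = mh, saturation = mean(hsv[2, ])), class = "skin_stats")
}

#' Build the sclera-limbus-iris region-of-interest mask
#'
#' Classifies pixels whose hue and saturation both match the skin statistics
#' as background, then takes the connected non-skin component containing the
#' patch center (falling back to the largest component if the center pixel
#' is skin-like) as the region of interest.
#'
#' @param patch an `eye_patch`.
#' @param stats a [skin_stats()] object, or NULL to estimate automatically
#'   from the outer 10% border frame of the patch.
#' @param hue_tol,sat_tol matching tolerances (degrees; saturation units).
#' @return logical H x W matrix (TRUE = region of interest) with the skin
#'   statistics attached as attribute `"skin_stats"`.
#' @export
build_roi_mask <- function(patch, stats = NULL, hue_tol = 20, sat_tol = 0.2) {
  img <- patch$img
  h <- dim(img)[1]; w <- dim(img)[2]
  ps_validate(h > 0 && w > 0, "empty patch", "roi")
  if (is.null(stats)) stats <- skin_stats(patch)
  hsv <- rgb2hsv(r = as.vector(img[, , 1]), g = as.vector(img[, , 2]),
                 b = as.vector(img[, , 3]), maxColorValue = 255)
  skin <- hue_dist(hsv[1, ] * 360, stats$hue) <= hue_tol &
    abs(hsv[2, ] - stats$saturation) <= sat_tol
  nonskin <- matrix(!skin, h, w)
  lab <- cpp_label_components(nonskin, 4L)
  if (max(lab) == 0) {
    ps_stop("region of interest empty: patch is entirely skin-like", "roi",
            class = "ps_detection_error")
  }
  ctr_lab <- lab[round((h - 1) / 2) + 1, round((w - 1) / 2) + 1]
  if (ctr_lab == 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    ctr_lab <- which.max(sizes)
  }
  mask <- lab == ctr_lab
  attr(mask, "skin_stats") <- stats
  mask
}

# Sub-pixel circle refinement: algebraic (Kasa) least-squares fit to the
# edge points lying near the Hough peak circle, restricted to the +/-45
# degree left/right arcs (|dy| <= |dx| from the candidate center) so eyelid
# chords do not pull the fit. Falls back to the Hough estimate when too few
# inliers remain.
refine_circle_fit <- function(pts, center, radius, band = 2) {
  dx <- pts[, "x"] - center[1]; dy <- pts[, "y"] - center[2]
  d <- sqrt(dx^2 + dy^2)
  inl <- abs(d - radius) <= band & abs(dy) <= abs(dx)
  if (sum(inl) < 6) return(list(center = center, radius = radius))
  x <- pts[inl, "x"]; y <- pts[inl, "y"]
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(sol)) return(list(center = center, radius = radius))
  cx <- unname(sol[1]) / 2; cy <- unname(sol[2]) / 2
  r2 <- sol[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(list(center = center, radius = radius))
  fit <- list(center = c(cx, cy), radius = sqrt(r2))
  # reject a degenerate fit that ran away from the vote peak
  if (sqrt(sum((fit$center - center)^2)) > 3 ||
      abs(fit$radius - radius) > 0.1 * radius) {
    return(list(center = center, radius = radius))
  }
  fit
}

# Boundary pixels (0-based x, y) of `dark` pixels having a 4-neighbour that
# is not dark.
boundary_points <- function(dark) {
  h <- nrow(dark); w <- ncol(dark)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- dark
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  idx <- which(dark & !interior, arr.ind = TRUE)
  cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
}

#' Detect the limbus on the Hirschberg still by arc-restricted circle Hough
#'
#' Thresholds the region of interest with IsoData to separate dark iris from
#' bright sclera, takes the boundary pixels of the dark region as edge
#' points, and accumulates a circle Hough transform in which each edge point
#' votes only for centers whose horizontal direction to the point is within
#' 45 degrees (the left and right limbus arcs), so eyelid-covered top and
#' bottom arcs contribute no votes. Radii scan
#' `radius_frac x corner distance` in 1 px steps; the peak cell wins (ties:
#' most votes, then larger radius, then smaller y, then smaller x), with a
#' vote-weighted sub-pixel refinement of center and radius and a +0.5 px
#' radius correction for the half-pixel inward bias of boundary pixels.
#'
#' @param patch Hirschberg `eye_patch`.
#' @param mask region-of-interest mask from [build_roi_mask()].
#' @param radius_frac radius search range as fractions of the eye-corner
#'   distance.
#' @param min_support minimum peak votes for a valid detection.
#' @param max_edge_points cap on edge points (evenly subsampled beyond it).
#' @return object of class `limbus_circle`: `center` (patch coords),
#'   `radius`, `score` (peak votes), `source = "hirschberg"`, `threshold`.
#' @export
detect_limbus_hirschberg <- function(patch, mask, radius_frac = c(0.15, 0.45),
                                     min_support = 20, max_edge_points = 900) {
  img <- patch$img
  h <- dim(img)[1]; w <- dim(img)[2]
  gray <- floor(clamp(img_gray(img), 0, 255))
  if (!any(mask)) {
    ps_stop("limbus detection failed: empty region of interest", "limbus",
            class = "ps_detection_error")
  }
  counts <- tabulate(gray[mask] + 1L, nbins = 256L)
  thr <- tryCatch(isodata_threshold(counts), ps_detection_error = function(e) {
    ps_stop("limbus detection failed: region has no intensity contrast",
            "limbus", class = "ps_detection_error")
  })
  dark <- mask & gray <= thr
  pts <- boundary_points(dark)
  if (nrow(pts) > max_edge_points) {
    keep <- unique(round(seq(1, nrow(pts), length.out = max_edge_points)))
    pts <- pts[keep, , drop = FALSE]
  }
  cd <- patch$corner_distance
  radii <- seq(max(3L, round(radius_frac[1] * cd)),
               max(4L, round(radius_frac[2] * cd)))
  if (nrow(pts) < 3) {
    ps_stop("limbus detection failed: too few edge points", "limbus",
            class = "ps_detection_error")
  }
  res <- cpp_hough_arc(as.integer(pts[, "x"]), as.integer(pts[, "y"]),
                       as.integer(w), as.integer(h), as.integer(radii))
  if (res[4] < min_support) {
    ps_stop(sprintf(
      "limbus detection failed: peak support %d below minimum %d",
      as.integer(res[4]), min_support), "limbus",
      class = "ps_detection_error")
  }
  fit <- refine_circle_fit(pts, center = c(res[5], res[6]), radius = res[7])
  structure(list(center = fit$center, radius = fit$radius + 0.5,
                 score = res[4], source = "hirschberg", threshold = thr),
            class = "limbus_circle")
}

#' Refine the limbus on the photorefraction frame by contrast maximization
#'
#' Keeps the radius found on the Hirschberg still (searching a +/-10%
#' tolerance band) and moves the center within a window to maximize contour
#' contrast: mean intensity over an outer annulus `[r, 1.15 r]` minus mean
#' over an inner annulus `[0.85 r, r)`, both restricted to the +/-45 degree
#' left/right arcs. The peak gets a parabolic sub-pixel refinement.
#'
#' @param patch red-reflex `eye_patch` of the same eye.
#' @param prior `limbus_circle` from the Hirschberg image.
#' @param window half-width of the center search window, px.
#' @return `limbus_circle` with `score` = contrast and
#'   `source = "photorefraction"`.
#' @export
refine_limbus_photorefraction <- function(patch, prior, window = 8) {
  gray <- img_gray(patch$img)
  cx0 <- round(prior$center[1]); cy0 <- round(prior$center[2])
  radii <- prior$radius * c(0.90, 0.95, 1.00, 1.05, 1.10)
  best <- NULL
  for (r in radii) {
    cm <- cpp_contrast_map(gray, as.integer(cx0), as.integer(cy0), r,
                           as.integer(window))
    if (all(is.na(cm))) next
    v <- max(cm, na.rm = TRUE)
    idx <- which(cm == v, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # smaller y, then x
    cand <- list(contrast = v, row = idx[1], col = idx[2], r = r, map = cm)
    if (is.null(best) || v > best$contrast ||
        (v == best$contrast && r > best$r)) {
      best <- cand
    }
  }
  if (is.null(best) || !is.finite(best$contrast) || best$contrast <= 0) {
    ps_stop("photorefraction limbus refinement failed: no positive contrast",
            "limbus", class = "ps_detection_error")
  }
  # parabolic sub-pixel refinement on the contrast surface
  refine1 <- function(cm, i, j, along) {
    c0 <- cm[i, j]
    if (along == "x") {
      if (j <= 1 || j >= ncol(cm)) return(0)
      cm1 <- cm[i, j - 1]; cp1 <- cm[i, j + 1]
    } else {
      if (i <= 1 || i >= nrow(cm)) return(0)
      cm1 <- cm[i - 1, j]; cp1 <- cm[i + 1, j]
    }
    if (anyNA(c(cm1, cp1))) return(0)
    den <- cm1 - 2 * c0 + cp1
    if (den >= 0) return(0)                # not a local max
    clamp(0.5 * (cm1 - cp1) / den, -0.5, 0.5)
  }
  dx <- refine1(best$map, best$row, best$col, "x")
  dy <- refine1(best$map, best$row, best$col, "y")
  center <- c(cx0 + (best$col - window - 1) + dx,
              cy0 + (best$row - window - 1) + dy)
  structure(list(center = center, radius = best$r, score = best$contrast,
                 source = "photorefraction", threshold = NA_integer_),
            class = "limbus_circle")
}

#' Detect the corneal luminous reflection spot
#'
#' Candidate pixels inside the limbus disk are those whose minimum channel
#' value is within `tol` of the disk-wide maximum of the minimum channel
#' (a cluster of maximal intensity across all channels) and at least
#' `min_intensity`; the largest 4-connected component is kept (size ties
#' broken by topmost, then leftmost centroid) and summarised by its largest
#' inscribed circle.
#'
#' @param patch Hirschberg `eye_patch`.
#' @param limbus `limbus_circle` for the same patch.
#' @param tol intensity tolerance as a fraction of the dynamic range.
#' @param min_intensity absolute floor for a pixel to count as a flash
#'   reflection.
#' @return object of class `clr_spot`: `center` (sub-pixel, patch coords),
#'   `radius`, `n`, `pixels` (n x 2, 0-based).
#' @export
detect_clr <- function(patch, limbus, tol = 0.02, min_intensity = 128) {
  img <- patch$img
  h <- dim(img)[1]; w <- dim(img)[2]
  g <- pixel_grid(h, w)
  disk <- (g$x - limbus$center[1])^2 + (g$y - limbus$center[2])^2 <=
    limbus$radius^2
  if (!any(disk)) {
    ps_stop("corneal reflection detection failed: empty limbus disk", "clr",
            class = "ps_detection_error")
  }
  minch <- pmin(img[, , 1], img[, , 2], img[, , 3])
  mx <- max(minch[disk])
  cand <- disk & minch >= mx - tol * 255 & minch >= min_intensity
  if (!any(cand)) {
    ps_stop("corneal reflection detection failed: no flash reflection inside the limbus",
            "clr", class = "ps_detection_error")
  }
  lab <- cpp_label_components(cand, 4L)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  best_size <- max(sizes)
  tied <- which(sizes == best_size)
  if (length(tied) > 1) {
    cent <- t(vapply(tied, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      c(mean(idx[, 1]), mean(idx[, 2]))          # (y, x)
    }, numeric(2)))
    tied <- tied[order(cent[, 1], cent[, 2])]
  }
  comp <- which(lab == tied[1], arr.ind = TRUE)
  xs <- comp[, 2] - 1L; ys <- comp[, 1] - 1L
  ic <- inscribed_circle(xs, ys)
  structure(list(center = ic$center, radius = ic$radius, n = length(xs),
                 pixels = cbind(x = xs, y = ys)),
            class = "clr_spot")
}

# Horizontal (flash-axis) extent of a retained crescent pixel set, in px.
# The integer pixel extent (max - min + 1) is quantized to the pixel pitch;
# both extremes are therefore refined to sub-pixel positions by locating the
# midpoint crossing of the brightness profile across the edge (standard
# intensity-based edge localisation). Falls back to the pixel extent for
# very thin sets or featureless profiles.
crescent_extent <- function(bright, xs, ys) {
  x_min <- min(xs); x_max <- max(xs)
  pixel_extent <- x_max - x_min + 1
  if (pixel_extent < 5) return(pixel_extent)
  h <- nrow(bright); w <- ncol(bright)
  refine <- function(x0, dir) {
    # brightness profile across the edge, averaged over the rows the
    # crescent occupies just inside this extreme
    rows <- unique(ys[xs == x0 + dir])
    if (length(rows) < 2) rows <- unique(ys[xs == x0])
    cols <- (x0 - 2 * dir):(x0 + 2 * dir)
    cols <- cols[cols >= 0 & cols <= w - 1]
    prof <- vapply(cols, function(x) mean(bright[rows + 1, x + 1]), numeric(1))
    b_in <- prof[match(x0 + 2 * dir, cols)]
    b_out <- prof[match(x0 - 2 * dir, cols)]
    if (is.na(b_in) || is.na(b_out) || abs(b_in - b_out) < 10) return(NA_real_)
    target <- (b_in + b_out) / 2
    s <- prof - target
    cross <- which(s[-1] * s[-length(s)] <= 0)
    if (length(cross) == 0) return(NA_real_)
    k <- cross[which.min(abs(cols[cross] - x0))]
    cols[k] + (0 - s[k]) / (s[k + 1] - s[k]) * (cols[k + 1] - cols[k])
  }
  e_min <- refine(x_min, +1L)
  e_max <- refine(x_max, -1L)
  if (is.na(e_min) || is.na(e_max) || e_max <= e_min) return(pixel_extent)
  e_max - e_min
}

#' Detect and measure the red reflex crescent
#'
#' Inside the limbus disk (excluding the corneal-reflection component), raw
#' crescent pixels are those with (a) the red channel brighter than green
#' and blue combined AND (b) brightness, `(R+G+B)/3`, more than twice the
#' median brightness of the limbus-disk pixels - or with a saturated red
#' channel. Components smaller than `min_component` pixels are discarded.
#' The retained set is summarised by its minimum-area enclosing ellipse
#' (circumscribed oval); the reported width is `alpha` times the extent of
#' the pixel set along the horizontal flash-displacement axis, with both
#' extremes localised to sub-pixel precision from the brightness profile
#' across the edge. The crescent
#' side is `"toward_flash"` when the pixel centroid lies on the flash side
#' of the limbus center (examiner's view). When the retained area reaches
#' `full_pupil_frac` of the limbus disk the pupil counts as fully lit and
#' the width is reported as the limbus diameter in mm.
#'
#' @param patch red-reflex `eye_patch`.
#' @param limbus refined `limbus_circle` for this patch.
#' @param clr `clr_spot` whose component is excluded (or NULL).
#' @param scale a `scale_calibration` (or any list with `alpha`).
#' @param flash_side `"left"` or `"right"` (examiner's view).
#' @param min_component minimum component size in pixels.
#' @param full_pupil_frac fully-lit-pupil area fraction of the limbus disk.
#' @return object of class `crescent`: `width_mm`, `side`, `full_pupil`,
#'   `n`, `ellipse`, `pixels`. An empty retained set is a valid crescent
#'   with width 0 and side `"none"`.
#' @export
detect_crescent <- function(patch, limbus, clr, scale,
                            flash_side = c("left", "right"),
                            min_component = 5, full_pupil_frac = 0.7) {
  flash_side <- match.arg(flash_side)
  ps_validate(scale$alpha > 0, "scale alpha must be positive", "crescent")
  img <- patch$img
  h <- dim(img)[1]; w <- dim(img)[2]
  g <- pixel_grid(h, w)
  disk <- (g$x - limbus$center[1])^2 + (g$y - limbus$center[2])^2 <=
    limbus$radius^2
  excl <- matrix(FALSE, h, w)
  if (!is.null(clr) && nrow(clr$pixels) > 0) {
    inb <- clr$pixels[, "x"] >= 0 & clr$pixels[, "x"] < w &
      clr$pixels[, "y"] >= 0 & clr$pixels[, "y"] < h
    excl[cbind(clr$pixels[inb, "y"] + 1L, clr$pixels[inb, "x"] + 1L)] <- TRUE
  }
  base <- disk & !excl
  empty <- new_crescent(0, "none", FALSE, 0L)
  if (!any(base)) return(empty)
  R <- img[, , 1]; G <- img[, , 2]; B <- img[, , 3]
  bright <- (R + G + B) / 3
  med <- median(bright[base])
  raw <- base & ((R > G + B & bright > 2 * med) | R >= 255)
  if (!any(raw)) return(empty)
  lab <- cpp_label_components(raw, 4L)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_component)
  if (length(keep) == 0) return(empty)
  sel <- lab > 0 & matrix(lab %in% keep, h, w)
  idx <- which(sel, arr.ind = TRUE)
  xs <- idx[, 2] - 1L; ys <- idx[, 1] - 1L
  n <- length(xs)
  full <- n >= full_pupil_frac * pi * limbus$radius^2
  width <- if (full) scale$alpha * 2 * limbus$radius
           else scale$alpha * crescent_extent(bright, xs, ys)
  centroid_x <- mean(xs)
  on_left <- centroid_x < limbus$center[1]
  side <- if (on_left == (flash_side == "left")) "toward_flash" else "away_from_flash"
  ell <- min_enclosing_ellipse(cbind(xs, ys))
  new_crescent(width, side, full, n, ellipse = ell, pixels = cbind(x = xs, y = ys))
}
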
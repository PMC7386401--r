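# Independent brute-force oracles used to validate the package's operators.

# All fixed points of the clamped IsoData update, found by exhaustive search
# over every admissible threshold.
bf_isodata_fixed_points <- function(counts) {
  lev <- 0:255
  occ <- lev[counts > 0]
  lo <- min(occ); hi <- max(occ)
  fp <- integer(0)
  for (t in lo:(hi - 1)) {
    below <- lev <= t
    m1 <- weighted.mean(lev[below], counts[below])
    m2 <- weighted.mean(lev[!below], counts[!below])
    tn <- min(max(floor((m1 + m2) / 2 + 0.5), lo), hi - 1)
    if (tn == t) fp <- c(fp, t)
  }
  fp
}

# Brute-force largest inscribed circle: every component pixel is a candidate
# center; its radius is the minimum distance to any non-component pixel in a
# generously padded bounding box. Plateau ties resolved by centroid, as the
# implementation defines.
bf_inscribed_circle <- function(xs, ys) {
  pad <- 2L
  gx <- (min(xs) - pad):(max(xs) + pad)
  gy <- (min(ys) - pad):(max(ys) + pad)
  all_pts <- expand.grid(x = gx, y = gy)
  in_comp <- paste(all_pts$x, all_pts$y) %in% paste(xs, ys)
  bg <- all_pts[!in_comp, ]
  dmin <- vapply(seq_along(xs), function(i) {
    sqrt(min((bg$x - xs[i])^2 + (bg$y - ys[i])^2))
  }, numeric(1))
  r <- max(dmin)
  plateau <- which(dmin > r - 1e-9)
  list(center = c(mean(xs[plateau]), mean(ys[plateau])), radius = r)
}

# Random 4-connected pixel blob grown from a seed pixel, within a size x
# size grid (0-based coordinates). The target size is capped at half the
# grid so growth always has room and terminates.
random_blob <- function(size = 20, n_target = 40) {
  n_target <- min(n_target, floor(size^2 / 2))
  start <- c(sample.int(size, 1) - 1L, sample.int(size, 1) - 1L)
  pts <- matrix(start, ncol = 2)
  keyset <- paste(start[1], start[2])
  while (nrow(pts) < n_target) {
    i <- sample.int(nrow(pts), 1)
    step <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))[sample.int(4, 1), ]
    cand <- pts[i, ] + step
    if (any(cand < 0) || any(cand >= size)) next
    key <- paste(cand[1], cand[2])
    if (key %in% keyset) next
    pts <- rbind(pts, cand)
    keyset <- c(keyset, key)
  }
  pts
}

# Direct R computation of the arc-restricted annulus contrast at one circle.
bf_contrast <- function(gray, cx, cy, r) {
  H <- nrow(gray); W <- ncol(gray)
  span <- ceiling(1.15 * r)
  si <- so <- 0; ni <- no <- 0
  for (dy in -span:span) for (dx in -span:span) {
    if (abs(dy) > abs(dx)) next
    x <- cx + dx; y <- cy + dy
    if (x < 0 || x >= W || y < 0 || y >= H) next
    d <- sqrt(dx^2 + dy^2)
    if (d >= 0.85 * r && d < r) { si <- si + gray[y + 1, x + 1]; ni <- ni + 1 }
    else if (d >= r && d <= 1.15 * r) { so <- so + gray[y + 1, x + 1]; no <- no + 1 }
  }
  so / no - si / ni
}

# Random histogram with a controllable number of occupied bins.
random_histogram <- function() {
  k <- sample(2:40, 1)
  bins <- sample.int(256, k) - 1L
  counts <- integer(256)
  counts[bins + 1L] <- sample.int(500, k, replace = TRUE)
  counts
}
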
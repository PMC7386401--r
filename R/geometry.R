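# Discrete and continuous geometry primitives shared by the segmentation
# operators.

#' Largest inscribed circle of a pixel component
#'
#' Finds the circle of maximal radius centred on the component whose interior
#' contains no background pixel, using the discrete distance-to-background
#' definition: the radius at a candidate center is the minimum Euclidean
#' distance from that pixel to any pixel outside the component. When several
#' pixels attain the maximal distance (a distance-transform plateau, e.g. at
#' the center of a symmetric spot) the reported center is the centroid of the
#' plateau, which gives sub-pixel localisation.
#'
#' @param xs,ys integer pixel coordinates of the component (0-based).
#' @return list with `center` (length-2, sub-pixel), `radius`, `n`.
#' @export
inscribed_circle <- function(xs, ys) {
  ps_validate(length(xs) >= 1 && length(xs) == length(ys),
              "inscribed_circle needs a non-empty pixel set")
  x0 <- min(xs) - 1L; y0 <- min(ys) - 1L
  w <- max(xs) - x0 + 2L; h <- max(ys) - y0 + 2L
  m <- matrix(FALSE, h, w)
  m[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- TRUE

  # Background pixels 4-adjacent to the component. The nearest background
  # pixel to any component pixel is always in this set (stepping from it
  # toward the query pixel must enter the component, else a closer
  # background pixel would exist).
  shift <- function(mm, dy, dx) {
    out <- matrix(FALSE, h, w)
    ys2 <- seq_len(h) + dy; xs2 <- seq_len(w) + dx
    ok_y <- ys2 >= 1 & ys2 <= h; ok_x <- xs2 >= 1 & xs2 <= w
    out[ok_y, ok_x] <- mm[ys2[ok_y], xs2[ok_x]]
    out
  }
  near_comp <- shift(m, 1, 0) | shift(m, -1, 0) | shift(m, 0, 1) | shift(m, 0, -1)
  adj <- which(!m & near_comp, arr.ind = TRUE)
  comp <- cbind(xs, ys)
  bx <- adj[, 2] + x0 - 1L; by <- adj[, 1] + y0 - 1L
  d2 <- outer(comp[, 1], bx, "-")^2 + outer(comp[, 2], by, "-")^2
  dmin <- sqrt(apply(d2, 1, min))
  r <- max(dmin)
  plateau <- which(dmin > r - 1e-9)
  list(center = c(mean(comp[plateau, 1]), mean(comp[plateau, 2])),
       radius = r, n = length(xs))
}

#' Minimum-area enclosing ellipse of a point set
#'
#' Computes the Loewner-John ellipse of the convex hull by Khachiyan's
#' iterative reweighting, then rescales so every point is contained exactly.
#' Degenerate sets (a single point or collinear points) yield a degenerate
#' ellipse with zero minor axis.
#'
#' @param pts n x 2 matrix of (x, y) points.
#' @param tol convergence tolerance of the Khachiyan iteration.
#' @return list with `center`, `semi_major`, `semi_minor`, `angle_deg`
#'   (orientation of the major axis), and the shape matrix `A` such that the
#'   ellipse is `(p - center)' A (p - center) <= 1` (NULL when degenerate).
#' @export
min_enclosing_ellipse <- function(pts, tol = 1e-7) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  ps_validate(nrow(pts) >= 1, "min_enclosing_ellipse needs at least one point")
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1) {
    return(list(center = pts[1, ], semi_major = 0, semi_minor = 0,
                angle_deg = 0, A = NULL))
  }
  # rank check for collinearity
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (n == 2 || sv[2] < 1e-9 * max(sv[1], 1)) {
    dirv <- svd(sweep(pts, 2, ctr))$v[, 1]
    proj <- as.vector(sweep(pts, 2, ctr) %*% dirv)
    mid <- ctr + dirv * (max(proj) + min(proj)) / 2
    return(list(center = mid, semi_major = (max(proj) - min(proj)) / 2,
                semi_minor = 0,
                angle_deg = rad2deg(atan2(dirv[2], dirv[1])), A = NULL))
  }
  hull <- chull(pts[, 1], pts[, 2])
  P <- pts[hull, , drop = FALSE]
  m <- nrow(P); d <- 2
  Q <- t(cbind(P, 1))                     # 3 x m
  u <- rep(1 / m, m)
  for (it in seq_len(5000)) {
    X <- Q %*% (u * t(Q))
    Mdiag <- colSums(Q * solve(X, Q))
    j <- which.max(Mdiag)
    step <- (Mdiag[j] - d - 1) / ((d + 1) * (Mdiag[j] - 1))
    if (!is.finite(step) || step < tol) break
    u <- u * (1 - step)
    u[j] <- u[j] + step
  }
  center <- as.vector(t(P) %*% u)
  S <- t(P) %*% (u * P) - center %o% center
  A <- solve(S) / d
  # rescale so the farthest point lies exactly on the ellipse
  dev <- sweep(pts, 2, center)
  q <- rowSums((dev %*% A) * dev)
  A <- A / max(q)
  e <- eigen(A, symmetric = TRUE)
  axes <- 1 / sqrt(e$values)              # e$values descending -> axes ascending
  major_vec <- e$vectors[, which.min(e$values)]
  list(center = center, semi_major = max(axes), semi_minor = min(axes),
       angle_deg = rad2deg(atan2(major_vec[2], major_vec[1])), A = A)
}

# Point-in-ellipse test used by tests and the crescent summary.
ellipse_contains <- function(ell, pts, slack = 1e-7) {
  if (is.null(ell$A)) return(rep(TRUE, nrow(pts)))
  dev <- sweep(matrix(as.numeric(pts), ncol = 2), 2, ell$center)
  rowSums((dev %*% ell$A) * dev) <= 1 + slack
}

# Area of the circular segment of depth `depth` cut from a disk of radius r
# by a vertical chord (used for crescent ground-truth area).
segment_area <- function(r, depth) {
  depth <- clamp(depth, 0, 2 * r)
  h <- r - depth
  r^2 * acos(h / r) - h * sqrt(pmax(r^2 - h^2, 0))
}
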
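#' @useDynLib photoscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif weighted.mean setNames
#' @importFrom utils read.csv write.csv
#' @importFrom grDevices rgb2hsv chull
"_PACKAGE"

# Structured error helper. `stage` names the pipeline stage that failed so
# batch runs can report where a case broke; `class` distinguishes validation
# from detection failures.
ps_stop <- function(message, stage, class = "ps_error", data = list()) {
  cond <- structure(
    c(list(message = message, call = NULL, stage = stage), data),
    class = unique(c(class, "ps_error", "error", "condition"))
  )
  stop(cond)
}

ps_validate <- function(ok, message, stage = "validate") {
  if (!isTRUE(ok)) ps_stop(message, stage, class = "ps_validation_error")
  invisible(TRUE)
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# 2x2 rotation matrix; positive angle rotates (x, y) counterclockwise in the
# mathematical sense. With image coordinates (x right, y down) this appears
# clockwise on screen; all package code uses this one convention.
rot_mat <- function(deg) {
  t <- deg2rad(deg)
  matrix(c(cos(t), sin(t), -sin(t), cos(t)), 2, 2)
}

# Apply `rot_mat(deg)` to an n x 2 matrix of points about a pivot.
rotate_points <- function(pts, deg, pivot = c(0, 0)) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  R <- rot_mat(deg)
  sweep(sweep(pts, 2, pivot) %*% t(R), 2, pivot, "+")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
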
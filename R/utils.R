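#' @keywords internal
"_PACKAGE"

## Spatial coordinates live on the torus [-1, 1) in both axes; one spatial
## period is 2 units, so a nominal speed of 1 corresponds to 2 units/s.

#' Wrap coordinates onto the periodic domain [-1, 1)
#'
#' @param x Numeric vector of coordinates.
#' @return Values wrapped into `[-1, 1)` by modular arithmetic.
#' @export
#' @examples
#' wrap_torus(1.15)   # -0.85
wrap_torus <- function(x) {
  ((x + 1) %% 2) - 1
}

## Signed wrapped difference a - b on the torus, in [-1, 1)
torus_diff <- function(a, b) {
  wrap_torus(a - b)
}

#' Weighted circular mean on the torus
#'
#' Positions on `[-1, 1)` are mapped to angles, averaged as unit vectors and
#' mapped back, so estimates near the domain edge are not corrupted by
#' wrap-around.
#'
#' @param x Positions in `[-1, 1)`.
#' @param w Non-negative weights (recycled/normalised internally).
#' @return The circular mean position in `[-1, 1)`.
#' @export
circ_mean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  th <- pi * (x + 1)
  m <- atan2(sum(w * sin(th)), sum(w * cos(th)))
  wrap_torus(m / pi - 1)
}

#' Weighted circular-aware standard deviation on the torus
#'
#' Deviations are taken from the weighted circular mean and wrapped before the
#' usual weighted second moment is formed. For a distribution much narrower
#' than the period this coincides with the linear SD; for the uniform
#' distribution on `[-1, 1)` it returns `2/sqrt(12)`.
#'
#' @inheritParams circ_mean
#' @return A single non-negative number (space units).
#' @export
circ_sd <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  w <- w / sum(w)
  mu <- circ_mean(x, w)
  d <- torus_diff(x, mu)
  sqrt(sum(w * d^2))
}

## Evaluate a function under a temporary, seeded RNG state; the caller's
## global RNG stream is left untouched.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

## Bilinear interpolation of a periodic matrix (values at pixel centers
## xg[i] = -1 + (i - 0.5) * 2/nx) at arbitrary torus coordinates.
interp_torus <- function(m, x, y) {
  nx <- nrow(m)
  ny <- ncol(m)
  px <- (x + 1) * nx / 2 + 0.5   # fractional pixel index, 1-based
  py <- (y + 1) * ny / 2 + 0.5
  i0 <- floor(px)
  j0 <- floor(py)
  fx <- px - i0
  fy <- py - j0
  i0 <- ((i0 - 1) %% nx) + 1
  j0 <- ((j0 - 1) %% ny) + 1
  i1 <- (i0 %% nx) + 1
  j1 <- (j0 %% ny) + 1
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i1, j0)] * fx * (1 - fy) +
    m[cbind(i0, j1)] * (1 - fx) * fy +
    m[cbind(i1, j1)] * fx * fy
}

## Pixel center coordinates for an n-pixel axis over [-1, 1)
pixel_centers <- function(n) {
  -1 + (seq_len(n) - 0.5) * 2 / n
}
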
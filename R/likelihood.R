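#' A pair of consecutive frames
#'
#' @param prev,cur Two grayscale frames (matrices of identical dimension).
#' @param delta_t Time between the frames, seconds (`> 0`).
#' @return An object of class `fle_frame_pair`.
#' @export
frame_pair <- function(prev, cur, delta_t) {
  if (!identical(dim(prev), dim(cur)))
    stop("frames must have identical dimensions")
  stopifnot(delta_t > 0)
  structure(list(prev = prev, cur = cur, delta_t = delta_t),
            class = "fle_frame_pair")
}

## Matched-filter amplitude map: circular cross-correlation of a frame with
## the dot template (Gaussian blob, sd = dot_size/2), normalised by the
## template energy E = sum(b^2). amp_map(f)[i, j] estimates the amplitude of
## a blob centered at pixel (i, j); torus periodicity is exact by
## construction. E (attribute "energy") sets the amplitude-noise scale
## sigma_noise/sqrt(E) of the estimate.
amp_map <- function(frame, dot_size) {
  nx <- nrow(frame); ny <- ncol(frame)
  b <- blob_image(pixel_centers(nx)[1], pixel_centers(ny)[1], nx, ny,
                  dot_size / 2)
  E <- sum(b^2)
  num <- Re(stats::fft(stats::fft(frame) * Conj(stats::fft(b)),
                       inverse = TRUE)) / (nx * ny)
  structure(num / E, energy = E)
}

## Log-evidence for states (x, y, u, v) given amplitude maps.
## a_cur is read at (x, y); a_prev at the back-transported (x - u dt, y - v dt)
## (bilinear on the torus). When a long-baseline map `a_long` (the frame
## `L_frames` steps earlier) is supplied, a third matched-filter term is read
## at (x - u L dt, y - v L dt): motion-energy detectors have extended
## temporal support, and over one frame step the displacement u dt is far
## smaller than the dot profile, so the longer baseline is what makes the
## velocity identifiable against the slow-speed prior.
loglik_states <- function(a_prev, a_cur, x, y, u, v, delta_t,
                          sigma_I, sigma_noise,
                          a_long = NULL, L_frames = 0,
                          a_mid = NULL, M_frames = 0) {
  E <- attr(a_cur, "energy") %||% 1
  ac <- interp_torus(a_cur, x, y)
  ap <- interp_torus(a_prev, wrap_torus(x - u * delta_t),
                     wrap_torus(y - v * delta_t))
  ## reward: matched-filter evidence along the hypothesised trajectory;
  ## penalty: brightness-constancy residual projected on the template
  ## subspace, at the amplitude-noise scale sigma_noise/sqrt(E) (each of the
  ## two amplitude estimates carries variance sigma_noise^2/E)
  lw <- (ac + ap) / (2 * sigma_I^2) -
    E * (ac - ap)^2 / (4 * sigma_noise^2)
  if (!is.null(a_mid) && M_frames > 0) {
    am <- interp_torus(a_mid, wrap_torus(x - u * M_frames * delta_t),
                       wrap_torus(y - v * M_frames * delta_t))
    lw <- lw + am / (2 * sigma_I^2)
  }
  if (!is.null(a_long) && L_frames > 0) {
    al <- interp_torus(a_long, wrap_torus(x - u * L_frames * delta_t),
                       wrap_torus(y - v * L_frames * delta_t))
    lw <- lw + al / (2 * sigma_I^2)
  }
  lw
}

#' Motion-energy likelihood of a state given two consecutive frames
#'
#' Sensory evidence for a candidate state `z = (x, y, u, v)` is computed from
#' template matched-filter (motion-energy) responses: each frame is correlated
#' with the known dot profile, yielding an amplitude estimate `a(x, y)`; the
#' state reads `a_cur` at its position and `a_prev` at the position
#' back-transported by its velocity (`(x - u dt, y - v dt)`, bilinear on the
#' torus). The unnormalised weight is
#' \deqn{w = \exp\left(\frac{a_{cur} + a_{prev}}{2\sigma_I^2}
#'   - \frac{(a_{cur} - a_{prev})^2}{2\sigma_{noise}^2}\right) + 10^{-12}.}
#' The first term rewards oriented space-time evidence (a blob present at the
#' claimed position, moving at the claimed velocity); the second is the
#' brightness-constancy residual projected onto the template subspace, which
#' penalises states whose claimed object appears in only one of the two frames
#' (onsets, offsets, disappearance). `sigma_I` sets the evidence gain (and
#' hence the integration time of the filter); `sigma_noise` the tolerance on
#' inter-frame amplitude constancy. The additive floor keeps weights strictly
#' positive.
#'
#' @param pair A [frame_pair()].
#' @param z State: a numeric vector `c(x, y, u, v)` or a data frame with
#'   columns `x`, `y`, `u`, `v` (vectorised).
#' @param sigma_I,sigma_noise Likelihood scales (see above), both `> 0`.
#' @param dot_size Template radius in space units (sd `dot_size / 2`).
#' @return Non-negative finite weight(s), one per state.
#' @export
likelihood_weight <- function(pair, z, sigma_I = 0.25, sigma_noise = 0.05,
                              dot_size = 0.05) {
  stopifnot(inherits(pair, "fle_frame_pair"), sigma_I > 0, sigma_noise > 0)
  if (is.numeric(z) && is.null(dim(z))) {
    z <- tibble::tibble(x = z[1], y = z[2], u = z[3], v = z[4])
  }
  if (any(!is.finite(c(z$u, z$v)))) stop("velocities must be finite")
  a_prev <- amp_map(pair$prev, dot_size)
  a_cur <- amp_map(pair$cur, dot_size)
  lw <- loglik_states(a_prev, a_cur, z$x, z$y, z$u, z$v, pair$delta_t,
                      sigma_I, sigma_noise)
  exp(pmin(lw, 700)) + 1e-12
}

#' Evaluate the likelihood over a grid of candidate states
#'
#' Elementwise application of [likelihood_weight()]; deterministic for fixed
#' inputs. Weights are returned both raw and normalised.
#'
#' @param pair A [frame_pair()].
#' @param grid Data frame of candidate states with columns `x`, `y`, `u`, `v`.
#' @param params An [model_params()] object supplying `sigma_I`,
#'   `sigma_noise`.
#' @param dot_size Template radius in space units.
#' @return A tibble (`class fle_likelihood_field`): the grid plus columns
#'   `log_weight` and `weight` (normalised to sum to 1).
#' @export
likelihood_field <- function(pair, grid, params = model_params(),
                             dot_size = 0.05) {
  if (NROW(grid) == 0) stop("grid must be non-empty")
  a_prev <- amp_map(pair$prev, dot_size)
  a_cur <- amp_map(pair$cur, dot_size)
  lw <- loglik_states(a_prev, a_cur, grid$x, grid$y, grid$u, grid$v,
                      pair$delta_t, params$sigma_I, params$sigma_noise)
  w <- exp(lw - max(lw)) + 1e-12
  out <- tibble::as_tibble(grid[c("x", "y", "u", "v")])
  out$log_weight <- lw
  out$weight <- w / sum(w)
  class(out) <- c("fle_likelihood_field", class(out))
  out
}
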
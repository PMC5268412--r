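#' Construct a weighted particle ensemble
#'
#' An ensemble is a tibble of particles (`x`, `y`, `u`, `v`) with normalised
#' weights `w`, representing the posterior over the state of one stimulus at
#' one frame. Attributes `frame_index` and `layer` (`"source"`, `"target"` or
#' `"smoothed"`) tag where in the filter it came from.
#'
#' @param states Data frame with columns `x`, `y`, `u`, `v`.
#' @param weights Non-negative weights; normalised to sum to 1.
#' @param frame_index Integer frame tag.
#' @param layer `"source"`, `"target"` or `"smoothed"`.
#' @return A tibble of class `fle_ensemble`.
#' @export
particle_ensemble <- function(states, weights = NULL,
                              frame_index = NA_integer_,
                              layer = c("source", "target", "smoothed")) {
  layer <- match.arg(layer)
  n <- nrow(states)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (any(weights < 0) || !all(is.finite(weights)))
    stop("weights must be finite and non-negative")
  s <- sum(weights)
  if (s <= 0) stop("degenerate ensemble: total weight is zero")
  out <- tibble::tibble(x = wrap_torus(states$x), y = wrap_torus(states$y),
                        u = states$u, v = states$v, w = weights / s)
  attr(out, "frame_index") <- as.integer(frame_index)
  attr(out, "layer") <- layer
  class(out) <- c("fle_ensemble", class(out))
  out
}

## Draw n particles from the pre-data prior: uniform position on the torus,
## velocities from the slow-speed prior N(0, sigma_p^2). Birth draws (the
## recruitment component during filtering) use the stationary velocity
## distribution of the transition kernel instead — a newly appearing object
## is hypothesised at the kernel's equilibrium speeds, which is what lets an
## unexpected static flash be captured.
prior_draw <- function(n, params, birth = FALSE) {
  sd_v <- params$sigma_p
  if (birth) {
    vv <- transition_noise_vars(params, params$delta_t)[["var_v"]]
    if (params$gamma < 1) sd_v <- sqrt(vv / (1 - params$gamma^2))
  }
  tibble::tibble(
    x = stats::runif(n, -1, 1), y = stats::runif(n, -1, 1),
    u = stats::rnorm(n, 0, sd_v), v = stats::rnorm(n, 0, sd_v)
  )
}

init_ensemble <- function(params, frame_index = 1L) {
  particle_ensemble(prior_draw(params$n_particles, params),
                    frame_index = frame_index, layer = "source")
}

#' Effective sample size of an ensemble
#' @param ens An [particle_ensemble()].
#' @return `1 / sum(w^2)`, between 1 and the particle count.
#' @export
ess <- function(ens) 1 / sum(ens$w^2)

## Systematic (stratified, variance-minimising) resampling, with a small
## roughening kernel (regularised particle filter) so that freshly cloned
## particles do not masquerade as a high-precision posterior: positions are
## jittered by half a read-out bin, velocities by a comparable fraction of
## their per-frame diffusion.
resample_systematic <- function(ens, jitter_x = 0.02, jitter_v = 0.1) {
  n <- nrow(ens)
  pts <- (stats::runif(1) + seq_len(n) - 1) / n
  idx <- findInterval(pts, cumsum(ens$w)) + 1L
  idx[idx > n] <- n
  st <- ens[idx, c("x", "y", "u", "v")]
  if (jitter_x > 0) {
    st$x <- st$x + stats::rnorm(n, 0, jitter_x)
    st$y <- st$y + stats::rnorm(n, 0, jitter_x)
  }
  if (jitter_v > 0) {
    st$u <- st$u + stats::rnorm(n, 0, jitter_v)
    st$v <- st$v + stats::rnorm(n, 0, jitter_v)
  }
  particle_ensemble(st, frame_index = attr(ens, "frame_index"),
                    layer = attr(ens, "layer"))
}

## Shared transport step; `recruit` is the per-particle probability of being
## redrawn from the prior (birth component of the transition mixture) and
## `rejuvenate` of redrawing only the velocity from the slow-speed prior.
pf_step <- function(ens, dt, params, recruit = 0, rejuvenate = 0) {
  st <- transition_sample(ens[c("x", "y", "u", "v")], dt, params)
  if (rejuvenate > 0) {
    rj <- stats::runif(nrow(st)) < rejuvenate
    if (any(rj)) {
      st$u[rj] <- stats::rnorm(sum(rj), 0, params$sigma_p)
      st$v[rj] <- stats::rnorm(sum(rj), 0, params$sigma_p)
    }
  }
  if (recruit > 0) {
    born <- stats::runif(nrow(st)) < recruit
    if (any(born)) st[born, ] <- prior_draw(sum(born), params, birth = TRUE)
  }
  particle_ensemble(st, ens$w, frame_index = attr(ens, "frame_index"),
                    layer = attr(ens, "layer"))
}

#' Prediction step of the particle filter
#'
#' Advances every particle by one draw from the transition kernel over `dt`
#' (see [transition_sample()]); weights are unchanged. With probability
#' `params$recruit` a particle is instead redrawn from the pre-data prior,
#' modelling the possibility that a new object has appeared.
#'
#' @param ens A [particle_ensemble()].
#' @param dt Time step in seconds.
#' @param params An [model_params()] object.
#' @return The advanced ensemble.
#' @export
pf_predict <- function(ens, dt, params) {
  pf_step(ens, dt, params, recruit = params$recruit,
          rejuvenate = params$rejuvenate)
}

#' Delay-compensating extrapolation step
#'
#' One transition-kernel step of size `dt` per particle with weights
#' unchanged: `dt = +tau` pushes the delayed posterior forward to the present
#' (the delay compensation), negative `dt` transports backwards (used by
#' fixed-lag smoothing). The same state-transition model as [pf_predict()] is
#' used, but without the birth/recruitment component.
#'
#' @inheritParams pf_predict
#' @param noise Whether to draw the transition diffusion noise (scaled to
#'   `|dt|`) or apply the deterministic transport-plus-damping projection
#'   only; defaults to `params$extrap_noise`.
#' @return The extrapolated ensemble.
#' @export
pf_extrapolate <- function(ens, dt, params, noise = params$extrap_noise) {
  if (noise) {
    out <- pf_step(ens, dt, params, recruit = 0)
  } else {
    st <- tibble::tibble(x = wrap_torus(ens$x + ens$u * dt),
                         y = wrap_torus(ens$y + ens$v * dt),
                         u = params$gamma * ens$u, v = params$gamma * ens$v)
    out <- particle_ensemble(st, ens$w,
                             frame_index = attr(ens, "frame_index"),
                             layer = attr(ens, "layer"))
  }
  attr(out, "layer") <- if (dt < 0) "smoothed" else "target"
  out
}

## Weight update from precomputed amplitude maps (internal fast path).
## `maps` is a list(prev, cur, long) of amplitude maps (`long` may be NULL).
pf_update_maps <- function(ens, maps, params, delta_t, shift_tau = 0) {
  x <- ens$x; u <- ens$u; y <- ens$y; v <- ens$v
  if (shift_tau != 0) {
    ## pull mode: evaluate the likelihood at the state transported back to
    ## the measurement time (deterministic back-transport; gamma > 0 needed)
    if (params$gamma <= 0)
      stop("pull mode requires gamma > 0 (not available for the PBP ablation)")
    ## extrapolation is a single kernel step of size tau, so one factor gamma
    u <- u / params$gamma
    v <- v / params$gamma
    x <- wrap_torus(x - u * shift_tau)
    y <- wrap_torus(y - v * shift_tau)
  }
  lw <- loglik_states(maps$prev, maps$cur, x, y, u, v, delta_t,
                      params$sigma_I, params$sigma_noise,
                      a_long = maps$long, L_frames = params$vel_baseline,
                      a_mid = maps$mid, M_frames = mid_baseline(params))
  w <- ens$w * (exp(lw - max(lw)) + 1e-12)
  if (sum(w) <= 0 || !all(is.finite(w)))
    stop("degenerate evidence: all particle weights vanished")
  out <- particle_ensemble(ens[c("x", "y", "u", "v")], w,
                           frame_index = attr(ens, "frame_index"),
                           layer = attr(ens, "layer"))
  if (ess(out) < nrow(out) / 2) out <- resample_systematic(out)
  out
}

#' Measurement update of the particle filter
#'
#' Multiplies particle weights by the motion-energy likelihood of a frame
#' pair (see [likelihood_weight()]), renormalises, and applies systematic
#' resampling whenever the effective sample size drops below half the
#' particle count.
#'
#' @param ens A [particle_ensemble()].
#' @param pair A [frame_pair()].
#' @param params An [model_params()] object.
#' @param dot_size Template radius in space units.
#' @return The updated (possibly resampled) ensemble.
#' @export
pf_update <- function(ens, pair, params, dot_size = 0.05) {
  maps <- list(prev = amp_map(pair$prev, dot_size),
               cur = amp_map(pair$cur, dot_size), mid = NULL, long = NULL)
  pf_update_maps(ens, maps, params, pair$delta_t)
}

## Mid-lag of the motion-energy temporal support (roughly a third of the
## full baseline); short enough that a brief flash still constrains its own
## velocity through it.
mid_baseline <- function(params) {
  M <- max(2L, as.integer(round(params$vel_baseline / 3)))
  if (M < params$vel_baseline) M else 0L
}
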
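#' Sample the motion-coherency transition kernel
#'
#' One step of the transport + diffusion + slow-speed-damping model over a
#' (possibly negative) time step `dt`:
#' \deqn{x' = x + u\,dt + \nu_x, \quad y' = y + v\,dt + \nu_y}
#' \deqn{u' = \gamma u + \nu_u, \quad v' = \gamma v + \nu_v}
#' with `gamma = (1 + D_V/sigma_p^2)^-1` and zero-mean Gaussian noise of
#' variances `D_X |dt|` (position) and `(sigma_p^-2 + D_V^-1)^-1 |dt|`
#' (velocity); positions are wrapped to the torus. The drift uses the signed
#' `dt`, so `dt < 0` transports backwards with the same noise magnitude.
#'
#' @param z Data frame of states with columns `x`, `y`, `u`, `v` (or a numeric
#'   vector `c(x, y, u, v)`).
#' @param dt Time step, seconds (signed).
#' @param params An [model_params()] object.
#' @return States of the same shape, transported one step.
#' @export
#' @examples
#' p <- model_params(D_X = 0, D_V = 0)
#' transition_sample(c(0, 0, 2, 0), 0.1, p)  # x' = 0.2, exactly
transition_sample <- function(z, dt, params) {
  vec <- is.numeric(z) && is.null(dim(z))
  if (vec) z <- tibble::tibble(x = z[1], y = z[2], u = z[3], v = z[4])
  n <- nrow(z)
  vars <- transition_noise_vars(params, dt)
  sx <- sqrt(vars[["var_x"]]); sv <- sqrt(vars[["var_v"]])
  out <- tibble::tibble(
    x = wrap_torus(z$x + z$u * dt + if (sx > 0) stats::rnorm(n, 0, sx) else 0),
    y = wrap_torus(z$y + z$v * dt + if (sx > 0) stats::rnorm(n, 0, sx) else 0),
    u = params$gamma * z$u + if (sv > 0) stats::rnorm(n, 0, sv) else 0,
    v = params$gamma * z$v + if (sv > 0) stats::rnorm(n, 0, sv) else 0
  )
  if (vec) unlist(out[1, ]) else out
}

#' Log-density of the transition kernel
#'
#' Density form of [transition_sample()]: independent wrapped Gaussians in
#' position (truncated at +/- 3 wraps; error < 1e-10 at the parameter scales
#' used here) and plain Gaussians in velocity. In the zero-variance
#' (deterministic transport) limit it returns `Inf` on the transported state
#' and `-Inf` elsewhere rather than erroring.
#'
#' @param z_new,z_old States: numeric vectors `c(x, y, u, v)` or data frames
#'   with those columns (vectorised over rows).
#' @param dt Time step, seconds (signed).
#' @param params An [model_params()] object.
#' @return Log-density value(s).
#' @export
transition_logdensity <- function(z_new, z_old, dt, params) {
  as_tbl <- function(z) {
    if (is.numeric(z) && is.null(dim(z)))
      tibble::tibble(x = z[1], y = z[2], u = z[3], v = z[4])
    else tibble::as_tibble(z)
  }
  zn <- as_tbl(z_new); zo <- as_tbl(z_old)
  n <- max(nrow(zn), nrow(zo))
  vars <- transition_noise_vars(params, dt)
  mx <- wrap_torus(zo$x + zo$u * dt)
  my <- wrap_torus(zo$y + zo$v * dt)
  mu <- params$gamma * zo$u
  mv <- params$gamma * zo$v
  ld_pos <- function(val, mean, var) {
    if (var == 0) return(ifelse(abs(torus_diff(val, mean)) < 1e-12, Inf, -Inf))
    ## wrapped normal, +/- 3 wraps
    dens <- 0
    for (kk in -3:3) dens <- dens + stats::dnorm(val + 2 * kk, mean, sqrt(var))
    log(dens)
  }
  ld_vel <- function(val, mean, var) {
    if (var == 0) return(ifelse(abs(val - mean) < 1e-12, Inf, -Inf))
    stats::dnorm(val, mean, sqrt(var), log = TRUE)
  }
  parts <- cbind(ld_pos(zn$x, mx, vars[["var_x"]]),
                 ld_pos(zn$y, my, vars[["var_x"]]),
                 ld_vel(zn$u, mu, vars[["var_v"]]),
                 ld_vel(zn$v, mv, vars[["var_v"]]))
  ## in the zero-variance limit a single off-image component makes the
  ## density zero regardless of the others
  out <- rowSums(parts)
  off <- apply(parts == -Inf, 1, any)
  out[off] <- -Inf
  if (length(out) == 1) out[[1]] else out
}
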
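#' Stimulus parameters
#'
#' Bundles the geometry and photometry of the synthetic flash-lag movies. The
#' spatio-temporal domain is a 3-torus: space is `[-1, 1)` in both axes and
#' time is `[0, T)`. A nominal dot speed `V = 1` means one spatial period (2
#' units) per temporal period (`T` seconds). Frame `k` (1-based) is stamped at
#' its midpoint `t_k = (k - 1/2) * delta_t`, so the conventional 5-frame flash
#' of a 100-frame, 1-s movie occupies frames 48 to 52, centered on `t = 0.5`.
#'
#' @param T Stimulus duration in seconds.
#' @param N_T Number of frames.
#' @param N_X,N_Y Pixel counts along x and y.
#' @param dot_size Dot radius in space units; dot and flash are rendered as
#'   isotropic Gaussian luminance blobs of standard deviation `dot_size / 2`.
#' @param V Dot speed in spatial periods per temporal period (may be negative
#'   for leftward motion).
#' @param dot_start,dot_stop Motion onset/offset in seconds.
#' @param dot_x0 Horizontal start position of the dot at `dot_start`.
#' @param I_noise Standard deviation of the additive i.i.d. Gaussian pixel
#'   noise.
#' @param T_f Flash duration in seconds; converted to a whole number of frames.
#' @param flash_time Time at which the flash is centered. `NULL` picks the
#'   condition default: mid-trajectory for `standard` and `reversal`,
#'   `dot_start` for `flash_initiated`, `dot_stop` for `flash_terminated`.
#' @param flash_dy Vertical offset of the flash from the dot path (dot path is
#'   the y = 0 axis).
#' @param C_dot,C_flash Relative contrasts in `[0, 1]`, scaling the peak blob
#'   amplitude.
#' @param condition One of `"standard"`, `"flash_initiated"`,
#'   `"flash_terminated"`, `"reversal"`.
#'
#' @return An object of class `fle_stim_params`: a validated list with all of
#'   the above plus derived fields `delta_t`, `flash_frames` (inclusive frame
#'   range) and `flash_x` (the dot-aligned horizontal flash position).
#' @export
#' @examples
#' p <- stim_params()
#' p$flash_frames  # 48 ... 52
stim_params <- function(T = 1, N_T = 100, N_X = 256, N_Y = 256,
                        dot_size = 0.05, V = 1,
                        dot_start = 0.2, dot_stop = 0.8, dot_x0 = -0.6,
                        I_noise = 0.05, T_f = 0.05,
                        flash_time = NULL, flash_dy = 0.25,
                        C_dot = 1, C_flash = 1,
                        condition = c("standard", "flash_initiated",
                                      "flash_terminated", "reversal")) {
  condition <- match.arg(condition)
  stopifnot(T > 0, N_T >= 2, N_X >= 2, N_Y >= 2, dot_size > 0,
            I_noise >= 0, T_f >= 0)
  if (!(dot_start >= 0 && dot_start <= dot_stop && dot_stop <= T))
    stop("need 0 <= dot_start <= dot_stop <= T")
  if (C_dot < 0 || C_dot > 1 || C_flash < 0 || C_flash > 1)
    stop("contrasts must lie in [0, 1]")
  delta_t <- T / N_T
  if (is.null(flash_time)) {
    flash_time <- switch(condition,
      standard = , reversal = (dot_start + dot_stop) / 2,
      flash_initiated = dot_start,
      flash_terminated = dot_stop)
  }
  n_f <- max(1L, round(T_f / delta_t))
  center <- ceiling(flash_time / delta_t)
  center <- min(max(center, 1L), N_T)
  lo <- center - ((n_f - 1L) %/% 2L)
  flash_frames <- seq.int(lo, lo + n_f - 1L)
  flash_frames <- flash_frames[flash_frames >= 1 & flash_frames <= N_T]

  ## flash horizontally aligned with the dot at the flash time
  fx <- dot_path_x(flash_time, dot_x0, V, dot_start, dot_stop, clamp = TRUE)

  structure(list(
    T = T, N_T = as.integer(N_T), N_X = as.integer(N_X), N_Y = as.integer(N_Y),
    delta_t = delta_t, dot_size = dot_size, V = V,
    dot_start = dot_start, dot_stop = dot_stop, dot_x0 = dot_x0,
    I_noise = I_noise, T_f = length(flash_frames) * delta_t,
    flash_time = flash_time, flash_frames = flash_frames,
    flash_x = fx, flash_dy = flash_dy,
    C_dot = C_dot, C_flash = C_flash, condition = condition
  ), class = "fle_stim_params")
}

## Undamped linear path of the dot, clamped or NA outside [dot_start, dot_stop].
## Speed V in periods/period = 2*V space units per second.
dot_path_x <- function(t, dot_x0, V, dot_start, dot_stop, clamp = FALSE) {
  tt <- if (clamp) pmin(pmax(t, dot_start), dot_stop) else t
  wrap_torus(dot_x0 + 2 * V * (tt - dot_start))
}

#' Model parameters for the delay-compensated tracker
#'
#' The transition prior transports position by velocity and damps velocity by
#' the slow-speed factor `gamma = (1 + D_V / sigma_p^2)^-1`, with Gaussian
#' diffusion in both (see [transition_sample()]). The likelihood has two
#' scales: `sigma_I`, the gain/integration scale on matched-filter evidence,
#' and `sigma_noise`, the tolerance on inter-frame amplitude constancy (see
#' [likelihood_weight()]).
#'
#' @param D_X Position diffusion parameter (space-units^2 per second).
#' @param D_V Velocity diffusion parameter.
#' @param sigma_p Scale of the zero-mean slow-speed prior.
#' @param tau Fixed sensory delay in seconds; must be an integer number of
#'   frames.
#' @param delta_t Frame step in seconds.
#' @param n_particles Ensemble size of the particle filter.
#' @param sigma_I Standard deviation in the motion-energy likelihood (evidence
#'   gain scale).
#' @param sigma_noise Assumed sensor noise scale (amplitude-constancy scale).
#' @param mode `"push"` (assimilate delayed frames, then extrapolate by
#'   `+tau`) or `"pull"` (recurse directly on the present-time posterior with
#'   an extrapolated likelihood). The two orderings agree for pure transport.
#' @param tracking `"split"` runs one independent filter per stimulus, each
#'   receiving the spatial half-plane nearer its stimulus path; `"joint"` runs
#'   a single filter on the full frames and attributes particles to dot/flash
#'   by half-plane at read-out time.
#' @param recruit Per-particle probability, at each prediction step, of being
#'   redrawn from the initial prior (uniform position, slow-speed-prior
#'   velocity). This mixture ("birth") component lets the filter acquire
#'   unexpected objects; essential in `"joint"` tracking.
#' @param rejuvenate Per-particle probability, at each prediction step, of
#'   redrawing only the velocity from the slow-speed prior while keeping the
#'   position. This heavy-tailed component of the velocity kernel keeps
#'   velocity hypotheses alive far from the current posterior, so the filter
#'   can lock onto a fast trajectory (or a reversal) that diffusion alone
#'   would explore far too slowly.
#' @param extrap_noise If `TRUE` the delay-compensating extrapolation step
#'   draws the transition diffusion noise scaled to `tau`; the default
#'   (`FALSE`) uses the deterministic anisotropic projection
#'   `(x + u tau, gamma u)` — the source-to-target mapping — so the target
#'   layer is not re-blurred at every frame by a full delay's worth of
#'   diffusion. Filtering (the per-frame `delta_t` steps) always keeps its
#'   diffusion.
#' @param vel_baseline Temporal support of the motion-energy likelihood, in
#'   frames: besides the consecutive-frame pair, matched-filter terms are
#'   read `vel_baseline` and roughly `vel_baseline/3` frames back along the
#'   candidate trajectory. Defaults to half the delay (50 ms at the standard
#'   settings, a physiologically plausible motion-energy integration
#'   window). Over a single frame step the dot displaces by far less than
#'   its own profile, so these longer baselines are what render velocity
#'   identifiable; making them much longer also makes the velocity estimate
#'   sluggish after a motion reversal.
#' @param pbp Logical; if `TRUE`, the position-based-prediction ablation:
#'   velocity carries no predictive precision (`D_V -> Inf`, so `gamma = 0`)
#'   and velocity diffusion is made isotropic with position diffusion
#'   (variance `D_X * |dt|`).
#'
#' @return An object of class `fle_model_params` (list), including the derived
#'   damping factor `gamma` and the delay in frames `d = tau / delta_t`.
#' @export
model_params <- function(D_X = 1, D_V = 1, sigma_p = 3, tau = 0.1,
                         delta_t = 0.01, n_particles = 2000,
                         sigma_I = 0.25, sigma_noise = 0.05,
                         mode = c("push", "pull"),
                         tracking = c("split", "joint"),
                         recruit = 0.1, rejuvenate = 0.1,
                         extrap_noise = FALSE, vel_baseline = NULL,
                         pbp = FALSE) {
  mode <- match.arg(mode)
  tracking <- match.arg(tracking)
  stopifnot(D_X >= 0, D_V >= 0, sigma_p > 0, tau >= 0, delta_t > 0,
            n_particles >= 2, sigma_I > 0, sigma_noise > 0,
            recruit >= 0, recruit < 1, rejuvenate >= 0, rejuvenate < 1)
  d <- tau / delta_t
  if (abs(d - round(d)) > 1e-8)
    stop("tau must be an integer number of frames (tau / delta_t = ", d, ")")
  d <- as.integer(round(d))
  if (is.null(vel_baseline)) vel_baseline <- max(1L, as.integer(round(d / 2)))
  structure(list(
    D_X = D_X, D_V = D_V, sigma_p = sigma_p, tau = tau, delta_t = delta_t,
    gamma = if (pbp) 0 else damping_factor(D_V, sigma_p),
    d = d, n_particles = as.integer(n_particles),
    sigma_I = sigma_I, sigma_noise = sigma_noise,
    mode = mode, tracking = tracking, recruit = recruit,
    rejuvenate = rejuvenate, extrap_noise = isTRUE(extrap_noise),
    vel_baseline = as.integer(vel_baseline), pbp = pbp
  ), class = "fle_model_params")
}

#' Slow-speed damping factor
#'
#' `gamma = (1 + D_V / sigma_p^2)^-1`, the velocity shrinkage per transition
#' step induced by the zero-mean Gaussian prior on slow speeds. `gamma -> 1`
#' for a weak prior (large `sigma_p`) or zero velocity diffusion.
#'
#' @param D_V Velocity diffusion parameter (`>= 0`).
#' @param sigma_p Slow-speed prior scale (`> 0`).
#' @return The damping factor in `(0, 1]`.
#' @export
#' @examples
#' damping_factor(1, 3)  # 0.9
damping_factor <- function(D_V, sigma_p) {
  stopifnot(D_V >= 0)
  if (sigma_p <= 0) stop("sigma_p must be > 0")
  1 / (1 + D_V / sigma_p^2)
}

#' Transition noise variances over a time step
#'
#' Position noise variance is `D_X * |dt|`; velocity noise variance is
#' `(sigma_p^-2 + D_V^-1)^-1 * |dt|` (harmonic combination of the slow-speed
#' prior and the velocity diffusion; for a weak prior it reduces to Brownian
#' diffusion `D_V * |dt|`). The magnitudes use `|dt|`, so backward transport
#' carries the same noise as forward. In the PBP ablation velocity diffusion
#' is isotropic with position (`D_X * |dt|`).
#'
#' @param params An [model_params()] object.
#' @param dt Time step in seconds (may be negative).
#' @return Named numeric vector `c(var_x, var_v)`.
#' @export
#' @examples
#' transition_noise_vars(model_params(), 0.01)  # var_v = 0.009
transition_noise_vars <- function(params, dt) {
  var_x <- params$D_X * abs(dt)
  var_v <- if (params$pbp) {
    params$D_X * abs(dt)
  } else if (params$D_V == 0) {
    0
  } else {
    1 / (1 / params$sigma_p^2 + 1 / params$D_V) * abs(dt)
  }
  c(var_x = var_x, var_v = var_v)
}

#' Read stimulus/model parameters from a JSON or YAML config file
#'
#' Keys mirror the argument names of [stim_params()] and [model_params()]
#' (`D_X`, `D_V`, `sigma_p`, `tau`, `N_T`, `N_X`, `N_Y`, `sigma_I`,
#' `sigma_noise`, `T`, `dot_size`, `V`, `dot_start`, `dot_stop`, `I_noise`,
#' `T_f`, ...). Unknown keys raise an error. The file may contain the two
#' groups at top level or under `stimulus:` / `model:`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with elements `stimulus` ([stim_params()]) and `model`
#'   ([model_params()]).
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  stim_cfg <- cfg$stimulus %||% cfg
  model_cfg <- cfg$model %||% cfg
  take <- function(x, fmls) x[intersect(names(x), fmls)]
  grouped <- !is.null(cfg$stimulus) || !is.null(cfg$model)
  if (grouped) {
    bad <- setdiff(names(cfg), c("stimulus", "model"))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    bad <- c(setdiff(names(stim_cfg), names(formals(stim_params))),
             setdiff(names(model_cfg), names(formals(model_params))))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  } else {
    bad <- setdiff(names(cfg),
                   union(names(formals(stim_params)), names(formals(model_params))))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  }
  stim <- do.call(stim_params, take(stim_cfg, names(formals(stim_params))))
  model_args <- take(model_cfg, names(formals(model_params)))
  model_args$delta_t <- stim$delta_t
  model <- do.call(model_params, model_args)
  list(stimulus = stim, model = model)
}

#' @export
print.fle_stim_params <- function(x, ...) {
  cat("<fle_stim_params> ", x$condition, ": ",
      x$N_X, "x", x$N_Y, " px, ", x$N_T, " frames (delta_t = ", x$delta_t,
      " s)\n  dot: V = ", x$V, ", t in [", x$dot_start, ", ", x$dot_stop,
      "], C = ", x$C_dot,
      "\n  flash: frames ", min(x$flash_frames), "-", max(x$flash_frames),
      " at (", round(x$flash_x, 3), ", ", x$flash_dy, "), C = ", x$C_flash,
      "\n  noise sd = ", x$I_noise, "\n", sep = "")
  invisible(x)
}

#' @export
print.fle_model_params <- function(x, ...) {
  cat("<fle_model_params> ", if (x$pbp) "PBP" else "dMBP",
      " (", x$mode, ", ", x$tracking, ")\n  D_X = ", x$D_X, ", D_V = ", x$D_V,
      ", sigma_p = ", x$sigma_p, ", gamma = ", round(x$gamma, 4),
      "\n  tau = ", x$tau, " s (", x$d, " frames), n_particles = ",
      x$n_particles, "\n  sigma_I = ", x$sigma_I, ", sigma_noise = ",
      x$sigma_noise, ", recruit = ", x$recruit, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
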
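#' Run the delay-compensated motion-based tracker on a movie
#'
#' The filter assimilates frames with the fixed sensory delay `tau`: at frame
#' `k` the *source* layer holds the posterior over the state at the delayed
#' time (frame `k - d`, `d = tau/delta_t`), updated with the newest available
#' frame pair; the *target* layer is the source posterior pushed forward by
#' `tau` through the motion-coherency transition kernel, i.e. the
#' delay-compensated estimate of the state at the present frame. During the
#' first `d + 1` frames no sensory input has arrived yet and only prediction
#' runs (the earliest part of a trajectory is necessarily missed).
#'
#' In `mode = "pull"` the target layer is instead computed by recursing
#' directly on the present-time posterior, multiplying in the likelihood
#' evaluated at the state back-transported by `tau`; for pure transport the
#' two orderings are algebraically identical, and with diffusion they agree
#' distributionally.
#'
#' With `tracking = "split"` (default) one filter per stimulus runs on the
#' frames restricted to the half-plane nearer that stimulus' path (dot path
#' `y = 0`, flash path `y = flash_dy`); with `tracking = "joint"` a single
#' filter sees the full frames and particles are attributed to dot or flash
#' by half-plane at read-out time ([get_ensemble()]).
#'
#' @param movie An [render_movie()] result.
#' @param params An [model_params()] object; `params$delta_t` must match the
#'   movie and `tau` must be a whole number of frames.
#' @param seed Integer seed for all filter randomness (same seed, same trace).
#' @return An object of class `fle_trace`: per-frame source and target
#'   ensembles per tracked stimulus, plus metadata.
#' @export
run_dmbp <- function(movie, params = NULL, seed = 1) {
  stopifnot(inherits(movie, "fle_movie"))
  if (is.null(params)) params <- model_params(delta_t = movie$delta_t)
  if (abs(params$delta_t - movie$delta_t) > 1e-12)
    stop("params$delta_t does not match the movie frame step")
  nt <- movie$params$N_T
  d <- params$d
  if (nt < d + 2) stop("movie must have at least tau/delta_t + 2 frames")
  tau <- params$tau
  dt <- params$delta_t
  dot_size <- movie$params$dot_size

  stims <- if (params$tracking == "split") c("dot", "flash") else "joint"
  masks <- lapply(stims, function(s) stim_mask(movie$params, s))
  names(masks) <- stims

  with_local_seed(seed, {
    src <- lapply(stims, function(s) init_ensemble(params))
    names(src) <- stims
    ens_out <- vector("list", nt)
    ## rolling buffer of amplitude maps per stimulus, indexed by frame
    map_buf <- lapply(stims, function(s) list())
    names(map_buf) <- stims
    L <- params$vel_baseline
    tgt <- src
    if (params$mode == "pull") {
      tgt <- lapply(src, function(e) pf_extrapolate(e, tau, params))
    }
    for (k in seq_len(nt)) {
      frame_entry <- list()
      j <- k - d  # newest available (delayed) frame
      if (j >= 1) {
        for (s in stims) {
          fr <- movie$frames[, , j]
          if (is.matrix(masks[[s]])) {
            ## the other stimulus' half-plane is replaced by background
            ## noise, not zeros: a silent region would be spuriously
            ## attractive (it pays no brightness-constancy cost)
            fr <- fr * masks[[s]] + (1 - masks[[s]]) *
              stats::rnorm(length(fr), 0, movie$params$I_noise)
          }
          map_buf[[s]][[as.character(j)]] <- amp_map(fr, dot_size)
          drop <- as.character(j - L - 1)
          if (!is.null(map_buf[[s]][[drop]])) map_buf[[s]][[drop]] <- NULL
        }
      }
      for (s in stims) {
        if (k > 1) src[[s]] <- pf_predict(src[[s]], dt, params)
        maps <- NULL
        if (j >= 2) {
          M <- mid_baseline(params)
          maps <- list(prev = map_buf[[s]][[as.character(j - 1)]],
                       cur = map_buf[[s]][[as.character(j)]],
                       mid = if (M > 0 && j - M >= 1)
                         map_buf[[s]][[as.character(j - M)]] else NULL,
                       long = if (j - L >= 1)
                         map_buf[[s]][[as.character(j - L)]] else NULL)
          src[[s]] <- pf_update_maps(src[[s]], maps, params, dt)
        }
        attr(src[[s]], "frame_index") <- k
        if (params$mode == "push") {
          tg <- pf_extrapolate(src[[s]], tau, params)
        } else {
          if (k > 1) tgt[[s]] <- pf_predict(tgt[[s]], dt, params)
          if (j >= 2) {
            tgt[[s]] <- pf_update_maps(tgt[[s]], maps, params, dt,
                                       shift_tau = tau)
          }
          tg <- tgt[[s]]
          attr(tg, "layer") <- "target"
        }
        attr(tg, "frame_index") <- k
        frame_entry[[s]] <- list(source = src[[s]], target = tg)
      }
      ens_out[[k]] <- frame_entry
    }
    structure(list(ensembles = ens_out, stim = movie$params, params = params,
                   seed = as.integer(seed), n_frames = nt),
              class = "fle_trace")
  })
}

#' Position-based-prediction (PBP) ablation
#'
#' Same machinery as [run_dmbp()] with the predictive use of velocity
#' removed: infinite velocity diffusion (`gamma = 0`) and isotropic diffusion
#' (velocity noise variance equal to the position one, `D_X |dt|`). The
#' target layer therefore spreads isotropically instead of along the motion
#' direction, and no flash-lag is produced.
#'
#' @inheritParams run_dmbp
#' @return An `fle_trace`.
#' @export
run_pbp <- function(movie, params = NULL, seed = 1) {
  if (is.null(params)) params <- model_params(delta_t = movie$delta_t)
  params$pbp <- TRUE
  params$gamma <- 0
  params$mode <- "push"
  run_dmbp(movie, params, seed)
}

## 0/1 mask over the pixel grid: the half-plane nearer the given stimulus
## path (boundaries at flash_dy/2 and its antipode). "joint" = no mask.
stim_mask <- function(stim, which = c("joint", "dot", "flash")) {
  which <- match.arg(which)
  if (which == "joint") return(1)
  yg <- pixel_centers(stim$N_Y)
  near_flash <- abs(torus_diff(yg, stim$flash_dy)) < abs(torus_diff(yg, 0))
  keep <- if (which == "flash") near_flash else !near_flash
  matrix(rep(as.numeric(keep), each = stim$N_X), stim$N_X, stim$N_Y)
}

#' Extract an ensemble from a trace
#'
#' @param trace An `fle_trace`.
#' @param frame Frame index.
#' @param layer `"source"`, `"target"` or `"smoothed"` (the latter only after
#'   [smooth_trace()]).
#' @param stimulus `"dot"` or `"flash"`. Under joint tracking the single
#'   ensemble is filtered to the half-plane nearer the requested stimulus'
#'   path and renormalised.
#' @return A [particle_ensemble()].
#' @export
get_ensemble <- function(trace, frame, layer = "target",
                         stimulus = c("dot", "flash")) {
  stimulus <- match.arg(stimulus)
  entry <- trace$ensembles[[frame]]
  if (!is.null(entry[[stimulus]])) {
    ens <- entry[[stimulus]][[layer]]
    if (is.null(ens)) stop("layer '", layer, "' not present at frame ", frame)
    return(ens)
  }
  ens <- entry$joint[[layer]]
  if (is.null(ens)) stop("layer '", layer, "' not present at frame ", frame)
  near_flash <- abs(torus_diff(ens$y, trace$stim$flash_dy)) <
    abs(torus_diff(ens$y, 0))
  keep <- if (stimulus == "flash") near_flash else !near_flash
  if (!any(keep)) stop("no particles attributed to ", stimulus,
                       " at frame ", frame)
  particle_ensemble(ens[keep, c("x", "y", "u", "v")], ens$w[keep],
                    frame_index = frame, layer = layer)
}

#' Fixed-lag backward smoothing (postdiction read-out)
#'
#' The smoothed estimate for frame `t` is the target posterior at the later
#' frame `t + tau_s/delta_t`, transported backwards by `tau_s` through the
#' same transition kernel — the position reported at a delayed subjective
#' time, re-aligned to physical time. Frames within `tau_s` of the end of the
#' trace cannot be smoothed and are dropped with a warning.
#'
#' @param trace An `fle_trace`.
#' @param tau_s Subjective latency in seconds (whole number of frames);
#'   `tau_s = 0` copies the target layer.
#' @param seed Integer seed for the backward-transport noise.
#' @return The trace with a `smoothed` layer added per stimulus.
#' @export
smooth_trace <- function(trace, tau_s, seed = 1) {
  params <- trace$params
  s <- tau_s / params$delta_t
  if (abs(s - round(s)) > 1e-8)
    stop("tau_s must be an integer number of frames")
  s <- as.integer(round(s))
  nt <- trace$n_frames
  if (s > 0 && s >= nt) stop("tau_s is beyond the trace end")
  stims <- names(trace$ensembles[[1]])
  with_local_seed(seed, {
    for (k in seq_len(nt)) {
      for (st in stims) {
        if (s == 0) {
          sm <- trace$ensembles[[k]][[st]]$target
          attr(sm, "layer") <- "smoothed"
        } else if (k + s <= nt) {
          sm <- pf_extrapolate(trace$ensembles[[k + s]][[st]]$target,
                               -tau_s, params)
        } else {
          next
        }
        attr(sm, "frame_index") <- k
        trace$ensembles[[k]][[st]]$smoothed <- sm
      }
    }
  })
  if (s > 0) warning("last ", s, " frame(s) have no smoothed estimate",
                     call. = FALSE)
  trace$tau_s <- tau_s
  trace
}

#' @export
print.fle_trace <- function(x, ...) {
  cat("<fle_trace> ", x$n_frames, " frames, ",
      if (x$params$pbp) "PBP" else "dMBP", " (", x$params$mode, ", ",
      x$params$tracking, "), seed ", x$seed,
      if (!is.null(x$tau_s)) paste0(", smoothed tau_s = ", x$tau_s) else "",
      "\n", sep = "")
  invisible(x)
}
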
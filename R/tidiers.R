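#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-frame summary of a filter trace
#'
#' @param x An `fle_trace`.
#' @param layers Layers to summarise (defaults to those present).
#' @param ... Unused.
#' @return A tibble with one row per (frame, stimulus, layer): time, MAP and
#'   circular-mean position, circular SD, precision, MAP and mean horizontal
#'   velocity, effective sample size.
#' @method tidy fle_trace
#' @export
tidy.fle_trace <- function(x, layers = NULL, ...) {
  stims <- if (!is.null(x$ensembles[[1]]$joint)) c("dot", "flash")
           else names(x$ensembles[[1]])
  tk <- frame_times(x$stim)
  purrr::map_dfr(seq_len(x$n_frames), function(k) {
    have <- names(x$ensembles[[k]][[1]])
    if (!is.null(x$ensembles[[k]]$joint)) have <- names(x$ensembles[[k]]$joint)
    lys <- layers %||% have
    lys <- intersect(lys, have)
    purrr::map_dfr(stims, function(s) {
      purrr::map_dfr(lys, function(ly) {
        ens <- get_ensemble(x, k, ly, s)
        h <- position_histogram(ens)
        tibble::tibble(
          frame = k, time = tk[k], stimulus = s, layer = ly,
          map_x = map_position(h),
          mean_x = circ_mean(ens$x, ens$w),
          sd_x = circ_sd(ens$x, ens$w),
          precision = as.numeric(ensemble_precision(ens, "x")),
          map_u = map_velocity(ens),
          mean_u = sum(ens$w * ens$u),
          ess = ess(ens)
        )
      })
    })
  })
}

#' One-row summary of a filter trace
#'
#' @param x An `fle_trace`.
#' @param ... Unused.
#' @return A tibble: frame count, particle count, mode, tracking scheme,
#'   delay in frames, and the mid-trajectory tracking error of the
#'   target-layer dot estimate (MAP minus physical position, space units).
#' @method glance fle_trace
#' @export
glance.fle_trace <- function(x, ...) {
  stim <- x$stim
  tk <- frame_times(stim)
  mid <- which.min(abs(tk - (stim$dot_start + stim$dot_stop) / 2))
  truth <- dot_position(tk[mid], stim)
  err <- NA_real_
  if (isTRUE(truth$visible)) {
    h <- position_histogram(get_ensemble(x, mid, "target", "dot"))
    err <- torus_diff(map_position(h), truth$x)
  }
  tibble::tibble(
    n_frames = x$n_frames, n_particles = x$params$n_particles,
    model = if (x$params$pbp) "pbp" else "dmbp",
    mode = x$params$mode, tracking = x$params$tracking,
    delay_frames = x$params$d, mid_tracking_error = err
  )
}
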
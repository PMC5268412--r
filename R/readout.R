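#' Weighted spatial histogram of an ensemble
#'
#' Bins particle positions on one axis into `n_bins` equal bins over the full
#' spatial range `[-1, 1)`; bin masses are particle weights, so they sum
#' to 1. Fifty bins is the conventional read-out resolution.
#'
#' @param ens A [particle_ensemble()].
#' @param n_bins Number of bins (`>= 1`).
#' @param axis `"x"` or `"y"`.
#' @return A tibble of class `fle_histogram` with columns `lo`, `hi`, `mid`,
#'   `mass`; attributes `axis`, `frame_index` and `wmean` (weighted circular
#'   mean, used for MAP tie-breaking).
#' @export
position_histogram <- function(ens, n_bins = 50, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (n_bins < 1) stop("n_bins must be >= 1")
  v <- ens[[axis]]
  idx <- pmin(floor((v + 1) / (2 / n_bins)) + 1L, n_bins)
  mass <- vapply(seq_len(n_bins),
                 function(b) sum(ens$w[idx == b]), numeric(1))
  lo <- -1 + (seq_len(n_bins) - 1) * 2 / n_bins
  out <- tibble::tibble(lo = lo, hi = lo + 2 / n_bins, mid = lo + 1 / n_bins,
                        mass = mass)
  attr(out, "axis") <- axis
  attr(out, "frame_index") <- attr(ens, "frame_index")
  attr(out, "wmean") <- circ_mean(v, ens$w)
  class(out) <- c("fle_histogram", class(out))
  out
}

#' Maximum-a-posteriori position from a histogram
#'
#' Center of the maximal-mass bin; exact ties are broken toward the bin whose
#' center is nearer the ensemble's weighted circular mean.
#'
#' @param h An [position_histogram()].
#' @return Position in space units.
#' @export
map_position <- function(h) {
  m <- which(h$mass == max(h$mass))
  if (length(m) > 1) {
    wm <- attr(h, "wmean") %||% 0
    m <- m[which.min(abs(torus_diff(h$mid[m], wm)))]
  }
  h$mid[m]
}

#' Precision (inverse spatial spread) of an ensemble
#'
#' `1 / SD` where SD is the weighted circular-aware standard deviation of the
#' particle positions on the given axis ([circ_sd()]). To avoid infinities
#' for degenerate (single-support) ensembles, the value is capped at
#' `1 / bin width` of the standard 50-bin read-out; a capped result carries
#' attribute `capped = TRUE`.
#'
#' @param ens A [particle_ensemble()].
#' @param axis `"x"` or `"y"`.
#' @param n_bins Bin count defining the cap (`cap = n_bins / 2`).
#' @return Precision in 1/space-units.
#' @export
ensemble_precision <- function(ens, axis = c("x", "y"), n_bins = 50) {
  axis <- match.arg(axis)
  sd <- circ_sd(ens[[axis]], ens$w)
  cap <- n_bins / 2  # 1 / (2 / n_bins)
  if (!is.finite(sd) || sd < 1 / cap) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  1 / sd
}

## Weighted histogram MAP of the horizontal velocity (50 bins over a
## symmetric range covering the particles).
map_velocity <- function(ens, n_bins = 50, r = 4) {
  idx <- pmin(pmax(floor((ens$u + r) / (2 * r / n_bins)) + 1L, 1L), n_bins)
  mass <- vapply(seq_len(n_bins), function(b) sum(ens$w[idx == b]), numeric(1))
  mids <- -r + (seq_len(n_bins) - 0.5) * 2 * r / n_bins
  m <- which.max(mass)
  mids[m]
}

#' Frame of maximal flash precision
#'
#' Searches the target-layer flash posterior for the frame at which its
#' precision ([ensemble_precision()], x axis) is maximal. The flash was
#' unexpected, so no information about it can exist before its delayed
#' arrival; the search window runs from `flash onset + tau` to
#' `flash offset + tau + 5` frames. Once locked, the precision saturates,
#' so near-ties (within 0.1% of the maximum) are resolved to the middle of
#' the plateau.
#'
#' @param trace An `fle_trace`.
#' @param layer Layer to read (default `"target"`).
#' @return The peak frame index, with attribute `precision` (the per-frame
#'   precision series over the search window).
#' @export
flash_peak_time <- function(trace, layer = "target") {
  stim <- trace$stim
  if (length(stim$flash_frames) == 0 || stim$C_flash <= 0)
    stop("stimulus contains no flash")
  d <- trace$params$d
  win <- seq.int(min(min(stim$flash_frames) + d, trace$n_frames),
                 min(trace$n_frames, max(stim$flash_frames) + d + 5))
  prec <- vapply(win, function(k) {
    as.numeric(ensemble_precision(get_ensemble(trace, k, layer, "flash"), "x"))
  }, numeric(1))
  plateau <- which(prec >= 0.999 * max(prec))
  peak <- win[plateau[ceiling((length(plateau) + 1) / 2)]]
  attr(peak, "precision") <- stats::setNames(prec, win)
  peak
}

#' Measure the flash-lag effect from a trace
#'
#' The lag is the spatial lead of the moving dot over the flash at the moment
#' the flash is best defined: `dot MAP x - flash MAP x` (50-bin target-layer
#' histograms), averaged over the five frames centered on
#' [flash_peak_time()], with positive sign along the motion direction.
#'
#' @param trace An `fle_trace`.
#' @param movie The movie the trace was run on (provides geometry and motion
#'   direction).
#' @param n_bins Histogram resolution.
#' @return A one-row tibble: `lag` (space units), `peak_frame`, `dot_x`,
#'   `flash_x` (window-mean MAP positions), `flash_precision`.
#' @export
measure_lag <- function(trace, movie, n_bins = 50) {
  stim <- movie$params
  peak <- flash_peak_time(trace)
  frames <- (peak - 2):(peak + 2)
  frames <- frames[frames >= 1 & frames <= trace$n_frames]
  ## MAP of the histogram averaged over the window (one estimate per
  ## stimulus, as in the conventional read-out protocol)
  avg_map <- function(stimulus) {
    hs <- lapply(frames, function(k) position_histogram(
      get_ensemble(trace, k, "target", stimulus), n_bins, "x"))
    h <- hs[[1]]
    h$mass <- rowMeans(vapply(hs, function(g) g$mass, numeric(n_bins)))
    attr(h, "wmean") <- circ_mean(vapply(hs, function(g) attr(g, "wmean"),
                                         numeric(1)))
    map_position(h)
  }
  dot_x <- avg_map("dot")
  flash_x <- avg_map("flash")
  tibble::tibble(
    lag = torus_diff(dot_x, flash_x) * sign(stim$V),
    peak_frame = as.integer(peak),
    dot_x = dot_x, flash_x = flash_x,
    flash_precision = max(attr(peak, "precision"))
  )
}

#' Flash processing delay
#'
#' Time from the arrival of the delayed flash to the flash-precision peak:
#' `(flash_peak_time - (flash center frame + tau/delta_t)) * delta_t`. The
#' flash is nominally an event at its center time; its delayed arrival is
#' that time plus the fixed delay.
#'
#' @param trace An `fle_trace`.
#' @return Delay in seconds (one frame = `delta_t`).
#' @export
flash_processing_delay <- function(trace) {
  stim <- trace$stim
  d <- trace$params$d
  center <- round(mean(range(stim$flash_frames)))
  (as.integer(flash_peak_time(trace)) - (center + d)) * trace$params$delta_t
}

#' First frame at which the estimated motion reverses
#'
#' For the motion-reversal experiment: the first frame, after tracking of the
#' initial (rightward, `V > 0`) motion is established, at which the
#' target-layer MAP horizontal velocity of the dot changes sign.
#'
#' @param trace An `fle_trace`.
#' @param layer Layer to read (default `"target"`).
#' @param established Time (s) after the *delayed* motion onset
#'   (`dot_start + tau`) from which the search starts — before that no dot
#'   information has reached the filter at all.
#' @param sustain Number of consecutive frames the sign change must persist.
#' @return Frame index (`NA` if no sign change occurs).
#' @export
reversal_frame <- function(trace, layer = "target", established = 0.1,
                           sustain = 3) {
  stim <- trace$stim
  sgn <- sign(stim$V)
  k0 <- which(frame_times(stim) >= stim$dot_start + trace$params$tau +
                established)[1]
  u <- vapply(seq.int(k0, trace$n_frames), function(k) {
    map_velocity(get_ensemble(trace, k, layer, "dot"))
  }, numeric(1))
  neg <- u * sgn < 0
  ## first sign change that is sustained (transient dips during early
  ## lock-on are not a motion reversal)
  run <- stats::filter(as.numeric(neg), rep(1, sustain), sides = 1)
  hit <- which(run == sustain)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(k0 + hit[1] - sustain)
}
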
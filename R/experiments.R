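#' Run one flash-lag experimental condition over seeded trials
#'
#' Generates one movie per trial (trial seeds `base_seed + 1, base_seed + 2,
#' ...`), runs the tracker, and computes the flash-lag read-outs. Twenty
#' independent repetitions is the conventional protocol.
#'
#' @param condition `"standard"`, `"flash_initiated"`, `"flash_terminated"`
#'   or `"reversal"`.
#' @param n_trials Number of independent repetitions (`>= 1`).
#' @param base_seed Base integer seed; trial `i` uses `base_seed + i`.
#' @param stim Named list of [stim_params()] overrides (e.g. `list(N_X = 128,
#'   C_dot = 0.5)`).
#' @param model Named list of [model_params()] overrides.
#' @param model_type `"dmbp"` or `"pbp"` (the no-motion-prediction ablation).
#' @param tau_s Optional smoothing latency in seconds; if given, the trace is
#'   smoothed ([smooth_trace()]) before read-out and `reversal_ms` is also
#'   reported for the smoothed layer.
#' @param out_dir Optional output directory: writes `results.csv`, a
#'   `manifest.json` with every parameter and seed, and per-trial trace
#'   summaries `trace_<trial>.csv`.
#' @param keep_traces If `TRUE`, attaches the trace objects as the
#'   `"traces"` attribute of the result (memory-hungry).
#' @return A tibble with one row per trial: `condition`, `trial`, `seed`,
#'   `lag`, `peak_frame`, `dot_x`, `flash_x`, `flash_precision`,
#'   `processing_delay_ms` and, for the reversal condition, `reversal_ms`
#'   (plus `reversal_smoothed_ms` when `tau_s` is given). Class
#'   `fle_results`.
#' @export
#' @examples
#' \donttest{
#' res <- run_condition("standard", n_trials = 2, base_seed = 1,
#'                      stim = list(N_X = 128, N_Y = 128),
#'                      model = list(n_particles = 500))
#' mean(res$lag)
#' }
run_condition <- function(condition = "standard", n_trials = 20,
                          base_seed = 0, stim = list(), model = list(),
                          model_type = c("dmbp", "pbp"), tau_s = NULL,
                          out_dir = NULL, keep_traces = FALSE) {
  model_type <- match.arg(model_type)
  stim$condition <- condition
  sp <- do.call(stim_params, stim)
  model$delta_t <- sp$delta_t
  mp <- do.call(model_params, model)
  runner <- if (model_type == "pbp") run_pbp else run_dmbp

  traces <- list()
  rows <- purrr::map(seq_len(n_trials), function(i) {
    seed <- base_seed + i
    movie <- render_movie(sp, seed = seed)
    trace <- runner(movie, mp, seed = seed + 1000000L)
    if (!is.null(tau_s)) trace <- suppressWarnings(smooth_trace(
      trace, tau_s, seed = seed + 2000000L))
    lg <- measure_lag(trace, movie)
    row <- tibble::tibble(
      condition = condition, model = model_type, trial = i, seed = seed,
      lag = lg$lag, peak_frame = lg$peak_frame,
      dot_x = lg$dot_x, flash_x = lg$flash_x,
      flash_precision = lg$flash_precision,
      processing_delay_ms = 1000 * flash_processing_delay(trace)
    )
    if (condition == "reversal") {
      rk <- reversal_frame(trace)
      row$reversal_ms <- if (is.na(rk)) NA_real_ else
        1000 * frame_times(sp)[rk]
      if (!is.null(tau_s)) {
        rs <- reversal_frame(trace, layer = "smoothed")
        row$reversal_smoothed_ms <- if (is.na(rs)) NA_real_ else
          1000 * frame_times(sp)[rs]
      }
    }
    if (keep_traces || !is.null(out_dir)) traces[[i]] <<- trace
    row
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("fle_results", class(res))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    manifest <- list(condition = condition, model = model_type,
                     n_trials = n_trials, base_seed = base_seed,
                     tau_s = tau_s, stimulus = unclass(sp),
                     model_params = unclass(mp))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (i in seq_len(n_trials)) {
      utils::write.csv(generics::tidy(traces[[i]]),
                       file.path(out_dir, sprintf("trace_%02d.csv", i)),
                       row.names = FALSE)
    }
  }
  if (keep_traces) attr(res, "traces") <- traces
  res
}

## Stimulus overrides for a speed sweep: the spatial trajectory span is held
## fixed (1.2 space units, or the full 0.6 s window for slow speeds) and the
## flash stays at the temporal midpoint of the motion.
stim_for_speed <- function(V, base = list()) {
  base$V <- V
  base$dot_start <- base$dot_start %||% 0.2
  dur <- min(0.6, 0.6 / abs(V))
  base$dot_stop <- base$dot_start + dur
  base$flash_time <- base$dot_start + dur / 2
  base
}

#' Sweep a stimulus variable and measure the flash-lag per value
#'
#' @param variable One of `"speed"`, `"dot_contrast"`, `"flash_contrast"`,
#'   `"flash_duration"`.
#' @param values Non-empty numeric vector of values to test. (Speeds in
#'   spatial periods per temporal period; contrasts in `[0, 1]`; durations in
#'   seconds.)
#' @param condition Condition to run each value under.
#' @param n_trials Trials per value.
#' @param base_seed Base seed; value `j`, trial `i` uses
#'   `base_seed + (j - 1) * n_trials + i`.
#' @param stim,model Overrides as in [run_condition()].
#' @param model_type `"dmbp"` or `"pbp"`.
#' @return A tibble of class `fle_sweep`: one row per (value, trial) with the
#'   [run_condition()] read-outs, tagged with `variable` and `value`.
#' @export
fle_sweep <- function(variable = c("speed", "dot_contrast", "flash_contrast",
                                   "flash_duration"),
                      values, condition = "standard", n_trials = 20,
                      base_seed = 0, stim = list(), model = list(),
                      model_type = "dmbp") {
  variable <- match.arg(variable)
  if (length(values) == 0) {
    out <- tibble::tibble(variable = character(), value = numeric())
    class(out) <- c("fle_sweep", class(out))
    return(out)
  }
  rows <- purrr::imap(values, function(v, j) {
    s <- stim
    s <- switch(variable,
      speed = stim_for_speed(v, s),
      dot_contrast = { s$C_dot <- v; s },
      flash_contrast = { s$C_flash <- v; s },
      flash_duration = { s$T_f <- v; s })
    res <- run_condition(condition, n_trials = n_trials,
                         base_seed = base_seed + (j - 1) * n_trials,
                         stim = s, model = model, model_type = model_type)
    res$variable <- variable
    res$value <- v
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fle_sweep", class(out))
  out
}
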
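#' Physical dot position at a given time
#'
#' The dot follows a linear trajectory `x(t) = dot_x0 + 2 V (t - dot_start)`
#' on the torus while `dot_start <= t <= dot_stop`, at fixed `y = 0`; outside
#' that interval it is absent. In the `reversal` condition the trajectory is
#' left-right mirrored (`x -> -x`) for `t >= T/2`.
#'
#' @param t Time(s) in seconds, `0 <= t < T`.
#' @param params A [stim_params()] object.
#' @return A tibble with columns `t`, `x`, `y`, `visible`. `x`/`y` are `NA`
#'   when the dot is absent.
#' @export
#' @examples
#' dot_position(c(0.2, 0.5, 0.9), stim_params())
dot_position <- function(t, params) {
  if (any(t < 0 | t >= params$T)) stop("t must lie in [0, T)")
  visible <- t >= params$dot_start & t <= params$dot_stop
  x <- dot_path_x(t, params$dot_x0, params$V, params$dot_start, params$dot_stop)
  if (params$condition == "reversal") {
    x <- ifelse(t >= params$T / 2, wrap_torus(-x), x)
  }
  tibble::tibble(
    t = t,
    x = ifelse(visible, x, NA_real_),
    y = ifelse(visible, 0, NA_real_),
    visible = visible
  )
}

## Gaussian luminance blob of peak amplitude 1 centered at (x0, y0),
## evaluated on the pixel grid with torus wrapping.
blob_image <- function(x0, y0, nx, ny, sigma_b) {
  dx <- torus_diff(pixel_centers(nx), x0)
  dy <- torus_diff(pixel_centers(ny), y0)
  exp(-outer(dx^2, dy^2, `+`) / (2 * sigma_b^2))
}

#' Render a synthetic flash-lag movie
#'
#' Each frame is `background (0) + C_dot * dot blob + C_flash * flash blob
#' (flash frames only) + i.i.d. N(0, I_noise^2)` pixel noise. Dot and flash
#' are isotropic Gaussian blobs of standard deviation `dot_size / 2`. The
#' flash sits at `(flash_x, flash_dy)`: horizontally aligned with the dot's
#' position at the flash time, vertically offset from the dot path. In the
#' `reversal` condition every frame of the second half of the movie
#' (`t >= T/2`) is the left-right mirror image of the corresponding standard
#' frame, so the horizontal motion reverses at mid-trajectory while the first
#' half is bit-identical to the standard movie under the same seed.
#'
#' @param params A [stim_params()] object.
#' @param seed Integer seed; the same seed reproduces the movie bit-exactly.
#' @return An object of class `fle_movie`: list with `frames` (an
#'   `N_X x N_Y x N_T` array), `delta_t`, `params`, `seed`.
#' @export
#' @examples
#' m <- render_movie(stim_params(N_X = 64, N_Y = 64), seed = 1)
#' dim(m$frames)
render_movie <- function(params, seed = 1) {
  stopifnot(inherits(params, "fle_stim_params"))
  nx <- params$N_X; ny <- params$N_Y; nt <- params$N_T
  sigma_b <- params$dot_size / 2
  flash_blob <- blob_image(params$flash_x, params$flash_dy, nx, ny, sigma_b)
  frames <- with_local_seed(seed, {
    noise <- array(stats::rnorm(nx * ny * nt, sd = params$I_noise),
                   dim = c(nx, ny, nt))
    tk <- frame_times(params)
    pos <- dot_position_std(tk, params)
    for (k in seq_len(nt)) {
      if (pos$visible[k] && params$C_dot > 0) {
        noise[, , k] <- noise[, , k] +
          params$C_dot * blob_image(pos$x[k], pos$y[k], nx, ny, sigma_b)
      }
      if (k %in% params$flash_frames && params$C_flash > 0) {
        noise[, , k] <- noise[, , k] + params$C_flash * flash_blob
      }
    }
    noise
  })
  if (params$condition == "reversal") {
    tk <- frame_times(params)
    for (k in which(tk >= params$T / 2)) {
      frames[, , k] <- frames[rev(seq_len(nx)), , k]
    }
  }
  structure(list(frames = frames, delta_t = params$delta_t,
                 params = params, seed = as.integer(seed)),
            class = "fle_movie")
}

## Frame timestamps: frame k covers [(k-1) dt, k dt), stamped at its midpoint.
frame_times <- function(params) {
  (seq_len(params$N_T) - 0.5) * params$delta_t
}

## Dot position of the *unmirrored* trajectory (used while rendering; the
## reversal mirror is applied to whole frames afterwards).
dot_position_std <- function(t, params) {
  visible <- t >= params$dot_start & t <= params$dot_stop
  x <- dot_path_x(t, params$dot_x0, params$V, params$dot_start, params$dot_stop)
  list(x = x, y = rep(0, length(t)), visible = visible)
}

#' @export
print.fle_movie <- function(x, ...) {
  cat("<fle_movie> ", paste(dim(x$frames), collapse = " x "),
      " (", x$params$condition, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write / read a movie as a PNG frame sequence with a JSON sidecar
#'
#' Frames are written as zero-padded grayscale PNGs (`frame_0001.png`, ...)
#' with intensities affinely mapped to `[0, 1]`; the mapping and all stimulus
#' parameters and the seed go into `movie.json`, so `read_movie()` restores
#' the array (up to 16-bit quantisation).
#'
#' @param movie An [render_movie()] result.
#' @param dir Output directory (created if needed).
#' @return `write_movie()` the directory, invisibly; `read_movie()` an
#'   `fle_movie`.
#' @export
write_movie <- function(movie, dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to write movies")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rng <- range(movie$frames)
  scale <- if (diff(rng) > 0) diff(rng) else 1
  nt <- dim(movie$frames)[3]
  for (k in seq_len(nt)) {
    img <- (movie$frames[, , k] - rng[1]) / scale
    ## png() expects row = y (top to bottom); store x along columns
    png::writePNG(t(img)[rev(seq_len(ncol(movie$frames))), , drop = FALSE],
                  file.path(dir, sprintf("frame_%04d.png", k)))
  }
  sidecar <- c(unclass(movie$params),
               list(seed = movie$seed, intensity_min = rng[1],
                    intensity_scale = scale))
  jsonlite::write_json(sidecar, file.path(dir, "movie.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_movie
#' @export
read_movie <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read movies")
  meta <- jsonlite::read_json(file.path(dir, "movie.json"), simplifyVector = TRUE)
  args <- meta[intersect(names(meta), names(formals(stim_params)))]
  args$flash_time <- meta$flash_time
  params <- do.call(stim_params, args)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$", full.names = TRUE))
  frames <- array(0, dim = c(params$N_X, params$N_Y, length(files)))
  for (k in seq_along(files)) {
    img <- png::readPNG(files[k])
    frames[, , k] <- t(img[rev(seq_len(nrow(img))), , drop = FALSE]) *
      meta$intensity_scale + meta$intensity_min
  }
  structure(list(frames = frames, delta_t = params$delta_t,
                 params = params, seed = as.integer(meta$seed)),
            class = "fle_movie")
}
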
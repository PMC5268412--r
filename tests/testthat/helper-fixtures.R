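## Reduced-resolution settings used throughout the unit tests: 128 px and
## 1000-2000 particles keep a full filter run around two seconds while
## preserving the model's behaviour.
quick_stim <- function(...) {
  stim_params(N_X = 128, N_Y = 128, ...)
}

quick_model <- function(...) {
  model_params(n_particles = 1000, ...)
}

## Deterministic transport settings (no diffusion, gamma = 1, no proposal
## mixture) for exactness tests.
transport_model <- function(...) {
  model_params(D_X = 0, D_V = 0, sigma_p = 1e6, recruit = 0, rejuvenate = 0,
               ...)
}

## Tiny noise-free movie on a coarse grid for oracle comparisons: the dot
## moves one grid cell per frame (speed 1 at delta_t = 0.05 on 20 cells).
coarse_stim <- function(I_noise = 0, ...) {
  stim_params(T = 1, N_T = 20, N_X = 32, N_Y = 32, I_noise = I_noise,
              C_flash = 0, V = 1, dot_start = 0.1, dot_stop = 0.9,
              dot_x0 = -0.5, ...)
}

## A four-particle ensemble at known states for read-out unit tests.
tiny_ensemble <- function(x = c(-0.5, 0, 0.25, 0.5), w = NULL) {
  particle_ensemble(
    tibble::tibble(x = x, y = 0, u = 0, v = 0),
    weights = w, frame_index = 1L
  )
}
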
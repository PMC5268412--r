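#' Grid specification for the exact filter oracle
#'
#' @param nx,ny Position cells along x / y (cell centers at the pixel-center
#'   convention over `[-1, 1)`).
#' @param u_vals,v_vals Velocity grid values.
#' @return A list of class `fle_grid_spec` with the grid axes.
#' @export
grid_spec <- function(nx = 20, ny = 1, u_vals = c(-2, 0, 2), v_vals = 0) {
  n_states <- nx * ny * length(u_vals) * length(v_vals)
  if (n_states > 5e5)
    stop("grid too large to enumerate (", n_states, " states)")
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 x = pixel_centers(nx), y = pixel_centers(ny),
                 u = u_vals, v = v_vals),
            class = "fle_grid_spec")
}

## Multiply tensor P along dimension `dim` by matrix M (rows index new cells).
tensor_mult <- function(P, M, dim) {
  d <- dim(P)
  perm <- c(dim, setdiff(seq_along(d), dim))
  Pm <- matrix(aperm(P, perm), nrow = d[dim])
  out <- M %*% Pm
  aperm(array(out, dim = d[perm]), order(perm))
}

## Circular shift of a tensor along `dim` by a fractional number of cells
## (linear interpolation between the two integer shifts; mass conserving).
circ_shift <- function(P, cells, dim) {
  n <- dim(P)[dim]
  s0 <- floor(cells)
  f <- cells - s0
  idx0 <- ((seq_len(n) - 1 - s0) %% n) + 1
  idx1 <- ((seq_len(n) - 1 - s0 - 1) %% n) + 1
  M <- matrix(0, n, n)
  M[cbind(seq_len(n), idx0)] <- 1 - f
  M[cbind(seq_len(n), idx1)] <- M[cbind(seq_len(n), idx1)] + f
  tensor_mult(P, M, dim)
}

## Wrapped-Gaussian circular convolution matrix over n cells spanning [-1, 1)
wrapped_gauss_mat <- function(n, var) {
  cell <- 2 / n
  centers <- pixel_centers(n)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    d <- torus_diff(centers, centers[j])
    dens <- 0
    for (kk in -3:3) dens <- dens + stats::dnorm(d + 2 * kk, 0, sqrt(var))
    M[, j] <- dens * cell
  }
  sweep(M, 2, colSums(M), "/")
}

## Velocity kernel matrix: u' = gamma * u + N(0, var), discretised on the
## velocity grid (columns normalised; deterministic limit maps to nearest).
vel_mat <- function(uvals, gamma, var) {
  n <- length(uvals)
  M <- matrix(0, n, n)
  for (j in seq_len(n)) {
    mu <- gamma * uvals[j]
    if (var == 0) {
      M[which.min(abs(uvals - mu)), j] <- 1
    } else {
      M[, j] <- stats::dnorm(uvals, mu, sqrt(var))
      M[, j] <- M[, j] / sum(M[, j])
    }
  }
  M
}

## One transition-kernel application over dt to a grid posterior.
grid_kernel_apply <- function(P, dt, params, grid) {
  vars <- transition_noise_vars(params, dt)
  ## transport positions by the velocity of each slice
  for (iu in seq_along(grid$u)) {
    sh <- grid$u[iu] * dt / (2 / grid$nx)
    if (sh != 0) P[, , iu, ] <- circ_shift(P[, , iu, , drop = FALSE], sh, 1)
  }
  if (grid$ny > 1) {
    for (iv in seq_along(grid$v)) {
      sh <- grid$v[iv] * dt / (2 / grid$ny)
      if (sh != 0) P[, , , iv] <- circ_shift(P[, , , iv, drop = FALSE], sh, 2)
    }
  }
  if (vars[["var_x"]] > 0) {
    P <- tensor_mult(P, wrapped_gauss_mat(grid$nx, vars[["var_x"]]), 1)
    if (grid$ny > 1)
      P <- tensor_mult(P, wrapped_gauss_mat(grid$ny, vars[["var_x"]]), 2)
  }
  if (length(grid$u) > 1 && (vars[["var_v"]] > 0 || params$gamma != 1))
    P <- tensor_mult(P, vel_mat(grid$u, params$gamma, vars[["var_v"]]), 3)
  if (length(grid$v) > 1 && (vars[["var_v"]] > 0 || params$gamma != 1))
    P <- tensor_mult(P, vel_mat(grid$v, params$gamma, vars[["var_v"]]), 4)
  P
}

#' Exact grid-filter oracle
#'
#' Brute-force implementation of the delayed predict/update/extrapolate
#' recursion by discretised integration over an enumerable state grid. The
#' push ordering assimilates the delayed frame pair into the source posterior
#' and transports it by `tau` to obtain the target; the pull ordering
#' recurses on the target directly, multiplying in the likelihood transported
#' forward by the same kernel. For pure transport (no diffusion, `gamma = 1`)
#' the two orderings are algebraically identical.
#'
#' @param movie An [render_movie()] result.
#' @param params An [model_params()] object.
#' @param grid A [grid_spec()].
#' @param mode `"push"` or `"pull"` (overrides `params$mode`).
#' @return A list of class `fle_grid_trace` with per-frame `source` and
#'   `target` posterior arrays (`nx x ny x nu x nv`, each summing to 1) and
#'   the grid.
#' @export
grid_filter <- function(movie, params, grid = grid_spec(),
                        mode = params$mode) {
  nt <- movie$params$N_T
  d <- params$d
  dt <- params$delta_t
  tau <- params$tau
  dims <- c(grid$nx, grid$ny, length(grid$u), length(grid$v))
  ## init: uniform position, slow-speed prior on velocity
  pu <- stats::dnorm(grid$u, 0, params$sigma_p)
  pv <- stats::dnorm(grid$v, 0, params$sigma_p)
  P0 <- array(1, dims)
  P0 <- P0 * rep(pu, each = prod(dims[1:2]))
  P0 <- P0 * rep(pv, each = prod(dims[1:3]))
  P0 <- P0 / sum(P0)

  states <- expand.grid(x = grid$x, y = grid$y, u = grid$u, v = grid$v,
                        KEEP.OUT.ATTRS = FALSE)
  L <- params$vel_baseline
  M <- mid_baseline(params)
  lik <- function(k) {
    ## likelihood of pair (k-1, k) on the grid (same form as the particle
    ## filter, including the mid/long-baseline matched-filter terms)
    a_prev <- amp_map(movie$frames[, , k - 1], movie$params$dot_size)
    a_cur <- amp_map(movie$frames[, , k], movie$params$dot_size)
    a_mid <- if (M > 0 && k - M >= 1)
      amp_map(movie$frames[, , k - M], movie$params$dot_size) else NULL
    a_long <- if (k - L >= 1)
      amp_map(movie$frames[, , k - L], movie$params$dot_size) else NULL
    lw <- loglik_states(a_prev, a_cur, states$x, states$y, states$u, states$v,
                        dt, params$sigma_I, params$sigma_noise,
                        a_long = a_long, L_frames = L,
                        a_mid = a_mid, M_frames = M)
    array(exp(lw - max(lw)) + 1e-12, dims)
  }

  S <- P0
  Tn <- grid_kernel_apply(P0, tau, params, grid)
  out <- vector("list", nt)
  for (k in seq_len(nt)) {
    if (k > 1) {
      S <- grid_kernel_apply(S, dt, params, grid)
      if (mode == "pull") Tn <- grid_kernel_apply(Tn, dt, params, grid)
    }
    if (k - d >= 2) {
      Lk <- lik(k - d)
      S <- S * Lk
      S <- S / sum(S)
      if (mode == "pull") {
        Lt <- grid_kernel_apply(Lk, tau, params, grid)
        Tn <- Tn * Lt
        Tn <- Tn / sum(Tn)
      }
    }
    Tk <- if (mode == "push") grid_kernel_apply(S, tau, params, grid) else Tn
    out[[k]] <- list(source = S / sum(S), target = Tk / sum(Tk))
  }
  structure(list(frames = out, grid = grid, params = params,
                 stim = movie$params, mode = mode),
            class = "fle_grid_trace")
}

#' MAP state of a grid posterior
#' @param P A posterior array from [grid_filter()].
#' @param grid The matching [grid_spec()].
#' @return Named numeric `c(x, y, u, v)`.
#' @export
grid_map <- function(P, grid) {
  idx <- arrayInd(which.max(P), dim(P))
  c(x = grid$x[idx[1]], y = grid$y[idx[2]],
    u = grid$u[idx[3]], v = grid$v[idx[4]])
}
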
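test_that("particle ensembles enforce normalisation and torus support", {
  e <- tiny_ensemble(w = c(2, 1, 1, 0))
  expect_equal(sum(e$w), 1)
  expect_equal(e$w[1], 0.5)
  e2 <- particle_ensemble(tibble::tibble(x = 1.3, y = -2.5, u = 0, v = 0))
  expect_true(all(e2$x >= -1 & e2$x < 1))
  expect_true(all(e2$y >= -1 & e2$y < 1))
  expect_error(particle_ensemble(tibble::tibble(x = 0, y = 0, u = 0, v = 0),
                                 weights = 0), "degenerate")
  expect_error(particle_ensemble(tibble::tibble(x = 0, y = 0, u = 0, v = 0),
                                 weights = -1), "non-negative")
  expect_equal(ess(tiny_ensemble()), 4)
})

test_that("prediction transports particles and preserves count and weights", {
  p <- transport_model()
  e <- tiny_ensemble()
  e$u <- 2
  out <- pf_predict(e, 0.1, p)
  expect_equal(nrow(out), 4)
  expect_equal(out$x, wrap_torus(e$x + 0.2))
  expect_equal(out$w, e$w)
  ## dt = 0 with zero noise is the identity
  expect_equal(pf_predict(e, 0, p)$x, e$x)
  ## stochastic case: weighted mean shifts by mean(u) * dt
  pm <- model_params(recruit = 0, rejuvenate = 0)
  set.seed(3)
  big <- particle_ensemble(tibble::tibble(
    x = runif(4000, -0.2, 0.2), y = 0, u = rnorm(4000, 1.5, 0.1), v = 0))
  shifted <- pf_predict(big, 0.01, pm)
  se <- sqrt(0.01) / sqrt(4000)
  expect_lt(abs(sum(shifted$w * torus_diff(shifted$x, big$x)) - 1.5 * 0.01),
            4 * se)
})

test_that("a flat likelihood leaves the posterior unchanged", {
  p <- quick_model()
  e <- tiny_ensemble(w = c(0.4, 0.3, 0.2, 0.1))
  pair <- frame_pair(matrix(0.2, 64, 64), matrix(0.2, 64, 64), 0.01)
  out <- pf_update(e, pair, p)
  expect_equal(out$w, e$w, tolerance = 1e-9)
})

test_that("the update concentrates weight on states supported by the evidence", {
  p <- quick_model(vel_baseline = 1)
  prev <- flashlag:::blob_image(-0.02, 0, 64, 64, 0.025)
  cur <- flashlag:::blob_image(0, 0, 64, 64, 0.025)
  e <- particle_ensemble(tibble::tibble(
    x = c(0, 0, 0.5, -0.5), y = 0, u = c(2, -2, 0, 0), v = 0))
  out <- pf_update(e, frame_pair(prev, cur, 0.01), p)
  ## after the update (and resampling) essentially all mass sits at the
  ## true state
  expect_gt(sum(out$w[abs(out$x) < 0.1 & out$u > 1]), 0.95)
})

test_that("the filter trace is reproducible and causal in the delay", {
  sp <- stim_params(N_X = 64, N_Y = 64, N_T = 40, T = 0.4,
                    dot_start = 0.05, dot_stop = 0.35, flash_time = 0.2)
  mp <- model_params(n_particles = 300)
  m <- render_movie(sp, seed = 1)
  t1 <- run_dmbp(m, mp, seed = 9)
  t2 <- run_dmbp(m, mp, seed = 9)
  expect_identical(t1$ensembles[[30]]$dot$target,
                   t2$ensembles[[30]]$dot$target)

  ## causality: perturbing frame k never changes output before k + tau/dt
  m2 <- m
  m2$frames[, , 25] <- m2$frames[, , 25] + 0.5
  t3 <- run_dmbp(m2, mp, seed = 9)
  for (k in 1:(25 + mp$d - 1)) {
    expect_identical(t1$ensembles[[k]]$dot$source,
                     t3$ensembles[[k]]$dot$source)
  }
  expect_false(identical(t1$ensembles[[25 + mp$d]]$dot$source,
                         t3$ensembles[[25 + mp$d]]$dot$source))
})

test_that("extrapolation is the anisotropic delay-compensation map", {
  p <- transport_model()
  e <- particle_ensemble(tibble::tibble(x = 0, y = 0, u = 2, v = 0))
  out <- pf_extrapolate(e, 0.1, p)
  expect_equal(out$x, 0.2)
  expect_equal(attr(out, "layer"), "target")
  expect_equal(pf_extrapolate(e, 0, p)$x, e$x)
  ## forward tau then backward tau restores the ensemble (gamma = 1)
  back <- pf_extrapolate(pf_extrapolate(e, 0.1, p), -0.1, p)
  expect_equal(back$x, e$x)
  expect_equal(back$u, e$u)
  expect_equal(attr(back, "layer"), "smoothed")
  ## with damping, velocity shrinks by gamma per step
  pd <- model_params(D_X = 0, recruit = 0, rejuvenate = 0)
  expect_equal(pf_extrapolate(e, 0.1, pd)$u, 0.9 * 2)
})

test_that("delay compensation: target tracks the physical dot, source lags", {
  sp <- quick_stim()
  m <- render_movie(sp, seed = 11)
  tr <- run_dmbp(m, model_params(n_particles = 2000), seed = 12)
  tk <- flashlag:::frame_times(sp)
  err_t <- err_s <- c()
  for (k in c(55, 60, 65)) {
    truth_now <- dot_position(tk[k], sp)$x
    truth_delayed <- dot_position(tk[k - 10], sp)$x
    map_t <- map_position(position_histogram(get_ensemble(tr, k, "target", "dot")))
    map_s <- map_position(position_histogram(get_ensemble(tr, k, "source", "dot")))
    err_t <- c(err_t, torus_diff(map_t, truth_now))
    err_s <- c(err_s, torus_diff(map_s, truth_delayed))
  }
  ## target MAP near the physical position (within ~1 bin on average),
  ## source MAP near the delayed position, i.e. lagging by ~V tau
  expect_lt(mean(abs(err_t)), 0.06)
  expect_lt(mean(abs(err_s)), 0.06)
})

test_that("push and pull orderings agree distributionally mid-trajectory", {
  sp <- quick_stim()
  m <- render_movie(sp, seed = 3)
  tp <- run_dmbp(m, model_params(n_particles = 2000, mode = "push"), seed = 7)
  tl <- run_dmbp(m, model_params(n_particles = 2000, mode = "pull"), seed = 7)
  for (k in c(60, 70)) {
    mp_ <- map_position(position_histogram(get_ensemble(tp, k, "target", "dot")))
    ml_ <- map_position(position_histogram(get_ensemble(tl, k, "target", "dot")))
    expect_lt(abs(torus_diff(mp_, ml_)), 0.09)  # within ~2 read-out bins
  }
})

test_that("smoothing re-aligns subjective time and degenerates to identity", {
  sp <- stim_params(N_X = 64, N_Y = 64, N_T = 30, T = 0.3,
                    dot_start = 0.05, dot_stop = 0.25, flash_time = 0.15)
  m <- render_movie(sp, seed = 2)
  tr <- run_dmbp(m, model_params(n_particles = 300), seed = 5)
  t0 <- smooth_trace(tr, 0)
  expect_equal(t0$ensembles[[10]]$dot$smoothed$x,
               t0$ensembles[[10]]$dot$target$x)
  expect_warning(ts <- smooth_trace(tr, 0.05, seed = 1), "smoothed estimate")
  expect_null(ts$ensembles[[30]]$dot$smoothed)
  expect_s3_class(ts$ensembles[[10]]$dot$smoothed, "fle_ensemble")
  expect_error(smooth_trace(tr, 0.003), "integer number of frames")
})

test_that("invalid model configurations are rejected", {
  expect_error(model_params(tau = 0.013), "integer number of frames")
  m <- render_movie(stim_params(N_X = 32, N_Y = 32, N_T = 8, T = 0.08,
                                dot_start = 0, dot_stop = 0.08,
                                flash_time = 0.04), seed = 1)
  expect_error(run_dmbp(m, model_params(delta_t = 0.01, tau = 0.1), seed = 1),
               "frames")
})
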
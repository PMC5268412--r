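test_that("the slow-speed damping factor has its closed form and limits", {
  expect_equal(damping_factor(1, 3), 0.9)
  expect_equal(damping_factor(0, 3), 1)            # no velocity diffusion
  expect_equal(damping_factor(1, 1e8), 1, tolerance = 1e-12)  # weak prior
  expect_error(damping_factor(1, 0), "sigma_p")
  ## monotone: decreasing in D_V, increasing in sigma_p
  expect_true(all(diff(vapply(c(0.5, 1, 2, 4), damping_factor,
                              numeric(1), sigma_p = 3)) < 0))
  expect_true(all(diff(vapply(c(1, 2, 4, 8), function(s)
    damping_factor(1, s), numeric(1))) > 0))
})

test_that("transition noise variances follow the harmonic-combination rule", {
  p <- model_params()
  v <- transition_noise_vars(p, 0.01)
  expect_equal(unname(v), c(0.01, 0.009))
  expect_equal(unname(transition_noise_vars(p, 0)), c(0, 0))
  ## |dt| is used: backward steps carry the same noise
  expect_equal(transition_noise_vars(p, -0.02), transition_noise_vars(p, 0.02))
  ## weak prior limit: velocity variance approaches Brownian D_V |dt|
  pw <- model_params(sigma_p = 1e6)
  expect_equal(transition_noise_vars(pw, 0.01)[["var_v"]], 0.01,
               tolerance = 1e-9)
})

test_that("noise-free transition is pure transport with torus wrapping", {
  p <- transport_model()
  expect_equal(unname(transition_sample(c(0, 0, 2, 0), 0.1, p)),
               c(0.2, 0, 2, 0))
  expect_equal(unname(transition_sample(c(0.95, 0, 2, 0), 0.1, p))[1], -0.85)
  ## backward transport inverts forward transport
  fwd <- transition_sample(c(0.3, -0.2, 1.5, -0.5), 0.1, p)
  back <- transition_sample(fwd, -0.1, p)
  expect_equal(unname(back), c(0.3, -0.2, 1.5, -0.5))
})

test_that("sampled transitions have the stated drift and variances", {
  p <- model_params()
  set.seed(42)
  z <- tibble::tibble(x = 0, y = 0, u = 2, v = 0)[rep(1, 10000), ]
  out <- transition_sample(z, 0.01, p)
  se <- sqrt(0.01) / sqrt(10000)
  expect_lt(abs(mean(torus_diff(out$x, 0)) - 2 * 0.01), 4 * se)
  expect_equal(var(out$x), 0.01, tolerance = 0.05)
  expect_equal(mean(out$u), 0.9 * 2, tolerance = 4 * sqrt(0.009 / 10000) / 1)
  expect_equal(var(out$u), 0.009, tolerance = 0.05)
})

test_that("transition log-density integrates to one and is symmetric", {
  p <- model_params()
  z_old <- c(0.1, -0.3, 1, -1)
  ## the kernel factorises; integrate on a product grid
  nx <- 80
  xg <- pixel_centers(nx)
  vars <- transition_noise_vars(p, 0.01)
  ug <- seq(0.9 - 6 * sqrt(vars[2]), 0.9 + 6 * sqrt(vars[2]), length.out = 60)
  g <- expand.grid(x = xg, y = xg, u = ug, v = -ug)
  ld <- transition_logdensity(g, tibble::tibble(x = 0.1, y = -0.3, u = 1, v = -1),
                              0.01, p)
  cell <- (2 / nx)^2 * diff(ug)[1]^2
  expect_equal(sum(exp(ld)) * cell, 1, tolerance = 1e-3)

  ## Gaussian symmetry around the transported mean
  m <- c(0.1 + 0.01, -0.3 - 0.01, 0.9, -0.9)
  d <- c(0.05, 0.05, 0.1, 0.1)
  expect_equal(transition_logdensity(m + d, z_old, 0.01, p),
               transition_logdensity(m - d, z_old, 0.01, p))
})

test_that("zero-variance log-density signals the deterministic image", {
  p <- transport_model()
  expect_identical(transition_logdensity(c(0.2, 0, 2, 0), c(0, 0, 2, 0), 0.1, p),
                   Inf)
  expect_identical(transition_logdensity(c(0.25, 0, 2, 0), c(0, 0, 2, 0), 0.1, p),
                   -Inf)
})

test_that("position variance grows linearly under repeated prediction", {
  ## gamma = 1 and no velocity diffusion: after n steps the position variance
  ## is n * D_X * dt (closed form), checked by Monte-Carlo
  p <- model_params(D_X = 0.5, D_V = 0, sigma_p = 3, recruit = 0,
                    rejuvenate = 0)
  set.seed(7)
  z <- tibble::tibble(x = 0, y = 0, u = 0, v = 0)[rep(1, 5000), ]
  for (i in 1:10) z <- transition_sample(z, 0.01, p)
  expect_equal(var(z$x), 10 * 0.5 * 0.01, tolerance = 0.1)
})

test_that("the PBP ablation removes velocity memory and isotropises diffusion", {
  p <- model_params(pbp = TRUE)
  expect_equal(p$gamma, 0)
  v <- transition_noise_vars(p, 0.01)
  expect_equal(v[["var_v"]], v[["var_x"]])
})
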
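test_that("noise schedules satisfy their invariants", {
  for (kind in c("linear", "cosine")) {
    s <- make_schedule(1000L, kind)
    expect_true(all(s$beta > 0 & s$beta < 1))
    expect_true(all(diff(s$alpha_bar) < 0))
    expect_equal(s$alpha_bar, cumprod(1 - s$beta), tolerance = 1e-12)
    expect_equal(s$alpha_bar[1], 1 - s$beta[1])
  }
  s <- make_schedule(1000L, "linear")
  expect_lt(s$alpha_bar[1000], 0.01)
  expect_error(make_schedule(0L), "T_steps")
  expect_error(make_schedule(10L, "linear", beta_start = 0.5, beta_end = 0.1),
               "beta")
})

test_that("q_sample and predict_x0 are exact mutual inverses", {
  s <- make_schedule(200L, "linear", 5e-4, 0.1)
  x0 <- with_seed(1L, array(stats::rnorm(16 * 16 * 3), c(16, 16, 3)))
  for (t in c(1L, 7L, 50L, 123L, 200L)) {
    eps <- with_seed(t, array(stats::rnorm(length(x0)), dim(x0)))
    xt <- q_sample(x0, t, eps, s)
    expect_lt(max(abs(predict_x0(xt, eps, t, s) - x0)), 1e-10)
  }
  ## noiseless branch and the zero-estimate branch
  t <- 10L
  expect_equal(q_sample(x0, t, 0 * x0, s), sqrt(s$alpha_bar[t]) * x0)
  xt <- q_sample(x0, t, 0 * x0, s)
  expect_equal(predict_x0(xt, 0 * xt, t, s), xt / sqrt(s$alpha_bar[t]))
  expect_error(q_sample(x0, 0L, x0, s), "out of range")
  expect_error(q_sample(x0, 201L, x0, s), "out of range")
})

test_that("predict_x0 is affine in its image arguments", {
  s <- make_schedule(100L)
  a <- with_seed(2L, matrix(stats::rnorm(64), 8))
  b <- with_seed(3L, matrix(stats::rnorm(64), 8))
  t <- 42L
  lhs <- predict_x0(2 * a, 3 * b, t, s) + predict_x0(-a, -2 * b, t, s)
  rhs <- predict_x0(a, b, t, s)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("forward-diffusion marginals have the prescribed variance", {
  s <- make_schedule(200L, "linear", 5e-4, 0.1)
  n <- 1e4
  for (t in c(40L, 140L)) {
    draws <- with_seed(t + 100L, stats::rnorm(n))
    xt <- q_sample(rep(0, n), t, draws, s)
    expect_lt(abs(stats::var(xt) / (1 - s$alpha_bar[t]) - 1), 0.03)
  }
})

test_that("voltage condition encoding reshapes row-major to a square map", {
  enc <- voltage_encoder_init(208L, 64L, 16L, seed = 4L)
  v <- with_seed(5L, stats::rnorm(208))
  m <- encode_voltage_condition(v, enc)
  expect_equal(dim(m), c(16L, 16L))
  ## zero input with zero biases through odd nonlinearity-free path:
  ## gelu(0) = 0, so the map is exactly zero
  expect_equal(encode_voltage_condition(rep(0, 208), enc),
               matrix(0, 16, 16))
  ## row-major convention: flat feature res*i + j lands at (row i+1, col j+1)
  enc_id <- enc
  probe <- 16 * 2 + 5  # 0-based flat 36 -> row 3, col 5 (1-based)
  enc_id$W2 <- matrix(0, 64, 256)
  enc_id$b2 <- numeric(256); enc_id$b2[probe] <- 1
  m2 <- encode_voltage_condition(v, enc_id)
  expect_equal(which(m2 != 0, arr.ind = TRUE)[1, ], c(row = 3L, col = 5L))
  expect_error(encode_voltage_condition(rep(0, 100), enc), "mismatch")
})

test_that("DDIM with the oracle noise predictor reconstructs any target", {
  s <- make_schedule(200L, "linear", 5e-4, 0.1)
  res <- 8L
  x0 <- with_seed(6L, array(stats::runif(res * res, -1, 1), c(res, res, 2)))
  ## oracle: for the x_t produced along the deterministic trajectory, return
  ## the eps that q_sample would have used, i.e. eps = (x_t - sqrt(ab) x0) /
  ## sqrt(1 - ab); plugging it into the update collapses to x0 exactly
  oracle <- function(x, t) {
    ab <- s$alpha_bar[t]
    (x - sqrt(ab) * x0) / sqrt(1 - ab)
  }
  for (n_steps in c(1L, 5L, 50L, 200L)) {
    out <- ddim_sample(oracle, c(res, res, 2L), s, n_steps, seed = 3L)
    expect_lt(max(abs(out - x0)), 1e-6)
  }
})

test_that("DDIM sampling is bit-reproducible for a fixed seed", {
  s <- make_schedule(50L, "linear", 2e-3, 0.4)
  net <- function(x, t) 0.5 * x
  a <- ddim_sample(net, c(4L, 4L, 1L), s, 10L, seed = 9L)
  b <- ddim_sample(net, c(4L, 4L, 1L), s, 10L, seed = 9L)
  expect_identical(a, b)
  c <- ddim_sample(net, c(4L, 4L, 1L), s, 10L, seed = 10L)
  expect_false(identical(a, c))
  expect_error(ddim_sample(net, c(4L, 4L, 1L), s, 100L, 1L), "n_steps")
})

test_that("model-unit conversion is exactly invertible over the phantom range", {
  d <- c(-0.91, -0.5, 0, 1, 5, 10)
  u <- dsigma_to_model(d)
  expect_true(all(abs(u) <= 1.01))
  expect_equal(model_to_dsigma(u), d, tolerance = 1e-10)
})

test_that("linearized physics loss vanishes on consistent data and is quadratic", {
  m <- small_mesh(300L)
  J <- small_jacobian()
  Jp <- pixel_jacobian(J, m, 32L)
  delta <- with_seed(8L, matrix(stats::rnorm(32 * 32, sd = 0.01), 32, 32))
  u <- dsigma_to_model(delta)
  v_t <- as.vector(Jp %*% as.vector(model_to_dsigma(u)))
  expect_equal(physics_loss(u, v_t, Jp), 0, tolerance = 1e-24)
  ## doubling the residual quadruples the loss
  l1 <- physics_loss(u, v_t + 1e-6, Jp)
  l2 <- physics_loss(u, v_t + 2e-6, Jp)
  expect_equal(l2 / l1, 4, tolerance = 1e-6)
  expect_error(physics_loss(u, v_t, NULL), "J_pix")
})

test_that("linearized and FEM physics losses agree for small contrasts", {
  m <- small_mesh(300L)
  p <- std_protocol(); el <- std_electrodes()
  J <- small_jacobian()
  Jp <- pixel_jacobian(J, m, 32L)
  v_ref <- homogeneous_frame()$values
  gm <- grid_to_elements_map(m, 32L)
  fem_ctx <- list(mesh = m, electrodes = el, protocol = p, v_ref = v_ref,
                  grid_map = gm)
  rel <- vapply(1:5, function(i) {
    ph <- sample_phantom("Single", i + 40L)
    ## shrink the phantom contrast into the linear regime
    base <- rasterize(ph, 128L, 32L)$pixels
    delta <- base / max(abs(base)) * 0.02
    u <- dsigma_to_model(delta)
    v_t <- 2 * as.vector(Jp %*% as.vector(delta))
    l_lin <- physics_loss(u, v_t, Jp)
    l_fem <- physics_loss(u, v_t, mode = "fem", fem = fem_ctx)
    abs(l_lin - l_fem) / l_fem
  }, numeric(1))
  expect_lt(stats::median(rel), 0.10)
})
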
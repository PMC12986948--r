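#' Noise schedule for the diffusion process
#'
#' Builds the beta/alpha/alpha-bar arrays of a denoising diffusion process.
#' The linear schedule interpolates beta from `beta_start` to `beta_end`
#' (DDPM defaults 1e-4 to 0.02 at T = 1000; shorter chains should scale the
#' range up accordingly so that alpha-bar still decays to near zero).  The
#' cosine schedule uses the squared-cosine alpha-bar profile.
#'
#' @param T_steps total diffusion steps T (>= 1).
#' @param kind `"linear"` or `"cosine"`.
#' @param beta_start,beta_end linear-schedule endpoints in (0, 1).
#' @return a `noise_schedule` with `T`, `beta`, `alpha`, `alpha_bar`.
#' @export
make_schedule <- function(T_steps, kind = c("linear", "cosine"),
                          beta_start = 1e-4, beta_end = 0.02) {
  kind <- match.arg(kind)
  if (T_steps < 1) stop("`T_steps` must be >= 1", call. = FALSE)
  beta <- if (kind == "linear") {
    if (beta_start <= 0 || beta_end >= 1 || beta_start > beta_end) {
      stop("invalid linear beta range", call. = FALSE)
    }
    seq(beta_start, beta_end, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(t) cos((t / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:T_steps) / f(0)
    pmin(pmax(1 - ab[-1] / ab[-(T_steps + 1)], 1e-8), 0.999)
  }
  alpha <- 1 - beta
  structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                 alpha_bar = cumprod(alpha), kind = kind),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("<noise_schedule> %s, T = %d, beta in [%.2e, %.2e], alpha_bar_T = %.3e\n",
              x$kind, x$T, min(x$beta), max(x$beta), x$alpha_bar[x$T]))
  invisible(x)
}

.check_t <- function(t, schedule) {
  if (any(t < 1L) || any(t > schedule$T)) {
    stop("diffusion step t out of range", call. = FALSE)
  }
}

#' Forward diffusion: noise a clean image to step t
#'
#' Returns `sqrt(alpha_bar_t) * x0 + sqrt(1 - alpha_bar_t) * eps` exactly.
#'
#' @param x0 clean image (any numeric array).
#' @param t diffusion step in 1..T.
#' @param eps noise realization of the same shape as `x0` (standard normal).
#' @param schedule a `noise_schedule`.
#' @return noisy image x_t of the same shape.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  .check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Invert the forward diffusion given a noise estimate
#'
#' Returns `(x_t - sqrt(1 - alpha_bar_t) * eps_hat) / sqrt(alpha_bar_t)`, the
#' analytic clean-image estimate; it is the exact inverse of [q_sample()]
#' when `eps_hat` equals the true noise.
#'
#' @param x_t noisy image at step `t`.
#' @param eps_hat predicted noise.
#' @inheritParams q_sample
#' @return clean-image estimate x0_hat.
#' @export
predict_x0 <- function(x_t, eps_hat, t, schedule) {
  .check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  if (any(ab < 1e-12)) stop("alpha_bar too small for stable x0 estimate", call. = FALSE)
  (x_t - sqrt(1 - ab) * eps_hat) / sqrt(ab)
}

## ---- model-unit conversion ------------------------------------------------
## The diffusion model operates on the log-conductivity contrast
##   u = log10(1 + delta_sigma / background) / 1.05,
## which maps the study's phase range (0.1 to 10 S/m on a 1 S/m background,
## with +/-10% amplitude perturbation) symmetrically into [-1, 1].  The map
## is strictly monotone with an exact closed-form inverse.

#' Convert a conductivity change (S/m) to model units
#' @param delta conductivity-change image/array (S/m).
#' @param background background conductivity (S/m).
#' @return array in model units, phantom values within [-1, 1].
#' @export
dsigma_to_model <- function(delta, background = 1.0) {
  log10(pmax(1 + delta / background, 1e-6)) / 1.05
}

#' Convert model units back to a conductivity change (S/m)
#' @param u array in model units.
#' @inheritParams dsigma_to_model
#' @return conductivity-change array (S/m).
#' @export
model_to_dsigma <- function(u, background = 1.0) {
  background * (10^(1.05 * u) - 1)
}

## derivative d(delta)/d(u), needed by the physics-loss gradient
.model_to_dsigma_grad <- function(u, background = 1.0) {
  background * log(10) * 1.05 * 10^(1.05 * u)
}

#' Two-layer perceptron encoder for the voltage condition
#'
#' Initializes the data-constrained condition branch: a two-layer MLP mapping
#' the 208-length normalized voltage-difference vector through a hidden layer
#' to res^2 features, reshaped row-major to a res x res spatial map.
#'
#' @param n_meas input measurement count.
#' @param hidden hidden width.
#' @param res output map resolution.
#' @param seed integer seed for weight initialization.
#' @return a `voltage_encoder` parameter list.
#' @export
voltage_encoder_init <- function(n_meas = 208L, hidden = 1024L, res = 64L,
                                 seed = 1L) {
  with_seed(seed, {
    structure(list(
      W1 = matrix(stats::rnorm(n_meas * hidden, sd = 0.05), n_meas, hidden),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(hidden * res^2, sd = 0.05), hidden, res^2),
      b2 = numeric(res^2),
      n_meas = n_meas, hidden = hidden, res = res
    ), class = "voltage_encoder")
  })
}

#' Encode voltage vectors to spatial condition maps
#'
#' Applies the two-layer perceptron (GELU nonlinearity between the layers)
#' and reshapes the output row-major: flat feature `res * i + j` lands at
#' image row `i`, column `j`.
#'
#' @param v_raw numeric vector of length `n_meas`, or a matrix with one
#'   vector per column.
#' @param enc a `voltage_encoder`.
#' @return for a single vector, a res x res matrix; for a matrix input, an
#'   array res x res x batch.
#' @export
encode_voltage_condition <- function(v_raw, enc) {
  v <- if (is.matrix(v_raw)) v_raw else matrix(v_raw, ncol = 1)
  if (nrow(v) != enc$n_meas) stop("voltage length mismatch", call. = FALSE)
  h <- gelu(crossprod(v, enc$W1) + matrix(enc$b1, ncol(v), enc$hidden, byrow = TRUE))
  o <- h %*% enc$W2 + matrix(enc$b2, ncol(v), enc$res^2, byrow = TRUE)
  maps <- vapply(seq_len(ncol(v)), function(b) {
    matrix(o[b, ], enc$res, enc$res, byrow = TRUE)
  }, matrix(0, enc$res, enc$res))
  if (is.matrix(v_raw)) maps else maps[, , 1]
}

#' Physics-consistency loss
#'
#' Measures how well a clean-image estimate reproduces the measured voltage
#' difference through the forward physics.  In the default linearized mode
#' the forward operator is the pixel-space sensitivity matrix (differentiable
#' and cheap); in `fem` mode the full nonlinear CEM solve is used, which is
#' reserved for evaluation and monitoring.
#'
#' @param x0_hat clean-image estimate(s) in model units: a res x res matrix
#'   or res x res x B array.
#' @param v_target target voltage vector(s), one per column, on the same
#'   (standardized or raw) scale as `J_pix` implies.
#' @param J_pix pixel-space sensitivity from [pixel_jacobian()], on the same
#'   measurement scale as `v_target` (required in linearized mode).
#' @param mode `"linearized"` or `"fem"`.
#' @param background background conductivity.
#' @param fem optional list(mesh, electrodes, protocol, v_ref, norm) for fem
#'   mode.
#' @return mean over the batch of the per-sample mean squared residual.
#' @export
physics_loss <- function(x0_hat, v_target, J_pix = NULL,
                         mode = c("linearized", "fem"), background = 1.0,
                         fem = NULL) {
  mode <- match.arg(mode)
  X <- if (length(dim(x0_hat)) == 3) x0_hat else array(x0_hat, c(dim(x0_hat), 1))
  V <- if (is.matrix(v_target)) v_target else matrix(v_target, ncol = 1)
  B <- dim(X)[3]
  if (mode == "linearized") {
    if (is.null(J_pix)) stop("linearized physics loss requires `J_pix`", call. = FALSE)
    D <- model_to_dsigma(X, background)
    P <- J_pix %*% matrix(D, ncol = B)   # column-major vectorization
    mean(colMeans((P - V)^2))
  } else {
    if (is.null(fem)) stop("fem mode requires mesh/protocol context", call. = FALSE)
    tot <- 0
    for (b in seq_len(B)) {
      delta <- model_to_dsigma(X[, , b], background)
      elem <- as.vector(fem$grid_map %*% as.vector(delta)) + background
      elem <- pmax(elem, 1e-4)
      v <- solve_forward(fem$mesh, elem, fem$electrodes, fem$protocol)$values -
        fem$v_ref
      if (!is.null(fem$scale)) v <- v / fem$scale
      tot <- tot + mean((v - V[, b])^2)
    }
    tot / B
  }
}

#' Deterministic DDIM sampling
#'
#' Starts from standard Gaussian noise at step T and iterates the
#' deterministic (eta = 0) update
#' `x_{t-1} = sqrt(alpha_bar_{t-1}) * x0_hat + sqrt(1 - alpha_bar_{t-1}) * eps_hat`
#' over an evenly spaced decreasing subsequence of steps that always includes
#' T and 1, where `x0_hat` comes from [predict_x0()].  Given fixed weights,
#' conditions and seed the output is bit-reproducible.
#'
#' @param eps_model function `(x_t, t) -> eps_hat` taking an H x W x B array
#'   and an integer step and returning the predicted noise (same shape); in
#'   normal use this closes over the trained denoiser and the conditions.
#' @param shape integer c(H, W, B) of the sample tensor.
#' @param schedule a `noise_schedule`.
#' @param n_steps number of sampling steps (default 50).
#' @param seed integer seed for the initial noise.
#' @param clip_x0 clamp range for the clean-image estimate during sampling
#'   (stabilizes early steps); `NULL` disables.
#' @return the final clean-image estimate, an H x W x B array (model units).
#' @export
ddim_sample <- function(eps_model, shape, schedule, n_steps = 50L, seed = 1L,
                        clip_x0 = c(-1.2, 1.2)) {
  T_ <- schedule$T
  if (n_steps < 1 || n_steps > T_) stop("`n_steps` must be in 1..T", call. = FALSE)
  steps <- unique(round(seq(T_, 1, length.out = n_steps)))
  x <- with_seed(seed, array(stats::rnorm(prod(shape)), shape))
  x0_hat <- NULL
  for (k in seq_along(steps)) {
    t <- steps[k]
    eps_hat <- eps_model(x, t)
    x0_hat <- predict_x0(x, eps_hat, t, schedule)
    if (!is.null(clip_x0)) x0_hat <- pmin(pmax(x0_hat, clip_x0[1]), clip_x0[2])
    if (k < length(steps)) {
      ab_prev <- schedule$alpha_bar[steps[k + 1]]
      x <- sqrt(ab_prev) * x0_hat + sqrt(1 - ab_prev) * eps_hat
    }
  }
  x0_hat
}
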
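## A miniature dataset shared by the training tests.
train_fixture <- function() {
  memo("train_ds", {
    cfg <- dataset_config(n_total = 40L, snr_levels_db = 40,
                          amplitudes_mA = 1.0, forward_elements = 300L,
                          inverse_elements = 200L, hi_res = 64L, lo_res = 16L)
    ds <- generate_dataset(cfg, 77L)
    folds <- kfold_split(ds, 5L, 78L)
    net <- unet_config(res = 16L, in_ch = 3L, widths = c(8L, 16L),
                       types = c("swin", "bimamba"), window = c(4L, NA),
                       heads = c(2L, NA), temb_dim = 16L, ssm_state = 2L)
    sch <- make_schedule(50L, "linear", 2e-3, 0.4)
    list(ds = ds, folds = folds, net = net, sch = sch)
  })
}

test_that("gamma = 0 reduces the objective to the plain denoising loss", {
  fx <- train_fixture()
  m <- train_diffusion(fx$ds, fx$folds, 1L, fx$net, fx$sch,
                       loss_config(gamma = 0), epochs = 1L, batch_size = 8L,
                       seed = 3L)
  idx <- which(fx$folds != 1L)[1:8]
  batch <- list(
    x0 = aperm(dsigma_to_model(fx$ds$target[, , idx]), c(3, 1, 2)),
    gn = aperm(dsigma_to_model(pmax(fx$ds$y_gn[, , idx], -0.999)), c(3, 1, 2)),
    v = fx$ds$y_noise[, idx])
  l <- total_loss(m, batch, fx$sch, loss_config(gamma = 0), seed = 5L)
  expect_identical(l$L_total, l$L_denoise)
  expect_equal(l$L_phys, 0)
  ## and the composite objective adds gamma * L_phys exactly
  l2 <- total_loss(m, batch, fx$sch, loss_config(gamma = 0.3), seed = 5L,
                   J_std = m$J_std,
                   v_phys = fx$ds$y_noise[, idx] +
                     fx$ds$norm_stats$mean / fx$ds$norm_stats$sd)
  expect_equal(l2$L_total, l2$L_denoise + 0.3 * l2$L_phys, tolerance = 1e-12)
  expect_equal(l2$L_denoise, l$L_denoise, tolerance = 1e-12)
})

test_that("training reduces the denoising loss and is seed-reproducible", {
  fx <- train_fixture()
  m1 <- train_diffusion(fx$ds, fx$folds, 1L, fx$net, fx$sch, loss_config(),
                        epochs = 3L, batch_size = 8L, seed = 11L)
  expect_lt(m1$log$L_denoise[3], m1$log$L_denoise[1])
  m2 <- train_diffusion(fx$ds, fx$folds, 1L, fx$net, fx$sch, loss_config(),
                        epochs = 3L, batch_size = 8L, seed = 11L)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params$head$W, m2$params$head$W)
})

test_that("the gamma ramp reaches its final value on schedule", {
  lc <- loss_config(gamma = 0.4, gamma_schedule = "linear_ramp")
  g <- vapply(1:9, function(ep) eitdiff:::.gamma_at(lc, ep, 9L), numeric(1))
  expect_equal(g[3], 0.4)                      # end of the first third
  expect_equal(g[9], 0.4)
  expect_true(all(diff(g) >= 0))
  expect_lt(g[1], 0.4)
  lc0 <- loss_config(gamma = 0.4)
  expect_equal(eitdiff:::.gamma_at(lc0, 1, 9L), 0.4)
})

test_that("checkpoints restore the model bit-exactly", {
  fx <- train_fixture()
  m <- train_diffusion(fx$ds, fx$folds, 1L, fx$net, fx$sch, loss_config(),
                       epochs = 1L, batch_size = 8L, seed = 13L)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  unlink(path)
  ti <- which(fx$folds == 1L)[1:4]
  r1 <- reconstruct_diffusion(m, fx$ds$y_noise[, ti], fx$ds$y_gn[, , ti],
                              n_steps = 10L, seed = 2L)
  r2 <- reconstruct_diffusion(m2, fx$ds$y_noise[, ti], fx$ds$y_gn[, , ti],
                              n_steps = 10L, seed = 2L)
  expect_identical(r1, r2)
})

test_that("condition-masked variants differ only in the masking flags", {
  base <- unet_config_tiny()
  dc <- unet_config_tiny(mask_gn = TRUE)
  pg <- unet_config_tiny(mask_vol = TRUE)
  keep <- setdiff(names(base), c("mask_vol", "mask_gn"))
  expect_identical(base[keep], dc[keep])
  expect_identical(base[keep], pg[keep])
  expect_true(dc$mask_gn); expect_false(dc$mask_vol)
  expect_true(pg$mask_vol); expect_false(pg$mask_gn)
  ## masking zeroes the corresponding input channel's influence
  p <- unet_init(dc, 1L)
  x <- with_seed(50L, array(stats::rnorm(2 * 32 * 32 * 3), c(2, 32, 32, 3)))
  x2 <- x; x2[, , , 3] <- 0
  o1 <- unet_forward(p, dc, x, 5L)$out
  o2 <- unet_forward(p, dc, x2, 5L)$out
  expect_identical(o1, o2)
})

test_that("reconstructions are deterministic given weights, conditions and seed", {
  fx <- train_fixture()
  m <- train_diffusion(fx$ds, fx$folds, 1L, fx$net, fx$sch, loss_config(),
                       epochs = 1L, batch_size = 8L, seed = 17L)
  ti <- which(fx$folds == 1L)[1:3]
  r1 <- reconstruct_diffusion(m, fx$ds$y_noise[, ti], fx$ds$y_gn[, , ti],
                              n_steps = 10L, seed = 4L)
  r2 <- reconstruct_diffusion(m, fx$ds$y_noise[, ti], fx$ds$y_gn[, , ti],
                              n_steps = 10L, seed = 4L)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(16L, 16L, 3L))
  ## outputs are conductivity changes, zero outside the disk
  expect_true(all(r1[!array(disk_mask(16L), dim(r1))] == 0))
})
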
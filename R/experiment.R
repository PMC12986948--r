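## Scaled-down benchmark study: generate a small synthetic dataset, train the
## multi-source conditional diffusion model (and its voltage-only ablation),
## reconstruct the held-out fold with DDIM, and score everything against the
## one-step Gauss-Newton baseline.  Shared by the acceptance tests, the
## acceptance script and the README example.

#' Configuration of the scaled-down benchmark study
#'
#' Study conditions: 300 samples split evenly over the five phantom subsets,
#' 16-electrode adjacent protocol at 1.0 mA, 40 dB measurement SNR, a ~500
#' element forward mesh against a ~300 element inverse mesh, 32 x 32 images,
#' a T = 200 linear noise schedule, 10 training epochs at batch size 8, and
#' DDIM-50 sampling.
#'
#' @param n_samples total sample count.
#' @param snr_db training/evaluation SNR in dB.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr initial Adam learning rate.
#' @param T_steps diffusion steps of the training schedule.
#' @param gamma physics-loss weight.
#' @param n_ddim DDIM sampling steps.
#' @param k_folds cross-validation folds; fold `fold` is held out.
#' @param fold held-out fold id.
#' @return a list of study settings.
#' @export
tiny_study_config <- function(n_samples = 300L, snr_db = 40, epochs = 10L,
                              batch_size = 8L, lr = 1e-3, T_steps = 200L,
                              gamma = 0.1, n_ddim = 50L, k_folds = 5L,
                              fold = 1L) {
  list(n_samples = n_samples, snr_db = snr_db, epochs = epochs,
       batch_size = batch_size, lr = lr, T_steps = T_steps, gamma = gamma,
       n_ddim = n_ddim, k_folds = k_folds, fold = fold)
}

#' Run the scaled-down reconstruction benchmark
#'
#' Generates the synthetic dataset, trains the multi-source conditional
#' diffusion model (`MS`) and, optionally, the voltage-only ablation (`DC`,
#' prior channel masked), reconstructs the held-out fold with the
#' deterministic DDIM sampler, and evaluates all methods (including the
#' one-step Gauss-Newton `TR` baseline, whose reconstructions are exactly
#' the stored prior images) with RE/CC/SSIM/Dice.
#'
#' @param seed master integer seed for the whole study.
#' @param study settings from [tiny_study_config()].
#' @param variants which diffusion variants to train: subset of
#'   `c("MS", "DC", "PG")`.
#' @param verbose print progress.
#' @return a `tiny_benchmark` list: dataset, fold assignment, test indices,
#'   trained models, reconstructions (res x res x N per method), and a
#'   `metrics_report` comparing methods on the held-out fold.
#' @export
run_tiny_benchmark <- function(seed = 1L, study = tiny_study_config(),
                               variants = c("MS", "DC"), verbose = FALSE) {
  variants <- match.arg(variants, c("MS", "DC", "PG"), several.ok = TRUE)
  seeds <- derive_seeds(seed, 8L)
  cfgd <- dataset_config(
    n_total = study$n_samples,
    snr_levels_db = study$snr_db,
    amplitudes_mA = 1.0,
    forward_elements = 500L,
    inverse_elements = 300L,
    hi_res = 128L, lo_res = 32L)
  if (verbose) message("generating dataset ...")
  ds <- generate_dataset(cfgd, seeds[1])
  folds <- kfold_split(ds, study$k_folds, seeds[2])
  test_idx <- which(folds == study$fold)
  schedule <- make_schedule(study$T_steps, "linear",
                            beta_start = 1e-4 * 1000 / study$T_steps,
                            beta_end = 0.02 * 1000 / study$T_steps)
  lc <- loss_config(gamma = study$gamma)

  masks <- list(MS = c(FALSE, FALSE), DC = c(FALSE, TRUE), PG = c(TRUE, FALSE))
  models <- list()
  recons <- list(TR = ds$y_gn[, , test_idx, drop = FALSE] *
                   array(disk_mask(cfgd$lo_res),
                         c(cfgd$lo_res, cfgd$lo_res, length(test_idx))))
  for (v in variants) {
    if (verbose) message("training ", v, " variant ...")
    cfg <- unet_config_tiny(mask_vol = masks[[v]][1], mask_gn = masks[[v]][2])
    models[[v]] <- train_diffusion(
      ds, folds, study$fold, cfg, schedule, lc,
      epochs = study$epochs, batch_size = study$batch_size, lr = study$lr,
      seed = seeds[3], verbose = verbose)
    if (verbose) message("sampling ", v, " variant ...")
    recons[[v]] <- reconstruct_diffusion(
      models[[v]], ds$y_noise[, test_idx, drop = FALSE],
      ds$y_gn[, , test_idx, drop = FALSE],
      n_steps = study$n_ddim, seed = seeds[4])
  }

  truth <- ds$target[, , test_idx, drop = FALSE]
  methods <- names(recons)
  n_t <- length(test_idx)
  report <- evaluate_recons(
    truth = array(rep(truth, length(methods)),
                  c(cfgd$lo_res, cfgd$lo_res, n_t * length(methods))),
    recon = array(unlist(recons, use.names = FALSE),
                  c(cfgd$lo_res, cfgd$lo_res, n_t * length(methods))),
    groups = data.frame(method = rep(methods, each = n_t)),
    mask = disk_mask(cfgd$lo_res))
  structure(list(dataset = ds, folds = folds, test_idx = test_idx,
                 models = models, recons = recons, report = report,
                 schedule = schedule, study = study, seed = seed),
            class = "tiny_benchmark")
}

#' @export
print.tiny_benchmark <- function(x, ...) {
  cat(sprintf("<tiny_benchmark> %d samples, held-out fold %d (n = %d)\n",
              x$study$n_samples, x$study$fold, length(x$test_idx)))
  print(x$report)
  invisible(x)
}

#' Noise-robustness sweep of a trained model
#'
#' Generates fresh phantoms, solves the forward problem once per phantom,
#' and re-injects measurement noise at each SNR level so every level shares
#' identical ground truths; reconstructs with the trained diffusion model
#' and the Gauss-Newton baseline and reports grouped metrics per level.
#'
#' @param model a trained `eit_diffusion_model`.
#' @param dataset the `eit_dataset` the model was trained on (supplies the
#'   meshes, reference frames, prior operator and normalization statistics).
#' @param levels_db SNR levels to sweep.
#' @param n_per_level phantoms evaluated at every level.
#' @param seed integer seed.
#' @param n_ddim DDIM steps.
#' @return a `metrics_report` grouped by (method, snr_db).
#' @export
noise_sweep <- function(model, dataset, levels_db = c(10, 20, 40, Inf),
                        n_per_level = 40L, seed = 1L, n_ddim = 50L) {
  cfgd <- dataset$config
  res <- cfgd$lo_res
  mesh_f <- build_disk_mesh(cfgd$forward_elements, cfgd$electrode_count,
                            cfgd$coverage)
  mesh_i <- dataset$inverse_mesh
  el <- electrode_array(cfgd$electrode_count, cfgd$contact_impedance,
                        cfgd$coverage)
  amp <- model$amplitude_mA
  proto <- build_adjacent_protocol(cfgd$electrode_count, amp)
  v_ref <- solve_forward(mesh_f, rep(cfgd$background, mesh_f$n_elements), el,
                         proto)$values
  reg <- build_regularizer(dataset$J_inv, "noser", cfgd$gn_lambda)
  gn_op <- gn_operator(dataset$J_inv, reg)
  pixmap <- mesh_pixel_map(mesh_i, res)
  stats <- dataset$norm_stats
  mask <- disk_mask(res)

  seeds <- derive_seeds(seed, 3L * n_per_level)
  subsets <- rep_len(c("Single", "Two", "Three", "Four", "Complex"),
                     n_per_level)
  truth <- array(0, c(res, res, n_per_level))
  v2_clean <- matrix(0, proto$n_measurements, n_per_level)
  for (i in seq_len(n_per_level)) {
    ## a tightly packed draw can exhaust the placement/motion retries;
    ## shift the seed and redraw rather than aborting the sweep
    ph <- NULL
    for (retry in 0:7) {
      off <- retry * 1000003L
      ph <- tryCatch({
        p0 <- sample_phantom(subsets[i], seeds[i] + off, cfgd$background)
        apply_motion(p0, if (i %% 2 == 0) "global" else "independent",
                     seeds[n_per_level + i] + off)
      }, error = function(e) NULL)
      if (!is.null(ph)) break
    }
    if (is.null(ph)) stop("phantom generation failed for sweep sample ", i)
    truth[, , i] <- rasterize(ph, cfgd$hi_res, res)$pixels
    sig2 <- phantom_to_mesh(ph, mesh_f)
    v2_clean[, i] <- solve_forward(mesh_f, sig2, el, proto)$values
  }

  ## common random numbers across levels: the same phantoms, the same
  ## underlying noise draws (scaled to each level's variance) and the same
  ## DDIM start noise, so metric differences between levels reflect the
  ## noise intensity alone
  all_truth <- list(); all_recon <- list(); all_groups <- list()
  for (li in seq_along(levels_db)) {
    lvl <- levels_db[li]
    y_raw <- matrix(0, proto$n_measurements, n_per_level)
    y_gn <- array(0, c(res, res, n_per_level))
    for (i in seq_len(n_per_level)) {
      v2n <- add_noise(v2_clean[, i], lvl, seeds[2L * n_per_level + i])
      y_raw[, i] <- v2n - v_ref
      gn <- as.vector(gn_op(y_raw[, i] / amp))
      y_gn[, , i] <- elements_to_grid(gn, mesh_i, res, pixmap)$pixels
    }
    y_std <- (y_raw - stats$mean) / stats$sd
    dm <- reconstruct_diffusion(model, y_std, y_gn, n_steps = n_ddim,
                                seed = seed)
    tr <- y_gn * array(mask, dim(y_gn))
    all_truth[[length(all_truth) + 1L]] <- truth
    all_recon[[length(all_recon) + 1L]] <- dm
    all_groups[[length(all_groups) + 1L]] <-
      data.frame(method = "MS", snr_db = lvl)[rep(1, n_per_level), ]
    all_truth[[length(all_truth) + 1L]] <- truth
    all_recon[[length(all_recon) + 1L]] <- tr
    all_groups[[length(all_groups) + 1L]] <-
      data.frame(method = "TR", snr_db = lvl)[rep(1, n_per_level), ]
  }
  n_tot <- n_per_level * 2L * length(levels_db)
  evaluate_recons(
    truth = array(unlist(all_truth), c(res, res, n_tot)),
    recon = array(unlist(all_recon), c(res, res, n_tot)),
    groups = do.call(rbind, all_groups),
    mask = mask)
}
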
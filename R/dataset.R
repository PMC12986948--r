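#' Configuration for synthetic dataset generation
#'
#' Collects the study conditions of the simulated dataset: a unit-disk domain
#' with 16 boundary electrodes, adjacent stimulation at 1.0/2.0/2.5 mA,
#' background 1.0 S/m, five phantom subsets, independent/global motion
#' augmentation, SNR levels Inf/40/30/20/10 dB, and separate forward
#' (generation) and inverse (reconstruction) meshes to avoid the inverse
#' crime.
#'
#' @param n_total total number of samples, split evenly over `subsets`.
#' @param subsets phantom subset names.
#' @param snr_levels_db SNR mixture; one level drawn uniformly per sample.
#' @param amplitudes_mA current-amplitude mixture; one drawn per sample.
#' @param motion_modes motion-augmentation mixture.
#' @param electrode_count number of electrodes.
#' @param coverage electrode coverage fraction.
#' @param contact_impedance contact impedance z_l (Ohm*m^2).
#' @param forward_elements target element count of the generation mesh.
#' @param inverse_elements target element count of the reconstruction mesh.
#' @param hi_res,lo_res rasterization and network resolutions.
#' @param gn_lambda regularization weight of the Gauss-Newton prior.
#' @param background background conductivity (S/m).
#' @return a `dataset_config` list.
#' @export
dataset_config <- function(n_total = 50,
                           subsets = c("Single", "Two", "Three", "Four", "Complex"),
                           snr_levels_db = c(Inf, 40, 30, 20, 10),
                           amplitudes_mA = c(1.0, 2.0, 2.5),
                           motion_modes = c("independent", "global"),
                           electrode_count = 16L,
                           coverage = 0.5,
                           contact_impedance = 1e-2,
                           forward_elements = 2000L,
                           inverse_elements = 800L,
                           hi_res = 256L,
                           lo_res = 64L,
                           gn_lambda = 0.05,
                           background = 1.0) {
  if (n_total %% length(subsets) != 0) {
    stop("`n_total` must divide evenly over the subsets", call. = FALSE)
  }
  structure(as.list(environment()), class = "dataset_config")
}

#' Even per-subset sample allocation
#'
#' @param config a `dataset_config`.
#' @return named integer vector of per-subset counts.
#' @export
allocate_samples <- function(config) {
  n <- config$n_total %/% length(config$subsets)
  stats::setNames(rep.int(n, length(config$subsets)), config$subsets)
}

#' Generate a synthetic time-difference EIT dataset
#'
#' Runs the full simulation pipeline for every sample: phantom sampling,
#' motion augmentation, projection to the forward mesh, CEM forward solves of
#' the inclusion and reference states, measurement-level Gaussian noise at the
#' sampled SNR, reference subtraction and global standardization, the one-step
#' Gauss-Newton prior on the (coarser) inverse mesh, and the rasterized
#' conductivity-change target.  The result is a pure function of
#' `(config, master_seed)`.
#'
#' @param config a `dataset_config`.
#' @param master_seed integer master seed; per-sample seeds are derived from it.
#' @param path optional file path; if given the dataset is serialized there
#'   with [write_dataset()].
#' @param progress print a progress line every 50 samples.
#' @return an `eit_dataset`: list with `y_noise` (208 x N, standardized),
#'   `y_gn` (lo_res x lo_res x N, S/m), `target` (lo_res x lo_res x N, S/m),
#'   `manifest` (data.frame: subset, snr_db, amplitude_mA, motion, seed),
#'   `norm_stats`, `config`, `inverse_mesh`, and the homogeneous-reference
#'   Jacobian `J_inv` used for the prior.
#' @export
generate_dataset <- function(config, master_seed, path = NULL, progress = FALSE) {
  stopifnot(inherits(config, "dataset_config"))
  alloc <- allocate_samples(config)
  N <- sum(alloc)
  seeds <- derive_seeds(master_seed, 3L * N)
  seed_phantom <- seeds[seq_len(N)]
  seed_motion <- seeds[N + seq_len(N)]
  seed_noise <- seeds[2L * N + seq_len(N)]
  subsets <- rep(names(alloc), times = alloc)

  mesh_f <- build_disk_mesh(config$forward_elements, config$electrode_count,
                            config$coverage)
  mesh_i <- build_disk_mesh(config$inverse_elements, config$electrode_count,
                            config$coverage)
  el <- electrode_array(config$electrode_count, config$contact_impedance,
                        config$coverage)
  protos <- lapply(config$amplitudes_mA, function(a) {
    build_adjacent_protocol(config$electrode_count, a)
  })
  refs <- lapply(protos, function(p) {
    solve_forward(mesh_f, rep(config$background, mesh_f$n_elements), el, p)$values
  })
  n_meas <- protos[[1]]$n_measurements

  ## amortized GN prior operator (homogeneous reference on the inverse mesh);
  ## the Jacobian scales linearly with drive amplitude, so dividing residuals
  ## by the amplitude lets one unit-amplitude operator serve all protocols
  proto_unit <- build_adjacent_protocol(config$electrode_count, 1.0)
  J_inv <- compute_jacobian(mesh_i, rep(config$background, mesh_i$n_elements),
                            el, proto_unit)
  reg <- build_regularizer(J_inv, "noser", config$gn_lambda)
  gn_op <- gn_operator(J_inv, reg)
  pixmap <- mesh_pixel_map(mesh_i, config$lo_res)

  y_raw <- matrix(0, n_meas, N)
  y_gn <- array(0, c(config$lo_res, config$lo_res, N))
  target <- array(0, c(config$lo_res, config$lo_res, N))
  man <- data.frame(subset = subsets, snr_db = NA_real_,
                    amplitude_mA = NA_real_, motion = NA_character_,
                    seed = seed_phantom, stringsAsFactors = FALSE)
  n_fail <- 0L
  ok_all <- rep(TRUE, N)
  for (i in seq_len(N)) {
    ## a tightly packed phantom can make the motion constraints infeasible;
    ## retry the whole sample under shifted seeds before declaring failure
    ok <- FALSE
    for (retry in 0:3) {
      off <- retry * 1000003L
      ok <- tryCatch({
        pick1 <- function(x) x[sample.int(length(x), 1L)]
        draw <- with_seed(seed_motion[i] + off, list(
          motion = pick1(config$motion_modes),
          snr = pick1(config$snr_levels_db),
          amp = pick1(config$amplitudes_mA)))
        ph <- sample_phantom(subsets[i], seed_phantom[i] + off,
                             config$background)
        ph <- apply_motion(ph, draw$motion, seed_motion[i] + off)
        proto <- protos[[match(draw$amp, config$amplitudes_mA)]]
        sig2 <- phantom_to_mesh(ph, mesh_f)
        v2 <- solve_forward(mesh_f, sig2, el, proto)$values
        v2n <- add_noise(v2, draw$snr, seed_noise[i])
        y <- v2n - refs[[match(draw$amp, config$amplitudes_mA)]]
        gn <- as.vector(gn_op(y / (draw$amp)))   # unit-amplitude Jacobian
        y_raw[, i] <- y
        y_gn[, , i] <- elements_to_grid(gn, mesh_i, config$lo_res, pixmap)$pixels
        target[, , i] <- rasterize(ph, config$hi_res, config$lo_res)$pixels
        man$snr_db[i] <- draw$snr
        man$amplitude_mA[i] <- draw$amp
        man$motion[i] <- draw$motion
        man$seed[i] <- seed_phantom[i] + off
        TRUE
      }, error = function(e) {
        if (retry == 3L) {
          message(sprintf("sample %d failed (seed %d): %s", i, seed_phantom[i],
                          conditionMessage(e)))
        }
        FALSE
      })
      if (ok) break
    }
    if (!ok) {
      n_fail <- n_fail + 1L
      ok_all[i] <- FALSE
    }
    if (progress && i %% 50L == 0L) {
      message(sprintf("generated %d / %d samples", i, N))
    }
  }
  if (n_fail > 0.01 * N) {
    stop(sprintf("dataset generation aborted: %d of %d samples failed", n_fail, N),
         call. = FALSE)
  }
  if (n_fail > 0L) {
    y_raw <- y_raw[, ok_all, drop = FALSE]
    y_gn <- y_gn[, , ok_all, drop = FALSE]
    target <- target[, , ok_all, drop = FALSE]
    man <- man[ok_all, , drop = FALSE]
    rownames(man) <- NULL
  }

  stats <- voltage_norm_stats(y_raw)
  ds <- structure(list(
    y_noise = (y_raw - stats$mean) / stats$sd,
    y_gn = y_gn,
    target = target,
    manifest = man,
    norm_stats = stats,
    config = config,
    master_seed = master_seed,
    inverse_mesh = mesh_i,
    J_inv = J_inv
  ), class = "eit_dataset")
  if (!is.null(path)) write_dataset(ds, path)
  ds
}

#' @export
print.eit_dataset <- function(x, ...) {
  cat(sprintf("<eit_dataset> %d samples, %d measurements, %dx%d images\n",
              ncol(x$y_noise), nrow(x$y_noise), x$config$lo_res, x$config$lo_res))
  print(table(x$manifest$subset))
  invisible(x)
}

#' Serialize a dataset to disk
#' @param ds an `eit_dataset`.
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  saveRDS(ds, path)
  invisible(path)
}

#' Read a serialized dataset
#' @param path file path written by [write_dataset()].
#' @return the `eit_dataset`.
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  stopifnot(inherits(ds, "eit_dataset"))
  ds
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `k` folds, stratified by phantom subset so
#' fold sizes within each stratum differ by at most one; with k = 5 this is
#' the 80/20 cross-validation split of the study.
#'
#' @param manifest dataset manifest (data.frame with a `subset` column), or an
#'   `eit_dataset`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k.
#' @export
kfold_split <- function(manifest, k = 5L, seed = 1L) {
  if (inherits(manifest, "eit_dataset")) manifest <- manifest$manifest
  n <- nrow(manifest)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  if (k > n) stop("`k` exceeds the sample count", call. = FALSE)
  folds <- integer(n)
  with_seed(seed, {
    for (s in unique(manifest$subset)) {
      idx <- which(manifest$subset == s)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}
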
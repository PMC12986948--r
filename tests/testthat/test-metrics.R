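test_that("all metrics attain their ideal values on identical images", {
  x <- with_seed(1L, matrix(stats::runif(64 * 64, -1, 2), 64, 64))
  expect_equal(relative_error(x, x), 0)
  expect_equal(corr_coeff(x, x), 1)
  expect_equal(ssim(x, x), 1)
  expect_equal(dice(x, x, contrast_scale = 1), 1)
})

test_that("relative error reproduces hand-computed values", {
  expect_equal(relative_error(matrix(c(3, 4)), matrix(c(0, 0))), 1)
  expect_equal(relative_error(matrix(c(3, 4)), matrix(c(3, 0))), 4 / 5)
  x <- with_seed(2L, matrix(stats::rnorm(16), 4))
  expect_equal(relative_error(x, 0 * x), 1)
  expect_error(relative_error(0 * x, x), "zero-norm")
})

test_that("correlation is affine-invariant and sign-sensitive", {
  x <- with_seed(3L, matrix(stats::rnorm(100), 10))
  expect_equal(corr_coeff(x, 2.5 * x + 3), 1, tolerance = 1e-12)
  expect_equal(corr_coeff(x, -x), -1)
  expect_warning(cc <- corr_coeff(x, x * 0), "constant")
  expect_true(is.na(cc))
})

test_that("global SSIM on a 4x4 pair matches the direct formula", {
  x <- with_seed(4L, matrix(stats::runif(16), 4))
  y <- with_seed(5L, matrix(stats::runif(16), 4))
  L <- diff(range(x))
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  ref <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(ssim(x, y, window = NULL), ref, tolerance = 1e-10)
  ## sliding-window version agrees with a brute-force window average
  xx <- with_seed(6L, matrix(stats::runif(100), 10))
  yy <- with_seed(7L, matrix(stats::runif(100), 10))
  brute <- mean(vapply(1:4, function(i) {
    vapply(1:4, function(j) {
      ssim(xx[i:(i + 6), j:(j + 6)], yy[i:(i + 6), j:(j + 6)],
           window = NULL, L = diff(range(xx)))
    }, numeric(1))
  }, numeric(4)))
  expect_equal(ssim(xx, yy, window = 7L), brute, tolerance = 1e-10)
  ## symmetric once the stability constants use a common dynamic range
  expect_equal(ssim(xx, yy, L = 1), ssim(yy, xx, L = 1), tolerance = 1e-12)
  expect_error(ssim(xx, yy, window = 20L), "window")
})

test_that("dice binarization follows the half-extreme rule with a 5% floor", {
  img <- matrix(0, 8, 8)
  expect_true(all(!binarize_for_dice(img)$positive))
  expect_true(all(!binarize_for_dice(img)$negative))
  img[2:4, 2:4] <- -0.9
  m <- binarize_for_dice(img)
  expect_equal(sum(m$negative), 9L)
  expect_true(all(!m$positive))
  ## sub-floor extremes yield empty masks
  expect_true(all(!binarize_for_dice(img * 0.01)$negative))
  ## boundary pixels exactly at the threshold are excluded
  img2 <- matrix(0, 4, 4); img2[1, 1] <- 1; img2[2, 2] <- 0.5
  expect_equal(sum(binarize_for_dice(img2, 1)$positive), 1L)
})

test_that("dice reproduces hand counts and is scale-invariant", {
  truth <- matrix(0, 8, 8); truth[1:2, 1:4] <- 1    # 8 pixels
  pred <- matrix(0, 8, 8); pred[2, 1:4] <- 1; pred[3, 1:2] <- 1  # 6 px, overlap 4
  expect_equal(dice(truth, pred, contrast_scale = 1), 2 * 4 / (8 + 6))
  expect_equal(dice(truth, pred, contrast_scale = 1),
               dice(3.7 * truth, 3.7 * pred, contrast_scale = 3.7))
  ## disjoint equal-area masks
  p2 <- matrix(0, 8, 8); p2[5:6, 5:8] <- 1
  expect_equal(dice(truth, p2, contrast_scale = 1), 0)
  ## phases are averaged only over those present in the truth
  t2 <- matrix(0, 8, 8); t2[1:2, 1:2] <- 1; t2[6:7, 6:7] <- -1
  p3 <- t2; p3[6:7, 6:7] <- 0
  expect_equal(dice(t2, p3, contrast_scale = 1), mean(c(1, 0)))
})

test_that("reference maps encode and decode masks losslessly", {
  low <- matrix(FALSE, 6, 6); low[1:2, 1:2] <- TRUE
  high <- matrix(FALSE, 6, 6); high[5:6, 5:6] <- TRUE
  bg <- !(low | high)
  labs <- encode_reference_map(bg, low, high)
  expect_equal(sort(unique(as.vector(labs))), c(0L, 1L, 2L))
  expect_equal(as.vector(table(labs)), c(sum(bg), sum(low), sum(high)))
  back <- decode_reference_map(labs)
  expect_identical(back$low, low)
  expect_identical(back$high, high)
  expect_identical(back$background, bg)
  expect_equal(encode_reference_map(matrix(TRUE, 2, 2), matrix(FALSE, 2, 2),
                                    matrix(FALSE, 2, 2)),
               matrix(0L, 2, 2))
  expect_error(encode_reference_map(bg, low, low), "overlap")
  expect_error(encode_reference_map(bg & !bg, low, high), "cover")
})

test_that("grouped evaluation reports mean and sample deviation per group", {
  res <- 16L
  truth <- with_seed(8L, array(stats::runif(res * res * 4, -1, 1), c(res, res, 4)))
  recon <- truth
  recon[, , 3:4] <- truth[, , 3:4] + 0.1
  rep_ <- evaluate_recons(truth, recon,
                          groups = data.frame(method = c("a", "a", "b", "b")))
  expect_equal(nrow(rep_$summary), 2L)
  a_row <- rep_$summary[rep_$summary$method == "a", ]
  expect_equal(a_row$RE_mean, 0)
  expect_equal(a_row$Dice_mean, 1)
  ## hand-computed grouped deviation: RE {0.1, 0.3} -> mean 0.2, sd 0.1414
  expect_equal(stats::sd(c(0.1, 0.3)), 0.1414, tolerance = 5e-4)
  ## permutation invariance of the grouped summary
  perm <- c(3, 1, 4, 2)
  rep2 <- evaluate_recons(truth[, , perm], recon[, , perm],
                          groups = data.frame(method = c("b", "a", "b", "a")))
  ord <- order(rep2$summary$method)
  expect_equal(rep2$summary[ord, -1], rep_$summary[order(rep_$summary$method), -1],
               tolerance = 1e-12, ignore_attr = TRUE)
})
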
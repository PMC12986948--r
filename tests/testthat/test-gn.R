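test_that("regularizers match their definitions with default lambda 0.05", {
  J <- with_seed(1L, matrix(stats::rnorm(40 * 25), 40, 25))
  rn <- build_regularizer(J, "noser")
  expect_equal(rn$lambda, 0.05)
  expect_equal(Matrix::diag(rn$matrix), colSums(J^2))
  ri <- build_regularizer(J, "tikhonov_identity", 0.2)
  expect_equal(as.matrix(ri$matrix), diag(25))
  Jz <- cbind(J, 0)
  expect_warning(build_regularizer(Jz, "noser"), "floored")
})

test_that("one-step solution matches the explicit dense inverse", {
  J <- with_seed(2L, matrix(stats::rnorm(60 * 50), 60, 50))
  dv <- with_seed(3L, stats::rnorm(60))
  reg <- build_regularizer(J, "noser", 0.05)
  x <- gn_onestep(J, reg, dv)
  M <- crossprod(J) + 0.05 * as.matrix(reg$matrix)
  x_ref <- solve(M) %*% crossprod(J, dv)
  expect_lt(max(abs(x - x_ref)) / max(abs(x_ref)), 1e-8)
  expect_equal(as.vector(gn_onestep(J, reg, rep(0, 60))), rep(0, 50))
})

test_that("vanishing regularization recovers the least-squares solution", {
  J <- with_seed(4L, matrix(stats::rnorm(80 * 30), 80, 30))
  x_true <- with_seed(5L, stats::rnorm(30))
  dv <- as.vector(J %*% x_true)
  reg <- build_regularizer(J, "tikhonov_identity", 1e-10)
  x <- as.vector(gn_onestep(J, reg, dv))
  expect_lt(max(abs(x - x_true)), 1e-6)
})

test_that("the update is linear in the data and shrinks monotonically in lambda", {
  J <- small_jacobian()$entries
  reg <- build_regularizer(J, "noser", 0.05)
  d1 <- with_seed(6L, stats::rnorm(208, sd = 1e-5))
  d2 <- with_seed(7L, stats::rnorm(208, sd = 1e-5))
  op <- gn_operator(J, reg)
  lin <- op(2.5 * d1 - 0.5 * d2)
  comb <- 2.5 * op(d1) - 0.5 * op(d2)
  expect_lt(max(abs(lin - comb)) / max(abs(comb)), 1e-10)
  norms <- vapply(c(0.005, 0.05, 0.5, 5), function(l) {
    sqrt(sum(gn_onestep(J, build_regularizer(J, "noser", l), d1)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("element fields map onto the pixel grid with exact masking", {
  m <- build_disk_mesh(200L, 16L, 0.5)
  pr <- elements_to_grid(rep(2.5, m$n_elements), m, 32L)
  expect_true(all(pr$pixels[pr$mask] == 2.5))
  expect_true(all(pr$pixels[!pr$mask] == 0))
  ## integral consistency for a smooth field
  f <- 1 + m$centroids[, 1]^2 + 0.5 * m$centroids[, 2]
  pr2 <- elements_to_grid(f, m, 64L)
  px_area <- (2 / 64)^2
  int_grid <- sum(pr2$pixels) * px_area
  int_mesh <- sum(f * m$areas)
  expect_lt(abs(int_grid - int_mesh) / abs(int_mesh), 0.05)
  expect_error(elements_to_grid(rep(1, 10), m), "element count")
})

test_that("noise-free single-inclusion prior peaks inside the true inclusion", {
  mf <- build_disk_mesh(800L, 16L, 0.5)
  mi <- small_mesh(300L)
  p <- std_protocol(); el <- std_electrodes()
  ph <- sample_phantom("Single", 12L)
  dv <- timediff_forward(mf, rep(1, mf$n_elements), phantom_to_mesh(ph, mf),
                         el, p)
  J <- small_jacobian()
  x <- gn_onestep(J, build_regularizer(J, "noser", 0.05), dv$values)
  pr <- elements_to_grid(as.vector(x), mi, 64L)
  pk <- which(abs(pr$pixels) == max(abs(pr$pixels)), arr.ind = TRUE)[1, ]
  inc <- ph$inclusions[[1]]
  ## inclusion bounding box in pixel coordinates, dilated by 3 pixels
  row_c <- (1 - inc$center[2]) / 2 * 64
  col_c <- (inc$center[1] + 1) / 2 * 64
  half <- inc$scale / 2 * 64 + 3
  expect_true(abs(pk["row"] - row_c) <= half + 0.5)
  expect_true(abs(pk["col"] - col_c) <= half + 0.5)
})

test_that("pixel-space sensitivity composes the element Jacobian with the grid map", {
  m <- small_mesh(300L)
  J <- small_jacobian()
  Jp <- pixel_jacobian(J, m, 32L)
  expect_equal(dim(Jp), c(208L, 32L * 32L))
  ## constant image maps to the constant element field response
  ones <- rep(1, 32 * 32)
  Mpe <- grid_to_elements_map(m, 32L)
  expect_equal(as.vector(Mpe %*% ones), rep(1, m$n_elements), tolerance = 1e-12)
  expect_equal(as.vector(Jp %*% ones), as.vector(J$entries %*% rep(1, m$n_elements)),
               tolerance = 1e-10)
})
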
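test_that("phantom subsets carry the prescribed inclusion counts and phases", {
  counts <- c(Single = 1L, Two = 2L, Three = 3L, Four = 4L)
  for (s in names(counts)) {
    ph <- sample_phantom(s, 101L)
    expect_equal(length(ph$inclusions), unname(counts[s]))
    expect_silent(validate_phantom(ph))
  }
  ph <- sample_phantom("Complex", 17L)
  expect_true(any(vapply(ph$inclusions,
                         function(i) i$shape %in% c("pentagram", "heart", "crescent"),
                         logical(1))))
  expect_equal(phase_conductivity("low"), 0.1)
  expect_equal(phase_conductivity("high"), 10.0)
  ## phase assignment is roughly balanced, amplitude factors in [0.9, 1.1]
  phases <- vapply(1:60, function(s) sample_phantom("Single", s)$inclusions[[1]]$phase,
                   character(1))
  expect_gt(mean(phases == "low"), 0.25)
  expect_lt(mean(phases == "low"), 0.75)
  af <- vapply(1:30, function(s) sample_phantom("Single", s)$inclusions[[1]]$amplitude_factor,
               numeric(1))
  expect_true(all(af >= 0.9 & af <= 1.1))
})

test_that("phantom sampling is deterministic in the seed", {
  expect_identical(sample_phantom("Three", 42L), sample_phantom("Three", 42L))
  expect_false(identical(sample_phantom("Three", 42L), sample_phantom("Three", 43L)))
})

test_that("global motion preserves pairwise centre distances exactly", {
  ph <- sample_phantom("Three", 5L)
  mv <- apply_motion(ph, "global", 99L)
  d0 <- dist(t(vapply(ph$inclusions, `[[`, numeric(2), "center")))
  d1 <- dist(t(vapply(mv$inclusions, `[[`, numeric(2), "center")))
  expect_equal(as.vector(d1), as.vector(d0), tolerance = 1e-12)
  expect_silent(validate_phantom(mv))
})

test_that("zero-magnitude motion bounds give the identity transform", {
  ph <- sample_phantom("Two", 8L)
  for (mode in c("independent", "global")) {
    mv <- apply_motion(ph, mode, 1L, trans_radius = 0, rot_range = 0)
    expect_equal(mv, ph, tolerance = 1e-15)
  }
})

test_that("independent motion displaces inclusions independently", {
  ph <- sample_phantom("Two", 12L)
  mv <- apply_motion(ph, "independent", 77L)
  d <- vapply(1:2, function(i) {
    sqrt(sum((mv$inclusions[[i]]$center - ph$inclusions[[i]]$center)^2))
  }, numeric(1))
  expect_false(isTRUE(all.equal(d[1], d[2])))
  expect_silent(validate_phantom(mv))
})

test_that("rasterization honours conductivity values, masking and block means", {
  ## homogeneous phantom renders to an all-zero difference image
  ph0 <- structure(list(subset = "Single", inclusions = list(), background = 1.0),
                   class = "phantom_spec")
  img0 <- rasterize(ph0, 128L, 32L)
  expect_true(all(img0$pixels == 0))
  ## centred low-phase circle: interior carries 0.1 - 1.0 = -0.9 S/m
  inc <- inclusion_spec("circle", c(0, 0), 0.3, phase = "low",
                        amplitude_factor = 1.0)
  ph <- structure(list(subset = "Single", inclusions = list(inc),
                       background = 1.0), class = "phantom_spec")
  img <- rasterize(ph, 256L, 64L)
  expect_equal(img$pixels[32, 32], -0.9, tolerance = 1e-12)
  expect_equal(min(img$pixels), -0.9)
  expect_true(all(img$pixels[!img$mask] == 0))
  ## hi-res/lo-res consistency: the lo-res pixel is its 4x4 block mean
  hi <- rasterize(ph, 256L, 256L)$sigma
  lo <- rasterize(ph, 256L, 64L)$sigma
  expect_equal(lo, block_mean(hi, 4L), tolerance = 1e-12)
  expect_error(rasterize(ph, 250L, 64L), "multiple")
})

test_that("block_mean equals a brute-force block average on random images", {
  x <- with_seed(3L, matrix(stats::runif(64 * 64), 64, 64))
  bm <- block_mean(x, 4L)
  for (probe in list(c(1, 1), c(5, 9), c(16, 16))) {
    i <- probe[1]; j <- probe[2]
    expect_equal(bm[i, j],
                 mean(x[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j)]))
  }
})

test_that("mesh projection agrees with the rasterized field", {
  m <- small_mesh(300L)
  ph <- sample_phantom("Two", 21L)
  sig <- phantom_to_mesh(ph, m)
  expect_length(sig, m$n_elements)
  ## empty phantom projects to the uniform background
  ph0 <- structure(list(subset = "Single", inclusions = list(), background = 1.0),
                   class = "phantom_spec")
  expect_equal(phantom_to_mesh(ph0, m), rep(1.0, m$n_elements))
  ## centroid lookups against a 256x256 raster: few disagreements
  hi <- rasterize(ph, 256L, 256L)$sigma
  g <- seq(-1 + 1 / 256, 1 - 1 / 256, length.out = 256)
  ctr <- m$centroids
  row <- pmin(pmax(round((1 - ctr[, 2]) / (2 / 256) + 0.5), 1), 256)
  col <- pmin(pmax(round((ctr[, 1] + 1) / (2 / 256) + 0.5), 1), 256)
  ras <- hi[cbind(row, col)]
  expect_lt(mean(abs(ras - sig) > 1e-9), 0.02)
})

test_that("inclusion containment and separation are enforced", {
  expect_error(inclusion_spec("circle", c(0.8, 0), 0.3), "0.9")
  expect_error(inclusion_spec("circle", c(0, 0), 0.3, amplitude_factor = 1.5),
               "amplitude_factor")
  ph <- sample_phantom("Four", 400L)
  cs <- t(vapply(ph$inclusions, `[[`, numeric(2), "center"))
  ss <- vapply(ph$inclusions, `[[`, numeric(1), "scale")
  for (i in 2:4) for (j in 1:(i - 1)) {
    expect_gte(sqrt(sum((cs[i, ] - cs[j, ])^2)), ss[i] + ss[j] + 0.05 - 1e-9)
  }
})
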
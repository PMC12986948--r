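## Parametric phantom generation: inclusion shapes, subset sampling, motion
## augmentation, rasterization, and projection onto FEM meshes.

.shape_names <- c("circle", "triangle", "square", "pentagram", "heart", "crescent")
.convex_shapes <- c("circle", "triangle", "square")
.nonconvex_shapes <- c("pentagram", "heart", "crescent")

#' Inclusion specification
#'
#' A single conductivity inclusion: a named shape at a position in the unit
#' disk with a radius-like scale, rotation, conductivity phase (low = 0.1 S/m,
#' high = 10.0 S/m) and a multiplicative amplitude perturbation in [0.9, 1.1]
#' emulating material inhomogeneity.
#'
#' @param shape one of circle, triangle, square, pentagram, heart, crescent.
#' @param center length-2 centre position.
#' @param scale radius-like size (circumradius of the unit shape).
#' @param rotation rotation angle in radians.
#' @param phase `"low"` (0.1 S/m) or `"high"` (10.0 S/m).
#' @param amplitude_factor multiplicative perturbation in [0.9, 1.1].
#' @return an `inclusion_spec` list.
#' @export
inclusion_spec <- function(shape, center, scale, rotation = 0,
                           phase = "low", amplitude_factor = 1.0) {
  shape <- match.arg(shape, .shape_names)
  phase <- match.arg(phase, c("low", "high"))
  if (scale <= 0) stop("`scale` must be positive", call. = FALSE)
  if (amplitude_factor < 0.9 || amplitude_factor > 1.1) {
    stop("`amplitude_factor` must lie in [0.9, 1.1]", call. = FALSE)
  }
  if (sqrt(sum(center^2)) + scale > 0.9 + 1e-9) {
    stop("inclusion not fully inside radius 0.9", call. = FALSE)
  }
  structure(list(shape = shape, center = as.numeric(center), scale = scale,
                 rotation = rotation, phase = phase,
                 amplitude_factor = amplitude_factor),
            class = "inclusion_spec")
}

#' Nominal conductivity of an inclusion (S/m), before amplitude perturbation
#' @param phase `"low"` or `"high"`.
#' @return 0.1 for low, 10.0 for high.
#' @export
phase_conductivity <- function(phase) {
  c(low = 0.1, high = 10.0)[[phase]]
}

## unit-frame point-in-shape tests (vectorized over points)
.heart_polygon <- local({
  t <- seq(0, 2 * pi, length.out = 129)[-129]
  x <- 16 * sin(t)^3
  y <- 13 * cos(t) - 5 * cos(2 * t) - 2 * cos(3 * t) - cos(4 * t)
  ## scale to unit bounding box (max half-extent 1), centred
  y <- y - (max(y) + min(y)) / 2
  s <- max(abs(c(x, y)))
  cbind(x / s, y / s)
})

.pentagram_polygon <- local({
  k <- 0:9
  ang <- pi / 2 + k * pi / 5
  r <- ifelse(k %% 2 == 0, 1, 1 / 2.6)
  cbind(r * cos(ang), r * sin(ang))
})

.point_in_polygon <- function(px, py, poly) {
  ## even-odd rule, vectorized over points
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

.unit_shape_test <- function(shape, px, py) {
  switch(shape,
    circle = px^2 + py^2 <= 1,
    square = pmax(abs(px), abs(py)) <= 1 / sqrt(2),
    triangle = {
      ## equilateral, circumradius 1, apex up
      v <- cbind(cos(pi / 2 + 2 * pi * (0:2) / 3), sin(pi / 2 + 2 * pi * (0:2) / 3))
      ok <- rep(TRUE, length(px))
      for (i in 1:3) {
        j <- i %% 3 + 1
        ok <- ok & ((v[j, 1] - v[i, 1]) * (py - v[i, 2]) -
                    (v[j, 2] - v[i, 2]) * (px - v[i, 1]) >= 0)
      }
      ok
    },
    pentagram = .point_in_polygon(px, py, .pentagram_polygon),
    heart = .point_in_polygon(px, py, .heart_polygon),
    crescent = {
      in1 <- px^2 + py^2 <= 1
      in2 <- (px - 0.45)^2 + py^2 <= 0.8^2
      in1 & !in2
    },
    stop("unknown shape", call. = FALSE))
}

#' Point-in-inclusion test
#'
#' @param inc an `inclusion_spec`.
#' @param px,py point coordinates (vectors).
#' @return logical vector.
#' @export
point_in_inclusion <- function(inc, px, py) {
  dx <- px - inc$center[1]; dy <- py - inc$center[2]
  co <- cos(-inc$rotation); si <- sin(-inc$rotation)
  qx <- (co * dx - si * dy) / inc$scale
  qy <- (si * dx + co * dy) / inc$scale
  .unit_shape_test(inc$shape, qx, qy)
}

#' Sample a random phantom from one of the five study subsets
#'
#' Subsets Single/Two/Three/Four carry that many inclusions drawn from the
#' basic convex shapes (circle, triangle, square); the Complex subset carries
#' 2-4 inclusions of which at least one is non-convex (pentagram, heart,
#' crescent).  Inclusion phases are low (0.1 S/m) or high (10.0 S/m) with
#' probability 1/2 each, amplitude factors are uniform in [0.9, 1.1], and
#' placements are rejection-sampled until every inclusion lies inside radius
#' 0.9 with pairwise circumcircle separation of at least 0.05.
#'
#' @param subset one of "Single", "Two", "Three", "Four", "Complex".
#' @param rng_seed integer seed; the same seed reproduces the phantom exactly.
#' @param background background conductivity (S/m), fixed at 1.0 in the study.
#' @return a `phantom_spec` with fields `subset`, `inclusions`, `background`.
#' @export
sample_phantom <- function(subset, rng_seed, background = 1.0) {
  subset <- match.arg(subset, c("Single", "Two", "Three", "Four", "Complex"))
  with_seed(rng_seed, {
    n_inc <- switch(subset, Single = 1L, Two = 2L, Three = 3L, Four = 4L,
                    Complex = sample(2:4, 1L))
    shapes <- if (subset == "Complex") {
      s <- sample(.shape_names, n_inc, replace = TRUE)
      s[1] <- sample(.nonconvex_shapes, 1L)
      sample(s)  # shuffle so the non-convex one is not always first
    } else {
      sample(.convex_shapes, n_inc, replace = TRUE)
    }
    incs <- vector("list", n_inc)
    for (i in seq_len(n_inc)) {
      placed <- FALSE
      for (try in 1:200) {
        sc <- stats::runif(1, 0.15, 0.35)
        rmax <- 0.9 - sc
        rr <- rmax * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        ctr <- c(rr * cos(th), rr * sin(th))
        ok <- TRUE
        if (i > 1) {
          for (j in seq_len(i - 1L)) {
            if (sqrt(sum((ctr - incs[[j]]$center)^2)) <
                sc + incs[[j]]$scale + 0.05) { ok <- FALSE; break }
          }
        }
        if (ok) {
          incs[[i]] <- inclusion_spec(
            shape = shapes[i], center = ctr, scale = sc,
            rotation = stats::runif(1, 0, 2 * pi),
            phase = sample(c("low", "high"), 1L),
            amplitude_factor = stats::runif(1, 0.9, 1.1))
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop(sprintf("phantom placement failed after 200 attempts (seed %d)",
                     rng_seed), call. = FALSE)
      }
    }
    structure(list(subset = subset, inclusions = incs, background = background),
              class = "phantom_spec")
  })
}

#' Validate phantom invariants (containment, separation, subset arity)
#' @param phantom a `phantom_spec`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_phantom <- function(phantom) {
  n <- length(phantom$inclusions)
  expected <- switch(phantom$subset, Single = 1L, Two = 2L, Three = 3L,
                     Four = 4L, Complex = NA_integer_)
  if (!is.na(expected) && n != expected) stop("inclusion count mismatch", call. = FALSE)
  if (phantom$subset == "Complex") {
    if (n < 1 || !any(vapply(phantom$inclusions,
                             function(i) i$shape %in% .nonconvex_shapes, logical(1)))) {
      stop("Complex phantom needs at least one non-convex inclusion", call. = FALSE)
    }
  }
  for (inc in phantom$inclusions) {
    if (sqrt(sum(inc$center^2)) + inc$scale > 0.9 + 1e-9) {
      stop("inclusion outside radius 0.9", call. = FALSE)
    }
  }
  if (n > 1) {
    for (i in 2:n) for (j in 1:(i - 1)) {
      a <- phantom$inclusions[[i]]; b <- phantom$inclusions[[j]]
      if (sqrt(sum((a$center - b$center)^2)) < a$scale + b$scale + 0.05 - 1e-9) {
        stop("inclusion separation below 0.05", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Apply random rigid motion to a phantom
#'
#' Independent mode gives every inclusion its own random translation (uniform
#' in a disc of radius `trans_radius`) and rotation (uniform in [0, 2*pi));
#' global mode applies a single shared rigid transform (rotation about the
#' domain centre plus translation), which preserves all pairwise centre
#' distances exactly.  Containment and separation invariants are re-enforced
#' by rejection resampling.
#'
#' @param phantom a valid `phantom_spec`.
#' @param mode `"independent"` or `"global"`.
#' @param rng_seed integer seed.
#' @param trans_radius translation magnitude bound (default 0.15).
#' @param rot_range rotation bound in radians (rotations drawn uniformly in
#'   `[0, rot_range)`); zero bounds give the identity transform.
#' @return a transformed `phantom_spec`.
#' @export
apply_motion <- function(phantom, mode = c("independent", "global"), rng_seed,
                         trans_radius = 0.15, rot_range = 2 * pi) {
  mode <- match.arg(mode)
  validate_phantom(phantom)
  runif0 <- function(hi) if (hi <= 0) 0 else stats::runif(1, 0, hi)
  with_seed(rng_seed, {
    for (attempt in 1:200) {
      cand <- phantom
      if (mode == "global") {
        th <- runif0(rot_range)
        rr <- trans_radius * sqrt(stats::runif(1))
        ta <- stats::runif(1, 0, 2 * pi)
        tv <- if (trans_radius > 0) c(rr * cos(ta), rr * sin(ta)) else c(0, 0)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        cand$inclusions <- lapply(phantom$inclusions, function(inc) {
          inc$center <- as.numeric(R %*% inc$center) + tv
          inc$rotation <- (inc$rotation + th) %% (2 * pi)
          inc
        })
      } else {
        cand$inclusions <- lapply(phantom$inclusions, function(inc) {
          rr <- trans_radius * sqrt(stats::runif(1))
          ta <- stats::runif(1, 0, 2 * pi)
          if (trans_radius > 0) {
            inc$center <- inc$center + c(rr * cos(ta), rr * sin(ta))
          }
          inc$rotation <- (inc$rotation + runif0(rot_range)) %% (2 * pi)
          inc
        })
      }
      ok <- tryCatch({ validate_phantom(cand); TRUE }, error = function(e) FALSE)
      if (ok) return(cand)
    }
    stop(sprintf("motion augmentation failed after 200 attempts (seed %d)",
                 rng_seed), call. = FALSE)
  })
}

#' Rasterize a phantom to conductivity images
#'
#' Renders the absolute conductivity at `hi_res` x `hi_res` over the square
#' [-1,1]^2 by a point-in-shape test at pixel centres (row 1 = top, later
#' inclusions overwrite earlier ones), block-mean downsamples to `lo_res`,
#' and forms the conductivity change `delta = sigma - background` inside the
#' disk mask (exactly 0 outside).
#'
#' @param phantom a `phantom_spec`.
#' @param hi_res rendering resolution (default 256), a multiple of `lo_res`.
#' @param lo_res output resolution (default 64).
#' @return a `conductivity_image`: list with `pixels` (lo_res x lo_res matrix
#'   of delta-sigma, S/m), `sigma` (absolute conductivity), `mask` (logical),
#'   `background`, `res`.
#' @export
rasterize <- function(phantom, hi_res = 256L, lo_res = 64L) {
  if (hi_res %% lo_res != 0) stop("`hi_res` must be a multiple of `lo_res`", call. = FALSE)
  g <- .grid_centers(hi_res)
  PX <- matrix(rep(g, each = hi_res), hi_res, hi_res)          # columns: x
  PY <- matrix(rep(rev(g), times = hi_res), hi_res, hi_res)    # rows: y, top first
  sig <- matrix(phantom$background, hi_res, hi_res)
  for (inc in phantom$inclusions) {
    inside <- point_in_inclusion(inc, as.vector(PX), as.vector(PY))
    sig[inside] <- phase_conductivity(inc$phase) * inc$amplitude_factor
  }
  lo_sigma <- block_mean(sig, hi_res %/% lo_res)
  mask <- disk_mask(lo_res)
  delta <- lo_sigma - phantom$background
  delta[!mask] <- 0
  structure(list(pixels = delta, sigma = lo_sigma, mask = mask,
                 background = phantom$background, res = lo_res),
            class = "conductivity_image")
}

#' @keywords internal
.grid_centers <- function(res) seq(-1 + 1 / res, 1 - 1 / res, length.out = res)

#' Logical mask of pixels whose centres lie inside the unit disk
#' @param res grid resolution.
#' @return res x res logical matrix (row 1 = top).
#' @export
disk_mask <- function(res) {
  g <- .grid_centers(res)
  X <- matrix(rep(g, each = res), res, res)
  Y <- matrix(rep(rev(g), times = res), res, res)
  X^2 + Y^2 <= 1
}

#' Block-mean downsampling by an integer factor
#' @param img matrix whose dimensions are multiples of `factor`.
#' @param factor block edge length.
#' @return downsampled matrix of block means.
#' @export
block_mean <- function(img, factor) {
  n <- nrow(img) %/% factor
  m <- ncol(img) %/% factor
  dim(img) <- c(factor, n, factor, m)
  out <- apply(img, c(2, 4), mean)
  out
}

#' Project a phantom onto a FEM mesh as an element conductivity field
#'
#' Each element takes the inclusion conductivity (phase value times amplitude
#' factor) if its centroid lies inside an inclusion (later inclusions
#' overwrite), else the background value.
#'
#' @param phantom a `phantom_spec`.
#' @param mesh an `eit_mesh`.
#' @return numeric vector of per-element conductivities (S/m).
#' @export
phantom_to_mesh <- function(phantom, mesh) {
  sig <- rep(phantom$background, mesh$n_elements)
  cx <- mesh$centroids[, 1]; cy <- mesh$centroids[, 2]
  for (inc in phantom$inclusions) {
    inside <- point_in_inclusion(inc, cx, cy)
    sig[inside] <- phase_conductivity(inc$phase) * inc$amplitude_factor
  }
  sig
}
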
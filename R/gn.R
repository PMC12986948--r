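#' Build a regularization operator for one-step Gauss-Newton inversion
#'
#' The NOSER operator is the diagonal of J^T J (sensitivity-weighted Tikhonov
#' matrix); `tikhonov_identity` uses the identity.  Diagonal entries that
#' vanish (elements the measurements cannot see) are floored at 1e-12 times
#' the largest entry with a warning.
#'
#' @param J a `sensitivity_matrix` (or bare matrix).
#' @param kind `"noser"` or `"tikhonov_identity"`.
#' @param lambda regularization weight, default 0.05.
#' @return a `regularizer` with fields `kind`, `matrix` (sparse symmetric
#'   PSD), `lambda`.
#' @export
build_regularizer <- function(J, kind = c("noser", "tikhonov_identity"),
                              lambda = 0.05) {
  kind <- match.arg(kind)
  Jm <- if (inherits(J, "sensitivity_matrix")) J$entries else J
  if (any(!is.finite(Jm))) stop("J must be finite", call. = FALSE)
  stopifnot_positive(lambda, "lambda")
  ne <- ncol(Jm)
  R <- if (kind == "noser") {
    d <- colSums(Jm^2)
    if (any(d == 0)) {
      warning("zero NOSER diagonal entries floored at 1e-12 * max")
      d[d == 0] <- 1e-12 * max(d)
    }
    Matrix::Diagonal(ne, d)
  } else {
    Matrix::Diagonal(ne, rep(1, ne))
  }
  structure(list(kind = kind, matrix = R, lambda = lambda),
            class = "regularizer")
}

#' One-step regularized Gauss-Newton update
#'
#' Solves `(J^T J + lambda R) x = J^T dv` by a dense symmetric positive
#' definite (Cholesky) solve, returning the conductivity-change estimate on
#' the inverse-mesh elements.  With `dv` the measured data residual against
#' the homogeneous reference this is both the classical TR baseline and the
#' physics-guided prior fed to the diffusion model.
#'
#' @param J a `sensitivity_matrix` (or bare matrix, measurements x elements).
#' @param reg a `regularizer` from [build_regularizer()].
#' @param dv data residual vector (or matrix with one residual per column).
#' @return conductivity-change estimate(s); vector, or matrix if `dv` is one.
#' @export
gn_onestep <- function(J, reg, dv) {
  Jm <- if (inherits(J, "sensitivity_matrix")) J$entries else J
  op <- gn_operator(Jm, reg)
  op(dv)
}

#' Precompute the one-step Gauss-Newton solve operator
#'
#' Factorizes `(J^T J + lambda R)` once and returns a function mapping data
#' residuals to updates; used to amortize the factorization over a dataset.
#'
#' @inheritParams gn_onestep
#' @return function `dv -> x`.
#' @export
gn_operator <- function(J, reg) {
  Jm <- if (inherits(J, "sensitivity_matrix")) J$entries else J
  M <- crossprod(Jm) + reg$lambda * as.matrix(reg$matrix)
  ch <- tryCatch(chol(M), error = function(e) {
    stop("Gauss-Newton normal matrix is not positive definite: ",
         conditionMessage(e), call. = FALSE)
  })
  function(dv) {
    rhs <- crossprod(Jm, dv)
    backsolve(ch, forwardsolve(t(ch), rhs))
  }
}

#' Map an inverse-mesh element field to a pixel image
#'
#' Each pixel inside the disk takes the value of the element containing its
#' centre (nearest element centroid for boundary slivers); pixels outside the
#' disk are exactly zero.
#'
#' @param update per-element values on `mesh`.
#' @param mesh the inverse `eit_mesh`.
#' @param res output resolution (default 64).
#' @param pixmap optional precomputed [mesh_pixel_map()] for `mesh`/`res`.
#' @return a `prior_image`: list with `pixels` (res x res), `mask`, `source`.
#' @export
elements_to_grid <- function(update, mesh, res = 64L, pixmap = NULL) {
  if (length(update) != mesh$n_elements) {
    stop("update length must equal the inverse-mesh element count", call. = FALSE)
  }
  pm <- pixmap %||% mesh_pixel_map(mesh, res)
  img <- matrix(0, res, res)
  img[pm$in_disk] <- update[pm$element[pm$in_disk]]
  structure(list(pixels = img, mask = pm$in_disk, source = "gn_onestep"),
            class = "prior_image")
}

#' Pixel-centre to mesh-element lookup
#'
#' For every pixel centre of a res x res grid over [-1,1]^2 (row 1 = top),
#' finds the containing triangle by barycentric tests, falling back to the
#' nearest element centroid for in-disk pixels that hit no triangle (boundary
#' slivers between the polygonal mesh hull and the true circle).
#'
#' @param mesh an `eit_mesh`.
#' @param res grid resolution.
#' @return list with `element` (res x res integer matrix, NA outside disk)
#'   and `in_disk` (logical mask).
#' @export
mesh_pixel_map <- function(mesh, res = 64L) {
  key <- paste0(.mesh_key(mesh), "_px", res)
  if (exists(key, envir = .mesh_cache_env, inherits = FALSE)) {
    return(get(key, envir = .mesh_cache_env))
  }
  g <- .grid_centers(res)
  X <- matrix(rep(g, each = res), res, res)
  Y <- matrix(rep(rev(g), times = res), res, res)
  in_disk <- X^2 + Y^2 <= 1
  px <- X[in_disk]; py <- Y[in_disk]
  elem <- .locate_points(mesh, px, py)
  ## fallback: nearest centroid
  miss <- is.na(elem)
  if (any(miss)) {
    for (i in which(miss)) {
      d2 <- (mesh$centroids[, 1] - px[i])^2 + (mesh$centroids[, 2] - py[i])^2
      elem[i] <- which.min(d2)
    }
  }
  element <- matrix(NA_integer_, res, res)
  element[in_disk] <- elem
  out <- list(element = element, in_disk = in_disk)
  assign(key, out, envir = .mesh_cache_env)
  out
}

## vectorized point location: barycentric sign tests against all elements
.locate_points <- function(mesh, px, py, tol = 1e-12) {
  tri <- mesh$triangles
  co <- mesh$node_coords
  n_pt <- length(px)
  elem <- rep(NA_integer_, n_pt)
  p1 <- co[tri[, 1], , drop = FALSE]
  p2 <- co[tri[, 2], , drop = FALSE]
  p3 <- co[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  for (e in seq_len(nrow(tri))) {
    un <- which(is.na(elem))
    if (length(un) == 0) break
    dx <- px[un] - p1[e, 1]; dy <- py[un] - p1[e, 2]
    l2 <- ((p3[e, 2] - p1[e, 2]) * dx - (p3[e, 1] - p1[e, 1]) * dy) / det[e]
    l3 <- (-(p2[e, 2] - p1[e, 2]) * dx + (p2[e, 1] - p1[e, 1]) * dy) / det[e]
    hit <- l2 >= -tol & l3 >= -tol & (l2 + l3) <= 1 + tol
    elem[un[hit]] <- e
  }
  elem
}

#' Pixel-image to mesh-element averaging operator
#'
#' Builds the sparse matrix `M` (elements x pixels) whose product with a
#' vectorized res x res image yields per-element values: the mean of the
#' pixels whose centres fall in each element (nearest pixel if an element
#' contains none).  Composing the element Jacobian with `M` gives the
#' pixel-space sensitivity used by the linearized physics-consistency loss.
#'
#' @param mesh an `eit_mesh`.
#' @param res image resolution.
#' @return sparse matrix (n_elements x res^2); vectorization is column-major
#'   over the (row, col) image layout.
#' @export
grid_to_elements_map <- function(mesh, res = 64L) {
  pm <- mesh_pixel_map(mesh, res)
  pix_idx <- which(pm$in_disk)            # column-major positions
  elems <- pm$element[pm$in_disk]
  ii <- elems; jj <- pix_idx; xx <- rep(1, length(ii))
  cnt <- tabulate(elems, nbins = mesh$n_elements)
  empty <- which(cnt == 0)
  if (length(empty) > 0) {
    g <- .grid_centers(res)
    X <- matrix(rep(g, each = res), res, res)
    Y <- matrix(rep(rev(g), times = res), res, res)
    for (e in empty) {
      d2 <- (X - mesh$centroids[e, 1])^2 + (Y - mesh$centroids[e, 2])^2
      j <- which.min(d2)
      ii <- c(ii, e); jj <- c(jj, j); xx <- c(xx, 1)
      cnt[e] <- 1L
    }
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(mesh$n_elements, res^2))
  Matrix::Diagonal(mesh$n_elements, 1 / cnt) %*% M
}

#' Pixel-space sensitivity matrix
#'
#' @param J a `sensitivity_matrix` on `mesh`.
#' @param mesh the inverse mesh.
#' @param res image resolution.
#' @return dense matrix (n_measurements x res^2) mapping a vectorized
#'   conductivity-change image to a predicted voltage difference.
#' @export
pixel_jacobian <- function(J, mesh, res = 64L) {
  Jm <- if (inherits(J, "sensitivity_matrix")) J$entries else J
  as.matrix(Jm %*% grid_to_elements_map(mesh, res))
}
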
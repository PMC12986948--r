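#' Triangulated unit-disk mesh with boundary electrodes
#'
#' Builds a structured triangulation of the unit disk from concentric rings of
#' nodes, with a boundary layout that places `electrode_count` equal metal arcs
#' uniformly around the circumference.  Electrode 1 starts at angle 0 and
#' numbering proceeds counter-clockwise.  The angular node count is graded
#' towards the centre (halving ring by ring) while remaining a multiple of the
#' electrode count, so the mesh maps onto itself exactly under rotation by one
#' electrode spacing.  That discrete rotational symmetry is what makes
#' homogeneous-disk measurement frames cyclically identical across injections.
#'
#' @param target_elements requested number of triangles (>= 64); the realized
#'   count is the closest achievable by the structured layout.
#' @param electrode_count number of boundary electrodes L (>= 4).
#' @param coverage fraction of the boundary covered by electrode metal,
#'   strictly between 0 and 1.  The realized coverage is quantized to the
#'   boundary edge length and reported in the returned object.
#' @return an object of class `eit_mesh` with fields `node_coords` (n x 2),
#'   `triangles` (E x 3, positively oriented), `boundary_edges` (node-index
#'   pairs around the boundary in CCW order), `electrode_edges` (list of L
#'   integer vectors of boundary-edge indices), element `areas` and
#'   `centroids`, and layout metadata.
#' @export
build_disk_mesh <- function(target_elements, electrode_count = 16L, coverage = 0.5) {
  if (target_elements < 64) stop("`target_elements` must be >= 64", call. = FALSE)
  if (electrode_count < 4) stop("`electrode_count` must be >= 4", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) stop("`coverage` must be in (0, 1)", call. = FALSE)
  L <- as.integer(electrode_count)

  ## boundary edges per electrode period: k must admit >= 1 metal edge and
  ## >= 1 gap edge; search (k, n_rings) for the closest element count
  feas_k <- Filter(function(k) {
    me <- round(coverage * k)
    me >= 1 && me <= k - 1
  }, as.integer(2^(1:6)))
  if (length(feas_k) == 0) {
    stop("infeasible electrode coverage: arcs would overlap or vanish", call. = FALSE)
  }
  best <- NULL
  for (k in feas_k) {
    for (m in 2:80) {
      cnt <- .disk_mesh_count(L, k, m)
      score <- abs(cnt - target_elements)
      if (is.null(best) || score < best$score ||
          (score == best$score && cnt > best$cnt)) {
        best <- list(k = k, m = m, cnt = cnt, score = score)
      }
    }
  }
  k <- best$k; m <- best$m
  n_b <- as.integer(L * k)

  ring_counts <- vapply(seq_len(m), function(j) {
    max(L, n_b %/% as.integer(2^floor(log2(m / j))))
  }, integer(1))
  ring_counts[m] <- n_b

  ## nodes: centre first, then rings from inner to outer
  coords <- matrix(0, nrow = 1L + sum(ring_counts), ncol = 2)
  ring_start <- integer(m)  # index of first node of each ring
  idx <- 2L
  for (j in seq_len(m)) {
    ring_start[j] <- idx
    nj <- ring_counts[j]
    ang <- 2 * pi * (seq_len(nj) - 1L) / nj
    r <- j / m
    coords[idx:(idx + nj - 1L), ] <- cbind(r * cos(ang), r * sin(ang))
    idx <- idx + nj
  }

  tri <- matrix(0L, nrow = best$cnt, ncol = 3)
  te <- 0L
  ## centre fan
  n1 <- ring_counts[1]
  for (i in seq_len(n1)) {
    ip <- i %% n1 + 1L
    te <- te + 1L
    tri[te, ] <- c(1L, ring_start[1] + i - 1L, ring_start[1] + ip - 1L)
  }
  ## annular strips
  for (j in seq_len(m - 1L)) {
    ni <- ring_counts[j]; no <- ring_counts[j + 1L]
    si <- ring_start[j]; so <- ring_start[j + 1L]
    if (no == ni) {
      for (i in seq_len(ni)) {
        ip <- i %% ni + 1L
        a <- si + i - 1L; b <- si + ip - 1L
        c1 <- so + i - 1L; d1 <- so + ip - 1L
        te <- te + 1L; tri[te, ] <- c(a, c1, d1)
        te <- te + 1L; tri[te, ] <- c(a, d1, b)
      }
    } else if (no == 2L * ni) {
      for (i in seq_len(ni)) {
        ip <- i %% ni + 1L
        a <- si + i - 1L; b <- si + ip - 1L
        o1 <- so + 2L * (i - 1L)
        o2 <- so + (2L * (i - 1L) + 1L)
        o3 <- so + (2L * i) %% no
        te <- te + 1L; tri[te, ] <- c(a, o1, o2)
        te <- te + 1L; tri[te, ] <- c(a, o2, b)
        te <- te + 1L; tri[te, ] <- c(b, o2, o3)
      }
    } else {
      stop("internal error: unsupported ring transition", call. = FALSE)
    }
  }
  stopifnot(te == best$cnt)

  ## boundary edges (outer ring, CCW); edge i connects node i to node i+1
  sb <- ring_start[m]
  b_from <- sb + (seq_len(n_b) - 1L)
  b_to <- sb + (seq_len(n_b) %% n_b)
  boundary_edges <- cbind(b_from, b_to)

  m_e <- round(coverage * k)
  electrode_edges <- lapply(seq_len(L), function(l) {
    (l - 1L) * k + seq_len(m_e)
  })

  geo <- .triangle_geometry(coords, tri)
  structure(list(
    node_coords = coords,
    triangles = tri,
    boundary_edges = boundary_edges,
    electrode_edges = electrode_edges,
    n_nodes = nrow(coords),
    n_elements = nrow(tri),
    n_electrodes = L,
    coverage = m_e / k,
    areas = geo$areas,
    centroids = geo$centroids,
    grad_x = geo$grad_x,
    grad_y = geo$grad_y,
    ring_counts = ring_counts,
    edges_per_period = k
  ), class = "eit_mesh")
}

.disk_mesh_count <- function(L, k, m) {
  n_b <- as.integer(L * k)
  rc <- vapply(seq_len(m), function(j) max(L, n_b %/% as.integer(2^floor(log2(m / j)))), integer(1))
  rc[m] <- n_b
  cnt <- rc[1]
  for (j in seq_len(m - 1L)) {
    cnt <- cnt + if (rc[j + 1L] == rc[j]) 2L * rc[j] else 3L * rc[j]
  }
  cnt
}

## per-element signed areas, centroids, and P1 basis gradient coefficients
.triangle_geometry <- function(coords, tri) {
  p1 <- coords[tri[, 1], , drop = FALSE]
  p2 <- coords[tri[, 2], , drop = FALSE]
  p3 <- coords[tri[, 3], , drop = FALSE]
  det <- (p2[, 1] - p1[, 1]) * (p3[, 2] - p1[, 2]) -
         (p3[, 1] - p1[, 1]) * (p2[, 2] - p1[, 2])
  areas <- det / 2
  centroids <- (p1 + p2 + p3) / 3
  ## grad phi_i = (b_i, c_i) / (2A)
  bx <- cbind(p2[, 2] - p3[, 2], p3[, 2] - p1[, 2], p1[, 2] - p2[, 2]) / det
  by <- cbind(p3[, 1] - p2[, 1], p1[, 1] - p3[, 1], p2[, 1] - p1[, 1]) / det
  list(areas = areas, centroids = centroids, grad_x = bx, grad_y = by)
}

#' Validate the structural invariants of a disk mesh
#'
#' Checks containment in the unit disk, positive orientation, electrode-arc
#' disjointness/contiguity, and total-area consistency with pi.
#'
#' @param mesh an `eit_mesh`.
#' @return `TRUE` invisibly; stops on violation.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "eit_mesh"))
  r <- sqrt(rowSums(mesh$node_coords^2))
  if (any(r > 1 + 1e-9)) stop("mesh node outside unit disk", call. = FALSE)
  if (any(mesh$areas <= 0)) stop("non-positively-oriented triangle", call. = FALSE)
  tot <- sum(mesh$areas)
  if (tot > pi || tot < pi - 0.05) {
    stop(sprintf("total mesh area %.4f outside [pi - 0.05, pi]", tot), call. = FALSE)
  }
  all_e <- unlist(mesh$electrode_edges)
  if (anyDuplicated(all_e) > 0) stop("electrode arcs overlap", call. = FALSE)
  for (ed in mesh$electrode_edges) {
    if (length(ed) > 1 && any(diff(sort(ed)) != 1L)) {
      stop("electrode arc is not contiguous", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf(
    "<eit_mesh> %d nodes, %d elements, %d electrodes (coverage %.3f), area %.4f\n",
    x$n_nodes, x$n_elements, x$n_electrodes, x$coverage, sum(x$areas)))
  invisible(x)
}

#' Element permutation under rotation by one electrode spacing
#'
#' The structured disk mesh is invariant under rotation by `2*pi/L`.  This
#' returns the permutation `p` such that element `i` maps onto element `p[i]`
#' after that rotation (matched by rotated centroid, nearest neighbour).
#'
#' @param mesh an `eit_mesh`.
#' @return integer permutation vector of length `n_elements`.
#' @export
mesh_rotation_permutation <- function(mesh) {
  L <- mesh$n_electrodes
  th <- 2 * pi / L
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  rc <- mesh$centroids %*% rot
  perm <- integer(mesh$n_elements)
  ## match within rings of equal radius for robustness
  rad <- sqrt(rowSums(mesh$centroids^2))
  ord <- order(rad)
  d2 <- function(a, b) (a[, 1] - b[1])^2 + (a[, 2] - b[2])^2
  for (i in seq_len(mesh$n_elements)) {
    cand <- which(abs(rad - rad[i]) < 1e-9)
    perm[i] <- cand[which.min(d2(mesh$centroids[cand, , drop = FALSE], rc[i, ]))]
  }
  perm
}
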
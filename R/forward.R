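#' Adjacent injection / adjacent measurement stimulation protocol
#'
#' With L electrodes the adjacent protocol injects current between every
#' neighbouring electrode pair (l, l+1 mod L) and, for each injection,
#' measures the differential voltage across every neighbouring pair that does
#' not touch an injecting electrode, giving L*(L-3) measurements per frame
#' (208 for L = 16).  Measurement pairs are listed in fixed cyclic order
#' starting from the electrode after the current sink, so frames are
#' bit-reproducible.
#'
#' @param electrode_count number of electrodes L (>= 5).
#' @param amplitude injected current amplitude in mA (the three study modes
#'   use 1.0, 2.0 and 2.5 mA; any positive value is accepted).
#' @return a `stim_protocol` object with `injection_pairs` (L x 2, source and
#'   sink), `measurement_pairs` (list of L matrices, (L-3) x 2, positive and
#'   negative electrode), `amplitude_mA`, and `n_measurements`.
#' @export
build_adjacent_protocol <- function(electrode_count = 16L, amplitude = 1.0) {
  L <- as.integer(electrode_count)
  if (L < 5) stop("adjacent protocol needs at least 5 electrodes", call. = FALSE)
  stopifnot_positive(amplitude, "amplitude")
  nxt <- function(x) (x %% L) + 1L
  inj <- cbind(source = seq_len(L), sink = nxt(seq_len(L)))
  meas <- lapply(seq_len(L), function(l) {
    src <- l; snk <- nxt(l)
    a <- nxt(snk)  # start from the electrode after the sink
    pairs <- matrix(0L, nrow = L - 3L, ncol = 2)
    r <- 0L
    while (r < L - 3L) {
      b <- nxt(a)
      if (!(a %in% c(src, snk)) && !(b %in% c(src, snk))) {
        r <- r + 1L
        pairs[r, ] <- c(a, b)
      }
      a <- b
    }
    colnames(pairs) <- c("pos", "neg")
    pairs
  })
  structure(list(
    injection_pairs = inj,
    measurement_pairs = meas,
    amplitude_mA = amplitude,
    n_electrodes = L,
    n_measurements = L * (L - 3L)
  ), class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> adjacent, L = %d, %.1f mA, %d measurements/frame\n",
              x$n_electrodes, x$amplitude_mA, x$n_measurements))
  invisible(x)
}

#' Electrode array description
#'
#' @param count number of electrodes.
#' @param contact_impedances per-electrode contact impedance z_l in Ohm*m^2
#'   (recycled to length `count`).  Defaults to 1e-2 for every electrode.
#' @param coverage boundary fraction covered by metal.
#' @return an `electrode_array` list.
#' @export
electrode_array <- function(count = 16L, contact_impedances = 1e-2, coverage = 0.5) {
  stopifnot_positive(contact_impedances, "contact_impedances")
  structure(list(
    count = as.integer(count),
    contact_impedances = rep_len(contact_impedances, count),
    coverage = coverage
  ), class = "electrode_array")
}

#' Assemble the complete-electrode-model FEM system
#'
#' Discretizes the governing equation div(sigma grad u) = 0 with the complete
#' electrode model boundary conditions using piecewise-linear triangular
#' elements.  Unknowns are the n node potentials, the L electrode potentials
#' U_l, and one Lagrange multiplier enforcing the grounding condition
#' sum_l U_l = 0 (which preserves symmetry and electrode interchangeability).
#'
#' @param mesh an `eit_mesh`.
#' @param sigma per-element conductivity vector (S/m, strictly positive).
#' @param electrodes an `electrode_array` (count must match the mesh).
#' @return a `cem_system` list with the sparse symmetric system matrix `K`
#'   ((n+L+1) square), the conductivity-dependent part `K_sigma` and the
#'   contact-impedance part `K_z` (for structural inspection), an
#'   `rhs(currents)` builder mapping per-electrode injected currents (A) to a
#'   right-hand side, and index bookkeeping.
#' @export
assemble_cem <- function(mesh, sigma, electrodes) {
  stopifnot(inherits(mesh, "eit_mesh"))
  if (length(sigma) != mesh$n_elements) {
    stop("sigma length must equal the element count", call. = FALSE)
  }
  stopifnot_positive(sigma, "sigma")
  L <- electrodes$count
  if (L != mesh$n_electrodes) stop("electrode count mismatch", call. = FALSE)
  n <- mesh$n_nodes
  ntot <- n + L + 1L

  asm <- .cem_assembly_cache(mesh)
  ## conductivity block: sum_e sigma_e * G_e
  vals <- asm$stiff_vals * sigma[asm$stiff_elem]
  K_sigma <- Matrix::sparseMatrix(i = asm$stiff_i, j = asm$stiff_j, x = vals,
                                  dims = c(ntot, ntot))

  ## electrode (contact impedance) terms
  z <- electrodes$contact_impedances
  zi <- 1 / z[asm$el_of_term]
  K_z <- Matrix::sparseMatrix(i = asm$el_i, j = asm$el_j, x = asm$el_vals * zi,
                              dims = c(ntot, ntot))

  ## grounding constraint row/column: sum U_l = 0
  gi <- c(rep.int(ntot, L), n + seq_len(L))
  gj <- c(n + seq_len(L), rep.int(ntot, L))
  K_g <- Matrix::sparseMatrix(i = gi, j = gj, x = rep.int(1, 2L * L),
                              dims = c(ntot, ntot))

  K <- K_sigma + K_z + K_g
  structure(list(
    K = K, K_sigma = K_sigma, K_z = K_z,
    n_nodes = n, n_electrodes = L, ntot = ntot,
    rhs = function(currents) {
      stopifnot(length(currents) == L)
      if (abs(sum(currents)) > 1e-12 * max(abs(currents), 1e-300)) {
        stop("injected currents must sum to zero", call. = FALSE)
      }
      c(rep.int(0, n), currents, 0)
    }
  ), class = "cem_system")
}

## Precompute sigma-independent assembly data: stiffness triplets per element
## and electrode boundary-integral triplets (scaled by 1/z at assembly time).
.cem_assembly_cache <- function(mesh) {
  key <- .mesh_key(mesh)
  if (exists(key, envir = .mesh_cache_env, inherits = FALSE)) {
    return(get(key, envir = .mesh_cache_env))
  }
  n <- mesh$n_nodes
  E <- mesh$n_elements
  L <- mesh$n_electrodes

  ## stiffness: K_loc[a,b] = A * (grad phi_a . grad phi_b)
  gx <- mesh$grad_x; gy <- mesh$grad_y; A <- mesh$areas
  tri <- mesh$triangles
  ii <- jj <- ee <- integer(9L * E); vv <- numeric(9L * E)
  p <- 0L
  for (a in 1:3) for (b in 1:3) {
    idx <- p * E + seq_len(E)
    ii[idx] <- tri[, a]
    jj[idx] <- tri[, b]
    ee[idx] <- seq_len(E)
    vv[idx] <- A * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
    p <- p + 1L
  }

  ## electrode terms; edge (p,q) of length s on electrode l contributes
  ##   (1/z_l) * s/6 * [2 1; 1 2]          to the node-node block
  ##   -(1/z_l) * s/2                      to node-electrode couplings
  ##   (1/z_l) * s                         to the electrode diagonal
  el_i <- el_j <- integer(0); el_v <- numeric(0); el_of <- integer(0)
  coords <- mesh$node_coords
  for (l in seq_len(L)) {
    for (ei in mesh$electrode_edges[[l]]) {
      pq <- mesh$boundary_edges[ei, ]
      s <- sqrt(sum((coords[pq[1], ] - coords[pq[2], ])^2))
      i_new <- c(pq[1], pq[2], pq[1], pq[2], pq[1], pq[2], n + l, n + l, n + l)
      j_new <- c(pq[1], pq[2], pq[2], pq[1], n + l, n + l, pq[1], pq[2], n + l)
      v_new <- c(s / 3, s / 3, s / 6, s / 6, -s / 2, -s / 2, -s / 2, -s / 2, s)
      el_i <- c(el_i, i_new); el_j <- c(el_j, j_new); el_v <- c(el_v, v_new)
      el_of <- c(el_of, rep.int(l, 9L))
    }
  }
  cache <- list(stiff_i = ii, stiff_j = jj, stiff_elem = ee, stiff_vals = vv,
                el_i = el_i, el_j = el_j, el_vals = el_v, el_of_term = el_of)
  ## store on the mesh object in the caller is not possible by value; cache
  ## in an environment keyed by mesh identity instead
  .mesh_cache_put(mesh, cache)
  cache
}

.mesh_cache_env <- new.env(parent = emptyenv())
.mesh_key <- function(mesh) {
  paste0("m", mesh$n_nodes, "_", mesh$n_elements, "_", mesh$n_electrodes,
         "_", format(sum(mesh$areas), digits = 17),
         "_", format(mesh$coverage, digits = 17))
}
.mesh_cache_put <- function(mesh, cache) {
  assign(.mesh_key(mesh), cache, envir = .mesh_cache_env)
}

#' Solve the EIT forward problem for a full measurement frame
#'
#' Runs every injection of the protocol through the CEM system and extracts
#' the differential electrode voltages, returning the absolute frame F(sigma).
#'
#' @param mesh an `eit_mesh`.
#' @param sigma per-element conductivity (S/m).
#' @param electrodes an `electrode_array`.
#' @param protocol a `stim_protocol`.
#' @return a `voltage_frame` with `values` (length L*(L-3), volts), `kind =
#'   "absolute"`, plus `node_potentials` (n x L) and `electrode_potentials`
#'   (L x L) for downstream sensitivity computations.
#' @export
solve_forward <- function(mesh, sigma, electrodes, protocol) {
  sys <- assemble_cem(mesh, sigma, electrodes)
  L <- sys$n_electrodes
  I_A <- protocol$amplitude_mA * 1e-3
  B <- matrix(0, sys$ntot, L)
  for (d in seq_len(L)) {
    cur <- numeric(L)
    cur[protocol$injection_pairs[d, 1]] <- I_A
    cur[protocol$injection_pairs[d, 2]] <- -I_A
    B[, d] <- sys$rhs(cur)
  }
  W <- as.matrix(Matrix::solve(sys$K, B))
  res <- max(abs(sys$K %*% W - B)) / max(abs(B))
  if (!is.finite(res) || res > 1e-8) {
    stop(sprintf("forward solve did not converge (relative residual %.3e)", res),
         call. = FALSE)
  }
  U <- W[sys$n_nodes + seq_len(L), , drop = FALSE]
  vals <- numeric(protocol$n_measurements)
  r <- 0L
  for (d in seq_len(L)) {
    mp <- protocol$measurement_pairs[[d]]
    nm <- nrow(mp)
    vals[r + seq_len(nm)] <- U[mp[, 1], d] - U[mp[, 2], d]
    r <- r + nm
  }
  structure(list(
    values = vals, kind = "absolute",
    protocol_id = sprintf("adjacent-L%d-%.1fmA", L, protocol$amplitude_mA),
    node_potentials = W[seq_len(sys$n_nodes), , drop = FALSE],
    electrode_potentials = U
  ), class = "voltage_frame")
}

#' @export
print.voltage_frame <- function(x, ...) {
  cat(sprintf("<voltage_frame> %s, %d measurements, range [%.3e, %.3e] V\n",
              x$kind, length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Time-difference forward operator
#'
#' Returns the boundary voltage difference F(sigma2) - F(sigma1) between the
#' current and reference conductivity states on the same mesh.
#'
#' @inheritParams solve_forward
#' @param sigma1 reference-state conductivity (per element, S/m).
#' @param sigma2 current-state conductivity (per element, S/m).
#' @return a `voltage_frame` of kind `"difference"`.
#' @export
timediff_forward <- function(mesh, sigma1, sigma2, electrodes, protocol) {
  f1 <- solve_forward(mesh, sigma1, electrodes, protocol)
  f2 <- solve_forward(mesh, sigma2, electrodes, protocol)
  structure(list(values = f2$values - f1$values, kind = "difference",
                 protocol_id = f1$protocol_id),
            class = "voltage_frame")
}

#' Sensitivity (Jacobian) matrix of the forward operator
#'
#' Computes J(sigma_ref) with entry (m, e) = d(measurement m)/d(sigma_e) by
#' the adjoint-field identity: for drive field u_d and measurement field u_m
#' (the latter realized by the reciprocal unit-current injection through the
#' measurement pair), the sensitivity of the transfer voltage to the
#' conductivity of element e is -area_e * (grad u_d . grad u_m).  Under the
#' adjacent protocol every measurement pattern coincides with a drive pattern,
#' so a single batch of L solves yields the full matrix.
#'
#' @inheritParams solve_forward
#' @param sigma_ref linearization point (per element, S/m).
#' @return a `sensitivity_matrix` with `entries` (n_measurements x n_elements,
#'   V per S/m) and the `reference_field`.
#' @export
compute_jacobian <- function(mesh, sigma_ref, electrodes, protocol) {
  if (length(sigma_ref) != mesh$n_elements) {
    stop("sigma_ref length must equal the element count", call. = FALSE)
  }
  fwd <- solve_forward(mesh, sigma_ref, electrodes, protocol)
  L <- protocol$n_electrodes
  I_A <- protocol$amplitude_mA * 1e-3
  Un <- fwd$node_potentials
  ## per-element field gradients for each drive: E x L
  tri <- mesh$triangles
  Gx <- mesh$grad_x[, 1] * Un[tri[, 1], ] + mesh$grad_x[, 2] * Un[tri[, 2], ] +
        mesh$grad_x[, 3] * Un[tri[, 3], ]
  Gy <- mesh$grad_y[, 1] * Un[tri[, 1], ] + mesh$grad_y[, 2] * Un[tri[, 2], ] +
        mesh$grad_y[, 3] * Un[tri[, 3], ]
  J <- matrix(0, protocol$n_measurements, mesh$n_elements)
  r <- 0L
  for (d in seq_len(L)) {
    mp <- protocol$measurement_pairs[[d]]
    for (q in seq_len(nrow(mp))) {
      md <- mp[q, 1]  # measurement pattern = drive injecting at (pos, pos+1)
      r <- r + 1L
      J[r, ] <- -mesh$areas * (Gx[, d] * Gx[, md] + Gy[, d] * Gy[, md]) / I_A
    }
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian entries", call. = FALSE)
  structure(list(entries = J, reference_field = sigma_ref,
                 protocol_id = fwd$protocol_id),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("<sensitivity_matrix> %d x %d, linearized at sigma in [%.3g, %.3g]\n",
              nrow(x$entries), ncol(x$entries),
              min(x$reference_field), max(x$reference_field)))
  invisible(x)
}
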
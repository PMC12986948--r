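## Shared small fixtures, memoised across test files.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

small_mesh <- function(target = 300L) {
  memo(paste0("mesh", target), build_disk_mesh(target, 16L, 0.5))
}

std_protocol <- function(amplitude = 1.0) {
  memo(paste0("proto", amplitude), build_adjacent_protocol(16L, amplitude))
}

std_electrodes <- function() memo("el", electrode_array(16L))

homogeneous_frame <- function(target = 300L) {
  memo(paste0("frame", target), {
    m <- small_mesh(target)
    solve_forward(m, rep(1, m$n_elements), std_electrodes(), std_protocol())
  })
}

small_jacobian <- function(target = 300L) {
  memo(paste0("jac", target), {
    m <- small_mesh(target)
    compute_jacobian(m, rep(1, m$n_elements), std_electrodes(), std_protocol())
  })
}

## naive reference implementations used as oracles -------------------------

## three-nested-loop window attention on a token array (M2, I, C)
naive_attention <- function(tokens, params, mask = NULL, B = 1L) {
  M2 <- dim(tokens)[1]; I <- dim(tokens)[2]; C <- dim(tokens)[3]
  heads <- params$heads; d <- C %/% heads
  bidx <- eitdiff:::.rel_position_index(params$M)
  X2 <- tokens; dim(X2) <- c(M2 * I, C)
  Q <- X2 %*% params$Wq; K <- X2 %*% params$Wk; V <- X2 %*% params$Wv
  dim(Q) <- dim(K) <- dim(V) <- c(M2, I, C)
  O <- array(0, c(M2, I, C))
  for (i in seq_len(I)) {
    for (h in seq_len(heads)) {
      cols <- ((h - 1) * d + 1):(h * d)
      S <- matrix(0, M2, M2)
      for (a in seq_len(M2)) for (b in seq_len(M2)) {
        S[a, b] <- sum(Q[a, i, cols] * K[b, i, cols]) / sqrt(d) +
          params$bias_table[bidx[a, b], h] +
          if (is.null(mask)) 0 else mask[a, b, (i - 1) %/% B + 1]
      }
      for (a in seq_len(M2)) {
        p <- exp(S[a, ] - max(S[a, ])); p <- p / sum(p)
        for (cc in cols) O[a, i, cc] <- sum(p * V[, i, cc])
      }
    }
  }
  O2 <- O; dim(O2) <- c(M2 * I, C)
  out <- O2 %*% params$Wo + rep(params$bo, each = M2 * I)
  dim(out) <- c(M2, I, C)
  out
}

## step-by-step scalar state-space recursion
naive_scan <- function(X, abar, bbar, Cc, D) {
  Tlen <- dim(X)[1]; B <- dim(X)[2]; C <- dim(X)[3]
  N <- ncol(abar)
  Y <- array(0, dim(X))
  for (b in seq_len(B)) {
    h <- matrix(0, C, N)
    for (t in seq_len(Tlen)) {
      x <- X[t, b, ]
      h <- h * abar + bbar * x
      Y[t, b, ] <- rowSums(Cc * h) + D * x
    }
  }
  Y
}
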
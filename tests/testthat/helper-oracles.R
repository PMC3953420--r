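# Independent oracles, coded directly from the continuous/discrete formulas
# with plain loops, kept deliberately separate from the package internals.

# brute-force periodic 5-point Laplacian by looping over nodes
oracle_lap5 <- function(f, hx, hy) {
  nx <- nrow(f); ny <- ncol(f)
  out <- matrix(0, nx, ny)
  wrap <- function(i, n) ((i - 1) %% n) + 1
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    out[i, j] <- (f[wrap(i - 1, nx), j] - 2 * f[i, j] + f[wrap(i + 1, nx), j]) / hx^2 +
      (f[i, wrap(j - 1, ny)] - 2 * f[i, j] + f[i, wrap(j + 1, ny)]) / hy^2
  }
  out
}

# dense assembly of the periodic 5-point operator; minimum-norm solve via
# pseudo-inverse (the operator is singular with the constant null vector)
oracle_poisson_pinv <- function(rhs, hx, hy) {
  nx <- nrow(rhs); ny <- ncol(rhs)
  n <- nx * ny
  A <- matrix(0, n, n)
  wrap <- function(i, m) ((i - 1) %% m) + 1
  id <- function(i, j) (j - 1) * nx + i
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    r <- id(i, j)
    A[r, r] <- -2 / hx^2 - 2 / hy^2
    A[r, id(wrap(i + 1, nx), j)] <- A[r, id(wrap(i + 1, nx), j)] + 1 / hx^2
    A[r, id(wrap(i - 1, nx), j)] <- A[r, id(wrap(i - 1, nx), j)] + 1 / hx^2
    A[r, id(i, wrap(j + 1, ny))] <- A[r, id(i, wrap(j + 1, ny))] + 1 / hy^2
    A[r, id(i, wrap(j - 1, ny))] <- A[r, id(i, wrap(j - 1, ny))] + 1 / hy^2
  }
  sv <- svd(A)
  tol <- max(sv$d) * 1e-10
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  matrix(sv$v %*% (dinv * (t(sv$u) %*% as.vector(rhs))), nx, ny)
}

# filament force oracle: staggered tension/bending formulas written out
# node-by-node (nodes numbered k = 0..N from free to clamped end)
oracle_filament_forces <- function(X, ds, cs, cb, clamp_tangent = c(-1, 0)) {
  n <- nrow(X)
  N <- n - 1
  Tm <- numeric(N)   # tension at midpoints k+1/2, k = 0..N-1
  tau <- matrix(0, N, 2)
  for (k in 0:(N - 1)) {
    d <- (X[k + 2, ] - X[k + 1, ]) / ds
    nd <- sqrt(sum(d^2))
    Tm[k + 1] <- if (nd >= 1) cs * (nd - 1) else 0
    tau[k + 1, ] <- d / nd
  }
  Fs <- matrix(0, n, 2)
  for (k in 1:(N - 1))
    Fs[k + 1, ] <- (Tm[k + 1] * tau[k + 1, ] - Tm[k] * tau[k, ]) / ds
  Fs[1, ] <- Tm[1] * tau[1, ] / ds
  Fs[n, ] <- -Tm[N] * tau[N, ] / ds
  D2 <- matrix(0, n, 2)  # (Dss X)_k
  for (k in 1:(N - 1))
    D2[k + 1, ] <- (X[k + 2, ] - 2 * X[k + 1, ] + X[k, ]) / ds^2
  D2[n, ] <- (clamp_tangent - (X[n, ] - X[n - 1, ]) / ds) / (0.5 * ds)
  Fb <- matrix(0, n, 2)
  for (k in 1:(N - 1))
    Fb[k + 1, ] <- -cb * (D2[k + 2, ] - 2 * D2[k + 1, ] + D2[k, ]) / ds^2
  Fb[1, ] <- -cb * (D2[3, ] - D2[2, ]) / ds^2
  Fb[n, ] <- 0
  list(Fs = Fs, Fb = Fb, F = Fs + Fb)
}

# measured 1-d partition-of-unity defect of the delta profile, computed once
POU_DEFECT <- local({
  g <- seq(0, 1, length.out = 257)
  offs <- -3:4
  max(abs(rowSums(ib_phi(outer(g, rep(1, length(offs))) - outer(rep(1, length(g)), offs))) - 1))
})
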
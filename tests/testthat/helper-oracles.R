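# Independent oracles used to cross-check the package implementations.
# Each one is deliberately written with a different algorithm than the
# code path it validates.

# Horn's quaternion method for optimal rigid superposition (independent of
# the SVD-based Kabsch in the package).  Returns the fit RMSD.
oracle_rigid_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  ss <- sum(Pc^2) + sum(Qc^2) - 2 * lam
  sqrt(max(ss, 0) / nrow(P))
}

# HOLE-style sphere maximization: largest probe sphere centred on the
# (known) z axis at elevation z that avoids every vdW sphere.
oracle_hole_radius <- function(x, z) {
  vapply(z, function(zz) {
    d <- sqrt(x$xyz[, 1]^2 + x$xyz[, 2]^2 + (x$xyz[, 3] - zz)^2)
    max(min(d - x$atoms$vdw), 0)
  }, 1.0)
}

# brute-force MHP: triple loop, no matrix algebra
oracle_mhp <- function(x, points, lambda = 2) {
  points <- matrix(points, ncol = 3)
  out <- numeric(nrow(points))
  for (p in seq_len(nrow(points))) {
    acc <- 0
    for (i in seq_len(nrow(x$xyz))) {
      d <- sqrt(sum((x$xyz[i, ] - points[p, ])^2))
      acc <- acc + x$atoms$f[i] * exp(-d / lambda)
    }
    out[p] <- acc
  }
  out
}

# fine-lattice ASA with randomized (seed-fixed) directions, independent of
# the deterministic spiral lattice in the package
oracle_asa <- function(x, probe = 1.4, n = 20000L, seed = 123L) {
  set.seed(seed)
  u <- matrix(rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  ext <- x$atoms$vdw + probe
  vapply(seq_len(nrow(x$xyz)), function(i) {
    pts <- sweep(u * ext[i], 2, x$xyz[i, ], `+`)
    free <- rep(TRUE, n)
    for (j in seq_len(nrow(x$xyz))[-i]) {
      free <- free & rowSums(sweep(pts, 2, x$xyz[j, ])^2) >= ext[j]^2
    }
    4 * pi * ext[i]^2 * mean(free)
  }, 1.0)
}

# shoelace area of a planar polygon given in order, computed in its plane
oracle_shoelace <- function(p) {
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr))
  uv <- sweep(p, 2, ctr) %*% sv$v[, 1:2]
  n <- nrow(uv)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + uv[i, 1] * uv[j, 2] - uv[j, 1] * uv[i, 2]
  }
  abs(s) / 2
}

# direct-sum covariance of selected atom coordinates over frames
oracle_covariance <- function(traj, idx) {
  nf <- dim(traj$coords)[3]
  X <- t(vapply(seq_len(nf),
                function(f) as.vector(t(traj$coords[idx, , f])),
                numeric(3 * length(idx))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  crossprod(Xc) / (nf - 1)
}
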
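# Shared independent oracles used across test files.

# Dense steady-state system for the 1D diffusion-decay problem with
# Dirichlet ends held at g: D u'' = lambda u, ghosts at 0 and n+1.
steady_1d_oracle <- function(n, h, D, lambda, g) {
  A <- diag(-2 - lambda * h^2 / D, n)
  A[cbind(1:(n - 1), 2:n)] <- 1
  A[cbind(2:n, 1:(n - 1))] <- 1
  b <- rep(0, n)
  b[1] <- b[n] <- -g
  solve(A, b)
}

# Dense steady-state solve of the 2D uptake problem
# (lambda + U occ) u = D lap(u), Dirichlet ghosts at g; small grids only.
steady_2d_oracle <- function(occ, h, D, lambda, uptake, g) {
  n <- nrow(occ); m <- ncol(occ)
  idx <- function(i, j) (j - 1) * n + i
  Dh2 <- D / h^2
  N <- n * m
  A <- matrix(0, N, N)
  b <- numeric(N)
  for (j in 1:m) for (i in 1:n) {
    k <- idx(i, j)
    dg <- lambda + uptake * occ[i, j]
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      dg <- dg + Dh2
      if (nb[1] >= 1 && nb[1] <= n && nb[2] >= 1 && nb[2] <= m)
        A[k, idx(nb[1], nb[2])] <- -Dh2
      else b[k] <- b[k] + Dh2 * g
    }
    A[k, k] <- dg
  }
  matrix(solve(A, b), n, m)
}

# largest-remainder apportionment by direct enumeration (independent of the
# package implementation): returns all optimal integer allocations that
# minimize the total absolute deviation from the quotas.
apportion_enumerate <- function(n, fractions) {
  quota <- n * fractions / 100
  base <- floor(quota)
  short <- n - sum(base)
  k <- length(fractions)
  if (short == 0) return(list(base))
  combos <- utils::combn(k, short, simplify = FALSE)
  dev <- vapply(combos, function(cc) {
    alloc <- base; alloc[cc] <- alloc[cc] + 1
    sum(abs(alloc - quota))
  }, numeric(1))
  lapply(combos[dev == min(dev) + 1e-12 | dev <= min(dev) + 1e-12], function(cc) {
    alloc <- base; alloc[cc] <- alloc[cc] + 1; alloc
  })
}
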
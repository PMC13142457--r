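# Independent oracles shared across test files.

# principal angles between column spaces, sine-based (numerically stable
# near zero): sin(theta) are the singular values of (I - Qa Qa') Qb
principalAngles <- function(A, B) {
  Qa <- qr.Q(qr(A)); Qb <- qr.Q(qr(B))
  s <- svd(Qb - Qa %*% (t(Qa) %*% Qb))$d
  asin(pmin(pmax(s, 0), 1))
}

# dense oracle: eigenvectors of solve(D) %*% B computed explicitly from the
# scatter-matrix definitions (nonsymmetric eigensolve, independent of the
# package's symmetric-whitening route)
denseLdaOracle <- function(X, labels, varFloor) {
  f <- factor(labels)
  mu <- colMeans(X)
  B <- matrix(0, ncol(X), ncol(X))
  d <- numeric(ncol(X))
  for (cl in levels(f)) {
    rows <- X[f == cl, , drop = FALSE]
    mk <- colMeans(rows)
    B <- B + nrow(rows) * outer(mk - mu, mk - mu)
    d <- d + colSums(sweep(rows, 2, mk)^2)
  }
  d <- pmax(d, 0) + varFloor
  eg <- eigen(diag(1 / d, ncol(X)) %*% B)
  k <- min(nlevels(f) - 1L, sum(Re(eg$values) > 1e-10))
  Re(eg$vectors[, seq_len(k), drop = FALSE])
}

# worst principal angle between package fit and dense oracle over random
# small instances
ldaOracleWorstAngle <- function(nInstances = 100L, seed = 42L) {
  set.seed(seed)
  worst <- 0
  for (r in seq_len(nInstances)) {
    n <- sample(10:60, 1); p <- sample(2:6, 1); K <- sample(2:3, 1)
    labels <- sample(rep(seq_len(K), length.out = n))
    X <- matrix(rnorm(n * p), n, p) +
      matrix(rnorm(K * p), K, p)[labels, ] * runif(1, 0, 2)
    fit <- fitDiagLDA(X, labels, varFloor = 1e-9)
    oracle <- denseLdaOracle(X, labels, varFloor = 1e-9)
    worst <- max(worst, max(principalAngles(fit@projection, oracle)))
  }
  worst
}
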
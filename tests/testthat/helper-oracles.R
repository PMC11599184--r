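# Independent oracles used to validate the package implementations.
# These deliberately re-derive every quantity from first principles
# (double loops, dense solves, exhaustive enumeration) and share no code
# with the functions they check.

# GRM: literal per-entry evaluation of the centred, frequency-scaled sum.
oracle_grm <- function(X) {
  n <- nrow(X); s <- ncol(X)
  p <- colSums(X) / (2 * n)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (v in seq_len(s))
      acc <- acc + (X[i, v] - 2 * p[v]) * (X[j, v] - 2 * p[v]) /
        (2 * p[v] * (1 - p[v]))
    G[i, j] <- acc / s
  }
  G
}

# MRM: literal per-entry evaluation through P = ab + 1, log,
# column standardisation (n-1 SD), M = X X' / p.
oracle_mrm <- function(ab) {
  P <- ab + 1
  L <- log(P)
  n <- nrow(L); p <- ncol(L)
  Xs <- matrix(0, n, p)
  for (j in seq_len(p)) {
    mu <- mean(L[, j])
    sdv <- sqrt(sum((L[, j] - mu)^2) / (n - 1))
    Xs[, j] <- (L[, j] - mu) / sdv
  }
  M <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n))
    M[i, k] <- sum(Xs[i, ] * Xs[k, ]) / p
  M
}

# Single-kernel REML by dense grid search over the variance ratio h,
# profiling out the total variance at each grid point.
oracle_reml_grid <- function(y, X, K, step = 0.001) {
  n <- length(y); p <- ncol(X); nr <- n - p
  hs <- seq(0, 1 - 1e-9, by = step)
  best <- -Inf; hbest <- NA
  for (h in hs) {
    V0 <- h * K + (1 - h) * diag(n)
    Vi <- tryCatch(solve(V0), error = function(e) NULL)
    if (is.null(Vi)) next
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    ss <- drop(t(r) %*% Vi %*% r)
    s2 <- ss / nr
    ll <- -0.5 * (nr * log(2 * pi) + nr * log(s2) +
                    as.numeric(determinant(V0)$modulus) +
                    as.numeric(determinant(XtViX)$modulus) + nr)
    if (ll > best) { best <- ll; hbest <- h }
  }
  list(loglik = best, h = hbest)
}

# Exhaustive two-sided rank-sum test for tiny groups.
oracle_wilcoxon_exact <- function(x, yv) {
  nx <- length(x); ny <- length(yv)
  r <- rank(c(x, yv))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  u_all <- apply(combos, 2, function(idx) {
    rr <- rank(c(x, yv))
    sum(rr[idx]) - nx * (nx + 1) / 2
  })
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Ordinary least squares through the normal equations.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  list(beta = drop(beta), resid = drop(y - X %*% beta))
}

# Small deterministic abundance matrix with exact detection fractions.
fixture_abundance <- function(n = 100, detects = c(0.29, 0.31, 0.50, 1.0),
                              seed = 42) {
  set.seed(seed)
  t_ <- length(detects)
  ab <- matrix(0, n, t_, dimnames = list(sprintf("S%04d", 1:n),
                                         paste0("tax", seq_len(t_))))
  for (j in seq_len(t_)) {
    k <- round(n * detects[j])
    ab[sample.int(n, k), j] <- runif(k, 0.1, 1)
  }
  # note: deliberately not row-normalised; these fixtures exercise
  # detection patterns and per-taxon values, not compositionality
  ab
}
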
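# Independent brute-force oracles used by the test suite. These deliberately
# take a different algorithmic route from the package implementation.

# Constrained least squares for AR(1) deconvolution, solved in jump space:
#   min 0.5*||y - K s||^2 + lambda * sum(s),  s >= 0,
# where K[t, u] = gamma^(t-u) for t >= u (so c = K s). Solved with a
# Lawson-Hanson active-set iteration on the KKT system; exact at
# convergence.
oracle_deconvolve <- function(y, gamma, lambda, tol = 1e-10, max_iter = 1000) {
  n <- length(y)
  K <- outer(seq_len(n), seq_len(n), function(t, u) ifelse(t >= u, gamma^(t - u), 0))
  Q <- crossprod(K)
  b <- crossprod(K, y) - lambda
  s <- numeric(n)
  passive <- rep(FALSE, n)
  for (iter in seq_len(max_iter)) {
    w <- b - Q %*% s
    w[passive] <- -Inf
    j <- which.max(w)
    if (w[j] <= tol) break
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- solve(Q[passive, passive, drop = FALSE], b[passive])
      if (all(z[passive] > tol)) {
        s <- z
        break
      }
      neg <- passive & z <= tol
      alpha <- min(s[neg] / (s[neg] - z[neg]))
      s <- s + alpha * (z - s)
      passive[passive & s <= tol] <- FALSE
      s[!passive] <- 0
    }
  }
  c_fit <- as.numeric(K %*% s)
  list(s = s, c = c_fit,
       objective = 0.5 * sum((y - c_fit)^2) + lambda * sum(s))
}

oasis_objective <- function(y, c_fit, gamma, lambda) {
  s <- c_fit - gamma * c(0, c_fit[-length(c_fit)])
  0.5 * sum((y - c_fit)^2) + lambda * sum(s)
}

# Exhaustive-enumeration Kruskal-Wallis H (no ties assumed handled by rank)
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  n <- length(x)
  g <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) * sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact two-sided Mann-Whitney p by enumeration of all arrangements
oracle_mw <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- min(u_of(seq_len(n1)), n1 * (n - n1) - u_of(seq_len(n1)))
  all_u <- apply(combn(n, n1), 2, function(idx) {
    u1 <- sum(r[idx]) - n1 * (n1 + 1) / 2
    min(u1, n1 * (n - n1) - u1)
  })
  list(u = u_obs, p = mean(all_u <= u_obs))
}
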
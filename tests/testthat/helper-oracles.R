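# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: moments come from a plain rejection-free sampler
# built on MASS::mvrnorm (eigen-based, unlike the package's Cholesky), and
# spanning trees are enumerated exhaustively with a hand-rolled union-find.

# Brute-force Monte-Carlo moments of a truncated Gaussian mixture:
# draw from the mixture the straightforward way, clip at zero, return moments.
oracle_truncated_mixture <- function(weights, means, covariances, n, seed) {
  set.seed(seed)
  K <- length(weights)
  M <- ncol(means)
  comp <- sample.int(K, n, replace = TRUE, prob = weights)
  X <- matrix(0, n, M)
  for (k in seq_len(K)) {
    idx <- which(comp == k)
    if (length(idx) == 0) next
    X[idx, ] <- MASS::mvrnorm(length(idx), means[k, ], covariances[[k]])
  }
  X <- pmax(X, 0)
  list(mean = colMeans(X), cov = stats::cov(X), se = apply(X, 2, stats::sd) / sqrt(n))
}

# Exhaustive minimum spanning tree weight on a small complete graph given a
# symmetric weight matrix; enumerates all (k choose 2) choose (k-1) edge sets
# and keeps the lightest acyclic connected one.
oracle_mst_weight <- function(W) {
  k <- nrow(W)
  if (k == 1) return(0)
  edges <- t(utils::combn(k, 2))
  wts <- W[edges]
  best <- Inf
  sets <- utils::combn(nrow(edges), k - 1)
  for (j in seq_len(ncol(sets))) {
    sel <- sets[, j]
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in sel) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a == b) { ok <- FALSE; break }  # cycle
      parent[a] <- b
    }
    if (ok) best <- min(best, sum(wts[sel]))
  }
  best
}

# Closed-form per-channel mean of a zero-truncated Gaussian mixture:
# E[max(X, 0)] = sum_k w_k [mu_k Phi(mu_k/s_k) + s_k phi(mu_k/s_k)].
oracle_truncated_mean <- function(gmm) {
  M <- ncol(gmm$means)
  out <- numeric(M)
  for (k in seq_along(gmm$weights)) {
    mu <- gmm$means[k, ]
    s <- sqrt(diag(gmm$covariances[[k]]))
    z <- ifelse(s > 0, mu / s, ifelse(mu >= 0, Inf, -Inf))
    out <- out + gmm$weights[k] * (mu * stats::pnorm(z) + s * stats::dnorm(z))
  }
  out
}

# Closed-form KL divergence between two multivariate normals.
oracle_gaussian_kl <- function(mu0, S0, mu1, S1) {
  M <- length(mu0)
  S1i <- solve(S1)
  0.5 * (sum(diag(S1i %*% S0)) +
           drop(t(mu1 - mu0) %*% S1i %*% (mu1 - mu0)) - M +
           log(det(S1) / det(S0)))
}

# Small labeled two-type reference drawn from known single-component GMMs.
make_two_type_reference <- function(n_per_type = 2000, M = 4, seed = 1) {
  g1 <- cell_type_gmm(1, matrix(seq(2, length.out = M, by = 0.5), 1),
                      list(diag(0.2, M)))
  g2 <- cell_type_gmm(1, matrix(seq(4, length.out = M, by = -0.3), 1),
                      list(diag(0.3, M)))
  model <- reference_model(list(A = g1, B = g2), c(0.5, 0.5))
  data <- simulate_cells(model, 2 * n_per_type, seed = seed)
  list(model = model, data = data)
}
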
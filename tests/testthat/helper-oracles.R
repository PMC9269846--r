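# Independent oracles used to cross-check the implementation.

# Optimal 1-D k-means by dynamic programming over sorted data.
# Returns the minimal within-cluster sum of squares. O(k n^2).
optimal_kmeans_1d_obj <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {            # within-SSE of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  dp <- matrix(Inf, nrow = k, ncol = n)
  for (j in 1:n) dp[1, j] <- sse(1, j)
  if (k > 1) for (kk in 2:k) for (j in kk:n) {
    for (i in kk:j) {
      v <- dp[kk - 1, i - 1] + sse(i, j)
      if (v < dp[kk, j]) dp[kk, j] <- v
    }
  }
  dp[k, n]
}

# within-SSE of the implementation's centers on the same data
kmeans_objective <- function(x, centers) {
  sum(vapply(x, function(xi) min((xi - centers)^2), 0))
}

# Exhaustive best-subset least squares over all supports of size t.
# Returns list(support sorted, coef, resid_norm).
brute_force_sparse_fit <- function(x, D, t) {
  K <- ncol(D)
  best <- list(resid = Inf)
  for (ss in utils::combn(K, t, simplify = FALSE)) {
    fit <- qr(D[, ss, drop = FALSE])
    if (fit$rank < t) next
    cf <- qr.coef(fit, x)
    r <- sqrt(sum((x - D[, ss, drop = FALSE] %*% cf)^2))
    if (r < best$resid) best <- list(resid = r, support = ss, coef = cf)
  }
  best
}

# plain-loop aggregation oracles
loop_aggregate <- function(coefs, kind) {
  d <- dim(coefs)
  out <- numeric(d[1] * d[3])
  for (l in seq_len(d[1])) for (a in seq_len(d[3])) {
    v <- coefs[l, , a]
    out[(l - 1) * d[3] + a] <- switch(kind,
      single = v[1], mean = mean(v), max = max(abs(v)))
  }
  out
}

# sort-based median with the lower-middle convention
sort_median_lower <- function(v) sort(v)[(length(v) + 1) %/% 2]

# planted dictionary fixture: unit-norm Gaussian generator plus exact
# t-sparse signals with coefficient magnitudes bounded away from zero
planted_dictionary <- function(L, K, n, t, seed, coherence_max = NULL) {
  set.seed(seed)
  repeat {
    G <- matrix(stats::rnorm(L * K), L)
    G <- sweep(G, 2, sqrt(colSums(G^2)), "/")
    if (is.null(coherence_max) || mutual_coherence(G) < coherence_max) break
  }
  X <- vapply(seq_len(n), function(i) {
    s <- sample(K, t)
    a <- stats::runif(t, 0.5, 2) * sample(c(-1, 1), t, replace = TRUE)
    as.numeric(G[, s, drop = FALSE] %*% a)
  }, numeric(L))
  list(G = G, X = X)
}

atom_recovery_rate <- function(G, D, thresh = 0.99) {
  Dm <- if (inherits(D, "sparse_dictionary")) D$D else as.matrix(D)
  M <- abs(crossprod(G, Dm))
  mean(apply(M, 1, max) > thresh)
}
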
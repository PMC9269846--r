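#' Dictionary object
#'
#' An L x K matrix of unit-norm atoms with provenance (`gabor`,
#' `learned`, or `ksvd`), build parameters, and the mutual coherence
#' (largest absolute inner product between distinct atoms).
#'
#' @param D L x K numeric matrix with unit-norm columns.
#' @param kind provenance string.
#' @param params list of build parameters.
#' @return a `sparse_dictionary`.
#' @export
sparse_dictionary <- function(D, kind, params = list()) {
  norms <- sqrt(colSums(D^2))
  if (any(abs(norms - 1) > 1e-10)) stop("dictionary columns must be unit norm")
  structure(list(D = D, kind = kind, params = params,
                 coherence = mutual_coherence(D)),
            class = "sparse_dictionary")
}

dictionary_matrix <- function(D) {
  if (inherits(D, "sparse_dictionary")) D$D else as.matrix(D)
}

#' Mutual coherence of a dictionary
#' @param D matrix or `sparse_dictionary`.
#' @return largest absolute inner product between distinct unit atoms.
#' @export
mutual_coherence <- function(D) {
  Dm <- dictionary_matrix(D)
  if (ncol(Dm) < 2) return(0)
  G <- abs(crossprod(Dm))
  diag(G) <- 0
  max(G)
}

#' Build a parametric Gabor dictionary
#'
#' Atoms are Gaussian-windowed cosines
#' `g(t) = exp(-(t-u)^2 / (2 sigma^2)) * cos(2 pi xi (t-u) + phi)`
#' enumerated over a deterministic grid: 5 scales in a geometric ladder
#' from L/32 to L/2, 8 equispaced translations, equispaced frequencies in
#' [0, 0.25] cycles/sample, and phases {0, pi/2}, in (sigma, xi, u, phi)
#' lexicographic order. Zero-norm atoms (xi = 0 with the quadrature
#' phase) and near-duplicates are skipped; the frequency count starts at
#' `ceil(K / 80)` and grows deterministically until K distinct atoms
#' exist. The enumeration is truncated to exactly K atoms and each atom
#' is normalized.
#'
#' @param L atom length in samples (>= 16).
#' @param K number of atoms (>= 1).
#' @return a `sparse_dictionary` of kind `"gabor"`.
#' @export
build_gabor <- function(L, K) {
  if (K < 1) stop("K must be >= 1")
  if (L < 16) stop("L must be >= 16")
  sigmas <- exp(seq(log(L / 32), log(L / 2), length.out = 5))
  us <- (seq_len(8) - 1) * L / 8
  phis <- c(0, pi / 2)
  t <- seq_len(L) - 1
  n_freq <- max(1L, ceiling(K / (5 * 8 * 2)))
  max_freq <- 16L * ceiling(K / (5 * 8 * 2)) + 64L
  repeat {
    xis <- if (n_freq == 1) 0 else seq(0, 0.25, length.out = n_freq)
    # (sigma, xi, u, phi) lexicographic enumeration
    grid <- expand.grid(phi = phis, u = us, xi = xis, sigma = sigmas,
                        KEEP.OUT.ATTRS = FALSE)
    atoms <- matrix(0, nrow = L, ncol = 0)
    for (i in seq_len(nrow(grid))) {
      sg <- grid$sigma[i]; xi <- grid$xi[i]; u <- grid$u[i]; phi <- grid$phi[i]
      g <- exp(-(t - u)^2 / (2 * sg^2)) * cos(2 * pi * xi * (t - u) + phi)
      nv <- sqrt(sum(g^2))
      if (nv < 1e-12) next
      g <- g / nv
      if (ncol(atoms) > 0 && max(abs(crossprod(atoms, g))) > 1 - 1e-8) next
      atoms <- cbind(atoms, g)
      if (ncol(atoms) == K) break
    }
    if (ncol(atoms) >= K) {
      return(sparse_dictionary(atoms[, seq_len(K), drop = FALSE], "gabor",
                               params = list(L = L, K = K, n_freq = n_freq)))
    }
    if (n_freq >= max_freq)
      stop("Gabor grid cannot supply ", K, " distinct atoms (achievable: ",
           ncol(atoms), ")")
    n_freq <- n_freq + 1L
  }
}

# shared helpers for the two dictionary learners -------------------------

sparse_code_matrix <- function(X, Dm, T_nonzero) {
  n <- ncol(X)
  C <- matrix(0, nrow = ncol(Dm), ncol = n)
  for (i in seq_len(n)) C[, i] <- omp_encode(X[, i], Dm, T_nonzero)$coef
  C
}

# per-column comparison against the previous iteration's codes: keeping
# whichever code reconstructs better under the current dictionary makes
# the coding step non-increasing in the training objective (greedy OMP
# alone carries no such guarantee)
best_of_codes <- function(X, Dm, C_new, C_old) {
  if (is.null(C_old)) return(C_new)
  r_new <- colSums((X - Dm %*% C_new)^2)
  r_old <- colSums((X - Dm %*% C_old)^2)
  keep_old <- r_old < r_new
  C_new[, keep_old] <- C_old[, keep_old]
  C_new
}

frob_objective <- function(X, Dm, C) sum((X - Dm %*% C)^2)

# replace an atom with the currently worst-reconstructed training column
worst_column <- function(X, Dm, C) {
  resid <- colSums((X - Dm %*% C)^2)
  X[, which.max(resid)]
}

# initial dictionary: from a seeded permutation of the training columns,
# greedily pick K mutually incoherent (normalized) columns — seeding two
# atoms on near-identical columns is the main cause of duplicate-atom
# local minima in both learners
seeded_init <- function(X, K, seed) {
  rng <- local_rng(seed)
  idx <- rng$int(ncol(X), ncol(X))
  cand <- X[, idx[seq_len(min(ncol(X), 8L * K))], drop = FALSE]
  norms <- sqrt(colSums(cand^2))
  cand <- sweep(cand[, norms > 0, drop = FALSE], 2, norms[norms > 0], "/")
  if (ncol(cand) < K) stop("not enough non-zero training columns")
  D0 <- cand[, 1, drop = FALSE]
  while (ncol(D0) < K) {
    coh <- apply(abs(crossprod(cand, D0)), 1, max)
    D0 <- cbind(D0, cand[, which.min(coh)])
  }
  unname(D0)
}

#' Learn a dictionary by alternating minimization (method of optimal
#' directions)
#'
#' Alternates OMP sparse coding of every training column with a global
#' dictionary update `D <- X C' (C C' + eps I)^-1`, column
#' renormalization (with compensating rescaling of the codes), and
#' replacement of unused atoms by the worst-reconstructed training
#' column. The Frobenius objective `||X - D C||_F^2` is recorded after
#' every iteration.
#'
#' @param X L x n matrix of training segments (n >= K).
#' @param K number of atoms.
#' @param T_nonzero non-zeros per code used during training (<= L).
#' @param iters number of alternations.
#' @param seed integer seed for the initial column sample.
#' @return a `sparse_dictionary` of kind `"learned"` with the objective
#'   trace in `params$objective`.
#' @export
learn_dictionary_mod <- function(X, K, T_nonzero, iters = 30, seed = 1) {
  check_learner_args(X, K, T_nonzero)
  Dm <- seeded_init(X, K, seed)
  objective <- numeric(0)
  C <- NULL
  for (it in seq_len(iters)) {
    C <- best_of_codes(X, Dm, sparse_code_matrix(X, Dm, T_nonzero), C)
    G <- tcrossprod(C)
    Dm <- X %*% t(C) %*% solve(G + 1e-8 * diag(K))
    renorm <- renormalize(Dm, C)
    Dm <- renorm$D; C <- renorm$C
    objective <- c(objective, frob_objective(X, Dm, C))
    Dm <- replace_dead_atoms(X, Dm, C)
  }
  finalize_dictionary(X, Dm, "learned", K, T_nonzero, iters, seed, objective)
}

#' Learn a dictionary by KSVD
#'
#' Same outer loop as [learn_dictionary_mod()], but the dictionary update
#' sweeps atoms one by one: for atom k, the residual restricted to the
#' signals that use it is formed with atom k removed, and its rank-1 SVD
#' yields the updated atom (first left singular vector) and its
#' coefficients (first singular value times the first right singular
#' vector). Unused atoms are replaced by the worst-reconstructed signal.
#'
#' @inheritParams learn_dictionary_mod
#' @return a `sparse_dictionary` of kind `"ksvd"` with the objective
#'   trace in `params$objective`.
#' @export
learn_dictionary_ksvd <- function(X, K, T_nonzero, iters = 30, seed = 1) {
  check_learner_args(X, K, T_nonzero)
  Dm <- seeded_init(X, K, seed)
  objective <- numeric(0)
  C <- NULL
  for (it in seq_len(iters)) {
    C <- best_of_codes(X, Dm, sparse_code_matrix(X, Dm, T_nonzero), C)
    for (k in seq_len(K)) {
      omega <- which(C[k, ] != 0)
      if (length(omega) == 0) {
        w <- worst_column(X, Dm, C)
        nv <- sqrt(sum(w^2))
        if (nv > 0) Dm[, k] <- w / nv
        next
      }
      Ek <- X[, omega, drop = FALSE] -
        Dm[, -k, drop = FALSE] %*% C[-k, omega, drop = FALSE]
      sv <- svd(Ek, nu = 1, nv = 1)
      Dm[, k] <- sv$u[, 1]
      C[k, omega] <- sv$d[1] * sv$v[, 1]
    }
    objective <- c(objective, frob_objective(X, Dm, C))
    Dm <- replace_dead_atoms(X, Dm, C)
  }
  finalize_dictionary(X, Dm, "ksvd", K, T_nonzero, iters, seed, objective)
}

check_learner_args <- function(X, K, T_nonzero) {
  if (ncol(X) < K) stop("need at least K training columns (n >= K)")
  if (T_nonzero > nrow(X)) stop("T must not exceed the atom length")
}

renormalize <- function(Dm, C) {
  norms <- sqrt(colSums(Dm^2))
  norms[norms < 1e-12] <- 1
  list(D = sweep(Dm, 2, norms, "/"), C = C * norms)
}

# unused atoms, and near-duplicates of an earlier atom, are re-seeded at
# the worst-reconstructed training column (standard KSVD housekeeping;
# prevents rank collapse and two atoms converging onto one generator)
replace_dead_atoms <- function(X, Dm, C, dup_thresh = 0.95) {
  dead <- rowSums(C != 0) == 0
  G <- abs(crossprod(Dm))
  G[upper.tri(G, diag = TRUE)] <- 0
  dup <- apply(G, 1, max) > dup_thresh   # near-duplicate of an earlier atom
  resid <- colSums((X - Dm %*% C)^2)
  ord <- order(resid, decreasing = TRUE)
  i <- 0L
  for (k in which(dead | dup)) {
    i <- i + 1L
    w <- X[, ord[min(i, length(ord))]]
    nv <- sqrt(sum(w^2))
    if (nv > 0) Dm[, k] <- w / nv
  }
  Dm
}

finalize_dictionary <- function(X, Dm, kind, K, T_nonzero, iters, seed, objective) {
  norms <- sqrt(colSums(Dm^2))
  norms[norms < 1e-12] <- 1
  Dm <- sweep(Dm, 2, norms, "/")
  sparse_dictionary(Dm, kind,
                    params = list(K = K, T = T_nonzero, iters = iters,
                                  seed = seed, objective = objective))
}
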
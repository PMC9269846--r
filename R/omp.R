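#' Orthogonal Matching Pursuit sparse coding of one segment
#'
#' Greedy atom selection: at each of up to `T` steps the atom with the
#' largest absolute correlation with the current residual is added to the
#' active set (ties broken toward the lowest atom index), all active
#' coefficients are re-fitted by least squares, and the residual is
#' recomputed. Iteration stops early once the residual norm falls below
#' `tol * ||x||`. Atoms that would make the active set numerically
#' rank-deficient are skipped in favor of the next-best candidate.
#'
#' @param x segment vector, length equal to the dictionary atom length.
#' @param D a `sparse_dictionary` (or plain L x K matrix).
#' @param T_nonzero maximum number of non-zero coefficients (0 <= T <= K).
#' @param tol relative residual tolerance for early stopping.
#' @return a `sparse_code`: dense `coef` vector (length K), `support`
#'   (selected indices in selection order), `residual_norm`.
#' @export
omp_encode <- function(x, D, T_nonzero, tol = 1e-7) {
  Dm <- dictionary_matrix(D)
  if (length(x) != nrow(Dm)) stop("segment length does not match atom length")
  K <- ncol(Dm)
  if (T_nonzero < 0 || T_nonzero > K) stop("T must lie in [0, K]")
  coef <- numeric(K)
  normx <- sqrt(sum(x^2))
  sel <- integer(0)
  r <- x
  if (T_nonzero > 0 && normx > 0) {
    banned <- rep(FALSE, K)
    while (length(sel) < T_nonzero) {
      cors <- abs(as.numeric(crossprod(Dm, r)))
      cors[sel] <- -Inf
      cors[banned] <- -Inf
      repeat {
        j <- which.max(cors)
        if (!is.finite(cors[j]) || cors[j] <= 1e-12 * max(normx, 1)) {
          j <- 0L; break
        }
        trial <- c(sel, j)
        qrX <- qr(Dm[, trial, drop = FALSE])
        if (qrX$rank == length(trial)) break
        banned[j] <- TRUE                # rank-deficient addition: skip atom
        cors[j] <- -Inf
      }
      if (j == 0L) break
      sel <- c(sel, j)
      cs <- qr.coef(qrX, x)
      r <- x - Dm[, sel, drop = FALSE] %*% cs
      if (sqrt(sum(r^2)) <= tol * normx) { coef[sel] <- cs; break }
      coef[sel] <- cs
    }
  }
  structure(list(coef = coef, support = sel,
                 residual_norm = sqrt(sum(r^2))),
            class = "sparse_code")
}

#' Reconstruct a segment from its sparse code
#'
#' @param code a `sparse_code`.
#' @param D the dictionary it was coded against.
#' @return numeric vector of length L.
#' @export
omp_reconstruct <- function(code, D) {
  as.numeric(dictionary_matrix(D) %*% code$coef)
}

#' Sparse-code every segment of a segment set
#'
#' Applies [omp_encode()] independently to each (lead, segment) slice.
#'
#' @param segs a `qrs_segments` object.
#' @param D dictionary whose atom length equals the segment length.
#' @param T_nonzero maximum non-zeros per code.
#' @param tol early-stop tolerance, see [omp_encode()].
#' @return coefficient array of dimension 12 x S x K.
#' @export
encode_segment_set <- function(segs, D, T_nonzero, tol = 1e-7) {
  Dm <- dictionary_matrix(D)
  S <- dim(segs$tensor)[2]
  K <- ncol(Dm)
  out <- array(0, dim = c(12L, S, K))
  for (lead in 1:12) {
    for (j in seq_len(S)) {
      out[lead, j, ] <- omp_encode(segs$tensor[lead, j, ], Dm, T_nonzero, tol)$coef
    }
  }
  out
}
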
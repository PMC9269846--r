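#' Estimate the beat count from a bank of detector results
#'
#' The beat count is the integer median of the per-(detector, lead) peak
#' counts, with the lower middle value taken when the count list has even
#' length. Empty results contribute a count of zero: every (detector,
#' lead) pair of the bank votes.
#'
#' @param results list of `detector_result` objects (or any list whose
#'   elements carry a `positions` vector).
#' @return integer beat count estimate.
#' @export
estimate_count <- function(results) {
  if (length(results) == 0) stop("results must be non-empty")
  counts <- vapply(results, function(r) length(r$positions), 0L)
  lower_median(counts)
}

lower_median <- function(counts) {
  s <- sort(counts)
  s[(length(s) + 1L) %/% 2L]
}

#' Localize R-peaks as 1-D k-means centers of pooled detections
#'
#' Pools every detected position across detectors and leads into one flat
#' list and clusters it with 1-D k-means into `k` clusters. Because
#' optimal one-dimensional clusters are contiguous over the sorted pool,
#' the problem is solved exactly (and deterministically) by dynamic
#' programming at the pool sizes that arise here; oversized pools fall
#' back to Lloyd iteration with deterministic quantile initialization and
#' merge-split refinement. Cluster centers are rounded to the nearest
#' integer sample, sorted, and deduplicated; if the pool holds fewer than
#' `k` distinct positions, `k` is reduced accordingly.
#'
#' @param results list of `detector_result` objects.
#' @param k number of beats to localize.
#' @param record_length record length in samples (positions must lie
#'   within it).
#' @return an `rpeak_annotation`: `k`, sorted integer `positions`,
#'   `usable` flag (`k >= 3`, the minimum for segmentation to yield a
#'   segment).
#' @export
localize_peaks <- function(results, k, record_length) {
  if (k < 0) stop("k must be non-negative")
  pool <- sort(unlist(lapply(results, function(r) r$positions), use.names = FALSE))
  if (k == 0) return(rpeak_annotation(integer(0)))
  if (length(pool) == 0) stop("k > 0 with an empty position pool")
  n_distinct <- length(unique(pool))
  if (n_distinct < k) k <- n_distinct
  centers <- kmeans_1d(pool, k, max_iter = 300)
  pos <- sort(unique(pmin(pmax(round(centers), 1L), record_length)))
  rpeak_annotation(as.integer(pos))
}

#' @rdname localize_peaks
#' @param positions sorted integer R-peak positions.
#' @export
rpeak_annotation <- function(positions) {
  positions <- as.integer(positions)
  k <- length(positions)
  structure(list(k = k, positions = positions, usable = k >= 3),
            class = "rpeak_annotation")
}

# 1-D k-means. In one dimension the optimal clustering has contiguous
# clusters over the sorted data, so it is solved exactly by dynamic
# programming in O(k n^2); this is deterministic and never worse than any
# iterative scheme. Pools beyond `exact_max` points fall back to Lloyd's
# algorithm with order-statistic quantile initialization plus
# deterministic merge-split refinement.
kmeans_1d <- function(x, k, max_iter = 300, exact_max = 2000) {
  x <- sort(x)
  n <- length(x)
  k <- min(k, length(unique(x)))
  if (n <= exact_max) return(kmeans_1d_exact(x, k))
  init_idx <- unique(pmax(1L, ceiling((seq_len(k) - 0.5) / k * n)))
  centers <- unique(x[init_idx])
  if (length(centers) < k) {           # degenerate pool: spread over distinct values
    ux <- unique(x)
    centers <- ux[unique(pmax(1L, ceiling((seq_len(k) - 0.5) / k * length(ux))))]
  }
  k <- length(centers)
  centers <- lloyd_1d(x, centers, max_iter)
  if (k >= 2) {
    for (move in seq_len(2L * k)) {
      improved <- merge_split_move(x, centers)
      if (is.null(improved)) break
      centers <- lloyd_1d(x, improved, max_iter)
    }
  }
  centers
}

# exact DP over sorted data: dp[kk, j] = optimal within-SSE of x[1..j]
# using kk clusters; cluster means recovered by backtracking
kmeans_1d_exact <- function(x, k) {
  n <- length(x)
  if (k <= 1) return(mean(x))
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  dp <- matrix(Inf, k, n)
  arg <- matrix(0L, k, n)
  j1 <- seq_len(n)
  dp[1, ] <- cs2[j1 + 1] - cs[j1 + 1]^2 / j1
  for (kk in 2:k) {
    for (j in kk:n) {
      i <- kk:j                        # candidate start of the last cluster
      len <- j - i + 1
      cost <- (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / len
      tot <- dp[kk - 1, i - 1] + cost
      b <- which.min(tot)
      dp[kk, j] <- tot[b]
      arg[kk, j] <- i[b]
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (kk in k:2) {
    i <- arg[kk, j]
    bounds[kk] <- i - 1L
    j <- i - 1L
  }
  vapply(seq_len(k), function(kk) mean(x[(bounds[kk] + 1):bounds[kk + 1]]), 0)
}

lloyd_1d <- function(x, centers, max_iter) {
  k <- length(centers)
  n <- length(x)
  assign_old <- integer(n)
  for (it in seq_len(max_iter)) {
    bounds <- if (k > 1) (centers[-1] + centers[-k]) / 2 else numeric(0)
    assign_new <- findInterval(x, bounds) + 1L
    if (identical(assign_new, assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      mem <- x[assign_new == j]
      if (length(mem)) {
        centers[j] <- mean(mem)
      } else {
        # empty cluster: re-seed at the point farthest from its center
        d <- abs(x - centers[assign_new])
        centers[j] <- x[which.max(d)]
      }
    }
    centers <- sort(centers)
  }
  centers
}

# within-SSE of a chunk, and its optimal two-cluster split (sorted input)
chunk_sse <- function(v) sum(v^2) - sum(v)^2 / length(v)

best_split <- function(v) {
  m <- length(v)
  if (m < 2) return(list(gain = 0, centers = NULL))
  cs <- cumsum(v); cs2 <- cumsum(v^2)
  left <- cs2[-m] - cs[-m]^2 / seq_len(m - 1)
  right <- (cs2[m] - cs2[-m]) - (cs[m] - cs[-m])^2 / (m - seq_len(m - 1))
  i <- which.min(left + right)
  list(gain = chunk_sse(v) - (left[i] + right[i]),
       centers = c(mean(v[1:i]), mean(v[(i + 1):m])))
}

# one improving move: merge the cheapest adjacent cluster pair and split
# the cluster with the largest two-means gain; NULL when nothing improves
merge_split_move <- function(x, centers) {
  k <- length(centers)
  if (k < 2) return(NULL)
  bounds <- (centers[-1] + centers[-k]) / 2
  lab <- findInterval(x, bounds) + 1L
  chunks <- split(x, factor(lab, levels = seq_len(k)))
  sses <- vapply(chunks, function(v) if (length(v)) chunk_sse(v) else 0, 0)
  merge_cost <- vapply(seq_len(k - 1), function(i) {
    u <- c(chunks[[i]], chunks[[i + 1]])
    (if (length(u)) chunk_sse(u) else 0) - sses[i] - sses[i + 1]
  }, 0)
  splits <- lapply(chunks, best_split)
  gains <- vapply(splits, `[[`, 0, "gain")
  best <- NULL; best_delta <- 1e-9
  for (i in seq_len(k - 1)) {
    for (j in seq_len(k)) {
      if (j == i || j == i + 1 || is.null(splits[[j]]$centers)) next
      delta <- gains[j] - merge_cost[i]
      if (delta > best_delta) { best <- c(i, j); best_delta <- delta }
    }
  }
  if (is.null(best)) return(NULL)
  i <- best[1]; j <- best[2]
  merged <- mean(c(chunks[[i]], chunks[[i + 1]]))
  keep <- setdiff(seq_len(k), c(i, i + 1, j))
  sort(c(centers[keep], merged, splits[[j]]$centers))
}

#' Consensus R-peak detection over a 12-lead record
#'
#' Composition of [run_detector_bank()], [estimate_count()] and
#' [localize_peaks()]: every detector runs on every lead, the beat count
#' is the median of all per-(detector, lead) counts, and the peak
#' positions are the 1-D k-means cluster centers of the pooled
#' detections. Deterministic for a fixed record.
#'
#' @param record an `ecg_record`.
#' @param detectors registered detector names.
#' @return an `rpeak_annotation`.
#' @export
detect_consensus <- function(record, detectors = c("twoavg", "christov", "engzee")) {
  results <- run_detector_bank(record, detectors)
  k <- estimate_count(results)
  localize_peaks(results, k, ncol(record$signal))
}

#' Beat-count MAE and matched position error of annotations vs truth
#'
#' Count MAE is the mean absolute difference between detected and true
#' beat counts over records. Position error is the mean absolute
#' difference (ms) over greedily matched peak pairs within a 75 ms
#' window: true peaks are matched in order to the nearest unused
#' detection.
#'
#' @param annotations list of `rpeak_annotation` objects.
#' @param truths list of `ecg_ground_truth` objects (or any list with a
#'   `positions` element).
#' @param fs sampling rate used to convert samples to ms.
#' @return list with `count_mae` (beats), `position_mae_ms`,
#'   `n_matched`, `n_records`.
#' @export
evaluate_rpeak_mae <- function(annotations, truths, fs = 500) {
  if (length(annotations) != length(truths))
    stop("annotations and truths must have equal length")
  if (length(annotations) == 0) stop("empty collections")
  count_err <- mapply(function(a, t) abs(a$k - length(t$positions)),
                      annotations, truths)
  win <- 0.075 * fs
  errs <- numeric(0)
  for (i in seq_along(annotations)) {
    det <- annotations[[i]]$positions
    used <- rep(FALSE, length(det))
    for (tp in truths[[i]]$positions) {
      if (!length(det)) break
      d <- abs(det - tp)
      d[used] <- Inf
      j <- which.min(d)
      if (length(j) && d[j] <= win) {
        errs <- c(errs, d[j] / fs * 1000)
        used[j] <- TRUE
      }
    }
  }
  list(count_mae = mean(count_err),
       position_mae_ms = if (length(errs)) mean(errs) else NA_real_,
       n_matched = length(errs),
       n_records = length(annotations))
}
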
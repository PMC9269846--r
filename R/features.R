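#' Segment-aggregation methods
#'
#' Collapse a per-record coefficient tensor (12 leads x S segments x K
#' atoms) into one flat record-level vector. Three record-level schemes
#' are provided: `single` keeps the first segment's coefficients,
#' `mean` averages each signed coefficient over segments, and `max`
#' takes the maximum absolute value over segments. Flattening is
#' lead-major: output index `(lead - 1) * K + atom`. The fourth scheme,
#' voting, operates per segment — see [per_segment_vectors()] and
#' [fit_voting()].
#'
#' @param coefs numeric array 12 x S x K with S >= 1.
#' @return numeric vector of length `12 * K`.
#' @export
aggregate_single <- function(coefs) {
  check_tensor(coefs)
  as.vector(t(coefs[, 1, , drop = TRUE]))
}

#' @rdname aggregate_single
#' @export
aggregate_mean <- function(coefs) {
  check_tensor(coefs)
  as.vector(t(apply_keep(coefs, mean)))
}

#' @rdname aggregate_single
#' @export
aggregate_max <- function(coefs) {
  check_tensor(coefs)
  as.vector(t(apply_keep(abs(coefs), max)))
}

check_tensor <- function(coefs) {
  if (!is.array(coefs) || length(dim(coefs)) != 3 || dim(coefs)[1] != 12)
    stop("coefs must be a 12 x S x K array")
  if (dim(coefs)[2] < 1) stop("at least one segment is required (S >= 1)")
}

# reduce over the segment dimension, keeping 12 x K
apply_keep <- function(a, f) {
  d <- dim(a)
  out <- matrix(0, nrow = d[1], ncol = d[3])
  for (l in seq_len(d[1])) {
    out[l, ] <- apply(a[l, , , drop = FALSE], 3, f)
  }
  out
}

# degenerate drop=TRUE when S == 1 collapses to 12 x K; restore shape
#' @noRd
.fix_slice <- function(x, K) {
  if (is.null(dim(x))) matrix(x, nrow = 12, ncol = K) else x
}

#' Record metadata features
#'
#' @param record an `ecg_record`.
#' @param segs the record's `qrs_segments` (supplies BPM and the mean
#'   resampling ratio).
#' @return numeric vector `c(sex, age, bpm, ratio)`.
#' @export
meta_features <- function(record, segs) {
  c(sex = as.numeric(record$sex), age = as.numeric(record$age),
    bpm = segs$bpm, ratio = mean(segs$ratios))
}

#' Assemble a record-level feature vector from blocks
#'
#' Blocks are concatenated in the fixed order signal, coef, meta
#' regardless of request order. The signal block is the 12 x S x L
#' segment tensor aggregated with the same method as the coefficient
#' block; the meta block is `c(sex, age, bpm, ratio)`.
#'
#' @param segs a `qrs_segments` (required for `signal` and `meta`).
#' @param coefs 12 x S x K coefficient tensor (required for `coef`).
#' @param record the `ecg_record` (required for `meta`).
#' @param blocks subset of `c("signal", "coef", "meta")`.
#' @param method aggregation method: `"single"`, `"mean"`, or `"max"`.
#' @return numeric feature vector with attribute `"blocks"` giving block
#'   boundaries.
#' @export
build_features <- function(segs = NULL, coefs = NULL, record = NULL,
                           blocks = c("signal", "coef", "meta"),
                           method = c("mean", "single", "max")) {
  method <- match.arg(method)
  blocks <- intersect(c("signal", "coef", "meta"), blocks)  # canonical order
  if (length(blocks) == 0) stop("at least one block must be requested")
  agg <- switch(method, single = aggregate_single,
                mean = aggregate_mean, max = aggregate_max)
  parts <- list()
  if ("signal" %in% blocks) {
    if (is.null(segs)) stop("signal block requested without segments")
    parts$signal <- agg(segs$tensor)
  }
  if ("coef" %in% blocks) {
    if (is.null(coefs)) stop("coef block requested without an encoding")
    parts$coef <- agg(coefs)
  }
  if ("meta" %in% blocks) {
    if (is.null(record) || is.null(segs)) stop("meta block requires record and segments")
    parts$meta <- unname(meta_features(record, segs))
  }
  out <- unlist(parts, use.names = FALSE)
  attr(out, "blocks") <- vapply(parts, length, 0L)
  attr(out, "method") <- method
  out
}

#' Per-segment feature vectors (voting input)
#'
#' One flat vector per segment: segment j's 12 x K coefficients and/or
#' 12 x L signal slice flattened lead-major, with the record metadata
#' appended if requested. All vectors of a record share its label
#' downstream.
#'
#' @inheritParams build_features
#' @return list of S numeric vectors of equal length.
#' @export
per_segment_vectors <- function(segs = NULL, coefs = NULL, record = NULL,
                                blocks = c("signal", "coef", "meta")) {
  blocks <- intersect(c("signal", "coef", "meta"), blocks)
  if (length(blocks) == 0) stop("at least one block must be requested")
  ref <- if (!is.null(coefs)) coefs else if (!is.null(segs)) segs$tensor else
    stop("per-segment vectors need segments or an encoding")
  S <- dim(ref)[2]
  if (S < 1) stop("at least one segment is required (S >= 1)")
  meta <- if ("meta" %in% blocks) {
    if (is.null(record) || is.null(segs)) stop("meta block requires record and segments")
    unname(meta_features(record, segs))
  } else NULL
  lapply(seq_len(S), function(j) {
    v <- numeric(0)
    if ("signal" %in% blocks) {
      if (is.null(segs)) stop("signal block requested without segments")
      v <- c(v, as.vector(t(.fix_slice(segs$tensor[, j, , drop = TRUE],
                                       dim(segs$tensor)[3]))))
    }
    if ("coef" %in% blocks) {
      if (is.null(coefs)) stop("coef block requested without an encoding")
      v <- c(v, as.vector(t(.fix_slice(coefs[, j, , drop = TRUE], dim(coefs)[3]))))
    }
    c(v, meta)
  })
}
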
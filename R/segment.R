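#' Segmentation configuration
#'
#' @param L fixed resampled segment length in samples (default 128;
#'   shorter than the smallest plausible RR interval at 500 Hz).
#' @param kind interpolation kind; only `"linear"` is supported.
#' @return a `segmentation_config`.
#' @export
segmentation_config <- function(L = 128, kind = "linear") {
  if (L < 16) stop("L must be >= 16")
  kind <- match.arg(kind, "linear")
  structure(list(L = as.integer(L), kind = kind), class = "segmentation_config")
}

#' Linearly resample a vector to a fixed length
#'
#' Interpolates onto `L` equally spaced points spanning the full index
#' range, preserving both endpoints.
#'
#' @param y numeric vector, length >= 2.
#' @param L target length.
#' @return numeric vector of length `L`.
#' @export
resample_to_length <- function(y, L) {
  if (length(y) < 2) stop("resampling needs at least 2 samples")
  stats::approx(x = seq_along(y), y = y, n = L)$y
}

#' Extract fixed-length QRS segments between R-peak midpoints
#'
#' Cuts the record at the midpoints of consecutive R-peaks
#' (`m_i = floor((r_i + r_{i+1}) / 2)`), discards the first and last
#' (boundary) segments, and linearly resamples each retained segment to
#' `cfg$L` samples on every lead. Each retained segment spans
#' `[m_{j-1}, m_j)` and contains exactly one R-peak, which sits at the
#' segment midpoint when RR intervals are equal. The per-segment
#' resampling ratio (original length / L) and the record BPM
#' (`60 * fs / mean RR`) are carried along as metadata.
#'
#' @param record an `ecg_record`.
#' @param ann an `rpeak_annotation` with `k >= 3`.
#' @param cfg a [segmentation_config()].
#' @return a `qrs_segments` object: `id`, `tensor` (12 x S x L array),
#'   `lengths`, `ratios`, `bpm`, `fs`, with `S = k - 2`.
#' @export
extract_segments <- function(record, ann, cfg = segmentation_config()) {
  if (!isTRUE(ann$usable) || ann$k < 3)
    stop("unusable annotation: segmentation needs at least 3 R-peaks")
  r <- ann$positions
  k <- ann$k
  mids <- floor((r[-k] + r[-1]) / 2)        # k - 1 midpoints
  S <- k - 2L
  L <- cfg$L
  tensor <- array(0, dim = c(12L, S, L))
  lengths <- integer(S)
  n <- ncol(record$signal)
  for (j in seq_len(S)) {
    lo <- mids[j]; hi <- min(mids[j + 1] - 1L, n)
    lengths[j] <- hi - lo + 1L
    for (lead in 1:12) {
      tensor[lead, j, ] <- resample_to_length(record$signal[lead, lo:hi], L)
    }
  }
  structure(list(id = record$id, tensor = tensor, lengths = lengths,
                 ratios = lengths / L,
                 bpm = 60 * record$fs / mean(diff(r)),
                 fs = record$fs),
            class = "qrs_segments")
}
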
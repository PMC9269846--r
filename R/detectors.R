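#' @title Single-lead R-peak detectors
#' @description Three classical single-lead R-peak detectors behind one
#'   contract: each takes a numeric vector and a sampling rate and returns
#'   sorted, deduplicated 1-based sample positions of detected R-peaks,
#'   with the first and last 100 ms excluded (filter transients). The
#'   detector registry is name-addressable so further detectors can be
#'   plugged in under the same contract.
#' @name detectors
NULL

# fixed configuration shared by the detectors (band edges Hz, windows ms)
DETECTOR_CONFIG <- list(
  twoavg = list(band = c(8, 20), qrs_win_ms = 120, beat_win_ms = 600,
                offset_frac = 0.15, min_block_ms = 80, refractory_ms = 300),
  christov = list(ma1_ms = 20, ma2_ms = 28, ma3_ms = 40, refractory_ms = 200),
  engzee = list(lp_taps = c(1, 4, 6, 4, 1), search_ms = 160,
                neg_ms = 10, refractory_ms = 200)
)

EDGE_MS <- 100  # candidate peaks inside the first/last 100 ms are discarded

# centered moving average with shrinking windows at the edges
moving_avg <- function(x, w) {
  w <- max(1L, as.integer(w))
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (w - half - 1L), n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

check_detector_input <- function(x, fs) {
  if (!is.numeric(x) || length(x) < 2 * fs)
    stop("signal too short: detectors need at least 2 s of samples")
  if (fs <= 0) stop("fs must be positive")
}

trim_edges <- function(peaks, n, fs) {
  margin <- round(EDGE_MS / 1000 * fs)
  sort(unique(peaks[peaks > margin & peaks <= n - margin]))
}

enforce_refractory <- function(peaks, strength, refr) {
  if (length(peaks) < 2) return(peaks)
  keep <- peaks[1]; keep_s <- strength[1]
  out <- numeric(0); out_s <- numeric(0)
  for (i in 2:length(peaks)) {
    if (peaks[i] - keep < refr) {
      if (strength[i] > keep_s) { keep <- peaks[i]; keep_s <- strength[i] }
    } else {
      out <- c(out, keep); out_s <- c(out_s, keep_s)
      keep <- peaks[i]; keep_s <- strength[i]
    }
  }
  c(out, keep)
}

#' Two-moving-average R-peak detector
#'
#' Band-passes the lead to the QRS band (8-20 Hz), rectifies, and
#' compares a QRS-scale moving average (120 ms) against a beat-scale
#' moving average (600 ms) plus a signal-level offset to form blocks of
#' interest; each sufficiently wide block contributes the position of its
#' rectified maximum. A 300 ms refractory period is enforced.
#'
#' @param x single-lead signal (numeric vector, mV).
#' @param fs sampling rate, Hz.
#' @return integer vector of sorted R-peak sample positions (1-based).
#' @export
detect_two_average <- function(x, fs) {
  check_detector_input(x, fs)
  cfg <- DETECTOR_CONFIG$twoavg
  bf <- signal::butter(3, cfg$band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x - mean(x))
  rect <- abs(y)
  if (max(rect) == 0) return(integer(0))
  ma_qrs <- moving_avg(rect, round(cfg$qrs_win_ms / 1000 * fs))
  ma_beat <- moving_avg(rect, round(cfg$beat_win_ms / 1000 * fs))
  thr <- ma_beat + cfg$offset_frac * mean(rect)
  active <- ma_qrs > thr
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  min_w <- round(cfg$min_block_ms / 1000 * fs)
  peaks <- numeric(0); strength <- numeric(0)
  for (b in which(r$values & r$lengths >= min_w)) {
    seg <- starts[b]:ends[b]
    j <- seg[which.max(rect[seg])]
    peaks <- c(peaks, j); strength <- c(strength, rect[j])
  }
  if (length(peaks) == 0) return(integer(0))
  peaks <- enforce_refractory(peaks, strength, round(cfg$refractory_ms / 1000 * fs))
  as.integer(trim_edges(peaks, length(x), fs))
}

#' Christov adaptive-threshold R-peak detector
#'
#' Forms a complex-lead surrogate by two short moving averages (power-line
#' and EMG suppression), an absolute first difference, and a 40 ms
#' smoothing average, then scans it with the combined adaptive threshold
#' M + F + R: a steep-slope component M held for 200 ms after each beat
#' and decaying until 1200 ms, an integrating component F tracking the
#' envelope, and a beat-expectation component R that lowers the threshold
#' once two-thirds of the expected RR interval has elapsed. Detections
#' within a 200 ms refractory period are suppressed and each detection is
#' refined to the rectified-signal maximum nearby.
#'
#' @inheritParams detect_two_average
#' @return integer vector of sorted R-peak sample positions (1-based).
#' @export
detect_christov <- function(x, fs) {
  check_detector_input(x, fs)
  cfg <- DETECTOR_CONFIG$christov
  ma1 <- moving_avg(x, round(cfg$ma1_ms / 1000 * fs))
  ma2 <- moving_avg(ma1, round(cfg$ma2_ms / 1000 * fs))
  y <- moving_avg(abs(c(0, diff(ma2))), round(cfg$ma3_ms / 1000 * fs))
  n <- length(y)
  if (max(y) == 0) return(integer(0))

  ms200 <- round(0.2 * fs); ms1200 <- round(1.2 * fs)
  ms50 <- round(0.05 * fs); ms350 <- round(0.35 * fs)
  init_win <- min(n, 2 * fs)

  mm <- rep(0.6 * max(y[1:init_win]), 5)   # buffer of recent slope thresholds
  m_cur <- mean(mm)
  f_cur <- mean(y[1:min(n, ms350)])
  qrs <- integer(0)
  rr_buf <- numeric(0)
  new_m5 <- mm[5]

  for (i in seq_len(n)) {
    last <- if (length(qrs)) qrs[length(qrs)] else -Inf
    elapsed <- i - last
    # steep-slope threshold M
    if (is.finite(last) && elapsed <= ms200) {
      new_m5 <- max(new_m5, 0.6 * y[i])
      if (new_m5 > 1.5 * mm[5]) new_m5 <- 1.1 * mm[5]
      m_cur <- mean(mm)
    } else if (is.finite(last) && elapsed == ms200 + 1) {
      mm <- c(mm[-1], new_m5)
      m_cur <- mean(mm)
    } else if (is.finite(last) && elapsed > ms200 && elapsed < ms1200) {
      dec <- 1 - 0.4 * (elapsed - ms200) / (ms1200 - ms200)
      m_cur <- mean(mm) * dec
    } else if (is.finite(last)) {
      m_cur <- 0.6 * mean(mm)
    }
    # integrating threshold F
    if (i > ms350) {
      f_cur <- f_cur + (max(y[(i - ms50 + 1):i]) -
                          max(y[(i - ms350 + 1):(i - ms350 + ms50)])) / 150
    }
    # beat-expectation threshold R
    r_cur <- 0
    if (length(rr_buf) >= 2 && is.finite(last)) {
      rm_exp <- mean(rr_buf)
      if (elapsed > 2 / 3 * rm_exp) {
        frac <- min(1, (elapsed - 2 / 3 * rm_exp) / (rm_exp / 3))
        r_cur <- -0.4 * mean(mm) * frac
      }
    }
    mfr <- m_cur + 0.1 * f_cur + r_cur
    if (y[i] > mfr && elapsed > ms200) {
      if (length(qrs)) {
        rr_buf <- c(rr_buf, i - last)
        if (length(rr_buf) > 5) rr_buf <- rr_buf[-1]
      }
      qrs <- c(qrs, i)
      new_m5 <- 0.6 * y[i]
    }
  }
  if (length(qrs) == 0) return(integer(0))
  refined <- refine_peaks(x, qrs, fs, before = 0.10, after = 0.04)
  refined <- enforce_refractory(refined, abs_centered(x, fs)[refined],
                                round(cfg$refractory_ms / 1000 * fs))
  as.integer(trim_edges(refined, length(x), fs))
}

# rectified, baseline-corrected view used for peak refinement
abs_centered <- function(x, fs) abs(x - moving_avg(x, round(0.6 * fs)))

# threshold crossings mark QRS onsets on delayed envelopes; snap each to
# the dominant deflection of the baseline-corrected raw lead nearby
refine_peaks <- function(x, idx, fs, before = 0.08, after = 0.08) {
  z <- abs_centered(x, fs)
  n <- length(x)
  vapply(idx, function(i) {
    lo <- max(1L, i - round(before * fs)); hi <- min(n, i + round(after * fs))
    w <- lo:hi
    w[which.max(z[w])]
  }, 0)
}

#' Engelse-Zeelenberg R-peak detector (adaptive-threshold variant)
#'
#' Differentiates the lead (`y[n] = x[n] - x[n-4]`), low-passes with the
#' [1 4 6 4 1] FIR kernel, and detects beats where the filtered signal
#' crosses an adaptive positive threshold followed, within 160 ms, by a
#' sustained excursion (10 ms) below the mirrored negative threshold —
#' the adaptive-threshold modification of the original fixed-threshold
#' scheme. The returned position is the dominant deflection of the raw
#' lead inside the accepted window.
#'
#' @inheritParams detect_two_average
#' @return integer vector of sorted R-peak sample positions (1-based).
#' @export
detect_engzee <- function(x, fs) {
  check_detector_input(x, fs)
  cfg <- DETECTOR_CONFIG$engzee
  xc <- x - mean(x)
  d <- xc - c(rep(0, 4), xc[1:(length(xc) - 4)])
  lp <- as.numeric(stats::filter(d, cfg$lp_taps, method = "convolution", sides = 1))
  lp[is.na(lp)] <- 0
  lp[1:min(length(lp), round(0.2 * fs))] <- 0
  n <- length(lp)
  if (max(abs(lp)) == 0) return(integer(0))

  ms160 <- round(cfg$search_ms / 1000 * fs)
  ms200 <- round(0.2 * fs); ms1200 <- round(1.2 * fs)
  neg_win <- round(cfg$neg_ms / 1000 * fs)
  init_win <- min(n, 2 * fs)
  mm <- rep(0.6 * max(lp[1:init_win]), 5)
  m_cur <- mean(mm)
  peaks <- integer(0)
  last <- -Inf
  thi <- NA_integer_
  neg_count <- 0L

  for (i in seq_len(n)) {
    elapsed <- i - last
    if (is.finite(last) && elapsed > ms200 && elapsed < ms1200) {
      m_cur <- mean(mm) * (1 - 0.4 * (elapsed - ms200) / (ms1200 - ms200))
    } else if (is.finite(last) && elapsed >= ms1200) {
      m_cur <- 0.6 * mean(mm)
    }
    if (is.na(thi)) {
      if (lp[i] > m_cur && elapsed > ms200) { thi <- i; neg_count <- 0L }
    } else if (i - thi > ms160) {
      thi <- NA_integer_; neg_count <- 0L    # no negative phase: reject
    } else {
      if (lp[i] < -m_cur) neg_count <- neg_count + 1L else neg_count <- 0L
      if (neg_count >= neg_win) {
        win <- max(1L, thi - round(0.01 * fs)):min(length(x), i)
        z <- abs_centered(x, fs)
        peaks <- c(peaks, win[which.max(z[win])])
        mm <- c(mm[-1], min(max(0.4 * max(lp[thi:i]), 0.2 * mm[5]), 1.5 * mm[5]))
        last <- i
        thi <- NA_integer_; neg_count <- 0L
      }
    }
  }
  if (length(peaks) == 0) return(integer(0))
  peaks <- enforce_refractory(peaks, abs_centered(x, fs)[peaks],
                              round(cfg$refractory_ms / 1000 * fs))
  as.integer(trim_edges(peaks, length(x), fs))
}

# ---- registry ----

detector_registry <- new.env(parent = emptyenv())

#' Register a detector under a name
#'
#' @param name detector name.
#' @param fn function of `(x, fs)` returning sorted peak positions.
#' @export
register_detector <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = detector_registry)
  invisible(name)
}

#' List registered detector names
#' @export
list_detectors <- function() sort(ls(detector_registry))

get_detector <- function(name) {
  if (!exists(name, envir = detector_registry, inherits = FALSE))
    stop("unknown detector: ", name)
  get(name, envir = detector_registry, inherits = FALSE)
}

register_default_detectors <- function() {
  register_detector("twoavg", detect_two_average)
  register_detector("christov", detect_christov)
  register_detector("engzee", detect_engzee)
}

.onLoad <- function(libname, pkgname) {
  register_default_detectors()
  register_default_classifiers()
}

#' Run a bank of detectors over all 12 leads
#'
#' One result per (detector, lead) pair. A detector failure on one lead
#' yields an empty result for that pair (with a warning) rather than
#' aborting the bank.
#'
#' @param record an `ecg_record`.
#' @param detectors character vector of registered detector names.
#' @return list of `detector_result` objects (`detector`, `lead`,
#'   `positions`), length `length(detectors) * 12`.
#' @export
run_detector_bank <- function(record, detectors = c("twoavg", "christov", "engzee")) {
  if (length(detectors) == 0) stop("at least one detector must be named")
  fns <- lapply(detectors, get_detector)   # errors early on unknown names
  out <- vector("list", length(detectors) * 12L)
  k <- 0L
  for (d in seq_along(detectors)) {
    for (lead in 1:12) {
      k <- k + 1L
      pos <- tryCatch(fns[[d]](record$signal[lead, ], record$fs),
                      error = function(e) {
                        warning(sprintf("%s failed on lead %d: %s",
                                        detectors[d], lead, conditionMessage(e)),
                                call. = FALSE)
                        integer(0)
                      })
      out[[k]] <- structure(list(detector = detectors[d], lead = lead,
                                 positions = as.integer(pos)),
                            class = "detector_result")
    }
  }
  out
}
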
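#' Beat template parameters
#'
#' Parametric description of one heartbeat as a sum of five Gaussian waves
#' (P, Q, R, S, T) plus an optional ST-level bump, baseline wander and
#' additive white noise. Amplitudes are in millivolts, wave centers are
#' offsets in seconds relative to the R peak, widths are Gaussian standard
#' deviations in seconds.
#'
#' @param amplitudes named numeric vector, mV, for waves P, Q, R, S, T.
#' @param offsets named numeric vector, s, wave centers relative to R;
#'   must be strictly increasing in the order P < Q < R < S < T.
#' @param widths named numeric vector, s, Gaussian widths; all positive.
#' @param st_offset ST-segment level shift (mV), rendered as a wide
#'   Gaussian centered between S and T.
#' @param wander_amp baseline wander amplitude (mV).
#' @param wander_freq baseline wander frequency (Hz).
#' @param noise_sd additive white-noise standard deviation (mV).
#' @return an object of class `beat_template`.
#' @export
beat_template <- function(amplitudes = c(P = 0.15, Q = -0.12, R = 1.2, S = -0.18, T = 0.35),
                          offsets = c(P = -0.20, Q = -0.035, R = 0, S = 0.035, T = 0.30),
                          widths = c(P = 0.035, Q = 0.012, R = 0.011, S = 0.013, T = 0.07),
                          st_offset = 0,
                          wander_amp = 0.05, wander_freq = 0.25,
                          noise_sd = 0.02) {
  waves <- c("P", "Q", "R", "S", "T")
  stopifnot(all(waves %in% names(amplitudes)),
            all(waves %in% names(offsets)),
            all(waves %in% names(widths)))
  amplitudes <- amplitudes[waves]; offsets <- offsets[waves]; widths <- widths[waves]
  if (any(widths <= 0)) stop("wave widths must be positive")
  if (any(diff(offsets) <= 0)) stop("wave offsets must be ordered P < Q < R < S < T")
  if (abs(amplitudes["R"]) <= max(abs(amplitudes[c("Q", "S")])))
    stop("R amplitude must dominate Q and S")
  if (!all(is.finite(c(amplitudes, offsets, widths, st_offset, wander_amp, wander_freq, noise_sd))))
    stop("template parameters must be finite")
  structure(list(amplitudes = amplitudes, offsets = offsets, widths = widths,
                 st_offset = st_offset, wander_amp = wander_amp,
                 wander_freq = wander_freq, noise_sd = noise_sd),
            class = "beat_template")
}

#' Synthetic disease-class specification
#'
#' A class label plus a morphology perturbation of the default beat
#' template (R-amplitude scaling, QRS widening, ST-level shift, T and P
#' scaling, Q deepening) and an admissible heart-rate range. The
#' perturbations emulate, in caricature, the morphology families of the
#' five diagnostic superclasses (normal, infarction, ST/T change,
#' conduction disturbance, hypertrophy).
#'
#' @param label class label (character).
#' @param r_scale multiplicative scaling of the R amplitude.
#' @param qrs_widen multiplicative widening of Q, R, S widths.
#' @param st_offset ST-level shift in mV.
#' @param t_scale multiplicative scaling of the T amplitude (negative
#'   values invert the T wave).
#' @param q_scale multiplicative scaling of the Q amplitude.
#' @param p_scale multiplicative scaling of the P amplitude.
#' @param bpm_range length-2 numeric, admissible beats/min, inside [30, 220].
#' @param class_label diagnostic superclass the label maps to (defaults to
#'   `label`); used when writing PTB-XL-style metadata for subclass tasks.
#' @return an object of class `synth_class_spec`.
#' @export
synth_class_spec <- function(label, r_scale = 1, qrs_widen = 1, st_offset = 0,
                             t_scale = 1, q_scale = 1, p_scale = 1,
                             bpm_range = c(55, 95), class_label = label) {
  stopifnot(length(bpm_range) == 2, bpm_range[1] <= bpm_range[2])
  if (bpm_range[1] < 30 || bpm_range[2] > 220)
    stop("bpm_range must lie within [30, 220]")
  pert <- c(r_scale, qrs_widen, st_offset, t_scale, q_scale, p_scale)
  if (!all(is.finite(pert))) stop("perturbations must be finite")
  structure(list(label = label, r_scale = r_scale, qrs_widen = qrs_widen,
                 st_offset = st_offset, t_scale = t_scale, q_scale = q_scale,
                 p_scale = p_scale, bpm_range = bpm_range,
                 class_label = class_label),
            class = "synth_class_spec")
}

apply_spec <- function(template, spec) {
  a <- template$amplitudes; w <- template$widths
  a["R"] <- a["R"] * spec$r_scale
  a["T"] <- a["T"] * spec$t_scale
  a["Q"] <- a["Q"] * spec$q_scale
  a["P"] <- a["P"] * spec$p_scale
  w[c("Q", "R", "S")] <- w[c("Q", "R", "S")] * spec$qrs_widen
  beat_template(amplitudes = a, offsets = template$offsets, widths = w,
                st_offset = template$st_offset + spec$st_offset,
                wander_amp = template$wander_amp,
                wander_freq = template$wander_freq,
                noise_sd = template$noise_sd)
}

# Fixed per-lead projection weights: one cardiac source seen through 12
# positive scalar projections, so the same beats (and the R maximum) are
# visible in every lead.
LEAD_WEIGHTS <- c(1.00, 0.80, 0.70, 0.90, 0.60, 0.75,
                  0.55, 0.85, 0.95, 1.05, 0.90, 0.65)

#' Default class specifications for the 2-, 5- and 15-class tasks
#'
#' The 5-class set mirrors the five diagnostic superclasses; the 15-class
#' set provides three morphology-graded subclasses per superclass; the
#' 2-class set is normal-versus-abnormal. Inter-class separability of the
#' noiseless average beats is asserted numerically at build time (mean
#' pairwise template distance must exceed five times the noise standard
#' deviation), so downstream classification sanity checks are meaningful.
#'
#' @param n_classes one of 2, 5, 15.
#' @param template base [beat_template()] the specs perturb.
#' @return list of [synth_class_spec()] objects.
#' @export
default_class_specs <- function(n_classes = 5, template = beat_template()) {
  base5 <- list(
    NORM = synth_class_spec("NORM"),
    MI   = synth_class_spec("MI", r_scale = 0.65, q_scale = 3.0, st_offset = -0.12),
    STTC = synth_class_spec("STTC", st_offset = 0.15, t_scale = -0.9),
    CD   = synth_class_spec("CD", qrs_widen = 1.9, r_scale = 0.85),
    HYP  = synth_class_spec("HYP", r_scale = 1.7, t_scale = 1.4)
  )
  specs <- switch(as.character(n_classes),
    "2" = list(synth_class_spec("NORM"),
               synth_class_spec("ABNORM", r_scale = 0.55, q_scale = 3,
                                st_offset = -0.15, qrs_widen = 1.8,
                                t_scale = -0.6)),
    "5" = unname(base5),
    "15" = {
      # three severity grades per superclass, each grade also carrying its
      # own R- and T-amplitude signature so same-superclass subclasses
      # remain mutually distinguishable
      grades <- c(0.7, 1.15, 1.6)
      r_grade <- c(0.85, 1.0, 1.2)
      t_grade <- c(1.25, 1.0, 0.8)
      out <- list()
      for (cl in names(base5)) {
        s <- base5[[cl]]
        for (g in seq_along(grades)) {
          gr <- grades[g]
          out[[length(out) + 1L]] <- synth_class_spec(
            label = paste0(cl, g),
            r_scale = (1 + (s$r_scale - 1) * gr) * r_grade[g],
            qrs_widen = 1 + (s$qrs_widen - 1) * gr,
            st_offset = s$st_offset * gr,
            t_scale = (1 + (s$t_scale - 1) * gr) * t_grade[g],
            q_scale = 1 + (s$q_scale - 1) * gr,
            bpm_range = s$bpm_range,
            class_label = cl)
        }
      }
      out
    },
    stop("n_classes must be 2, 5 or 15"))
  assert_class_separability(specs, template)
  specs
}

# Mean pairwise distance between noiseless average beats must exceed
# 5 * noise sd, otherwise the spec set is too weak to support sanity tests.
assert_class_separability <- function(specs, template, fs = 500) {
  beats <- lapply(specs, function(s) render_beat(apply_spec(template, s), fs))
  L <- max(vapply(beats, length, 1L))
  beats <- lapply(beats, function(b) c(b, numeric(L - length(b))))
  d <- utils::combn(length(beats), 2, function(ij) {
    sqrt(mean((beats[[ij[1]]] - beats[[ij[2]]])^2))
  })
  if (mean(d) <= 5 * template$noise_sd)
    stop("class specs are not separable: mean inter-class beat distance <= 5 * noise sd")
  invisible(TRUE)
}

# Noiseless single-beat waveform on [-0.35 s, +0.45 s] around R.
render_beat <- function(template, fs) {
  t <- seq(-0.35, 0.45, by = 1 / fs)
  y <- numeric(length(t))
  for (wv in c("P", "Q", "R", "S", "T")) {
    y <- y + template$amplitudes[wv] *
      exp(-(t - template$offsets[wv])^2 / (2 * template$widths[wv]^2))
  }
  if (template$st_offset != 0) {
    st_c <- (template$offsets["S"] + template$offsets["T"]) / 2
    y <- y + template$st_offset * exp(-(t - st_c)^2 / (2 * 0.05^2))
  }
  y
}

#' Generate one synthetic 12-lead ECG record
#'
#' Places a sum-of-Gaussians beat template at RR intervals of
#' `60 * fs / bpm` samples with seeded uniform jitter, projects the single
#' cardiac source onto 12 leads through fixed positive weights, and adds
#' per-lead baseline wander and white noise. The true R-peak sample
#' positions are returned as ground truth. Identical seeds yield
#' bit-identical records.
#'
#' @param spec a [synth_class_spec()].
#' @param bpm heart rate in beats/min; must lie in the spec's range.
#' @param duration record length in seconds.
#' @param fs sampling rate in Hz.
#' @param seed integer seed.
#' @param jitter relative uniform RR jitter (0 disables; default 0.05).
#' @param template base [beat_template()] before the spec's perturbation.
#' @return list with elements `record` (class `ecg_record`: `id`,
#'   12 x N `signal` matrix in mV, `fs`, `age`, `sex`, `labels`) and
#'   `truth` (class `ecg_ground_truth`: sorted 1-based R positions,
#'   `label`).
#' @export
generate_record <- function(spec, bpm, duration = 10, fs = 500, seed = 1,
                            jitter = 0.05, template = beat_template()) {
  if (fs <= 0 || duration <= 0) stop("fs and duration must be positive")
  if (bpm < spec$bpm_range[1] || bpm > spec$bpm_range[2])
    stop("bpm outside the spec's admissible range")
  tm <- apply_spec(template, spec)
  n <- round(duration * fs)
  rr <- 60 * fs / bpm
  rng <- local_rng(seed)

  # R-peak placement: first peak at half an RR interval, then jittered RR
  # steps while the next peak still clears a short end margin.
  peaks <- numeric(0)
  pos <- rr / 2
  while (pos <= n - max(rr * 0.1, 0.15 * fs)) {
    peaks <- c(peaks, pos)
    step <- rr * (1 + if (jitter > 0) rng$unif(1, -jitter, jitter) else 0)
    pos <- pos + step
  }
  peaks_i <- pmin(pmax(round(peaks), 1), n)

  # single cardiac source: superpose every wave of every beat
  t_idx <- seq_len(n)
  src <- numeric(n)
  st_c <- (tm$offsets["S"] + tm$offsets["T"]) / 2
  for (p in peaks_i) {
    for (wv in c("P", "Q", "R", "S", "T")) {
      c_s <- p + tm$offsets[wv] * fs
      w_s <- tm$widths[wv] * fs
      lo <- max(1L, floor(c_s - 5 * w_s)); hi <- min(n, ceiling(c_s + 5 * w_s))
      if (lo <= hi) {
        idx <- lo:hi
        src[idx] <- src[idx] + tm$amplitudes[wv] * exp(-(idx - c_s)^2 / (2 * w_s^2))
      }
    }
    if (tm$st_offset != 0) {
      c_s <- p + st_c * fs; w_s <- 0.05 * fs
      lo <- max(1L, floor(c_s - 5 * w_s)); hi <- min(n, ceiling(c_s + 5 * w_s))
      idx <- lo:hi
      src[idx] <- src[idx] + tm$st_offset * exp(-(idx - c_s)^2 / (2 * w_s^2))
    }
  }

  sig <- matrix(0, nrow = 12, ncol = n)
  for (l in 1:12) {
    wander <- if (tm$wander_amp > 0) {
      phase <- rng$unif(1, 0, 2 * pi)
      tm$wander_amp * sin(2 * pi * tm$wander_freq * t_idx / fs + phase)
    } else 0
    noise <- if (tm$noise_sd > 0) rng$norm(n, 0, tm$noise_sd) else 0
    sig[l, ] <- LEAD_WEIGHTS[l] * src + wander + noise
  }

  age <- round(rng$unif(1, 30, 85))
  sex <- as.integer(rng$unif(1) < 0.5)
  record <- structure(list(id = sprintf("synth_%08d", seed %% 1e8),
                           signal = sig, fs = fs, age = age, sex = sex,
                           labels = stats::setNames(100, spec$label)),
                      class = "ecg_record")
  truth <- structure(list(positions = as.integer(peaks_i), label = spec$label),
                     class = "ecg_ground_truth")
  list(record = record, truth = truth)
}

# Seeded RNG stream that saves and restores the global .Random.seed, so
# generator calls never disturb (and are never disturbed by) user RNG use.
local_rng <- function(seed) {
  env <- new.env()
  with_state <- function(fn) function(...) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(env$state)) set.seed(seed)
    else assign(".Random.seed", env$state, envir = globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
  list(unif = with_state(function(n, min = 0, max = 1) stats::runif(n, min, max)),
       norm = with_state(function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd)),
       int  = with_state(function(n, max) sample.int(max, n)))
}

#' Generate a labelled synthetic dataset
#'
#' `n_per_class` records per class specification, each with a per-record
#' seed derived deterministically from the master seed and a heart rate
#' drawn uniformly from the spec's BPM range.
#'
#' @param specs list of [synth_class_spec()] objects.
#' @param n_per_class records per class (>= 1).
#' @param seed master integer seed.
#' @param duration,fs,jitter,template passed to [generate_record()].
#' @return list of `list(record, truth)` entries, `n_per_class` per class,
#'   in class-major order.
#' @export
generate_dataset <- function(specs, n_per_class, seed = 1, duration = 10,
                             fs = 500, jitter = 0.05, template = beat_template()) {
  if (length(specs) == 0) stop("specs must be a non-empty list")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  rng <- local_rng(seed)
  total <- length(specs) * n_per_class
  rec_seeds <- rng$int(total, .Machine$integer.max %/% 2L)
  out <- vector("list", total)
  i <- 0L
  for (spec in specs) {
    for (j in seq_len(n_per_class)) {
      i <- i + 1L
      bpm <- rng$unif(1, spec$bpm_range[1], spec$bpm_range[2])
      entry <- generate_record(spec, bpm = bpm, duration = duration, fs = fs,
                               seed = rec_seeds[i], jitter = jitter,
                               template = template)
      entry$record$id <- sprintf("synth_%05d", i)
      out[[i]] <- entry
    }
  }
  out
}
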
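# Shared fixtures, built in code at test time.

quiet_template <- function(noise_sd = 0) {
  beat_template(noise_sd = noise_sd)
}

# one clean 60-BPM record with known truth
clean_record <- function(seed = 42, bpm = 60, noise_sd = 0, jitter = 0.05) {
  generate_record(synth_class_spec("NORM"), bpm = bpm, seed = seed,
                  jitter = jitter, template = quiet_template(noise_sd))
}

# hand-built detector results
det_result <- function(positions, detector = "x", lead = 1) {
  structure(list(detector = detector, lead = lead,
                 positions = as.integer(positions)),
            class = "detector_result")
}

# random coefficient tensor
random_tensor <- function(S, K, seed = 1, sparsity = 0.3) {
  set.seed(seed)
  a <- array(stats::rnorm(12 * S * K), dim = c(12, S, K))
  a * (array(stats::runif(12 * S * K), dim = dim(a)) < sparsity)
}

# linearly separable two-class feature rows
separable_rows <- function(n_per_class = 20, p = 4, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * p), ncol = p),
             matrix(stats::rnorm(n_per_class * p, mean = gap), ncol = p))
  list(X = X, y = rep(c("a", "b"), each = n_per_class))
}
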
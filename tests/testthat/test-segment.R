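# wide Gaussian bumps at peak positions survive linear resampling
bump_record <- function(peaks, n = 5000) {
  sig <- matrix(0, 12, n)
  idx <- seq_len(n)
  for (p in peaks) sig <- sig + rep(exp(-(idx - p)^2 / (2 * 12^2)), each = 12)
  structure(list(id = "r", signal = sig, fs = 500), class = "ecg_record")
}

test_that("midpoint rule: peaks [1000,2000,3000,4000] give 2 segments around inner peaks", {
  peaks <- c(1000, 2000, 3000, 4000)
  rec <- bump_record(peaks)
  segs <- extract_segments(rec, rpeak_annotation(peaks), segmentation_config(128))
  expect_equal(dim(segs$tensor), c(12, 2, 128))
  expect_equal(segs$lengths, c(1000L, 1000L))        # [1500,2500) and [2500,3500)
  expect_equal(segs$ratios, c(1000, 1000) / 128)
  # each retained segment contains exactly one bump (peaks 2000 and 3000)
  for (j in 1:2) {
    above <- segs$tensor[1, j, ] > 0.5
    runs <- rle(above)
    expect_equal(sum(runs$values), 1)
  }
})

test_that("equal RR intervals center each retained peak at the segment midpoint", {
  peaks <- seq(500, 4500, by = 500)
  rec <- bump_record(peaks)
  segs <- extract_segments(rec, rpeak_annotation(peaks), segmentation_config(128))
  for (j in seq_len(dim(segs$tensor)[2])) {
    at <- which.max(segs$tensor[1, j, ])
    expect_lte(abs(at - 64), 1)                      # midpoint +/- parity
  }
})

test_that("segment count is k - 2 over randomized annotations", {
  set.seed(5)
  rec <- structure(list(id = "r",
                        signal = matrix(stats::rnorm(12 * 5000), 12), fs = 500),
                   class = "ecg_record")
  for (i in 1:20) {
    k <- sample(3:25, 1)
    peaks <- sort(sample(seq(50, 4950), k))
    while (any(diff(peaks) < 4)) peaks <- sort(sample(seq(50, 4950), k))
    segs <- extract_segments(rec, rpeak_annotation(peaks), segmentation_config(128))
    expect_equal(dim(segs$tensor)[2], k - 2)
    expect_true(all(segs$ratios > 0))
  }
  expect_error(extract_segments(rec, rpeak_annotation(c(10, 20)),
                                segmentation_config(128)), "unusable")
})

test_that("a 60-BPM synthetic record yields 8 segments of ~500 samples", {
  g <- clean_record(seed = 17)
  ann <- detect_consensus(g$record)
  segs <- extract_segments(g$record, ann)
  expect_equal(dim(segs$tensor)[2], 8)
  expect_true(all(abs(segs$lengths - 500) < 60))
  expect_true(all(abs(segs$ratios - 500 / 128) < 0.5))
  expect_lt(abs(segs$bpm - 60), 3)
  # resampled peak index within L/2 +/- L/8
  for (j in 1:8) {
    at <- which.max(segs$tensor[1, j, ])
    expect_true(abs(at - 64) <= 16)
  }
})

test_that("linear resampling preserves endpoints, identity and constants", {
  expect_equal(resample_to_length(c(0, 1), 3), c(0, 0.5, 1))
  y <- stats::rnorm(128)
  expect_equal(resample_to_length(y, 128), y)
  expect_equal(resample_to_length(rep(2.5, 40), 16), rep(2.5, 16))
  y2 <- cumsum(stats::runif(50))
  r <- resample_to_length(y2, 31)
  expect_equal(r[1], y2[1]); expect_equal(r[31], y2[50])
  expect_gte(min(r), min(y2)); expect_lte(max(r), max(y2))
  expect_error(resample_to_length(1, 8), "at least 2")
  expect_error(segmentation_config(L = 8), ">= 16")
})
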
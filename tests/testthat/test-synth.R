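test_that("a 60-BPM 10-s record has 12 x 5000 samples and 10 beats ~500 apart", {
  g <- clean_record(seed = 7)
  expect_identical(dim(g$record$signal), c(12L, 5000L))
  expect_length(g$truth$positions, 10)
  expect_true(all(abs(diff(g$truth$positions) - 500) <= 500 * 0.06))
  expect_true(all(g$truth$positions >= 1 & g$truth$positions <= 5000))
  expect_true(all(diff(g$truth$positions) > 0))
})

test_that("equal seeds give bit-identical records; different seeds differ", {
  a <- generate_record(synth_class_spec("NORM"), bpm = 72, seed = 123)
  b <- generate_record(synth_class_spec("NORM"), bpm = 72, seed = 123)
  c <- generate_record(synth_class_spec("NORM"), bpm = 72, seed = 124)
  expect_identical(a$record$signal, b$record$signal)
  expect_identical(a$truth$positions, b$truth$positions)
  expect_false(identical(a$record$signal, c$record$signal))
})

test_that("with zero noise the per-lead argmax in each RR window is the true R", {
  g <- clean_record(seed = 5, noise_sd = 0)
  pos <- g$truth$positions
  half <- round(mean(diff(pos)) / 2) - 5
  for (lead in c(1, 5, 12)) {
    x <- g$record$signal[lead, ]
    for (p in pos) {
      w <- max(1, p - half):min(length(x), p + half)
      expect_identical(w[which.max(x[w])], p)
    }
  }
})

test_that("single noiseless jitter-free beat peaks exactly at the truth", {
  g <- generate_record(synth_class_spec("NORM"), bpm = 60, duration = 1,
                       seed = 1, jitter = 0,
                       template = beat_template(noise_sd = 0, wander_amp = 0))
  expect_length(g$truth$positions, 1)
  expect_identical(which.max(g$record$signal[1, ]), as.integer(g$truth$positions))
})

test_that("generate_dataset bookkeeping: counts, determinism, label coverage", {
  specs <- default_class_specs(5)
  ds <- generate_dataset(specs, n_per_class = 4, seed = 3)
  expect_length(ds, 20)
  labs <- vapply(ds, function(e) e$truth$label, "")
  expect_equal(unname(table(labs)[vapply(specs, `[[`, "", "label")]),
               rep(4L, 5), ignore_attr = TRUE)
  ds2 <- generate_dataset(specs, n_per_class = 4, seed = 3)
  expect_identical(ds[[7]]$record$signal, ds2[[7]]$record$signal)
  ds15 <- generate_dataset(default_class_specs(15), n_per_class = 1, seed = 1)
  expect_length(unique(vapply(ds15, function(e) e$truth$label, "")), 15)
})

test_that("invalid template and spec arguments are rejected", {
  expect_error(beat_template(widths = c(P = -1, Q = 0.01, R = 0.01,
                                        S = 0.01, T = 0.05)), "positive")
  expect_error(beat_template(offsets = c(P = 0.1, Q = -0.03, R = 0,
                                         S = 0.03, T = 0.3)), "ordered")
  expect_error(synth_class_spec("X", bpm_range = c(10, 80)), "30")
  expect_error(generate_record(synth_class_spec("NORM"), bpm = 60,
                               duration = -1), "positive")
  expect_error(generate_record(synth_class_spec("NORM"), bpm = 200), "range")
  expect_error(generate_dataset(list(), 5), "non-empty")
})

test_that("default class specs are separable at the built-in noise level", {
  for (nc in c(2, 5, 15)) expect_silent(default_class_specs(nc))
  expect_error(default_class_specs(5, beat_template(noise_sd = 0.2)),
               "separable")
})
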
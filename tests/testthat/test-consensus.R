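test_that("beat-count estimate is the lower-middle median of result counts", {
  mk <- function(counts) lapply(counts, function(k) det_result(seq_len(k) * 100))
  expect_equal(estimate_count(mk(c(10, 10, 10, 9, 11))), 10)
  expect_equal(estimate_count(mk(c(8, 9))), 8)          # lower middle
  expect_equal(estimate_count(mk(c(0, 0, 0))), 0)
  expect_error(estimate_count(list()), "non-empty")
})

test_that("median matches a sort-based oracle over random count multisets", {
  set.seed(42)
  for (i in 1:1000) {
    counts <- sample(0:30, size = sample(1:40, 1), replace = TRUE)
    res <- lapply(counts, function(k) det_result(seq_len(k)))
    expect_identical(estimate_count(res), sort_median_lower(counts))
  }
})

test_that("localization returns the exact positions for singleton clusters", {
  res <- list(det_result(c(100, 600, 1100)))
  ann <- localize_peaks(res, 3, 5000)
  expect_equal(ann$positions, c(100L, 600L, 1100L))
  expect_true(ann$usable)
  expect_equal(localize_peaks(res, 0, 5000)$k, 0)
  expect_false(localize_peaks(res, 0, 5000)$usable)
  expect_error(localize_peaks(list(det_result(integer(0))), 2, 100), "empty")
})

test_that("k-means centers land within the jitter of planted cluster truth", {
  set.seed(3)
  truth <- c(500, 1500, 2500)
  for (rep in 1:10) {
    pool <- unlist(lapply(truth, function(t)
      t + sample(-5:5, 36, replace = TRUE)))
    res <- list(det_result(sort(pool)))
    ann <- localize_peaks(res, 3, 3000)
    expect_equal(ann$k, 3)
    expect_true(all(abs(ann$positions - truth) <= 5))
  }
})

test_that("k-means objective is within 1% of the DP optimum on random pools", {
  set.seed(7)
  for (rep in 1:25) {
    k <- sample(2:8, 1)
    centers_true <- sort(sample(100:4900, k))
    pool <- unlist(lapply(centers_true, function(c)
      c + round(stats::rnorm(sample(5:30, 1), 0, 8))))
    centers <- ecgpursuit:::kmeans_1d(pool, k)
    got <- kmeans_objective(pool, centers)
    opt <- optimal_kmeans_1d_obj(pool, k)
    expect_lte(got, opt * 1.01 + 1e-9)
    # reported positions are the rounded centers
    ann <- localize_peaks(list(det_result(sort(pool))), k, 5000)
    expect_equal(ann$positions, sort(unique(as.integer(round(centers)))))
    # the large-pool iterative path stays close to the optimum too
    centers_it <- ecgpursuit:::kmeans_1d(pool, k, exact_max = 0)
    expect_lte(kmeans_objective(pool, centers_it), opt * 1.10 + 1e-9)
  }
})

test_that("k is reduced when the pool has fewer distinct positions", {
  res <- list(det_result(c(10, 10, 10, 20)))
  ann <- localize_peaks(res, 3, 100)
  expect_equal(ann$k, 2)
  expect_equal(ann$positions, c(10L, 20L))
})

test_that("consensus annotation is permutation invariant and in contract", {
  g <- clean_record(seed = 21, noise_sd = 0.05)
  res <- run_detector_bank(g$record)
  k <- estimate_count(res)
  a1 <- localize_peaks(res, k, 5000)
  set.seed(1)
  a2 <- localize_peaks(sample(res), k, 5000)
  expect_identical(a1$positions, a2$positions)
  expect_true(all(diff(a1$positions) > 0))
  expect_true(all(a1$positions >= 1 & a1$positions <= 5000))
})

test_that("consensus detects the true beats and shrugs off an outlier detector", {
  g <- clean_record(seed = 31, noise_sd = 0)
  ann <- detect_consensus(g$record)
  expect_equal(ann$k, 10)
  expect_lt(max(abs(ann$positions - g$truth$positions)) / 500 * 1000, 40)
  # doubling detector: counts 20 against two honest 10s
  doubler <- lapply(1:12, function(l)
    det_result(sort(c(g$truth$positions, g$truth$positions + 250)),
               "doubler", l))
  honest <- lapply(1:24, function(i)
    det_result(g$truth$positions, paste0("h", i %% 2), (i - 1) %% 12 + 1))
  k <- estimate_count(c(doubler, honest))
  expect_equal(k, 10)
  # all-flat record
  flat <- g$record; flat$signal[] <- 0
  expect_false(detect_consensus(flat)$usable)
})

test_that("count MAE and matched position error follow their definitions", {
  ann <- list(rpeak_annotation(c(100, 200)), rpeak_annotation(1:11 * 100))
  tr <- list(list(positions = c(100, 200)), list(positions = 1:10 * 100))
  m <- evaluate_rpeak_mae(ann, tr)
  expect_equal(m$count_mae, 0.5)              # (0 + 1)/2
  expect_equal(m$position_mae_ms, 0)
  det <- list(rpeak_annotation(c(95, 210)), rpeak_annotation(c(400)))
  tru <- list(list(positions = c(100, 200)), list(positions = c(100, 200)))
  m2 <- evaluate_rpeak_mae(det, tru)
  expect_equal(m2$count_mae, 0.5)
  expect_equal(m2$position_mae_ms, mean(c(5, 10)) / 500 * 1000)
  expect_equal(m2$n_matched, 2)               # 400 is beyond the 75 ms window
  expect_error(evaluate_rpeak_mae(det, tru[1]), "equal length")
})
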
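test_that("aggregations match brute-force loops on random tensors", {
  for (seed in 1:5) {
    coefs <- random_tensor(S = 6, K = 17, seed = seed)
    expect_equal(aggregate_single(coefs), loop_aggregate(coefs, "single"),
                 tolerance = 1e-12)
    expect_equal(aggregate_mean(coefs), loop_aggregate(coefs, "mean"),
                 tolerance = 1e-12)
    expect_equal(aggregate_max(coefs), loop_aggregate(coefs, "max"),
                 tolerance = 1e-12)
  }
})

test_that("aggregation corner cases and the indexing contract hold", {
  coefs <- array(0, dim = c(12, 2, 8))
  coefs[2, 1, 4] <- 7                       # lead 2, segment 1, atom 4
  s <- aggregate_single(coefs)
  expect_equal(s[(2 - 1) * 8 + 4], 7)
  coefs[5, 2, 3] <- 99                      # later segment: ignored by single
  expect_equal(aggregate_single(coefs)[(5 - 1) * 8 + 3], 0)
  # signed mean, absolute max
  coefs2 <- array(0, dim = c(12, 2, 4))
  coefs2[1, 1, 1] <- 1; coefs2[1, 2, 1] <- -1
  expect_equal(aggregate_mean(coefs2)[1], 0)
  coefs2[1, 2, 1] <- -3
  expect_equal(aggregate_max(coefs2)[1], 3)
  expect_equal(aggregate_max(array(0, c(12, 3, 4))), rep(0, 48))
  # S = 1 collapse: single == mean == |max|
  one <- random_tensor(S = 1, K = 9, seed = 3)
  expect_equal(aggregate_single(one), aggregate_mean(one))
  expect_equal(abs(aggregate_single(one)), aggregate_max(one))
  expect_error(aggregate_mean(array(0, c(12, 0, 4))), "S >= 1")
})

test_that("aggregation is equivariant under atom permutations", {
  coefs <- random_tensor(S = 4, K = 10, seed = 7)
  perm <- sample(10)
  permuted <- coefs[, , perm, drop = FALSE]
  for (f in list(aggregate_mean, aggregate_max, aggregate_single)) {
    a <- matrix(f(coefs), nrow = 12, byrow = TRUE)
    b <- matrix(f(permuted), nrow = 12, byrow = TRUE)
    expect_equal(b, a[, perm], tolerance = 1e-12)
  }
})

make_parts <- function(seed = 4, K = 20) {
  g <- clean_record(seed = seed)
  ann <- detect_consensus(g$record)
  segs <- extract_segments(g$record, ann)
  D <- build_gabor(128, K)
  list(record = g$record, segs = segs, coefs = encode_segment_set(segs, D, 5))
}

test_that("feature blocks have the documented sizes and canonical order", {
  p <- make_parts()
  meta_only <- build_features(segs = p$segs, record = p$record, blocks = "meta")
  expect_length(meta_only, 4)
  full <- build_features(segs = p$segs, coefs = p$coefs, record = p$record,
                         blocks = c("meta", "coef", "signal"), method = "mean")
  expect_length(full, 12 * 128 + 12 * 20 + 4)
  expect_equal(attr(full, "blocks"),
               c(signal = 12L * 128L, coef = 12L * 20L, meta = 4L))
  # order of request does not matter
  full2 <- build_features(segs = p$segs, coefs = p$coefs, record = p$record,
                          blocks = c("signal", "coef", "meta"), method = "mean")
  expect_identical(as.numeric(full), as.numeric(full2))
  expect_error(build_features(segs = p$segs, record = p$record,
                              blocks = c("coef")), "without an encoding")
})

test_that("per-segment vectors isolate segments and average back to the mean", {
  p <- make_parts()
  vs <- per_segment_vectors(segs = p$segs, coefs = p$coefs, record = p$record,
                            blocks = "coef")
  S <- dim(p$coefs)[2]
  expect_length(vs, S)
  expect_length(unique(vapply(vs, length, 0L)), 1)
  # vector j depends only on segment j
  coefs2 <- p$coefs; coefs2[, 2, ] <- 0
  vs2 <- per_segment_vectors(segs = p$segs, coefs = coefs2, record = p$record,
                             blocks = "coef")
  expect_identical(vs[[1]], vs2[[1]])
  expect_false(identical(vs[[2]], vs2[[2]]))
  # mean of per-segment coef vectors equals the mean aggregation
  expect_equal(colMeans(do.call(rbind, vs)), aggregate_mean(p$coefs),
               tolerance = 1e-12)
})
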
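test_that("stratified splits are disjoint, exhaustive, proportional, deterministic", {
  labels <- rep(c("A", "B"), each = 50)
  sp <- split_records(labels, seed = 1)
  expect_length(sp$train, 70); expect_length(sp$val, 15); expect_length(sp$test, 15)
  expect_setequal(unlist(sp), 1:100)
  expect_identical(sp, split_records(labels, seed = 1))
  expect_false(identical(sp, split_records(labels, seed = 2)))
  # per-class proportions within one record of the global fractions
  for (cl in c("A", "B")) {
    n_tr <- sum(labels[sp$train] == cl)
    expect_lte(abs(n_tr - 35), 1)
  }
})

test_that("imbalanced stratified splits keep minority records in the test set", {
  labels <- rep(c("maj", "min"), times = c(90, 10))
  for (seed in 1:10) {
    sp <- split_records(labels, seed = seed)
    expect_gte(sum(labels[sp$test] == "min"), 1)
    expect_setequal(unlist(sp), 1:100)
  }
  expect_warning(split_records(c("a", "a", "a", "b"), seed = 1), "fewer than 3")
})

test_that("voting pools segment rows for fitting and averages probabilities", {
  fx <- separable_rows()
  segv <- lapply(seq_along(fx$y), function(i) list(fx$X[i, ], fx$X[i, ] + 0.01))
  vm <- fit_voting("tree", segv, fx$y)
  # training accuracy 1.0 on separable data
  preds <- vapply(segv, function(v) predict_voting(vm, v)$class, "")
  expect_equal(preds, fx$y)
  # averaging contract, checked against hand arithmetic with a stub adapter
  stub <- list(fit = function(X, y) NULL,
               predict_prob = function(m, X) {
                 p <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, byrow = TRUE)
                 colnames(p) <- c("a", "b")
                 p[seq_len(nrow(X)), , drop = FALSE]
               })
  vm2 <- structure(list(adapter = stub, model = NULL, levels = c("a", "b")),
                   class = "voting_model")
  out <- predict_voting(vm2, list(1, 2))
  expect_equal(unname(out$prob), c(0.7, 0.3))
  expect_equal(out$class, "a")
  # single segment reduces to the base model
  out1 <- predict_voting(vm2, list(1))
  expect_equal(unname(out1$prob), c(0.9, 0.1))
  # segment order invariance
  g <- do.call(rbind, segv[[3]])
  expect_equal(predict_voting(vm, segv[[3]])$prob,
               predict_voting(vm, rev(segv[[3]]))$prob)
})

test_that("voting refuses adapters without probability outputs", {
  no_prob <- list(fit = function(X, y) NULL, predict_prob = NULL)
  expect_error(fit_voting(no_prob, list(list(1)), "a"), "probability")
})

test_that("binary metric formulas evaluate exactly on integer counts", {
  m <- metrics_from_counts(tp = 90, tn = 85, fp = 15, fn = 10)
  expect_equal(m$accuracy, 0.875)
  expect_equal(m$precision, 90 / 105)
  expect_equal(m$recall, 0.9)
  expect_equal(m$balanced_accuracy, (0.9 + 0.85) / 2)
  expect_equal(m$f1, 2 * (90 / 105) * 0.9 / (90 / 105 + 0.9))
  y <- rep(c("n", "p"), times = c(3, 3))
  expect_equal(compute_metrics(y, y)$accuracy, 1)
  expect_equal(compute_metrics(y, y)$f1, 1)
})

test_that("macro metrics equal per-class loops and BAcc equals macro recall", {
  set.seed(11)
  for (C in c(3, 5)) {
    classes <- letters[1:C]
    y_true <- sample(classes, 200, replace = TRUE)
    y_pred <- ifelse(stats::runif(200) < 0.6, y_true,
                     sample(classes, 200, replace = TRUE))
    rep_ <- compute_metrics(y_true, y_pred, classes = classes)
    recalls <- vapply(classes, function(cl)
      sum(y_true == cl & y_pred == cl) / sum(y_true == cl), 0)
    expect_equal(rep_$recall, mean(recalls))
    expect_equal(rep_$balanced_accuracy, mean(recalls))
    expect_equal(rep_$accuracy, mean(y_true == y_pred))
  }
  expect_error(compute_metrics(character(0), character(0)), "empty")
  expect_error(compute_metrics(c("a", "b"), "a"), "mismatch")
})

test_that("every shipped classifier adapter fits and emits valid probabilities", {
  fx <- separable_rows(n_per_class = 15)
  for (nm in c("rf", "xgboost", "svm", "tree", "knn", "nb", "mlp")) {
    adapter <- ecgpursuit:::get_classifier(nm)
    m <- adapter$fit(fx$X, fx$y)
    p <- adapter$predict_prob(m, fx$X)
    expect_equal(dim(p), c(30, 2))
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(unname(rowSums(p)), rep(1, 30), tolerance = 1e-6)
    acc <- mean(colnames(p)[max.col(p, ties.method = "first")] == fx$y)
    expect_gte(acc, 0.9)
  }
})
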
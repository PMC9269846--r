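#' Stratified train/validation/test split
#'
#' Splits record indices into disjoint, exhaustive train/validation/test
#' sets at the given fractions. Under stratification each class is split
#' at the same fractions (largest-remainder rounding, with ties broken
#' toward the split currently furthest below its global target), so
#' per-class proportions stay within one record of the global fractions.
#'
#' @param labels per-record class labels.
#' @param fractions length-3 numeric summing to 1 (train, val, test).
#' @param seed integer seed; the split is deterministic per seed.
#' @param stratify stratify by class (default TRUE).
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_records <- function(labels, fractions = c(0.70, 0.15, 0.15), seed = 1,
                          stratify = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(labels)
  if (n == 0) stop("no records to split")
  rng <- local_rng(seed)
  groups <- if (stratify) split(seq_len(n), labels) else list(seq_len(n))
  small <- names(Filter(function(g) length(g) < 3, groups))
  if (stratify && length(small))
    warning("classes with fewer than 3 records split best-effort: ",
            paste(small, collapse = ", "))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  assigned <- c(train = 0, val = 0, test = 0)
  for (g in groups) {
    idx <- g[rng$int(length(g), length(g))]
    quota <- length(g) * fractions
    base <- floor(quota)
    rem <- length(g) - sum(base)
    if (rem > 0) {
      frac_part <- quota - base
      deficit <- n * fractions - (assigned + base)
      ord <- order(-frac_part, -deficit)
      base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    cuts <- cumsum(base)
    out$train <- c(out$train, idx[seq_len(base[1])])
    out$val <- c(out$val, if (base[2] > 0) idx[(cuts[1] + 1):cuts[2]] else integer(0))
    out$test <- c(out$test, if (base[3] > 0) idx[(cuts[2] + 1):cuts[3]] else integer(0))
    assigned <- assigned + base
  }
  lapply(out, sort)
}

# ---- classifier adapters ----------------------------------------------

classifier_registry <- new.env(parent = emptyenv())

#' Register a classifier adapter
#'
#' An adapter is a list with `fit(X, y)` returning a fitted model and
#' `predict_prob(model, X)` returning an n x C probability matrix with
#' class levels as column names (or NULL if the model cannot emit
#' probabilities, in which case voting refuses it).
#'
#' @param name adapter name.
#' @param adapter list with `fit` and `predict_prob` functions.
#' @export
register_classifier <- function(name, adapter) {
  stopifnot(is.function(adapter$fit), is.function(adapter$predict_prob) ||
              is.null(adapter$predict_prob))
  assign(name, adapter, envir = classifier_registry)
  invisible(name)
}

#' List registered classifier adapter names
#' @export
list_classifiers <- function() sort(ls(classifier_registry))

get_classifier <- function(name) {
  if (!exists(name, envir = classifier_registry, inherits = FALSE))
    stop("unknown classifier: ", name)
  get(name, envir = classifier_registry, inherits = FALSE)
}

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    stop("classifier adapter requires the '", pkg, "' package")
}

order_probs <- function(p, levels) {
  p <- p[, levels, drop = FALSE]
  p / pmax(rowSums(p), .Machine$double.eps)
}

scale_fit <- function(X) {
  mu <- colMeans(X); sd <- apply(X, 2, stats::sd); sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
scale_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")

register_default_classifiers <- function() {
  register_classifier("rf", list(
    fit = function(X, y) {
      need_pkg("ranger")
      ranger::ranger(x = as.data.frame(X), y = factor(y), probability = TRUE,
                     num.trees = 300, seed = 7, num.threads = 1)
    },
    predict_prob = function(m, X) {
      p <- stats::predict(m, data = as.data.frame(X), num.threads = 1)$predictions
      order_probs(p, colnames(p))
    }))
  register_classifier("xgboost", list(
    fit = function(X, y) {
      need_pkg("xgboost")
      y <- factor(y)
      m <- xgboost::xgboost(x = as.matrix(X), y = y, nrounds = 60,
                            max_depth = 6, learning_rate = 0.3,
                            nthreads = 1, verbosity = 0, seed = 7)
      list(model = m, levels = levels(y))
    },
    predict_prob = function(m, X) {
      p <- stats::predict(m$model, as.matrix(X), type = "response")
      if (is.null(dim(p))) {          # binary: probability of the second level
        p <- cbind(1 - p, p)
        colnames(p) <- m$levels
      }
      p[, m$levels, drop = FALSE]
    }))
  register_classifier("svm", list(
    fit = function(X, y) {
      need_pkg("e1071")
      e1071::svm(x = as.matrix(X), y = factor(y), probability = TRUE)
    },
    predict_prob = function(m, X) {
      pred <- stats::predict(m, as.matrix(X), probability = TRUE)
      p <- attr(pred, "probabilities")
      order_probs(p, m$levels)
    }))
  register_classifier("tree", list(
    fit = function(X, y) {
      need_pkg("rpart")
      df <- as.data.frame(X); df$.y <- factor(y)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    predict_prob = function(m, X) {
      stats::predict(m, as.data.frame(X), type = "prob")
    }))
  register_classifier("knn", list(
    fit = function(X, y) {
      need_pkg("caret")
      s <- scale_fit(as.matrix(X))
      list(model = caret::knn3(x = scale_apply(as.matrix(X), s),
                               y = factor(y), k = 5), scale = s)
    },
    predict_prob = function(m, X) {
      stats::predict(m$model, scale_apply(as.matrix(X), m$scale), type = "prob")
    }))
  register_classifier("nb", list(
    fit = function(X, y) {
      need_pkg("e1071")
      list(model = e1071::naiveBayes(as.data.frame(X), factor(y)),
           levels = levels(factor(y)))
    },
    predict_prob = function(m, X) {
      stats::predict(m$model, as.data.frame(X), type = "raw")
    }))
  register_classifier("mlp", list(
    fit = function(X, y) {
      need_pkg("nnet")
      s <- scale_fit(as.matrix(X))
      y <- factor(y)
      utils::capture.output(
        m <- nnet::nnet(scale_apply(as.matrix(X), s), nnet::class.ind(y),
                        size = 16, decay = 1e-3, maxit = 200, softmax = TRUE,
                        MaxNWts = 1e6, trace = FALSE))
      list(model = m, scale = s, levels = levels(y))
    },
    predict_prob = function(m, X) {
      p <- stats::predict(m$model, scale_apply(as.matrix(X), m$scale))
      colnames(p) <- m$levels
      p
    }))
}

# ---- voting meta-classifier -------------------------------------------

#' Fit the voting meta-classifier
#'
#' Fits the underlying adapter on the union of all per-segment vectors,
#' each labelled with its record's class. Records therefore weight the
#' fit in proportion to their segment counts.
#'
#' @param classifier adapter name (see [list_classifiers()]) or adapter
#'   list; must provide probability outputs.
#' @param segment_vectors list over records, each a list of per-segment
#'   feature vectors (see [per_segment_vectors()]).
#' @param labels per-record class labels.
#' @return a `voting_model`.
#' @export
fit_voting <- function(classifier, segment_vectors, labels) {
  adapter <- if (is.character(classifier)) get_classifier(classifier) else classifier
  if (is.null(adapter$predict_prob))
    stop("voting requires a classifier with probability outputs")
  if (any(vapply(segment_vectors, length, 0L) < 1))
    stop("every record must contribute at least one segment vector")
  X <- do.call(rbind, lapply(segment_vectors, function(v) do.call(rbind, v)))
  y <- rep(labels, vapply(segment_vectors, length, 0L))
  structure(list(adapter = adapter, model = adapter$fit(X, factor(y)),
                 levels = levels(factor(y))),
            class = "voting_model")
}

#' Predict a record's class by averaging per-segment probabilities
#'
#' @param fitted a `voting_model`.
#' @param segment_vectors the record's list of per-segment vectors.
#' @return list with `class` (argmax of the averaged probabilities, ties
#'   broken toward the lowest class index) and `prob` (named probability
#'   vector).
#' @export
predict_voting <- function(fitted, segment_vectors) {
  if (length(segment_vectors) < 1) stop("at least one segment vector required")
  X <- do.call(rbind, segment_vectors)
  p <- fitted$adapter$predict_prob(fitted$model, X)
  p <- p[, fitted$levels, drop = FALSE]
  avg <- colMeans(p)
  list(class = fitted$levels[which.max(avg)], prob = avg)
}

# ---- metrics ----------------------------------------------------------

#' Binary classification metrics from confusion counts
#'
#' Direct evaluation of the standard formulas:
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`, `Precision = TP/(TP+FP)`,
#' `Recall = TP/(TP+FN)`, `F1 = 2 P R/(P+R)`,
#' `BAcc = (TP/(TP+FN) + TN/(TN+FP))/2`.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named list of the five metrics.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn) {
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = precision,
       recall = recall,
       f1 = 2 * precision * recall / (precision + recall),
       balanced_accuracy = (tp / (tp + fn) + tn / (tn + fp)) / 2)
}

#' Classification metrics report
#'
#' For two classes the positive-class formulas of
#' [metrics_from_counts()] are used; for more classes precision, recall,
#' and F1 are macro-averaged over one-vs-rest classes and balanced
#' accuracy equals macro recall (the mean of per-class recalls). Classes
#' with a zero denominator contribute 0 with a warning.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes class level set (defaults to the union of observed
#'   labels, sorted).
#' @param positive positive class for the binary case (defaults to the
#'   second level).
#' @return a `metrics_report` list: `accuracy`, `precision`, `recall`,
#'   `f1`, `balanced_accuracy`, `confusion` (C x C table, rows = truth).
#' @export
compute_metrics <- function(y_true, y_pred, classes = NULL, positive = NULL) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(as.character(y_true),
                                                 as.character(y_pred))))
  y_true <- factor(y_true, levels = classes)
  y_pred <- factor(y_pred, levels = classes)
  conf <- table(truth = y_true, predicted = y_pred)
  acc <- sum(diag(conf)) / sum(conf)
  C <- length(classes)
  if (C == 2) {
    if (is.null(positive)) positive <- classes[2]
    pos <- which(classes == positive); neg <- setdiff(1:2, pos)
    m <- metrics_from_counts(tp = conf[pos, pos], tn = conf[neg, neg],
                             fp = conf[neg, pos], fn = conf[pos, neg])
    rep_ <- c(m, list(confusion = conf))
  } else {
    per_class <- function(i) {
      tp <- conf[i, i]
      fp <- sum(conf[-i, i]); fn <- sum(conf[i, -i])
      p <- if (tp + fp == 0) { warning("undefined precision for class ",
                                       classes[i], "; contributing 0"); 0 }
           else tp / (tp + fp)
      r <- if (tp + fn == 0) { warning("undefined recall for class ",
                                       classes[i], "; contributing 0"); 0 }
           else tp / (tp + fn)
      f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
      c(p, r, f)
    }
    prf <- vapply(seq_len(C), per_class, numeric(3))
    rep_ <- list(accuracy = acc, precision = mean(prf[1, ]),
                 recall = mean(prf[2, ]), f1 = mean(prf[3, ]),
                 balanced_accuracy = mean(prf[2, ]), confusion = conf)
  }
  structure(rep_, class = "metrics_report")
}

# ---- experiment driver ------------------------------------------------

#' Experiment configuration
#'
#' @param dict_kind `"gabor"`, `"learned"`, or `"ksvd"`.
#' @param dict_size number of atoms K.
#' @param T_nonzero non-zeros per sparse code.
#' @param method aggregation: `"single"`, `"mean"`, `"max"`, `"voting"`.
#' @param blocks feature blocks, subset of `c("signal", "coef", "meta")`.
#' @param classifier adapter name.
#' @param seeds integer seeds; the experiment repeats per seed and
#'   reports the mean.
#' @param L resampled segment length.
#' @param dict_train_max maximum training segments for dictionary
#'   learning (seeded subsample of the training split).
#' @param dict_iters dictionary-learning iterations.
#' @return an `experiment_config`.
#' @export
experiment_config <- function(dict_kind = "gabor", dict_size = 125,
                              T_nonzero = 20, method = "mean",
                              blocks = "coef", classifier = "rf",
                              seeds = c(1, 2, 3), L = 128,
                              dict_train_max = 20000, dict_iters = 15) {
  if ("coef" %in% blocks && T_nonzero > dict_size)
    stop("infeasible configuration: T exceeds the dictionary size")
  structure(list(dict_kind = dict_kind, dict_size = dict_size,
                 T_nonzero = T_nonzero, method = method, blocks = blocks,
                 classifier = classifier, seeds = seeds, L = L,
                 dict_train_max = dict_train_max, dict_iters = dict_iters),
            class = "experiment_config")
}

#' Prepare a dataset for classification experiments
#'
#' Runs consensus R-peak detection and QRS segmentation on every record,
#' dropping records whose annotation is unusable (< 3 beats).
#'
#' @param dataset list of records or of `list(record, truth)` entries.
#' @param detectors detector names for [detect_consensus()].
#' @param L resampled segment length.
#' @return list with `records`, `segments`, `labels` (parallel lists) and
#'   `dropped` (ids of unusable records).
#' @export
prepare_dataset <- function(dataset, detectors = c("twoavg", "christov", "engzee"),
                            L = 128) {
  cfg <- segmentation_config(L)
  records <- list(); segments <- list(); labels <- character(0); dropped <- character(0)
  for (entry in dataset) {
    rec <- if (!is.null(entry$record)) entry$record else entry
    lab <- if (!is.null(entry$truth)) entry$truth$label else names(rec$labels)[1]
    ann <- detect_consensus(rec, detectors)
    if (!ann$usable) { dropped <- c(dropped, rec$id); next }
    records[[length(records) + 1L]] <- rec
    segments[[length(segments) + 1L]] <- extract_segments(rec, ann, cfg)
    labels <- c(labels, lab)
  }
  list(records = records, segments = segments, labels = labels, dropped = dropped)
}

#' Run a classification experiment
#'
#' For each seed: split the records 70/15/15 (stratified); build or learn
#' the dictionary (learned dictionaries use a seeded subsample of
#' training-split segments only); sparse-code every segment; assemble
#' features with the configured aggregation and blocks; fit the
#' classifier on the training split; evaluate on validation and test.
#' Returns the across-seed mean of the test metrics plus per-seed
#' reports.
#'
#' @param cfg an [experiment_config()].
#' @param prepared output of [prepare_dataset()].
#' @param relabel optional function mapping labels to a coarser task
#'   (e.g. binary).
#' @return list with `mean` (named metric means over seeds), `per_seed`
#'   (list of `metrics_report`s), `val_per_seed`, and `n_test`.
#' @export
run_experiment <- function(cfg, prepared, relabel = NULL) {
  labels <- prepared$labels
  if (!is.null(relabel)) labels <- vapply(labels, relabel, "")
  segs <- prepared$segments
  recs <- prepared$records
  n <- length(labels)
  if (n < 10) stop("too few usable records for an experiment")
  need_coef <- "coef" %in% cfg$blocks
  dict_static <- !need_coef || cfg$dict_kind == "gabor"
  coefs_cache <- NULL

  encode_all <- function(D) lapply(segs, encode_segment_set, D = D,
                                   T_nonzero = cfg$T_nonzero)

  if (need_coef && dict_static) {
    D <- build_gabor(cfg$L, cfg$dict_size)
    coefs_cache <- encode_all(D)
  }

  per_seed <- list(); val_seed <- list()
  for (seed in cfg$seeds) {
    sp <- split_records(labels, seed = seed)
    coefs <- coefs_cache
    if (need_coef && !dict_static) {
      train_mat <- do.call(cbind, lapply(segs[sp$train], function(s) {
        d <- dim(s$tensor)
        matrix(aperm(s$tensor, c(3, 1, 2)), nrow = d[3])
      }))
      if (ncol(train_mat) > cfg$dict_train_max) {
        rng <- local_rng(seed + 777L)
        train_mat <- train_mat[, rng$int(ncol(train_mat), ncol(train_mat))[
          seq_len(cfg$dict_train_max)], drop = FALSE]
      }
      learner <- switch(cfg$dict_kind, learned = learn_dictionary_mod,
                        ksvd = learn_dictionary_ksvd,
                        stop("unknown dictionary kind: ", cfg$dict_kind))
      D <- learner(train_mat, cfg$dict_size, cfg$T_nonzero,
                   iters = cfg$dict_iters, seed = seed)
      coefs <- encode_all(D)
    }

    if (cfg$method == "voting") {
      vecs <- lapply(seq_len(n), function(i)
        per_segment_vectors(segs = segs[[i]], coefs = coefs[[i]],
                            record = recs[[i]], blocks = cfg$blocks))
      model <- fit_voting(cfg$classifier, vecs[sp$train], labels[sp$train])
      pred_for <- function(ix) vapply(ix, function(i)
        predict_voting(model, vecs[[i]])$class, "")
      val_rep <- compute_metrics(labels[sp$val], pred_for(sp$val),
                                 classes = sort(unique(labels)))
      test_rep <- compute_metrics(labels[sp$test], pred_for(sp$test),
                                  classes = sort(unique(labels)))
    } else {
      X <- do.call(rbind, lapply(seq_len(n), function(i)
        build_features(segs = segs[[i]], coefs = coefs[[i]], record = recs[[i]],
                       blocks = cfg$blocks, method = cfg$method)))
      adapter <- get_classifier(cfg$classifier)
      model <- adapter$fit(X[sp$train, , drop = FALSE], factor(labels[sp$train]))
      predict_cls <- function(ix) {
        p <- adapter$predict_prob(model, X[ix, , drop = FALSE])
        colnames(p)[max.col(p, ties.method = "first")]
      }
      val_rep <- compute_metrics(labels[sp$val], predict_cls(sp$val),
                                 classes = sort(unique(labels)))
      test_rep <- compute_metrics(labels[sp$test], predict_cls(sp$test),
                                  classes = sort(unique(labels)))
    }
    per_seed[[as.character(seed)]] <- test_rep
    val_seed[[as.character(seed)]] <- val_rep
  }
  metric_names <- c("accuracy", "precision", "recall", "f1", "balanced_accuracy")
  means <- vapply(metric_names, function(m)
    mean(vapply(per_seed, function(r) r[[m]], 0)), 0)
  list(mean = means, per_seed = per_seed, val_per_seed = val_seed,
       n_test = length(split_records(labels, seed = cfg$seeds[1])$test))
}
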
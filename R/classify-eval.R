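# Balanced-per-class evaluation protocol: holdout splits, classifier
# stand-ins with library defaults, confusion/accuracy/AUC/macro-PRF
# reports, repeated experiments.

#' Split specification
#'
#' @param mode `"balanced_holdout"` (reserve `n_test_per_class` examples of
#'   every class for testing) or `"fraction_split"` (random
#'   `test_fraction` holdout).
#' @param n_test_per_class Test examples per class (balanced mode).
#' @param test_fraction Test fraction in `(0, 1)` (fraction mode).
#' @param seed Base seed; repetition `r` uses `seed + r - 1`.
#' @param repetitions Number of independent repetitions (default 10).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(mode = c("balanced_holdout", "fraction_split"),
                       n_test_per_class = 50, test_fraction = 0.2,
                       seed = 1, repetitions = 10) {
  mode <- match.arg(mode)
  if (mode == "balanced_holdout") stopifnot(n_test_per_class >= 1)
  else stopifnot(test_fraction > 0, test_fraction < 1)
  structure(list(mode = mode, n_test_per_class = n_test_per_class,
                 test_fraction = test_fraction, seed = seed,
                 repetitions = repetitions),
            class = "split_spec")
}

#' Balanced per-class holdout split
#'
#' Reserves exactly `n_test_per_class` uniformly sampled members of every
#' class for testing; the complement trains. With a balanced test set,
#' chance accuracy is `1/k` regardless of the original class imbalance.
#'
#' @param labels Class labels for all rows.
#' @param n_test_per_class Test examples per class.
#' @param seed Integer seed.
#' @return List with disjoint integer vectors `train` and `test`.
#' @export
balanced_holdout <- function(labels, n_test_per_class, seed = 1) {
  y <- factor(labels)
  sizes <- table(y)
  bad <- sizes < n_test_per_class + 1
  if (any(bad))
    stopf("class(es) too small for %d test examples: %s", n_test_per_class,
          paste(sprintf("%s (n = %d)", names(sizes)[bad], sizes[bad]),
                collapse = ", "))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  test <- unlist(lapply(levels(y), function(cl)
    sample(which(y == cl), n_test_per_class)), use.names = FALSE)
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Random fraction split
#'
#' @param labels Class labels for all rows.
#' @param test_fraction Fraction held out for testing.
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`.
#' @export
fraction_split <- function(labels, test_fraction = 0.2, seed = 1) {
  n <- length(labels)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  test <- sort(sample(n, max(1, round(test_fraction * n))))
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Classifier specification
#'
#' Stand-ins mirroring common "default settings" of interactive
#' classification tools: `bagged_trees` = 30 bootstrap-aggregated unpruned
#' CARTs (random forest with `mtry = p`), `mlp_narrow` / `mlp_wide` =
#' single-hidden-layer networks with 10 / 100 units (1000-iteration cap,
#' standardized inputs), `knn` = 10-neighbour Euclidean vote, `linear_svm`
#' = linear-kernel SVM with probability outputs.
#'
#' @param family One of `"bagged_trees"`, `"mlp_narrow"`, `"mlp_wide"`,
#'   `"knn"`, `"linear_svm"`.
#' @param standardize Standardize inputs with training statistics; default
#'   TRUE except for trees.
#' @param ... Family-specific overrides (`ntree`, `size`, `maxit`, `k`,
#'   `cost`).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(family = c("bagged_trees", "mlp_narrow", "mlp_wide",
                                  "knn", "linear_svm"),
                       standardize = NULL, ...) {
  family <- match.arg(family)
  defaults <- switch(family,
    bagged_trees = list(ntree = 30),
    mlp_narrow = list(size = 10, maxit = 1000),
    mlp_wide = list(size = 100, maxit = 1000),
    knn = list(k = 10),
    linear_svm = list(cost = 1))
  hp <- utils::modifyList(defaults, list(...))
  if (is.null(standardize)) standardize <- family != "bagged_trees"
  structure(list(family = family, hyper = hp, standardize = standardize),
            class = "model_spec")
}

# training-fold preprocessing: median imputation + optional standardization
.fit_preproc <- function(X, standardize) {
  med <- vapply(X, function(v) stats::median(v, na.rm = TRUE), numeric(1))
  med[is.na(med)] <- 0
  ctr <- scl <- NULL
  X <- .apply_preproc(X, list(medians = med))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- vapply(X, stats::sd, numeric(1))
    scl[scl == 0 | is.na(scl)] <- 1
  }
  list(medians = med, center = ctr, scale = scl)
}

.apply_preproc <- function(X, pp) {
  for (j in seq_along(X)) {
    v <- X[[j]]
    v[is.na(v)] <- pp$medians[[j]]
    if (!is.null(pp$center)) v <- (v - pp$center[[j]]) / pp$scale[[j]]
    X[[j]] <- v
  }
  X
}

#' Train a classifier on selected rows
#'
#' Median imputation and (if flagged) standardization statistics are
#' computed from the training rows only and stored for prediction, so no
#' test information leaks into preprocessing.
#'
#' @param table Feature data.frame with a `Group` label column (already
#'   restricted to the desired feature subset).
#' @param train_idx Training row indices (non-empty).
#' @param spec A [model_spec()].
#' @param seed Integer seed controlling any training randomness.
#' @param label_col Name of the label column.
#' @return Object of class `ecg_classifier`; use [predict.ecg_classifier()].
#' @export
train_classifier <- function(table, train_idx, spec = model_spec(),
                             seed = 1, label_col = "Group") {
  stopifnot(inherits(spec, "model_spec"), length(train_idx) > 0)
  sl <- .split_features_label(table, label_col)
  y <- droplevels(sl$y[train_idx])
  if (nlevels(y) < 2) stopf("training set contains a single class")
  Xtr <- sl$X[train_idx, , drop = FALSE]
  pp <- .fit_preproc(Xtr, spec$standardize)
  Xtr <- .apply_preproc(Xtr, pp)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  hp <- spec$hyper
  fit <- switch(spec$family,
    bagged_trees = randomForest::randomForest(
      x = Xtr, y = y, ntree = hp$ntree, mtry = ncol(Xtr), replace = TRUE),
    mlp_narrow = ,
    mlp_wide = nnet::nnet(
      x = as.matrix(Xtr), y = nnet::class.ind(y), size = hp$size,
      softmax = TRUE, maxit = hp$maxit, trace = FALSE,
      MaxNWts = 100000, decay = 1e-4),
    knn = list(X = as.matrix(Xtr), y = y, k = hp$k),
    linear_svm = e1071::svm(x = as.matrix(Xtr), y = y, kernel = "linear",
                            cost = hp$cost, probability = TRUE))
  structure(list(spec = spec, fit = fit, preproc = pp, levels = levels(y),
                 features = names(sl$X), label_col = label_col, seed = seed),
            class = "ecg_classifier")
}

# vote-fraction kNN scores (distance ties broken by index order)
.knn_scores <- function(fit, Xnew) {
  n <- nrow(Xnew)
  scores <- matrix(0, n, nlevels(fit$y),
                   dimnames = list(NULL, levels(fit$y)))
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(fit$X) - Xnew[i, ])^2))
    nb <- fit$y[order(d)[seq_len(fit$k)]]
    tab <- table(nb) / fit$k
    scores[i, names(tab)] <- as.numeric(tab)
  }
  scores
}

#' Predict classes and per-class scores
#'
#' @param object An [train_classifier()] model.
#' @param newdata Feature data.frame with the training feature columns.
#' @param ... Unused.
#' @return List with `class` (factor) and `scores` (matrix, rows summing
#'   to 1 where the family emits probabilities).
#' @export
predict.ecg_classifier <- function(object, newdata, ...) {
  X <- newdata[, object$features, drop = FALSE]
  X <- .apply_preproc(X, object$preproc)
  scores <- switch(object$spec$family,
    bagged_trees = stats::predict(object$fit, X, type = "prob"),
    mlp_narrow = ,
    mlp_wide = stats::predict(object$fit, as.matrix(X)),
    knn = .knn_scores(object$fit, as.matrix(X)),
    linear_svm = {
      pr <- stats::predict(object$fit, as.matrix(X), probability = TRUE)
      attr(pr, "probabilities")[, object$levels, drop = FALSE]
    })
  scores <- scores[, object$levels, drop = FALSE]
  cls <- factor(object$levels[max.col(scores, ties.method = "first")],
                levels = object$levels)
  list(class = cls, scores = scores)
}

# one-vs-rest AUC via the rank (Mann-Whitney) statistic; equals the
# trapezoidal ROC area with tied scores counted half
.auc_ovr <- function(scores, truth) {
  vapply(colnames(scores), function(cl) {
    pos <- truth == cl
    np <- sum(pos)
    nn <- sum(!pos)
    if (np == 0 || nn == 0) return(NA_real_)
    r <- rank(scores[, cl])
    (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  }, numeric(1))
}

#' Evaluate a trained classifier on held-out rows
#'
#' @param model An [train_classifier()] model.
#' @param table The feature table the split indices refer to.
#' @param test_idx Test row indices (disjoint from training).
#' @return Object of class `eval_report`: confusion matrix (rows = true),
#'   accuracy, per-class one-vs-rest AUC, macro precision / recall / F1
#'   (per-class then unweighted mean; a class never predicted gets
#'   precision 0 with a warning).
#' @export
evaluate <- function(model, table, test_idx) {
  stopifnot(inherits(model, "ecg_classifier"))
  truth <- factor(table[[model$label_col]][test_idx], levels = model$levels)
  pred <- predict(model, table[test_idx, , drop = FALSE])
  conf <- table(true = truth, predicted = pred$class)
  acc <- sum(diag(conf)) / sum(conf)
  tp <- diag(conf)
  prec <- ifelse(colSums(conf) == 0, NA, tp / colSums(conf))
  if (anyNA(prec)) {
    warnf("class(es) never predicted get precision 0: %s",
          paste(model$levels[is.na(prec)], collapse = ", "))
    prec[is.na(prec)] <- 0
  }
  rec <- ifelse(rowSums(conf) == 0, 0, tp / rowSums(conf))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  structure(list(confusion = conf, accuracy = acc,
                 auc = .auc_ovr(pred$scores, truth),
                 macro_precision = mean(prec), macro_recall = mean(rec),
                 macro_f1 = mean(f1), n_test = length(test_idx),
                 family = model$spec$family),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s, n_test = %d):\n", x$family, x$n_test))
  cat(sprintf("  accuracy: %.4f   macro P/R/F1: %.4f / %.4f / %.4f\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  cat("  per-class AUC:",
      paste(sprintf("%s %.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Run a repeated balanced-protocol experiment
#'
#' For each repetition: draw a fresh split, train every model on the
#' requested feature subset, evaluate on the held-out rows; then average
#' the metrics across repetitions.
#'
#' @param table Full feature table with a `Group` label column.
#' @param feature_subset Either a registered subset name (see
#'   [feature_subset()]), a character vector of column names, or a
#'   `ranked_features` object (its top-k names are used).
#' @param split A [split_spec()].
#' @param models List of [model_spec()]s (a single spec is accepted).
#' @param label_col Name of the label column.
#' @return Object of class `experiment_result`: per-model mean metrics and
#'   the per-repetition [evaluate()] reports.
#' @export
run_experiment <- function(table, feature_subset = "all38",
                           split = split_spec(),
                           models = list(model_spec("bagged_trees")),
                           label_col = "Group") {
  if (inherits(models, "model_spec")) models <- list(models)
  cols <- if (inherits(feature_subset, "ranked_features"))
    feature_subset$features
  else if (length(feature_subset) == 1 &&
           feature_subset %in% c("general4", "morph13", "ours29", "all38"))
    feature_subset(feature_subset)
  else as.character(feature_subset)
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stopf("feature(s) absent from table: %s", paste(missing, collapse = ", "))
  sub <- table[, c(cols, label_col)]

  reps <- lapply(seq_len(split$repetitions), function(r) {
    seed_r <- split$seed + r - 1
    idx <- if (split$mode == "balanced_holdout")
      balanced_holdout(sub[[label_col]], split$n_test_per_class, seed_r)
    else fraction_split(sub[[label_col]], split$test_fraction, seed_r)
    lapply(models, function(ms) {
      fit <- train_classifier(sub, idx$train, ms, seed = seed_r,
                              label_col = label_col)
      evaluate(fit, sub, idx$test)
    })
  })
  fams <- vapply(models, function(m) m$family, character(1))
  summary <- do.call(rbind, lapply(seq_along(models), function(j) {
    metr <- function(f) mean(vapply(reps, function(r) r[[j]][[f]], numeric(1)))
    data.frame(family = fams[j], accuracy = metr("accuracy"),
               macro_precision = metr("macro_precision"),
               macro_recall = metr("macro_recall"),
               macro_f1 = metr("macro_f1"),
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, repetitions = reps, features = cols,
                 split = split, n_features = length(cols)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Experiment: %d features, %d repetition(s), %s protocol\n",
              x$n_features, x$split$repetitions, x$split$mode))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
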
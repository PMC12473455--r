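# Balanced evaluation protocol: splits, leakage, metrics, repeated
# experiments.

strong_table <- function(n_per_class = 60, seed = 1)
  generate_feature_table(
    n_per_class,
    effect = list(s1 = c(0, 3, 0, 3), s2 = c(0, 0, 3, 3), s3 = c(0, 3, 3, 0)),
    n_features = 10, seed = seed)

test_that("balanced holdout emits exactly n per class, disjoint, seeded", {
  labs <- factor(rep(c("a", "b", "c", "d"), times = c(1000, 1000, 1000, 1000)))
  sp <- balanced_holdout(labs, 500, seed = 3)
  expect_length(sp$test, 2000)
  expect_true(all(table(labs[sp$test]) == 500))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_equal(sort(c(sp$train, sp$test)), seq_along(labs))
  sp2 <- balanced_holdout(labs, 500, seed = 3)
  expect_identical(sp, sp2)
  expect_error(balanced_holdout(factor(rep("a", 5), levels = "a"), 5),
               "too small")
  small <- factor(c(rep("a", 10), rep("b", 3)))
  expect_error(balanced_holdout(small, 3), "b \\(n = 3\\)")
})

test_that("preprocessing statistics come from training rows only", {
  tab <- strong_table(30, seed = 7)
  idx <- balanced_holdout(tab$Group, 5, seed = 1)
  fit1 <- train_classifier(tab, idx$train, model_spec("knn"), seed = 1)
  # corrupt a test-only row grotesquely: training statistics must not move
  tab2 <- tab
  tab2[idx$test[1], "s1"] <- 1e6
  tab2[idx$test[2], "s2"] <- NA
  fit2 <- train_classifier(tab2, idx$train, model_spec("knn"), seed = 1)
  expect_identical(fit1$preproc, fit2$preproc)
})

test_that("classifier families train, predict and are seed-deterministic", {
  tab <- strong_table(30, seed = 11)
  idx <- balanced_holdout(tab$Group, 8, seed = 2)
  for (fam in c("bagged_trees", "mlp_narrow", "knn", "linear_svm")) {
    fit <- train_classifier(tab, idx$train, model_spec(fam), seed = 5)
    pr <- predict(fit, tab[idx$test, ])
    expect_length(pr$class, 32)
    expect_equal(dim(pr$scores), c(32, 4))
    expect_equal(unname(rowSums(pr$scores)), rep(1, 32), tolerance = 1e-6)
    fit2 <- train_classifier(tab, idx$train, model_spec(fam), seed = 5)
    expect_equal(predict(fit2, tab[idx$test, ])$class, pr$class)
  }
  # separable 2-class toy: perfect training accuracy for bagged trees
  toy <- data.frame(x = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)),
                    Group = factor(rep(c("lo", "hi"), each = 20)))
  fit <- train_classifier(toy, 1:40, model_spec("bagged_trees"), seed = 1)
  expect_equal(unname(predict(fit, toy)$class), toy$Group)
  one_class <- data.frame(x = rnorm(10), Group = factor(rep("a", 10)))
  expect_error(train_classifier(one_class, 1:10, model_spec("knn")),
               "single class")
})

test_that("kNN vote fractions agree with the reference implementation", {
  skip_if_not_installed("class")
  tab <- strong_table(25, seed = 13)
  idx <- balanced_holdout(tab$Group, 5, seed = 4)
  fit <- train_classifier(tab, idx$train, model_spec("knn", k = 7), seed = 1)
  pr <- predict(fit, tab[idx$test, ])
  Xtr <- scale(as.matrix(tab[idx$train, 1:10]))
  Xte <- scale(as.matrix(tab[idx$test, 1:10]),
               center = attr(Xtr, "scaled:center"),
               scale = attr(Xtr, "scaled:scale"))
  ref <- class::knn(Xtr, Xte, tab$Group[idx$train], k = 7, prob = TRUE)
  # winning-class vote fraction must match where there is a unique winner
  win_prob <- apply(pr$scores, 1, max)
  agree <- abs(win_prob - attr(ref, "prob")) < 1e-9
  expect_gt(mean(agree), 0.9)   # ties may break differently
})

test_that("evaluation metrics match hand-computed values", {
  # engineer an exact confusion [[40,10],[10,40]] with a 1-NN
  train <- data.frame(x = c(0, 1),
                      Group = factor(c("P", "N"), levels = c("P", "N")))
  test_x <- c(rep(0, 40), rep(1, 10),    # true P: 40 right, 10 wrong
              rep(1, 40), rep(0, 10))    # true N: 40 right, 10 wrong
  test <- data.frame(x = test_x,
                     Group = factor(rep(c("P", "N"), each = 50),
                                    levels = c("P", "N")))
  tab <- rbind(train, test)
  fit <- train_classifier(tab, 1:2, model_spec("knn", k = 1,
                                               standardize = FALSE))
  rep_ <- evaluate(fit, tab, 3:102)
  expect_equal(unname(as.vector(rep_$confusion)), c(40, 10, 10, 40))
  expect_equal(rep_$accuracy, 0.8)
  expect_equal(rep_$macro_f1, 0.8)
  expect_equal(rep_$macro_precision, 0.8)
  expect_equal(rep_$macro_recall, 0.8)
  expect_equal(sum(rep_$confusion), rep_$n_test)
})

test_that("perfect predictions score 1 on every metric", {
  base <- strong_table(30, seed = 17)
  tab <- data.frame(oracle = as.integer(base$Group),  # feature = label
                    Group = base$Group)
  idx <- balanced_holdout(tab$Group, 8, seed = 5)
  fit <- train_classifier(tab, idx$train, model_spec("knn", k = 1), seed = 1)
  rep_ <- evaluate(fit, tab, idx$test)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$macro_f1, 1)
  expect_true(all(rep_$auc == 1))
})

test_that("one-vs-rest AUC agrees with pROC and is ~0.5 for noise", {
  skip_if_not_installed("pROC")
  set.seed(23)
  truth <- factor(sample(c("a", "b"), 300, replace = TRUE))
  scores <- cbind(a = runif(300), b = runif(300))
  mine <- ecglead2:::.auc_ovr(scores, truth)
  for (cl in c("a", "b")) {
    ref <- suppressMessages(pROC::auc(pROC::roc(
      truth == cl, scores[, cl], levels = c(FALSE, TRUE), direction = "<")))
    expect_equal(unname(mine[cl]), as.numeric(ref), tolerance = 1e-12)
  }
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    tr <- factor(sample(c("a", "b"), 1000, replace = TRUE))
    sc <- cbind(a = runif(1000), b = runif(1000))
    mean(ecglead2:::.auc_ovr(sc, tr))
  }, numeric(1))
  expect_lt(max(abs(aucs - 0.5)), 0.05)
})

test_that("experiments aggregate repetitions; chance is 1/k when shuffled", {
  tab <- strong_table(60, seed = 19)
  res <- run_experiment(tab, feature_subset = c("s1", "s2", "s3"),
                        split = split_spec(n_test_per_class = 20, seed = 1,
                                           repetitions = 3),
                        models = model_spec("bagged_trees"))
  expect_s3_class(res, "experiment_result")
  expect_gt(res$summary$accuracy, 0.8)
  expect_length(res$repetitions, 3)
  # shuffling labels collapses accuracy to chance despite class imbalance
  set.seed(29)
  imb <- generate_feature_table(40, n_features = 5, seed = 31)
  imb <- imb[c(1:160, 1:40), ]          # make one class over-represented
  imb$Group <- sample(imb$Group)
  res0 <- run_experiment(imb, feature_subset = sprintf("feat%02d", 1:5),
                         split = split_spec(n_test_per_class = 10, seed = 2,
                                            repetitions = 5),
                         models = model_spec("knn"))
  expect_lt(abs(res0$summary$accuracy - 0.25), 0.1)
  expect_error(run_experiment(tab, feature_subset = "nope",
                              models = model_spec("knn")), "absent")
})

test_that("registered subsets restrict the trained model's inputs", {
  coh <- generate_cohort(3, classes = c("AFIB", "SB", "SR", "ST"), seed = 37,
                         noise = noise_spec(0, 0.1, 0, 50, 0))
  tab <- assemble_feature_table(coh$records, coh$diagnostics,
                                rhythm_scheme("four"), denoise = FALSE)
  res <- run_experiment(tab, feature_subset = "ours29",
                        split = split_spec(n_test_per_class = 1, seed = 1,
                                           repetitions = 1),
                        models = model_spec("knn", k = 1))
  expect_equal(res$n_features, 29)
  expect_identical(sort(res$features), sort(feature_subset("ours29")))
})
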
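# small separable three-class feature set (20 per class, distinct means);
# sep = 6 puts class centers far enough apart that even single axis-aligned
# tree splits generalize (the separable limit)
class_fixture <- function(n_per = 20, p = 12, sep = 6, seed = 41) {
  set.seed(seed)
  classes <- c("metabolic", "inflammatory", "other")
  centers <- rbind(c(rep(sep, 4), rep(0, p - 4)),
                   c(rep(0, 4), rep(sep, 4), rep(0, p - 8)),
                   rep(0, p))
  x <- do.call(rbind, lapply(1:3, function(i) {
    matrix(rnorm(n_per * p, mean = rep(centers[i, ], each = n_per)), n_per, p)
  }))
  rownames(x) <- sprintf("r%03d", seq_len(nrow(x)))
  colnames(x) <- sprintf("f%02d", seq_len(p))
  labels <- stats::setNames(rep(classes, each = n_per), rownames(x))
  list(x = x, labels = labels)
}

# colsample < 1 forces the trees to spread over the redundant informative
# features; with all features available every tree reuses one threshold,
# which does not generalize to test points beyond the training range
small_gbt_grid <- data.frame(n_estimators = 100, max_depth = 3,
                             learning_rate = 0.3, subsample = 1,
                             colsample_bytree = 0.3, gamma = 0)

test_that("stratified folds balance classes within one example", {
  labels <- stats::setNames(rep(c("metabolic", "inflammatory", "other"),
                                times = c(50, 50, 50)),
                            sprintf("r%03d", 1:150))
  folds <- stratified_folds(labels, 10, seed = 2)
  for (f in 1:10)
    expect_true(all(table(labels[folds == f]) == 5))

  # the published subcutaneous label counts: 44/40/50
  labels2 <- stats::setNames(rep(c("metabolic", "inflammatory", "other"),
                                 times = c(44, 40, 50)),
                             sprintf("q%03d", 1:134))
  folds2 <- stratified_folds(labels2, 10, seed = 3)
  counts <- table(labels2, folds2)
  expect_true(all(abs(counts - rowMeans(counts)) <= 1))
  # folds are disjoint and exhaustive by construction (one id, one fold)
  expect_setequal(names(folds2), names(labels2))
  expect_true(all(folds2 %in% 1:10))

  expect_error(stratified_folds(labels2, 45), "fewer folds")
})

test_that("metrics follow the one-vs-rest formulas", {
  # perfect three-class prediction
  perfect <- confusion_counts(rep(c("metabolic", "inflammatory", "other"), 10),
                              rep(c("metabolic", "inflammatory", "other"), 10))
  m <- compute_metrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$average_accuracy, 1)

  # binary all-wrong
  wrong <- confusion_counts(rep(c("metabolic", "other"), 5),
                            rep(c("other", "metabolic"), 5),
                            classes = c("metabolic", "other"))
  expect_warning(mw <- compute_metrics(wrong), NA)
  expect_equal(mw$recall, 0)
  expect_equal(mw$precision, 0)
  expect_equal(mw$accuracy, 0)

  # 3-class confusion with rows (8,1,1 / 2,7,1 / 0,2,8)
  truth <- rep(c("metabolic", "inflammatory", "other"), each = 10)
  pred <- c(rep("metabolic", 8), "inflammatory", "other",
            rep("metabolic", 2), rep("inflammatory", 7), "other",
            rep("inflammatory", 2), rep("other", 8))
  cm <- confusion_counts(truth, pred)
  m3 <- compute_metrics(cm)
  # overall agreement 23/30 appears in each class's (TP+TN)/n
  expect_equal(unname(cm[, "TP"] + cm[, "TN"]) / 30,
               c(26, 24, 26) / 30)
  # brute-force per-example oracle
  oracle <- t(vapply(c("metabolic", "inflammatory", "other"), function(cl) {
    tp <- sum(truth == cl & pred == cl); fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl); tn <- 30 - tp - fp - fn
    c(acc = (tp + tn) / 30, prec = tp / (tp + fp), rec = tp / (tp + fn),
      f1 = tp / (tp + 0.5 * (fp + fn)))
  }, numeric(4)))
  expect_equal(m3$per_class$accuracy, unname(oracle[, "acc"]))
  expect_equal(m3$per_class$precision, unname(oracle[, "prec"]))
  expect_equal(m3$per_class$recall, unname(oracle[, "rec"]))
  expect_equal(m3$per_class$f1, unname(oracle[, "f1"]))
  expect_equal(m3$average_accuracy, mean(oracle[, "acc"]))
})

test_that("metrics equal the brute-force loop on random confusion tables", {
  classes <- c("metabolic", "inflammatory", "other")
  for (s in 1:100) {
    set.seed(s)
    truth <- sample(classes, 30, replace = TRUE)
    pred <- sample(classes, 30, replace = TRUE)
    cm <- confusion_counts(truth, pred)
    suppressWarnings(m <- compute_metrics(cm))
    ora <- vapply(classes, function(cl) {
      tp <- sum(truth == cl & pred == cl); fp <- sum(truth != cl & pred == cl)
      fn <- sum(truth == cl & pred != cl); tn <- 30 - tp - fp - fn
      c((tp + tn) / 30,
        if (tp + fp > 0) tp / (tp + fp) else 0,
        if (tp + fn > 0) tp / (tp + fn) else 0,
        if (tp + 0.5 * (fp + fn) > 0) tp / (tp + 0.5 * (fp + fn)) else 0)
    }, numeric(4))
    expect_equal(m$accuracy, mean(ora[1, ]), tolerance = 1e-12)
    expect_equal(m$precision, mean(ora[2, ]), tolerance = 1e-12)
    expect_equal(m$recall, mean(ora[3, ]), tolerance = 1e-12)
    expect_equal(m$f1, mean(ora[4, ]), tolerance = 1e-12)
  }
})

test_that("separable classes reach perfect accuracy for all three families", {
  fx <- class_fixture()
  for (fam in c("gbt", "svm", "knn")) {
    spec <- classifier_spec(fam,
                            grid = switch(fam, gbt = small_gbt_grid,
                                          svm = data.frame(cost = 1),
                                          knn = data.frame(k = 5)),
                            seed = 7)
    cv <- train_eval(fx$x, fx$labels, spec, n_folds = 5)
    expect_equal(cv$mean_accuracy, 1, info = fam)
    # probability rows sum to 1
    probs <- as.matrix(cv$oof[, c("metabolic", "inflammatory", "other")])
    expect_true(all(abs(rowSums(probs) - 1) < 1e-6), info = fam)
    # pooled and per-fold metrics agree on balanced separable data
    expect_lt(abs(cv$metrics$accuracy - cv$fold_metrics$mean[["accuracy"]]),
              0.02)
  }
})

test_that("label permutation drives accuracy to chance", {
  fx <- class_fixture(n_per = 30)
  set.seed(44)
  shuffled <- stats::setNames(sample(fx$labels), names(fx$labels))
  cv <- train_eval(fx$x, shuffled,
                   classifier_spec("gbt", grid = small_gbt_grid, seed = 3),
                   n_folds = 5)
  # binomial noise around 1/3 at n = 90: sd ~ 0.05
  expect_lt(abs(cv$mean_accuracy - 1 / 3), 0.2)
})

test_that("cross-validation is reproducible and reports misclassifications", {
  fx <- class_fixture(sep = 0.8, seed = 45)  # overlapping classes
  spec <- classifier_spec("gbt", grid = small_gbt_grid, seed = 11)
  a <- train_eval(fx$x, fx$labels, spec, n_folds = 5)
  b <- train_eval(fx$x, fx$labels, spec, n_folds = 5)
  expect_identical(a$oof, b$oof)
  expect_lt(a$mean_accuracy, 1)
  # misclassification report lists exactly the out-of-fold errors with probs
  expect_identical(a$misclassified$receptor,
                   a$oof$receptor[a$oof$true != a$oof$predicted])
  expect_true(all(c("metabolic", "inflammatory", "other") %in%
                    names(a$misclassified)))
})

test_that("the final model predicts the training classes and guards its schema", {
  fx <- class_fixture()
  model <- fit_final(fx$x, fx$labels, "gbt",
                     as.list(small_gbt_grid), seed = 5)
  expect_s3_class(model, "receptor_classifier")
  tab <- predict(model, fx$x)
  expect_true(all(abs(rowSums(tab[, c("metabolic", "inflammatory", "other")])
                      - 1) < 1e-6))
  expect_identical(tab$predicted, unname(fx$labels[tab$receptor]))
  # determinism
  model2 <- fit_final(fx$x, fx$labels, "gbt", as.list(small_gbt_grid),
                      seed = 5)
  expect_identical(predict(model2, fx$x), tab)
  # schema mismatch names the offending columns
  bad <- fx$x
  colnames(bad)[1] <- "rogue"
  expect_error(predict(model, bad), "rogue")
})
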
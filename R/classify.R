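# Three-class receptor classification: gradient-boosted trees, linear SVM
# and k-NN under stratified 10-fold cross-validation with grid search, the
# one-vs-rest confusion-count metrics, and a final fitted model object.

CLASS_ORDER <- c("metabolic", "inflammatory", "other")

#' Classifier specification
#'
#' Model family plus its hyperparameter grid. Defaults follow the tuned
#' search spaces: gradient-boosted trees over
#' `n_estimators {100,300} x max_depth {3,5} x learning_rate {0.01,0.03,0.09}
#' x subsample {0.9,1.0} x colsample_bytree {0.3,0.5,0.9} x gamma {0,1,5}`;
#' k-NN over odd `k` in 3..15 (Euclidean distance); linear SVM over a log
#' grid of `C`.
#'
#' @param family `"gbt"`, `"svm"` or `"knn"`.
#' @param grid data.frame of hyperparameter combinations; `NULL` for the
#'   family default.
#' @param seed integer seed used for every stochastic fit.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = c("gbt", "svm", "knn"), grid = NULL,
                            seed = 1L) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      gbt = expand.grid(n_estimators = c(100, 300), max_depth = c(3, 5),
                        learning_rate = c(0.01, 0.03, 0.09),
                        subsample = c(0.9, 1.0),
                        colsample_bytree = c(0.3, 0.5, 0.9),
                        gamma = c(0, 1, 5)),
      knn = data.frame(k = seq(3, 15, by = 2)),
      svm = data.frame(cost = c(0.01, 0.1, 1, 10, 100)))
  }
  if (nrow(grid) == 0L) stop("empty hyperparameter grid")
  if (family == "knn" && any(grid$k < 1 | grid$k %% 2 == 0))
    stop("k-NN neighbourhood sizes must be odd and >= 1")
  structure(list(family = family, grid = grid, seed = as.integer(seed)),
            class = "classifier_spec")
}

#' Stratified cross-validation folds
#'
#' Deterministic stratified partitioning: receptors are shuffled within
#' class under the seed and dealt round-robin into `n_folds` folds, so each
#' fold's class counts differ from proportionality by at most one.
#'
#' @param labels named character vector of class labels (no unlabeled
#'   entries).
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return named integer vector of fold ids (1..n_folds) over the
#'   receptors.
#' @export
stratified_folds <- function(labels, n_folds = 10, seed = 1L) {
  tab <- table(labels)
  small <- names(tab)[tab < n_folds]
  if (length(small))
    stop("class(es) smaller than the fold count (", paste(small, collapse = ", "),
         "); use fewer folds")
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  folds <- stats::setNames(integer(length(labels)), names(labels))
  for (cl in names(tab)) {
    members <- sample(names(labels)[labels == cl])
    folds[members] <- rep(seq_len(n_folds), length.out = length(members))
  }
  folds
}

## one-vs-rest confusion counts pooled over examples
confusion_counts <- function(true, pred, classes = CLASS_ORDER) {
  n <- length(true)
  counts <- t(vapply(classes, function(cl) {
    tp <- sum(true == cl & pred == cl)
    fp <- sum(true != cl & pred == cl)
    fn <- sum(true == cl & pred != cl)
    c(TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  }, numeric(4)))
  rownames(counts) <- classes
  counts
}

#' Classification metrics from one-vs-rest confusion counts
#'
#' Per class: `Accuracy = (TP+TN)/n`, `Recall = TP/(TP+FN)`,
#' `Precision = TP/(TP+FP)`, `F1 = TP/(TP + (FP+FN)/2)`. Headline values
#' are unweighted means over classes; `average_accuracy` is the mean
#' per-class accuracy. Empty denominators give 0 with a warning.
#'
#' @param counts class x (TP, FP, TN, FN) matrix, e.g. from pooled
#'   cross-validation test folds.
#' @return list: `per_class` data.frame and macro `accuracy`, `precision`,
#'   `recall`, `f1`, `average_accuracy`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(all(c("TP", "FP", "TN", "FN") %in% colnames(counts)))
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning(what, " undefined for empty class(es); reported as 0")
    out
  }
  n <- rowSums(counts)
  acc <- (counts[, "TP"] + counts[, "TN"]) / n
  rec <- safe_div(counts[, "TP"], counts[, "TP"] + counts[, "FN"], "recall")
  prec <- safe_div(counts[, "TP"], counts[, "TP"] + counts[, "FP"], "precision")
  f1 <- safe_div(counts[, "TP"],
                 counts[, "TP"] + 0.5 * (counts[, "FP"] + counts[, "FN"]), "F1")
  per_class <- data.frame(class = rownames(counts), accuracy = acc,
                          precision = prec, recall = rec, f1 = f1,
                          row.names = NULL)
  list(per_class = per_class,
       accuracy = mean(acc), precision = mean(prec), recall = mean(rec),
       f1 = mean(f1), average_accuracy = mean(acc))
}

## ---- per-family fit/predict -------------------------------------------

## features arrive raw (may contain NA); trees route missingness natively,
## svm/knn standardize on training statistics and zero-impute
fit_predict <- function(family, params, x_train, y_train, x_test, seed) {
  classes <- levels(y_train)
  switch(family,
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(x_train,
                                     label = as.integer(y_train) - 1L,
                                     missing = NA)
      bst <- xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = length(classes),
                      max_depth = params$max_depth,
                      eta = params$learning_rate,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      gamma = params$gamma,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
      p <- stats::predict(bst, xgboost::xgb.DMatrix(x_test, missing = NA))
      colnames(p) <- classes
      rownames(p) <- rownames(x_test)
      p
    },
    svm = {
      st <- train_standardizer(x_train)
      set.seed(seed)  # Platt scaling uses internal cross-validation
      fit <- e1071::svm(st$apply(x_train), y_train, kernel = "linear",
                        cost = params$cost, scale = FALSE,
                        type = "C-classification", probability = TRUE)
      pr <- attr(stats::predict(fit, st$apply(x_test), probability = TRUE),
                 "probabilities")
      pr[, classes, drop = FALSE]
    },
    knn = knn_probabilities(x_train, y_train, x_test, params$k),
    stop("unknown model family: ", family))
}

train_standardizer <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  mu[!is.finite(mu)] <- 0
  list(apply = function(m) {
    z <- sweep(sweep(m, 2, mu), 2, sd_, "/")
    z[is.na(z)] <- 0
    z
  })
}

## Euclidean k-NN with full vote proportions and deterministic ties
## (nearest neighbours by distance, then training order)
knn_probabilities <- function(x_train, y_train, x_test, k) {
  st <- train_standardizer(x_train)
  tr <- st$apply(x_train)
  te <- st$apply(x_test)
  classes <- levels(y_train)
  d2 <- outer(rowSums(te^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(te)), rowSums(tr^2)) - 2 * te %*% t(tr)
  p <- t(apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(min(k, length(row)))]
    tabulate(as.integer(y_train[nn]), nbins = length(classes)) / length(nn)
  }))
  dimnames(p) <- list(rownames(x_test), classes)
  p
}

## argmax with ties broken by the fixed class order
argmax_class <- function(prob) {
  classes <- colnames(prob)
  ord <- match(CLASS_ORDER[CLASS_ORDER %in% classes], classes)
  prob2 <- prob[, ord, drop = FALSE]
  colnames(prob2)[apply(prob2, 1, which.max)]
}

## ---- cross-validated grid search --------------------------------------

#' Cross-validated training and grid search
#'
#' For every grid point, fits on each training fold and collects
#' out-of-fold predictions; the best grid point maximizes mean per-fold
#' overall accuracy (ties broken toward the smaller model: the grid is
#' scanned in increasing-size order). Metrics for the winner are computed
#' both from the pooled confusion counts and as per-fold mean and standard
#' deviation.
#'
#' @param features a `feature_matrix` or plain receptor x feature matrix.
#' @param labels a `label_set` or named character vector (unlabeled entries
#'   ignored).
#' @param spec a [classifier_spec()].
#' @param folds fold assignment from [stratified_folds()]; built
#'   automatically when `NULL`.
#' @param n_folds folds when `folds` is `NULL`.
#' @return a `cv_result`: best hyperparameters, pooled confusion counts and
#'   metrics, per-fold metric mean/sd, out-of-fold probability table,
#'   misclassification report, and the full grid accuracy table.
#' @export
train_eval <- function(features, labels, spec, folds = NULL, n_folds = 10) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  lab <- if (inherits(labels, "label_set")) labels$labels else labels
  lab <- lab[lab %in% CLASS_ORDER]
  lab <- lab[names(lab) %in% rownames(x)]
  if (is.null(folds)) folds <- stratified_folds(lab, n_folds, spec$seed)
  folds <- folds[names(lab)]
  y <- factor(lab, levels = CLASS_ORDER[CLASS_ORDER %in% lab])
  xl <- x[names(lab), , drop = FALSE]
  fold_ids <- sort(unique(folds))
  for (f in fold_ids) {
    tr_classes <- table(y[folds != f])
    if (any(tr_classes == 0))
      stop("fold ", f, " leaves a class absent from training")
  }

  # scan the grid smallest model first so accuracy ties keep the simpler
  # one; among models tied on both accuracy and size, prefer the better
  # out-of-fold log-loss (the better-calibrated fit)
  grid <- spec$grid[order_grid(spec$family, spec$grid), , drop = FALSE]
  best <- NULL
  grid_acc <- numeric(nrow(grid))
  grid_logloss <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    prob <- matrix(NA_real_, length(lab), nlevels(y),
                   dimnames = list(names(lab), levels(y)))
    fold_acc <- numeric(length(fold_ids))
    for (i in seq_along(fold_ids)) {
      f <- fold_ids[i]
      te <- folds == f
      p <- fit_predict(spec$family, params, xl[!te, , drop = FALSE],
                       y[!te], xl[te, , drop = FALSE], spec$seed)
      prob[te, ] <- p[, levels(y)]
      fold_acc[i] <- mean(argmax_class(p[, levels(y), drop = FALSE]) ==
                            as.character(y[te]))
    }
    grid_acc[g] <- mean(fold_acc)
    grid_logloss[g] <- -mean(log(pmax(prob[cbind(seq_along(y),
                                                 as.integer(y))], 1e-15)))
    better <- is.null(best) ||
      grid_acc[g] > best$mean_accuracy + 1e-12 ||
      (abs(grid_acc[g] - best$mean_accuracy) <= 1e-12 &&
         identical(model_size(spec$family, params),
                   model_size(spec$family, best$params)) &&
         grid_logloss[g] < best$logloss - 1e-12)
    if (better) {
      best <- list(params = params, prob = prob, fold_acc = fold_acc,
                   mean_accuracy = grid_acc[g], logloss = grid_logloss[g])
    }
  }

  pred <- argmax_class(best$prob)
  truth <- as.character(y)
  pooled <- confusion_counts(truth, pred, levels(y))
  pooled_metrics <- compute_metrics(pooled)
  per_fold <- t(vapply(fold_ids, function(f) {
    te <- folds == f
    m <- compute_metrics(confusion_counts(truth[te], pred[te], levels(y)))
    c(accuracy = m$accuracy, precision = m$precision, recall = m$recall,
      f1 = m$f1)
  }, numeric(4)))
  oof <- data.frame(receptor = names(lab), true = truth, predicted = pred,
                    best$prob, row.names = NULL, check.names = FALSE)
  structure(list(family = spec$family,
                 best_params = best$params,
                 mean_accuracy = best$mean_accuracy,
                 logloss = best$logloss,
                 fold_accuracy = best$fold_acc,
                 pooled_counts = pooled,
                 metrics = pooled_metrics,
                 fold_metrics = list(mean = colMeans(per_fold),
                                     sd = apply(per_fold, 2, stats::sd)),
                 oof = oof,
                 misclassified = oof[oof$true != oof$predicted, , drop = FALSE],
                 grid = cbind(grid, mean_accuracy = grid_acc,
                              logloss = grid_logloss),
                 folds = folds,
                 seed = spec$seed),
            class = "cv_result")
}

order_grid <- function(family, grid) {
  switch(family,
         gbt = order(grid$n_estimators, grid$max_depth),
         knn = order(grid$k),
         svm = order(grid$cost),
         seq_len(nrow(grid)))
}

## the spec of "smaller model" per family: tree count and depth / k / C
model_size <- function(family, params) {
  switch(family,
         gbt = c(params$n_estimators, params$max_depth),
         knn = params$k,
         svm = params$cost,
         0)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cross-validated %s: mean fold accuracy %.3f\n",
              x$family, x$mean_accuracy))
  cat("best hyperparameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = "=",
            collapse = ", "), "\n")
  cat(sprintf("pooled macro metrics: precision %.3f recall %.3f F1 %.3f\n",
              x$metrics$precision, x$metrics$recall, x$metrics$f1))
  invisible(x)
}

## ---- final model -------------------------------------------------------

#' Fit the final classifier on all labeled receptors
#'
#' @param features a `feature_matrix` or plain matrix.
#' @param labels a `label_set` or named character vector.
#' @param family model family (see [classifier_spec()]).
#' @param params named list of hyperparameters, e.g. `best_params` from
#'   [train_eval()].
#' @param seed integer seed.
#' @return a `receptor_classifier` with `predict`, `print` and `summary`
#'   methods. Prediction validates the feature schema by hash before
#'   scoring.
#' @export
fit_final <- function(features, labels, family, params, seed = 1L) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  lab <- if (inherits(labels, "label_set")) labels$labels else labels
  lab <- lab[lab %in% CLASS_ORDER]
  lab <- lab[names(lab) %in% rownames(x)]
  y <- factor(lab, levels = CLASS_ORDER[CLASS_ORDER %in% lab])
  xl <- x[names(lab), , drop = FALSE]
  model <- switch(family,
    gbt = {
      dtrain <- xgboost::xgb.DMatrix(xl, label = as.integer(y) - 1L,
                                     missing = NA)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob", num_class = nlevels(y),
                      max_depth = params$max_depth, eta = params$learning_rate,
                      subsample = params$subsample,
                      colsample_bytree = params$colsample_bytree,
                      gamma = params$gamma, nthread = 1, seed = seed),
        data = dtrain, nrounds = params$n_estimators, verbose = 0)
    },
    svm = {
      st <- train_standardizer(xl)
      set.seed(seed)
      list(fit = e1071::svm(st$apply(xl), y, kernel = "linear",
                            cost = params$cost, scale = FALSE,
                            type = "C-classification", probability = TRUE),
           standardizer = st)
    },
    knn = list(x = xl, y = y),
    stop("unknown model family: ", family))
  obj <- structure(list(model = model, family = family, params = params,
                        classes = levels(y), schema = colnames(x),
                        schema_hash = schema_hash(colnames(x)),
                        train_receptors = names(lab), seed = seed),
                   class = "receptor_classifier")
  obj
}

schema_hash <- function(cols) {
  f <- tempfile(); on.exit(unlink(f))
  writeLines(cols, f)
  unname(tools::md5sum(f))
}

#' @export
print.receptor_classifier <- function(x, ...) {
  cat(sprintf("receptor classifier (%s): %d classes, %d features, %d training receptors\n",
              x$family, length(x$classes), length(x$schema),
              length(x$train_receptors)))
  invisible(x)
}

#' @export
summary.receptor_classifier <- function(object, ...) {
  print(object)
  cat("classes:", paste(object$classes, collapse = ", "), "\n")
  cat("hyperparameters:",
      paste(names(object$params), unlist(object$params), sep = "=",
            collapse = ", "), "\n")
  cat("feature schema hash:", object$schema_hash, "\n")
  invisible(object)
}

#' Predict class probabilities for receptors
#'
#' @param object a `receptor_classifier`.
#' @param features a `feature_matrix` or plain matrix whose column schema
#'   matches training (checked by hash; mismatches are an error naming the
#'   missing/extra columns).
#' @param ... unused.
#' @return a probability table: data.frame with receptor, one probability
#'   column per class, `predicted` and `max_prob`.
#' @export
predict.receptor_classifier <- function(object, features, ...) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  if (!identical(schema_hash(colnames(x)), object$schema_hash)) {
    missing <- setdiff(object$schema, colnames(x))
    extra <- setdiff(colnames(x), object$schema)
    stop("feature schema mismatch; missing: ",
         paste(utils::head(missing, 5), collapse = ", "),
         "; extra: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  prob <- switch(object$family,
    gbt = {
      p <- stats::predict(object$model, xgboost::xgb.DMatrix(x, missing = NA))
      colnames(p) <- object$classes
      rownames(p) <- rownames(x)
      p
    },
    svm = {
      pr <- attr(stats::predict(object$model$fit,
                                object$model$standardizer$apply(x),
                                probability = TRUE), "probabilities")
      pr[, object$classes, drop = FALSE]
    },
    knn = knn_probabilities(object$model$x, object$model$y, x,
                            object$params$k))
  predicted <- argmax_class(prob)
  data.frame(receptor = rownames(x), prob, predicted = predicted,
             max_prob = apply(prob, 1, max), row.names = NULL,
             check.names = FALSE)
}
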
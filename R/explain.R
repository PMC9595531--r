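# Shapley feature attribution, probability-cutoff prediction of unlabeled
# receptors, and cross-tissue comparison of predictions.

#' Shapley feature attributions
#'
#' For the gradient-boosted tree family this is the exact tree-path Shapley
#' decomposition of each class margin (local accuracy: base value plus the
#' feature attributions reproduce the class margin for every receptor). For
#' other families a permutation-sampling approximation against a reference
#' point is available via `method = "permutation"` (flagged approximate;
#' attributions sum to the probability difference from the reference).
#'
#' @param classifier a `receptor_classifier`.
#' @param features a `feature_matrix` or plain matrix with the training
#'   schema.
#' @param method `"auto"` (tree decomposition for gbt, otherwise an error
#'   pointing at the fallback), `"tree"`, or `"permutation"`.
#' @param n_perm permutations per receptor for the fallback.
#' @param seed seed for the fallback sampling.
#' @return an `attribution_table`: `values` (receptor x class x feature
#'   array), `base` (per-class base values), `margins` (receptor x class),
#'   `importance` (feature x class mean |attribution| plus an `overall`
#'   column), `feature_values`, `approximate` flag.
#' @export
shap_attribution <- function(classifier, features,
                             method = c("auto", "tree", "permutation"),
                             n_perm = 50, seed = 1L) {
  method <- match.arg(method)
  x <- if (inherits(features, "feature_matrix")) features$features else features
  if (method == "auto") {
    if (classifier$family == "gbt") method <- "tree"
    else stop("exact tree Shapley values need a tree-ensemble model; ",
              "use method = \"permutation\" for the ", classifier$family,
              " family (approximate)")
  }
  if (method == "tree" && classifier$family != "gbt")
    stop("method \"tree\" requires the gbt family")
  if (method == "tree") {
    contrib <- stats::predict(classifier$model,
                              xgboost::xgb.DMatrix(x, missing = NA),
                              predcontrib = TRUE)
    p <- dim(contrib)[3] - 1L
    vals <- contrib[, , seq_len(p), drop = FALSE]
    dimnames(vals) <- list(rownames(x), classifier$classes, colnames(x))
    base <- contrib[1, , p + 1L]
    names(base) <- classifier$classes
    margins <- stats::predict(classifier$model,
                              xgboost::xgb.DMatrix(x, missing = NA),
                              outputmargin = TRUE)
    dimnames(margins) <- list(rownames(x), classifier$classes)
    approximate <- FALSE
  } else {
    ps <- permutation_shap(classifier, x, n_perm, seed)
    vals <- ps$values
    base <- ps$base
    margins <- ps$prob
    approximate <- TRUE
  }
  imp <- apply(abs(vals), c(3, 2), mean)
  importance <- cbind(imp, overall = rowMeans(imp))
  structure(list(values = vals, base = base, margins = margins,
                 importance = importance, feature_values = x,
                 approximate = approximate),
            class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, ...) {
  cat(sprintf("Shapley attributions: %d receptors x %d classes x %d features%s\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              if (x$approximate) " (permutation approximation)" else ""))
  invisible(x)
}

## permutation-sampling Shapley values against a zero-imputed
## column-median reference point, on the probability scale
permutation_shap <- function(classifier, x, n_perm, seed) {
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  ref <- apply(x, 2, stats::median, na.rm = TRUE)
  ref[!is.finite(ref)] <- 0
  classes <- classifier$classes
  p <- ncol(x)
  predfun <- function(m) {
    rownames(m) <- paste0("r", seq_len(nrow(m)))
    as.matrix(stats::predict(classifier, m)[, classes])
  }
  base <- drop(predfun(matrix(ref, 1, p, dimnames = list(NULL, colnames(x)))))
  vals <- array(0, c(nrow(x), length(classes), p),
                dimnames = list(rownames(x), classes, colnames(x)))
  for (i in seq_len(nrow(x))) {
    xi <- x[i, ]
    acc <- array(0, c(length(classes), p))
    for (s in seq_len(n_perm)) {
      ord <- sample.int(p)
      prev <- base
      # walk the permutation, adding one feature of x at a time
      grid <- matrix(rep(ref, p), p, p, byrow = TRUE,
                     dimnames = list(NULL, colnames(x)))
      for (j in seq_len(p)) grid[j, ord[seq_len(j)]] <- xi[ord[seq_len(j)]]
      preds <- predfun(grid)
      for (j in seq_len(p)) {
        acc[, ord[j]] <- acc[, ord[j]] + (preds[j, ] - prev)
        prev <- preds[j, ]
      }
    }
    vals[i, , ] <- acc / n_perm
  }
  prob <- predfun(x)
  rownames(prob) <- rownames(x)
  list(values = vals, base = base, prob = prob)
}

#' Top features by mean absolute attribution
#'
#' @param attribution an `attribution_table`.
#' @param class a class name for per-class ranking, or `NULL` for the
#'   over-classes average.
#' @param n how many features (default 10).
#' @return data.frame feature, mean_abs_attribution, ranked.
#' @export
top_features <- function(attribution, class = NULL, n = 10) {
  imp <- if (is.null(class)) attribution$importance[, "overall"]
         else attribution$importance[, class]
  ord <- order(imp, decreasing = TRUE)[seq_len(min(n, length(imp)))]
  data.frame(feature = rownames(attribution$importance)[ord],
             mean_abs_attribution = unname(imp[ord]), row.names = NULL)
}

#' Predict unlabeled receptors at a probability cutoff
#'
#' @param classifier a `receptor_classifier`.
#' @param features features of the unlabeled receptors (training schema).
#' @param cutoff probability threshold; a prediction passes only when its
#'   maximum class probability is strictly greater (default 0.85).
#' @return prediction table: receptor, per-class probabilities, `predicted`,
#'   `max_prob`, `passes_cutoff`.
#' @export
predict_unlabeled <- function(classifier, features, cutoff = 0.85) {
  tab <- stats::predict(classifier, features)
  tab$passes_cutoff <- tab$max_prob > cutoff
  tab
}

#' Compare predictions across two tissues
#'
#' A receptor is `consistent` when both tissues predict the same class with
#' maximum probability strictly above `cutoff`; it `switches` when some
#' class's probability differs between tissues by strictly more than
#' `switch_diff`.
#'
#' @param preds_a,preds_b prediction tables from [predict_unlabeled()] for
#'   the two tissues.
#' @param cutoff consistency probability threshold (default 0.85).
#' @param switch_diff probability-difference threshold (default 0.85).
#' @return list: `table` (receptor, per-tissue predictions/probabilities,
#'   `consistent`, `switch`, `switch_class`), `only_a`, `only_b` (receptor
#'   ids present in one tissue only).
#' @export
cross_tissue_compare <- function(preds_a, preds_b, cutoff = 0.85,
                                 switch_diff = 0.85) {
  shared <- intersect(preds_a$receptor, preds_b$receptor)
  only_a <- setdiff(preds_a$receptor, shared)
  only_b <- setdiff(preds_b$receptor, shared)
  if (length(shared) == 0L) {
    warning("no shared receptors between the two prediction tables")
    return(list(table = data.frame(), only_a = only_a, only_b = only_b))
  }
  a <- preds_a[match(shared, preds_a$receptor), ]
  b <- preds_b[match(shared, preds_b$receptor), ]
  classes <- intersect(CLASS_ORDER, names(preds_a))
  diffs <- abs(as.matrix(a[, classes, drop = FALSE]) -
                 as.matrix(b[, classes, drop = FALSE]))
  max_diff <- apply(diffs, 1, max)
  switch_class <- classes[apply(diffs, 1, which.max)]
  out <- data.frame(
    receptor = shared,
    predicted_a = a$predicted, predicted_b = b$predicted,
    max_prob_a = a$max_prob, max_prob_b = b$max_prob,
    consistent = a$predicted == b$predicted &
      a$max_prob > cutoff & b$max_prob > cutoff,
    switch = max_diff > switch_diff,
    switch_class = ifelse(max_diff > switch_diff, switch_class, NA_character_),
    row.names = NULL)
  for (cl in classes) {
    out[[paste0(cl, "_a")]] <- a[[cl]]
    out[[paste0(cl, "_b")]] <- b[[cl]]
  }
  list(table = out, only_a = only_a, only_b = only_b)
}
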
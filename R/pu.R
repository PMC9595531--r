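# Positive-unlabeled bagging with linear SVMs: derive the "other" class from
# the metabolic positives against the unlabeled receptor pool.

#' Assemble the two positive label lists
#'
#' The inflammatory list is intersected with the receptor catalog, then
#' genes already labeled metabolic and genes on the exclusion list (the
#' stand-in for a curated metabolic/growth-process filter) are removed. The
#' metabolic list is intersected with the catalog only.
#'
#' @param metabolic character vector (or path to a one-gene-per-line file).
#' @param inflammatory character vector or path.
#' @param exclusion character vector or path; may be empty.
#' @param catalog receptor catalog ids.
#' @return list with `metabolic` and `inflammatory` character vectors.
#' @export
assemble_positive_lists <- function(metabolic, inflammatory,
                                    exclusion = character(0), catalog) {
  as_list <- function(x) if (length(x) == 1L && file.exists(x)) read_gene_list(x) else x
  met <- intersect(as_list(metabolic), catalog)
  inf <- setdiff(setdiff(intersect(as_list(inflammatory), catalog), met),
                 as_list(exclusion))
  shared <- intersect(met, inf)
  if (length(shared))
    stop("genes present in both positive lists after subtraction: ",
         paste(shared, collapse = ", "))
  list(metabolic = met, inflammatory = inf)
}

## standardize columns and zero-impute missing entries (linear SVMs cannot
## consume missingness); constant columns become all-zero
svm_ready <- function(x) {
  mu <- colMeans(x, na.rm = TRUE)
  sd_ <- apply(x, 2, stats::sd, na.rm = TRUE)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  mu[!is.finite(mu)] <- 0
  z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  z[is.na(z)] <- 0
  z
}

#' Positive-unlabeled bagging with linear SVMs
#'
#' Each iteration draws `|positives|` unlabeled points with replacement as
#' provisional negatives, fits a linear SVM (positives vs sampled
#' negatives), and scores the out-of-bag unlabeled points with the signed
#' decision value (oriented so positives score high). The final score per
#' unlabeled receptor is its mean OOB decision value; low scores mark
#' likely true negatives.
#'
#' @param features a `feature_matrix` or plain receptor x feature matrix.
#' @param positives receptor ids of the positive class.
#' @param unlabeled receptor ids of the unlabeled pool (disjoint from
#'   `positives`).
#' @param T number of bagging iterations (default 100).
#' @param cost linear-SVM regularization constant.
#' @param seed integer seed.
#' @return an `oob_scores` list: `scores` (named mean OOB decision values,
#'   lower = more negative), `n_oob` (evaluations per receptor),
#'   `unscored` (ids never OOB), `T`.
#' @export
pu_bagging <- function(features, positives, unlabeled, T = 100, cost = 1,
                       seed = 1L) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  if (length(positives) < 5) stop("need at least 5 positive receptors")
  if (length(intersect(positives, unlabeled)))
    stop("positives and unlabeled sets overlap")
  missing <- setdiff(c(positives, unlabeled), rownames(x))
  if (length(missing))
    stop("receptors absent from the feature matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  z <- svm_ready(x[c(positives, unlabeled), , drop = FALSE])
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  np <- length(positives)
  sum_scores <- stats::setNames(rep(0, length(unlabeled)), unlabeled)
  n_oob <- stats::setNames(rep(0L, length(unlabeled)), unlabeled)
  y <- factor(c(rep("pos", np), rep("neg", np)), levels = c("pos", "neg"))
  for (t in seq_len(T)) {
    bag <- sample(unlabeled, np, replace = TRUE)
    oob <- setdiff(unlabeled, bag)
    if (length(oob) == 0L) next
    train <- rbind(z[positives, , drop = FALSE], z[bag, , drop = FALSE])
    fit <- e1071::svm(train, y, kernel = "linear", cost = cost,
                      scale = FALSE, type = "C-classification")
    dv_train <- attr(stats::predict(fit, train, decision.values = TRUE),
                     "decision.values")[, 1]
    flip <- if (mean(dv_train[seq_len(np)]) < 0) -1 else 1
    dv <- attr(stats::predict(fit, z[oob, , drop = FALSE],
                              decision.values = TRUE), "decision.values")[, 1]
    sum_scores[oob] <- sum_scores[oob] + flip * dv
    n_oob[oob] <- n_oob[oob] + 1L
  }
  unscored <- names(n_oob)[n_oob == 0L]
  if (length(unscored))
    warning("receptors never out-of-bag after ", T, " iterations: ",
            paste(unscored, collapse = ", "))
  scores <- ifelse(n_oob > 0L, sum_scores / n_oob, NA_real_)
  structure(list(scores = scores, n_oob = n_oob, unscored = unscored, T = T),
            class = "oob_scores")
}

#' @export
print.oob_scores <- function(x, ...) {
  cat(sprintf("PU bagging OOB scores: %d receptors over %d iterations (%d unscored)\n",
              length(x$scores), x$T, length(x$unscored)))
  invisible(x)
}

#' Select the "other" class from OOB scores
#'
#' The `K` scored receptors with the lowest mean OOB decision values (ties
#' broken by receptor id) become the negative, "other", class — sized to
#' keep the training set balanced against the positive lists.
#'
#' @param oob an `oob_scores` object.
#' @param K how many receptors to retain (default 50).
#' @return character vector of selected receptor ids.
#' @export
select_other <- function(oob, K = 50) {
  if (K == 0) return(character(0))
  scored <- oob$scores[!is.na(oob$scores)]
  if (length(scored) < K) {
    warning("only ", length(scored), " scored receptors; returning all")
    K <- length(scored)
  }
  ord <- order(scored, names(scored))
  sort(names(scored)[ord[seq_len(K)]])
}

#' Assemble the three-class label set
#'
#' @param metabolic,inflammatory,other disjoint receptor id sets.
#' @param catalog full receptor catalog; members in none of the three sets
#'   are labeled `"unlabeled"`.
#' @return a `label_set`: list with `labels` (named character vector over
#'   the catalog), `provenance`, and `counts`.
#' @export
assemble_labels <- function(metabolic, inflammatory, other, catalog) {
  sets <- list(metabolic = metabolic, inflammatory = inflammatory, other = other)
  for (i in 1:2) for (j in (i + 1):3) {
    shared <- intersect(sets[[i]], sets[[j]])
    if (length(shared))
      stop("label sets not disjoint (", names(sets)[i], "/", names(sets)[j],
           "): ", paste(shared, collapse = ", "))
  }
  if (length(other) == 0L)
    warning("empty \"other\" set: emitting a two-class label set")
  labels <- stats::setNames(rep("unlabeled", length(catalog)), catalog)
  provenance <- stats::setNames(rep("held-out", length(catalog)), catalog)
  labels[intersect(metabolic, catalog)] <- "metabolic"
  provenance[intersect(metabolic, catalog)] <- "given-positive"
  labels[intersect(inflammatory, catalog)] <- "inflammatory"
  provenance[intersect(inflammatory, catalog)] <- "given-positive"
  labels[intersect(other, catalog)] <- "other"
  provenance[intersect(other, catalog)] <- "PU-selected"
  structure(list(labels = labels, provenance = provenance,
                 counts = table(factor(labels, levels = c("metabolic",
                                                          "inflammatory",
                                                          "other",
                                                          "unlabeled")))),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat("receptor labels:\n")
  print(x$counts)
  invisible(x)
}

#' Derive labels end to end (PU step included)
#'
#' Convenience wrapper: assembles the positive lists, runs PU bagging with
#' the metabolic receptors as positives against the unlabeled pool
#' (inflammatory receptors excluded from that pool), selects the bottom-`K`
#' scored receptors as "other", and returns the combined label set.
#'
#' @inheritParams assemble_positive_lists
#' @inheritParams pu_bagging
#' @inheritParams select_other
#' @return list: `labels` (a `label_set`), `oob` (the score table),
#'   `positive_lists`.
#' @export
derive_labels <- function(features, metabolic, inflammatory,
                          exclusion = character(0), catalog, T = 100, K = 50,
                          cost = 1, seed = 1L) {
  x <- if (inherits(features, "feature_matrix")) features$features else features
  catalog <- intersect(catalog, rownames(x))
  pos <- assemble_positive_lists(metabolic, inflammatory, exclusion, catalog)
  unlabeled <- setdiff(catalog, c(pos$metabolic, pos$inflammatory))
  oob <- pu_bagging(features, pos$metabolic, unlabeled, T = T, cost = cost,
                    seed = seed)
  other <- select_other(oob, K)
  labels <- assemble_labels(pos$metabolic, pos$inflammatory, other, catalog)
  list(labels = labels, oob = oob, positive_lists = pos)
}
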
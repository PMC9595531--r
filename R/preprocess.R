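#' Remove samples by death-circumstance (Hardy) code
#'
#' GTEx-style donor screening: samples whose DTHHRDY code falls in
#' `excluded_codes` are dropped from both the matrix and the metadata.
#' Code 4 (slow death after long illness) is excluded by default so that the
#' cohort reflects reasonably healthy donors at the time of death.
#'
#' @param expr an [expression_matrix()].
#' @param meta sample metadata with `sample_id` and `hardy_code` columns.
#' @param excluded_codes integer codes to remove (default 4).
#' @return list with filtered `expr` and `meta`; sample order preserved.
#' @export
filter_samples_by_death <- function(expr, meta, excluded_codes = 4L) {
  validate_metadata(meta)
  missing <- setdiff(colnames(expr), meta$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "))
  meta <- meta[match(colnames(expr), meta$sample_id), , drop = FALSE]
  keep <- !(meta$hardy_code %in% excluded_codes)
  if (!any(keep))
    stop("no samples remain after excluding hardy codes ",
         paste(excluded_codes, collapse = ", "))
  list(expr = subset_expr(expr, j = keep),
       meta = meta[keep, , drop = FALSE])
}

#' Filter genes on TPM abundance
#'
#' Keeps a gene iff it reaches `min_tpm` in at least `min_fraction` of
#' samples (boundaries inclusive), has nonzero variance, and no missing
#' values.
#'
#' @param expr an [expression_matrix()] at stage `"tpm"`.
#' @param min_tpm abundance threshold (default 0.1 TPM).
#' @param min_fraction fraction of samples required at or above `min_tpm`
#'   (default 0.8).
#' @return the filtered matrix, still at stage `"tpm"`.
#' @export
filter_genes <- function(expr, min_tpm = 0.1, min_fraction = 0.8) {
  require_stage(expr, "tpm", "filter_genes")
  v <- unclass_matrix(expr)
  frac <- rowMeans(v >= min_tpm, na.rm = TRUE)
  no_na <- !apply(is.na(v), 1, any)
  vars <- apply(v, 1, stats::var)
  keep <- frac >= min_fraction & no_na & !is.na(vars) & vars > 0
  subset_expr(expr, i = keep)
}

#' Log2-transform TPM values
#'
#' @param expr an [expression_matrix()] at stage `"tpm"`.
#' @param pseudocount added before the log (default 1).
#' @return matrix at stage `"log2"` with values `log2(x + pseudocount)`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  require_stage(expr, "tpm", "log2_transform")
  v <- unclass_matrix(expr)
  if (any(v < 0, na.rm = TRUE)) stop("negative values: not a TPM matrix")
  if (any(v + pseudocount <= 0, na.rm = TRUE))
    stop("pseudocount too small: log2 of a non-positive value")
  set_stage(expr, log2(v + pseudocount), "log2")
}

#' Quantile-normalize samples
#'
#' Forces every sample's value distribution onto the across-sample mean of
#' sorted values. Ties within a sample receive the mean of the reference
#' values at their tied ranks, so within-sample rank order is preserved.
#'
#' @param expr an [expression_matrix()] at stage `"log2"`.
#' @return matrix at stage `"qnorm"`.
#' @export
quantile_normalize <- function(expr) {
  require_stage(expr, "log2", "quantile_normalize")
  v <- unclass_matrix(expr)
  if (anyNA(v)) stop("missing values: filter genes before normalizing")
  if (ncol(v) == 1L) return(set_stage(expr, v, "qnorm"))
  sorted <- apply(v, 2, sort)
  reference <- rowMeans(sorted)
  out <- apply(v, 2, function(col) {
    rk <- rank(col, ties.method = "average")
    # fractional (tied) ranks get the mean of the reference at the tied slots
    lo <- floor(rk); hi <- ceiling(rk)
    (reference[lo] + reference[hi]) / 2
  })
  dimnames(out) <- dimnames(v)
  set_stage(expr, out, "qnorm")
}

#' Remove outlier samples with an isolation forest
#'
#' Samples are projected onto their top principal components and scored by
#' an isolation forest; the highest-scoring `contamination` fraction is
#' removed. Anomalous samples need fewer random splits to isolate, giving
#' shorter average tree path lengths and anomaly scores near 1.
#'
#' @param expr an [expression_matrix()] (any stage past TPM; typically
#'   quantile-normalized).
#' @param contamination fraction of samples to flag, in \[0, 0.5).
#' @param seed integer seed for tree construction.
#' @param n_components principal components used as the feature space.
#' @param n_trees trees in the forest.
#' @return list with `expr` (outliers removed), `removed` (sample ids) and
#'   `scores` (named anomaly scores in \[0,1\]).
#' @export
remove_outlier_samples <- function(expr, contamination = 0.05, seed = 1L,
                                   n_components = 20, n_trees = 200) {
  if (ncol(expr) < 10) stop("need at least 10 samples for outlier screening")
  if (contamination >= 0.5) stop("`contamination` must be < 0.5")
  v <- unclass_matrix(expr)
  if (contamination <= 0)
    return(list(expr = expr, removed = character(0),
                scores = stats::setNames(rep(0, ncol(v)), colnames(v))))
  k <- min(n_components, ncol(v) - 1L, nrow(v))
  pcs <- stats::prcomp(t(v), center = TRUE, scale. = FALSE, rank. = k)$x
  scores <- isolation_forest_scores(pcs, n_trees = n_trees, seed = seed)
  names(scores) <- colnames(v)
  n_remove <- floor(contamination * ncol(v))
  if (n_remove == 0)
    return(list(expr = expr, removed = character(0), scores = scores))
  ord <- order(scores, decreasing = TRUE)
  removed <- colnames(v)[sort(ord[seq_len(n_remove)])]
  list(expr = subset_expr(expr, j = setdiff(colnames(v), removed)),
       removed = removed, scores = scores)
}

#' Residualize expression on known confounders
#'
#' Per gene, ordinary least squares of expression on a shared design built
#' from the named metadata columns (categoricals one-hot with first level
#' dropped, age bracket and ischemic time numeric), always with an
#' intercept. Residuals `Exp - fitted` replace the expression values.
#'
#' @param expr an [expression_matrix()].
#' @param meta sample metadata aligned to the matrix columns.
#' @param confounders metadata column names to adjust for; empty vector fits
#'   an intercept-only model (per-gene mean-centering).
#' @return list with `residuals` (stage `"residual"`) and `model` (list:
#'   `coefficients` gene x design matrix, `design`).
#' @export
residualize <- function(expr, meta,
                        confounders = c("batch", "ischemic_time", "sex",
                                        "age_bracket", "hardy_code")) {
  v <- unclass_matrix(expr)
  meta <- meta[match(colnames(v), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata does not cover all samples")
  missing <- setdiff(confounders, names(meta))
  if (length(missing))
    stop("confounders absent from metadata: ", paste(missing, collapse = ", "))
  design <- build_design(meta, confounders)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient confounder design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(design, t(v))
  resid <- t(fit$residuals)
  dimnames(resid) <- dimnames(v)
  coefs <- t(fit$coefficients)
  rownames(coefs) <- rownames(v)
  list(residuals = set_stage(expr, resid, "residual"),
       model = list(coefficients = coefs, design = design))
}

build_design <- function(meta, confounders) {
  n <- nrow(meta)
  if (length(confounders) == 0L)
    return(matrix(1, n, 1, dimnames = list(meta$sample_id, "(Intercept)")))
  cols <- lapply(confounders, function(cn) {
    x <- meta[[cn]]
    # batch / sex / hardy code are one-hot (drop first); age bracket and
    # ischemic time enter as numbers
    if (cn %in% c("batch", "sex", "hardy_code") || !is.numeric(x)) {
      f <- factor(x)
      if (nlevels(f) < 2) {
        warning("confounder '", cn, "' is constant; dropped from the design")
        return(NULL)
      }
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cn, levels(f)[-1])
      mm
    } else {
      m <- matrix(as.numeric(x), ncol = 1, dimnames = list(NULL, cn))
      if (stats::var(m) == 0) {
        warning("confounder '", cn, "' is constant; dropped from the design")
        return(NULL)
      }
      m
    }
  })
  design <- do.call(cbind, c(list(`(Intercept)` = matrix(1, n, 1)), cols))
  colnames(design)[1] <- "(Intercept)"
  rownames(design) <- meta$sample_id
  design
}

#' Run the full preprocessing chain
#'
#' Death-code filter, TPM gene filter, log2 transform, quantile
#' normalization, isolation-forest outlier removal, confounder
#' residualization — in that order.
#'
#' @inheritParams filter_samples_by_death
#' @inheritParams filter_genes
#' @inheritParams remove_outlier_samples
#' @inheritParams residualize
#' @param pseudocount log2 pseudocount.
#' @return list: `residuals`, `meta` (aligned to retained samples),
#'   `removed_samples`, `model`, and per-stage gene/sample counts in
#'   `counts`.
#' @export
preprocess <- function(expr, meta, excluded_codes = 4L, min_tpm = 0.1,
                       min_fraction = 0.8, pseudocount = 1,
                       contamination = 0.05,
                       confounders = c("batch", "ischemic_time", "sex",
                                       "age_bracket", "hardy_code"),
                       seed = 1L) {
  s1 <- filter_samples_by_death(expr, meta, excluded_codes)
  e <- filter_genes(s1$expr, min_tpm, min_fraction)
  e <- log2_transform(e, pseudocount)
  e <- quantile_normalize(e)
  out <- remove_outlier_samples(e, contamination, seed = seed)
  meta2 <- s1$meta[match(colnames(out$expr), s1$meta$sample_id), , drop = FALSE]
  res <- residualize(out$expr, meta2, confounders)
  list(residuals = res$residuals, meta = meta2,
       removed_samples = out$removed, model = res$model,
       counts = c(samples_in = ncol(expr), samples_kept = ncol(out$expr),
                  genes_in = nrow(expr), genes_kept = nrow(e)))
}
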
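# Signed weighted co-expression network: robust correlation, soft
# thresholding, topological overlap, module detection and merging.

#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation: each gene is median-centered, scaled by
#' 9*MAD, and observations get Tukey biweight weights `(1 - u^2)^2` for
#' `|u| < 1` (zero beyond), so values far from the median contribute little.
#' Genes with MAD = 0 but positive variance fall back to Pearson weighting
#' for their pairs; constant genes get correlation 0 with a warning.
#'
#' @param expr genes x samples matrix (typically the residual matrix).
#' @return gene x gene correlation matrix, symmetric with unit diagonal.
#' @export
bicor_matrix <- function(expr) {
  v <- unclass_matrix(expr)
  if (ncol(v) < 4) stop("biweight midcorrelation needs at least 4 samples")
  if (anyNA(v)) stop("missing values in expression matrix")
  med <- apply(v, 1, stats::median)
  centered <- v - med
  mad_ <- apply(abs(centered), 1, stats::median)
  u <- centered / (9 * mad_)
  w <- (1 - u^2)^2 * (abs(u) < 1)
  xt <- centered * w
  # MAD = 0: Pearson fallback per gene; constant genes become zero vectors
  flat <- which(mad_ == 0)
  if (length(flat)) {
    vf <- v[flat, , drop = FALSE]
    xt[flat, ] <- vf - rowMeans(vf)
  }
  norms <- sqrt(rowSums(xt^2))
  zero <- norms == 0
  if (any(zero)) {
    warning("constant genes given correlation 0: ",
            paste(rownames(v)[zero], collapse = ", "))
    norms[zero] <- 1
  }
  cmat <- tcrossprod(xt / norms)
  cmat[cmat > 1] <- 1
  cmat[cmat < -1] <- -1
  diag(cmat) <- 1
  cmat
}

#' Signed adjacency from a correlation matrix
#'
#' `a_ij = (0.5 * (1 + cor_ij))^beta`: negatively correlated pairs get
#' near-zero connection strength, so modules contain only positively
#' correlated genes.
#'
#' @param cor_mat gene x gene correlation matrix.
#' @param beta soft-thresholding power (> 0).
#' @return adjacency matrix in \[0,1\] with unit diagonal and a `beta`
#'   attribute.
#' @export
signed_adjacency <- function(cor_mat, beta) {
  if (length(beta) != 1L || beta <= 0) stop("`beta` must be a positive scalar")
  adj <- (0.5 * (1 + cor_mat))^beta
  diag(adj) <- 1
  attr(adj, "beta") <- beta
  adj
}

#' Choose the soft-thresholding power by scale-free fit
#'
#' For each candidate power, builds the signed adjacency, computes the
#' connectivities `k_i = sum_{j != i} a_ij`, bins `log10(k)` and regresses
#' log10 bin frequency on log10 mean bin connectivity. The signed fit index
#' is `-sign(slope) * R^2` (scale-free topology implies a negative slope).
#' Returns the smallest power reaching `target_r2`; if none does, the
#' `fallback_power` (default 14) is used.
#'
#' @param cor_mat gene x gene correlation matrix.
#' @param candidate_powers powers to scan.
#' @param target_r2 required signed R^2 (default 0.8).
#' @param fallback_power power used when no candidate reaches the target.
#' @param n_bins connectivity histogram bins.
#' @return list: `beta` (chosen power), `reached_target` (logical), and
#'   `diagnostics` (data.frame power, signed_r2, slope, mean_k).
#' @export
pick_power <- function(cor_mat, candidate_powers = 1:20, target_r2 = 0.8,
                       fallback_power = 14, n_bins = 10) {
  stopifnot(length(candidate_powers) >= 1)
  diag_rows <- lapply(candidate_powers, function(b) {
    adj <- signed_adjacency(cor_mat, b)
    k <- rowSums(adj) - 1
    if (max(k) - min(k) < .Machine$double.eps^0.5)
      stop("degenerate connectivities: all genes equally connected")
    fit <- scale_free_fit(k, n_bins)
    data.frame(power = b, signed_r2 = fit$signed_r2, slope = fit$slope,
               mean_k = mean(k))
  })
  diagnostics <- do.call(rbind, diag_rows)
  if (length(candidate_powers) == 1L)
    return(list(beta = candidate_powers, reached_target = NA,
                diagnostics = diagnostics))
  hit <- which(diagnostics$signed_r2 >= target_r2)
  if (length(hit)) {
    list(beta = diagnostics$power[hit[1]], reached_target = TRUE,
         diagnostics = diagnostics)
  } else {
    list(beta = fallback_power, reached_target = FALSE,
         diagnostics = diagnostics)
  }
}

scale_free_fit <- function(k, n_bins = 10) {
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, breaks, include.lowest = TRUE)
  counts <- tapply(k, bin, length)
  means <- tapply(k, bin, mean)
  ok <- !is.na(counts) & counts > 0 & means > 0
  x <- log10(means[ok]); y <- log10(counts[ok])
  if (length(x) < 3) return(list(signed_r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[["x"]]
  list(signed_r2 = -sign(slope) * r2, slope = slope)
}

#' Topological overlap similarity
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`. High
#' overlap means two genes share network neighbors as well as a direct
#' connection.
#'
#' @param adj adjacency from [signed_adjacency()].
#' @return list: `tom` similarity matrix and `diss = 1 - tom`.
#' @export
tom_similarity <- function(adj) {
  a <- adj
  diag(a) <- 1
  k <- rowSums(a) - 1
  shared <- a %*% a
  # strip the u = i and u = j terms (diagonal is 1): (A^2)_ij - 2 a_ij
  numer <- shared - 2 * a + a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- numer / denom
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adj)
  list(tom = tom, diss = 1 - tom)
}

#' Detect modules by hierarchical clustering of TOM dissimilarity
#'
#' Average-linkage clustering of `1 - TOM`, cut at a static height as a
#' deterministic stand-in for dynamic tree cutting. The default cut
#' (`"gap"`) is placed at the midpoint of the widest gap among the upper
#' merge heights: tight modules assemble low in the tree while
#' module-joining and stray-gene merges sit high, so the widest gap
#' separates the two regimes whether or not unclustered background genes
#' are present. `"quantile"` cuts at `cut_height_quantile` of the merge
#' heights instead. Clusters smaller than `min_module_size` get the
#' unassigned label 0; the rest are relabeled 1..M by decreasing size (ties
#' by smallest gene id).
#'
#' @param diss_tom gene x gene dissimilarity matrix.
#' @param min_module_size smallest cluster kept as a module (default 30).
#' @param cut_method `"gap"` (default) or `"quantile"`.
#' @param cut_height_quantile quantile of merge heights for
#'   `cut_method = "quantile"`.
#' @return a `module_partition`: list with `labels` (named integer vector,
#'   0 = unassigned), `sizes`, `dendrogram`, `cut_height`.
#' @export
detect_modules <- function(diss_tom, min_module_size = 30,
                           cut_method = c("gap", "quantile"),
                           cut_height_quantile = 0.8) {
  cut_method <- match.arg(cut_method)
  stopifnot(is.matrix(diss_tom), nrow(diss_tom) == ncol(diss_tom))
  hc <- stats::hclust(stats::as.dist(diss_tom), method = "average")
  h <- sort(hc$height)
  cut_height <- if (cut_method == "quantile" || length(h) < 3) {
    stats::quantile(h, cut_height_quantile, names = FALSE)
  } else {
    upper <- h[h >= stats::median(h)]
    gaps <- diff(upper)
    i <- which.max(gaps)
    (upper[i] + upper[i + 1]) / 2
  }
  raw <- stats::cutree(hc, h = cut_height)
  labels <- relabel_modules(raw, rownames(diss_tom), min_module_size)
  if (all(labels == 0L))
    warning("no cluster reached min_module_size; empty partition")
  module_partition(labels, dendrogram = hc, cut_height = cut_height)
}

## drop small clusters to 0 and relabel survivors 1..M by size (ties by
## smallest member gene id, lexicographic)
relabel_modules <- function(raw, gene_ids, min_module_size) {
  names(raw) <- gene_ids
  tab <- table(raw)
  keep <- names(tab)[tab >= min_module_size]
  first_gene <- vapply(keep, function(cl) min(gene_ids[raw == cl]), character(1))
  ord <- keep[order(-tab[keep], first_gene)]
  labels <- stats::setNames(rep(0L, length(raw)), gene_ids)
  for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  labels
}

module_partition <- function(labels, dendrogram = NULL, cut_height = NA_real_) {
  structure(list(labels = labels,
                 sizes = table(labels[labels > 0L]),
                 dendrogram = dendrogram,
                 cut_height = cut_height),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module partition: %d modules, %d genes assigned, %d unassigned\n",
              length(x$sizes), sum(x$labels > 0L), sum(x$labels == 0L)))
  invisible(x)
}

#' Module eigengenes
#'
#' Per module, gene profiles are standardized across samples and the first
#' right singular vector is taken as the eigengene (unit norm), oriented so
#' the mean correlation with member genes is nonnegative. The explained
#' variance fraction `d1^2 / sum(d^2)` is reported.
#'
#' @param expr genes x samples matrix.
#' @param partition a `module_partition`.
#' @return list: `eigengenes` (module x sample matrix, rows `ME1..MEm`) and
#'   `var_explained` (named numeric).
#' @export
compute_eigengenes <- function(expr, partition) {
  v <- unclass_matrix(expr)
  labels <- partition$labels[rownames(v)]
  mods <- sort(unique(labels[labels > 0L]))
  if (length(mods) == 0L) stop("partition has no assigned modules")
  eig <- matrix(NA_real_, length(mods), ncol(v),
                dimnames = list(paste0("ME", mods), colnames(v)))
  ve <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    if (length(genes) == 1L) {
      warning("module ", mods[i], " has a single gene; eigengene = its profile")
      x <- as.numeric(scale(v[genes, ]))
      eig[i, ] <- x / sqrt(sum(x^2))
      ve[i] <- 1
      next
    }
    xs <- t(scale(t(v[genes, , drop = FALSE])))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (mean(stats::cor(t(v[genes, , drop = FALSE]), e)) < 0) e <- -e
    eig[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = eig, var_explained = ve)
}

#' Module membership (kME)
#'
#' Correlation of every gene's profile with every module eigengene;
#' cross-module entries are kept because they feed the classifier features.
#'
#' @param expr genes x samples matrix.
#' @param eig result of [compute_eigengenes()] (or a module x sample matrix).
#' @return gene x module matrix of correlations.
#' @export
compute_kme <- function(expr, eig) {
  v <- unclass_matrix(expr)
  e <- if (is.list(eig)) eig$eigengenes else eig
  if (!identical(colnames(v), colnames(e)))
    stop("expression and eigengene matrices cover different samples")
  sds <- apply(v, 1, stats::sd)
  zero <- sds == 0
  kme <- matrix(0, nrow(v), nrow(e), dimnames = list(rownames(v), rownames(e)))
  if (any(!zero))
    kme[!zero, ] <- stats::cor(t(v[!zero, , drop = FALSE]), t(e))
  if (any(zero))
    warning("zero-variance genes get kME 0: ",
            paste(rownames(v)[zero], collapse = ", "))
  kme
}

#' Merge modules with correlated eigengenes
#'
#' Modules whose eigengenes cluster below `merge_height` on dissimilarity
#' `1 - cor` (average linkage) are unioned; eigengenes are recomputed and
#' the procedure iterates to a fixed point. The default 0.25 corresponds to
#' an eigengene correlation of 0.75.
#'
#' @param expr genes x samples matrix (for eigengene recomputation).
#' @param partition a `module_partition`.
#' @param merge_height dissimilarity threshold (default 0.25).
#' @param max_iter safety bound on merge rounds.
#' @return list: `partition` (merged, relabeled by size) and `eigengenes`
#'   (recomputed, with `var_explained`).
#' @export
merge_modules <- function(expr, partition, merge_height = 0.25, max_iter = 20) {
  labels <- partition$labels
  if (!any(labels > 0L)) stop("partition has no assigned modules")
  v <- unclass_matrix(expr)
  for (iter in seq_len(max_iter)) {
    eig <- compute_eigengenes(v, module_partition(labels))
    m <- nrow(eig$eigengenes)
    if (m < 2L) break
    diss <- 1 - stats::cor(t(eig$eigengenes))
    if (min(diss[upper.tri(diss)]) >= merge_height) break
    hc <- stats::hclust(stats::as.dist(diss), method = "average")
    groups <- stats::cutree(hc, h = merge_height)
    mod_ids <- as.integer(sub("^ME", "", rownames(eig$eigengenes)))
    new <- labels
    for (g in unique(groups)) {
      members <- mod_ids[groups == g]
      new[labels %in% members] <- min(members)
    }
    # relabel 1..M by size, ties by smallest gene id
    assigned <- new > 0L
    relab <- relabel_modules(new[assigned], names(new)[assigned],
                             min_module_size = 1L)
    labels[assigned] <- relab
    labels[!assigned] <- 0L
  }
  eig <- compute_eigengenes(v, module_partition(labels))
  list(partition = module_partition(labels,
                                    dendrogram = partition$dendrogram,
                                    cut_height = partition$cut_height),
       eigengenes = eig)
}

#' Build the co-expression network end to end
#'
#' Biweight midcorrelation, soft-thresholding power selection (or a fixed
#' power), signed adjacency, TOM, module detection, merging, eigengenes and
#' kME in one call.
#'
#' @param expr genes x samples residual matrix.
#' @param power `"auto"` to select by scale-free fit, or a fixed number.
#' @param min_module_size,cut_method,cut_height_quantile see
#'   [detect_modules()].
#' @param merge_height see [merge_modules()].
#' @return list: `partition`, `eigengenes`, `kme`, `power`,
#'   `power_diagnostics`.
#' @export
build_network <- function(expr, power = "auto", min_module_size = 30,
                          cut_method = "gap", cut_height_quantile = 0.8,
                          merge_height = 0.25) {
  cmat <- bicor_matrix(expr)
  if (identical(power, "auto")) {
    sel <- pick_power(cmat)
    beta <- sel$beta
    diagnostics <- sel$diagnostics
  } else {
    beta <- as.numeric(power)
    diagnostics <- NULL
  }
  adj <- signed_adjacency(cmat, beta)
  tom <- tom_similarity(adj)
  part <- detect_modules(tom$diss, min_module_size, cut_method,
                         cut_height_quantile)
  merged <- merge_modules(expr, part, merge_height)
  kme <- compute_kme(expr, merged$eigengenes)
  list(partition = merged$partition, eigengenes = merged$eigengenes,
       kme = kme, power = beta, power_diagnostics = diagnostics)
}
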
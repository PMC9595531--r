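# Per-receptor feature assembly: the receptor's module pathway scores, that
# module's eigengene correlations with every module, and the receptor's kME
# to every module.

#' Pairwise eigengene correlation matrix
#'
#' @param eig result of [compute_eigengenes()] (or a module x sample
#'   matrix).
#' @return module x module Pearson correlation matrix, symmetric with unit
#'   diagonal.
#' @export
eigengene_correlation_matrix <- function(eig) {
  e <- if (is.list(eig)) eig$eigengenes else eig
  if (nrow(e) < 2L)
    warning("single module: eigengene correlation matrix is 1 x 1")
  cc <- stats::cor(t(e))
  dimnames(cc) <- list(rownames(e), rownames(e))
  cc
}

#' Build the receptor feature matrix
#'
#' Receptor `r` assigned to module `m` receives the concatenation of (1)
#' module `m`'s full pathway score vector (missing where the pathway has no
#' overlap with the module), (2) row `m` of the eigengene correlation
#' matrix, and (3) the receptor's own kME to every module. Receptors that
#' are unassigned (module 0) or absent from the partition are excluded and
#' listed in the drop report.
#'
#' @param catalog character vector of receptor gene ids.
#' @param partition a `module_partition`.
#' @param enrichment long table from [enrich_modules()].
#' @param eig_cor matrix from [eigengene_correlation_matrix()].
#' @param kme matrix from [compute_kme()].
#' @return a `feature_matrix`: list with `features` (receptor x feature
#'   matrix), `module` (named receptor-to-module map), `dropped`
#'   (data.frame receptor, reason), and `schema` (column names).
#' @export
build_feature_matrix <- function(catalog, partition, enrichment, eig_cor, kme) {
  labels <- partition$labels
  status <- ifelse(!(catalog %in% names(labels)), "absent",
                   ifelse(labels[catalog] == 0L, "unassigned", "ok"))
  dropped <- data.frame(receptor = catalog[status != "ok"],
                        reason = status[status != "ok"],
                        stringsAsFactors = FALSE)
  kept <- catalog[status == "ok"]
  if (length(kept) == 0L) stop("no receptor falls inside an assigned module")
  rec_module <- labels[kept]

  pathways <- unique(enrichment$pathway)
  mods <- sort(unique(enrichment$module))
  score_by_module <- matrix(NA_real_, length(mods), length(pathways),
                            dimnames = list(paste0("ME", mods), pathways))
  idx <- cbind(match(paste0("ME", enrichment$module), rownames(score_by_module)),
               match(enrichment$pathway, pathways))
  score_by_module[idx] <- enrichment$score

  me_names <- rownames(eig_cor)
  cols <- c(paste0("pathway.", pathways),
            paste0("MEcor.", me_names),
            paste0("kME.", me_names))
  features <- matrix(NA_real_, length(kept), length(cols),
                     dimnames = list(kept, cols))
  for (i in seq_along(kept)) {
    me <- paste0("ME", rec_module[i])
    features[i, ] <- c(score_by_module[me, ],
                       eig_cor[me, me_names],
                       kme[kept[i], me_names])
  }
  structure(list(features = features,
                 module = rec_module,
                 dropped = dropped,
                 schema = cols),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature matrix: %d receptors x %d features (%d dropped), %.1f%% missing\n",
              nrow(x$features), ncol(x$features), nrow(x$dropped),
              100 * mean(is.na(x$features))))
  invisible(x)
}
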
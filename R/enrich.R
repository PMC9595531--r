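# Hypergeometric pathway enrichment of modules, BH correction, and the
# -log2 score transform used as classifier features.

#' Hypergeometric enrichment of one module
#'
#' Upper-tail hypergeometric test `P(X >= k)` of the overlap between the
#' module and each gene set, with `N = |universe|`,
#' `K = |pathway intersect universe|`, `n = |module|`, `k = |overlap|`.
#' Pathways with zero overlap are emitted with `p = 1` and a missing score:
#' they become missing features downstream, not zeros.
#'
#' @param module_genes character vector of the module's genes.
#' @param genesets a `gene_set_collection`.
#' @param universe all analyzed genes (the expressed background).
#' @param module_id optional label recorded in the table.
#' @return an enrichment data.frame: module, pathway, category, overlap,
#'   module_size, pathway_size, universe_size, p_value, p_adjusted, score.
#' @export
hypergeom_enrich <- function(module_genes, genesets, universe,
                             module_id = NA) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  module_genes <- unique(module_genes)
  if (!all(module_genes %in% universe))
    stop("module genes outside the universe: ",
         paste(utils::head(setdiff(module_genes, universe), 5), collapse = ", "))
  N <- length(universe)
  n <- length(module_genes)
  rows <- lapply(names(genesets$sets), function(pw) {
    set_in_universe <- intersect(genesets$sets[[pw]], universe)
    K <- length(set_in_universe)
    k <- length(intersect(set_in_universe, module_genes))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(module = module_id, pathway = pw,
               category = unname(genesets$categories[[pw]]),
               overlap = k, module_size = n, pathway_size = K,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_adjusted <- bh_adjust(tab$p_value)
  tab$score <- ifelse(tab$overlap > 0, score_transform(tab$p_adjusted), NA_real_)
  tab
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control: delegates to [stats::p.adjust()] with
#' `method = "BH"` after validating the input range.
#'
#' @param p_values numeric vector in \[0,1\].
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Transform adjusted p-values to enrichment scores
#'
#' `score = -log2(p_adjusted)`, with the input floored at 1e-300 so the
#' transform stays finite. Missing inputs propagate to missing scores.
#'
#' @param p_adjusted adjusted p-values in (0, 1\].
#' @return scores, strictly decreasing in `p_adjusted`.
#' @export
score_transform <- function(p_adjusted) {
  -log2(pmax(p_adjusted, 1e-300))
}

#' Enrich every module of a partition
#'
#' @param partition a `module_partition`.
#' @param genesets a `gene_set_collection`.
#' @param universe analyzed gene ids; defaults to all genes in the
#'   partition.
#' @return long-format enrichment table over all modules (label > 0).
#' @export
enrich_modules <- function(partition, genesets, universe = NULL) {
  labels <- partition$labels
  if (is.null(universe)) universe <- names(labels)
  mods <- sort(unique(labels[labels > 0L]))
  tabs <- lapply(mods, function(m) {
    hypergeom_enrich(names(labels)[labels == m], genesets, universe,
                     module_id = m)
  })
  do.call(rbind, tabs)
}

#' Module x pathway score matrix for significant pathways
#'
#' The numeric backing of the enrichment heatmap: keeps pathways reaching
#' `p_adjusted <= significance_cutoff` in at least one module and returns
#' their score matrix (missing where a pathway has no overlap with a
#' module).
#'
#' @param enrichment long table from [enrich_modules()].
#' @param significance_cutoff adjusted-p threshold (default 0.01).
#' @return list: `scores` (module x pathway matrix) and `categories`
#'   (named character vector for the retained pathways).
#' @export
heatmap_matrix <- function(enrichment, significance_cutoff = 0.01) {
  sig <- tapply(enrichment$p_adjusted <= significance_cutoff,
                enrichment$pathway, any)
  keep <- names(sig)[sig]
  if (length(keep) == 0L) {
    warning("no pathway significant at cutoff ", significance_cutoff)
    return(list(scores = matrix(numeric(0), 0, 0), categories = character(0)))
  }
  sub <- enrichment[enrichment$pathway %in% keep, ]
  mods <- sort(unique(sub$module))
  # preserve the collection's pathway order
  keep <- unique(enrichment$pathway)[unique(enrichment$pathway) %in% keep]
  scores <- matrix(NA_real_, length(mods), length(keep),
                   dimnames = list(paste0("ME", mods), keep))
  for (i in seq_len(nrow(sub)))
    scores[paste0("ME", sub$module[i]), sub$pathway[i]] <- sub$score[i]
  cats <- sub$category[match(keep, sub$pathway)]
  list(scores = scores, categories = stats::setNames(cats, keep))
}
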
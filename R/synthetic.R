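#' Configuration for the synthetic expression generator
#'
#' The generator emulates the statistical structure the pipeline assumes in a
#' bulk TPM matrix: planted co-expression modules driven by latent sample
#' factors, linear confounder effects (batch, sex, age bracket, ischemic
#' time, death-circumstance code), globally shifted outlier samples, pathway
#' gene sets concentrated in specific modules, receptor genes with planted
#' metabolic / inflammatory / other identities, and low-expression decoy
#' genes that the 0.1-TPM/80% filter must remove.
#'
#' @param n_samples number of samples.
#' @param n_modules number of planted modules (>= 3; modules are assigned to
#'   the three receptor classes cyclically).
#' @param genes_per_module genes in each planted module.
#' @param n_background_genes unstructured noise genes.
#' @param within_module_cor target pairwise correlation of genes sharing a
#'   module, in (0,1).
#' @param factor_cor correlation planted between module latent factors, in
#'   \[0, 1); real module eigengenes are correlated (which is why merging at
#'   0.25 exists), so 0 would make the module-correlation features an
#'   unrealistically clean module encoding. Must stay below the merge
#'   threshold's correlation (0.75) to keep modules distinct.
#' @param n_pathways number of gene sets to emit.
#' @param pathway_module_affinity fraction of a pathway's genes drawn from
#'   its assigned module.
#' @param pathway_size genes per pathway.
#' @param n_receptors_per_class planted receptors per class.
#' @param confounder_effect_size standard deviation (in log2 units) of the
#'   per-gene confounder coefficients; 0 disables confounding.
#' @param outlier_fraction fraction of samples given a global shift, in
#'   \[0, 0.5).
#' @param low_expression_fraction decoy genes added as a fraction of the
#'   structured genes; their baseline sits below the TPM filter.
#' @param held_out_fraction fraction of receptors per class withheld from the
#'   label lists (they stay in the catalog as unlabeled, with a ground-truth
#'   class for prediction checks).
#' @param seed integer seed; identical configs give byte-identical output.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 200,
                             n_modules = 8,
                             genes_per_module = 200,
                             n_background_genes = 400,
                             within_module_cor = 0.6,
                             factor_cor = 0.3,
                             n_pathways = 40,
                             pathway_module_affinity = 0.8,
                             pathway_size = 30,
                             n_receptors_per_class = 50,
                             confounder_effect_size = 0.5,
                             outlier_fraction = 0.05,
                             low_expression_fraction = 0.1,
                             held_out_fraction = 0.5,
                             seed = 1L) {
  cfg <- list(n_samples = n_samples, n_modules = n_modules,
              genes_per_module = genes_per_module,
              n_background_genes = n_background_genes,
              within_module_cor = within_module_cor,
              factor_cor = factor_cor,
              n_pathways = n_pathways,
              pathway_module_affinity = pathway_module_affinity,
              pathway_size = pathway_size,
              n_receptors_per_class = n_receptors_per_class,
              confounder_effect_size = confounder_effect_size,
              outlier_fraction = outlier_fraction,
              low_expression_fraction = low_expression_fraction,
              held_out_fraction = held_out_fraction,
              seed = as.integer(seed))
  counts <- c("n_samples", "n_modules", "genes_per_module", "n_background_genes",
              "n_pathways", "pathway_size", "n_receptors_per_class")
  for (f in counts)
    if (length(cfg[[f]]) != 1L || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]]))
      stop("`", f, "` must be a positive integer")
  if (within_module_cor <= 0 || within_module_cor >= 1)
    stop("`within_module_cor` must lie in (0, 1)")
  if (factor_cor < 0 || factor_cor >= 0.75)
    stop("`factor_cor` must lie in [0, 0.75) to keep modules unmergeable")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("`outlier_fraction` must lie in [0, 0.5)")
  if (pathway_module_affinity < 0 || pathway_module_affinity > 1)
    stop("`pathway_module_affinity` must lie in [0, 1]")
  if (n_modules < 3)
    stop("`n_modules` must be >= 3 so each receptor class owns a module")
  per_class_capacity <- floor(n_modules / 3) * genes_per_module
  if (n_receptors_per_class > per_class_capacity)
    stop(sprintf(paste0("sizing error: %d receptors per class requested but the ",
                        "class's modules hold only %d genes"),
                 n_receptors_per_class, per_class_capacity))
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic receptor-classification dataset
#'
#' Gene `i` planted in module `m` has log2 expression
#' `base_i + w * e_m + eps` with `w = sqrt(r)`, `sd(eps) = sqrt(1 - r)` and
#' `e_m` a standard-normal latent sample profile, so the expected pairwise
#' within-module correlation is `r = within_module_cor`. Confounders add
#' per-gene linear effects; outlier samples get a +4 log2 global shift;
#' values are exponentiated back to TPM scale.
#'
#' @param config a [synthetic_config()].
#' @return a `receptor_sim` list: `expr` (TPM [expression_matrix()]), `meta`
#'   (sample metadata), `genesets` (a `gene_set_collection`), `receptors`
#'   (catalog of receptor gene ids), `labels` (list with `metabolic`,
#'   `inflammatory`, `exclusion` character vectors), `truth` (planted ground
#'   truth), `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(config$seed)

  M <- config$n_modules
  n <- config$n_samples
  r <- config$within_module_cor
  n_mod_genes <- M * config$genes_per_module
  n_struct <- n_mod_genes + config$n_background_genes
  n_decoy <- round(config$low_expression_fraction * n_struct)
  n_genes <- n_struct + n_decoy

  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  sample_ids <- sprintf("S%04d", seq_len(n))

  module_of <- c(rep(seq_len(M), each = config$genes_per_module),
                 rep(0L, config$n_background_genes + n_decoy))
  names(module_of) <- gene_ids

  ## latent factors: one sample profile per module with pairwise
  ## correlation factor_cor (exchangeable), standardized to unit empirical
  ## variance so planted correlations are tight around the target
  raw <- matrix(stats::rnorm(M * n), M, n)
  if (config$factor_cor > 0) {
    sigma <- matrix(config$factor_cor, M, M)
    diag(sigma) <- 1
    raw <- crossprod(chol(sigma), raw)
  }
  factors <- t(scale(t(raw)))
  dimnames(factors) <- list(paste0("ME", seq_len(M)), sample_ids)

  ## variance budget per gene: signal r + confounders c^2 + noise = 1, so the
  ## planted within-module correlation stays ~r even with confounding on
  w <- sqrt(r)
  c2 <- max(0, min(config$confounder_effect_size^2, 1 - r - 0.04))
  noise_sd_mod <- sqrt(max(1 - r - c2, 0.04))
  noise_sd_bg <- sqrt(max(1 - c2, 0.04))
  z <- matrix(stats::rnorm(n_genes * n, sd = noise_sd_bg), n_genes, n,
              dimnames = list(gene_ids, sample_ids))
  idx_mod <- which(module_of > 0L)
  z[idx_mod, ] <- w * factors[module_of[idx_mod], , drop = FALSE] +
    matrix(stats::rnorm(length(idx_mod) * n, sd = noise_sd_mod),
           length(idx_mod), n)

  ## sample metadata
  meta <- data.frame(
    sample_id = sample_ids,
    batch = sample(c("B1", "B2", "B3"), n, replace = TRUE),
    ischemic_time = round(stats::rlnorm(n, meanlog = log(400), sdlog = 0.4)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_bracket = sample(seq(20, 70, by = 10), n, replace = TRUE),
    hardy_code = sample(0:4, n, replace = TRUE,
                        prob = c(0.25, 0.20, 0.25, 0.20, 0.10)),
    stringsAsFactors = FALSE
  )

  ## linear confounder effects on the log2 scale
  if (config$confounder_effect_size > 0) {
    design <- stats::model.matrix(
      ~ batch + sex + age_bracket + ischemic_time + hardy_code,
      data = transform(meta, batch = factor(batch), sex = factor(sex)))[, -1, drop = FALSE]
    design <- scale(design)
    # per-gene coefficients scaled so the total confounder variance is
    # ~confounder_effect_size^2 (in SD units of the log2 signal)
    coefs <- matrix(stats::rnorm(n_genes * ncol(design),
                                 sd = sqrt(c2 / ncol(design))),
                    n_genes, ncol(design))
    z <- z + coefs %*% t(design)
  }

  ## planted outlier samples: a global log2 shift (depth-like artifact) of
  ## random sign and magnitude 1.5-2.5, plus sample-specific noise, so each
  ## outlier is anomalous in its own way (as degraded samples are) rather
  ## than forming one tight collinear cluster
  outlier <- stats::setNames(rep(FALSE, n), sample_ids)
  n_out <- round(config$outlier_fraction * n)
  if (n_out > 0) {
    shifted <- sample(n, n_out)
    mag <- stats::runif(n_out, 1.5, 2.5) * sample(c(-1, 1), n_out, replace = TRUE)
    z[, shifted] <- sweep(z[, shifted, drop = FALSE], 2, mag, "+") +
      matrix(stats::rnorm(n_genes * n_out, sd = 0.7), n_genes, n_out)
    outlier[shifted] <- TRUE
  }

  ## per-gene baseline abundance; decoys sit below the 0.1-TPM filter
  base <- c(stats::runif(n_struct, 3, 8), rep(log2(0.02), n_decoy))
  tpm <- 2^(z + base)

  ## class layout: modules assigned to classes cyclically
  classes <- c("metabolic", "inflammatory", "other")
  class_of_module <- classes[((seq_len(M) - 1L) %% 3L) + 1L]

  ## pathways concentrate in their assigned module, with a graded share in
  ## the other modules of the same functional class (pathways of one theme
  ## recruit genes from several co-regulated modules, so a class pathway
  ## scores across all of the class's modules, highest in its own)
  pathway_module <- ((seq_len(config$n_pathways) - 1L) %% M) + 1L
  names(pathway_module) <- sprintf("PW%03d", seq_len(config$n_pathways))
  sets <- vector("list", config$n_pathways)
  names(sets) <- names(pathway_module)
  struct_ids <- gene_ids[seq_len(n_struct)]
  struct_mod <- module_of[seq_len(n_struct)]
  for (p in seq_len(config$n_pathways)) {
    m <- pathway_module[p]
    siblings <- setdiff(which(class_of_module == class_of_module[m]), m)
    n_in <- round(config$pathway_module_affinity * config$pathway_size)
    n_sib <- round(0.75 * (config$pathway_size - n_in))
    in_mod <- sample(gene_ids[module_of == m], min(n_in, config$genes_per_module))
    sib <- if (length(siblings) && n_sib > 0)
      sample(struct_ids[struct_mod %in% siblings], n_sib) else character(0)
    rest_pool <- setdiff(struct_ids[!(struct_mod %in% c(m, siblings))], sib)
    rest <- sample(rest_pool, config$pathway_size - length(in_mod) - length(sib))
    sets[[p]] <- c(in_mod, sib, rest)
  }
  categories <- stats::setNames(
    c(metabolic = "Metabolism", inflammatory = "Immune",
      other = "Cellular")[class_of_module[pathway_module]],
    names(pathway_module))
  genesets <- gene_set_collection(sets, categories)

  ## receptors: genes sampled from the class's modules, concentrated in the
  ## class's first module (receptors of one function co-cluster: roughly
  ## half of a class's receptors share a dominant module, the rest scatter
  ## over the class's remaining modules)
  receptor_class <- character(0)
  receptors <- character(0)
  for (cl in classes) {
    mods <- which(class_of_module == cl)
    wts <- 2^(-seq_along(mods))
    gene_wts <- wts[match(module_of, mods)]
    gene_wts[is.na(gene_wts)] <- 0
    picked <- sample(gene_ids, config$n_receptors_per_class, prob = gene_wts)
    receptors <- c(receptors, picked)
    receptor_class <- c(receptor_class,
                        stats::setNames(rep(cl, length(picked)), picked))
  }

  ## hold out a fraction per class as unlabeled
  held_out <- unlist(lapply(classes, function(cl) {
    members <- names(receptor_class)[receptor_class == cl]
    sample(members, floor(config$held_out_fraction * length(members)))
  }), use.names = FALSE)
  labeled <- setdiff(receptors, held_out)
  labels <- list(
    metabolic = intersect(labeled, names(receptor_class)[receptor_class == "metabolic"]),
    inflammatory = intersect(labeled, names(receptor_class)[receptor_class == "inflammatory"]),
    exclusion = character(0)
  )

  truth <- list(module = module_of,
                factors = factors,
                receptor_class = receptor_class,
                class_of_module = stats::setNames(class_of_module, paste0("ME", seq_len(M))),
                pathway_module = pathway_module,
                outlier = outlier,
                held_out = held_out)

  structure(list(expr = expression_matrix(tpm, "tpm"),
                 meta = meta,
                 genesets = genesets,
                 receptors = receptors,
                 labels = labels,
                 truth = truth,
                 config = config),
            class = "receptor_sim")
}

#' @export
print.receptor_sim <- function(x, ...) {
  cat(sprintf(paste0("synthetic receptor dataset: %d genes x %d samples, ",
                     "%d modules, %d pathways, %d receptors (%d labeled)\n"),
              nrow(x$expr), ncol(x$expr), x$config$n_modules,
              length(x$genesets$sets), length(x$receptors),
              length(x$labels$metabolic) + length(x$labels$inflammatory)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits expression TSV and GCT 1.2, metadata TSV, gene sets GMT, label
#' lists, receptor catalog, and ground truth JSON.
#'
#' @param sim a `receptor_sim` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "receptor_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression_tsv = file.path(dir, "expression.tsv"),
    expression_gct = file.path(dir, "expression.gct"),
    metadata = file.path(dir, "metadata.tsv"),
    genesets = file.path(dir, "pathways.gmt"),
    receptors = file.path(dir, "receptors.txt"),
    metabolic = file.path(dir, "metabolic.txt"),
    inflammatory = file.path(dir, "inflammatory.txt"),
    exclusion = file.path(dir, "exclusion.txt"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_expression_tsv(sim$expr, paths["expression_tsv"])
  write_expression_gct(sim$expr, paths["expression_gct"])
  write_tsv(sim$meta, paths["metadata"])
  write_gmt(sim$genesets, paths["genesets"])
  write_gene_list(sim$receptors, paths["receptors"])
  write_gene_list(sim$labels$metabolic, paths["metabolic"])
  write_gene_list(sim$labels$inflammatory, paths["inflammatory"])
  write_gene_list(sim$labels$exclusion, paths["exclusion"])
  truth <- sim$truth
  truth$factors <- NULL  # large; regenerable from the config
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
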
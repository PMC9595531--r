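# End-to-end pipeline driver: preprocess -> network -> enrichment ->
# features -> PU labeling -> cross-validated classification -> attribution
# and cutoff prediction, with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: 0.1 TPM in 80%
#' of samples for the gene filter, Hardy code 4 exclusion, contamination
#' 0.05 for outlier screening, soft power `"auto"` (fallback 14), minimum
#' module size 30, merge height 0.25, enrichment significance 0.01, 100 PU
#' iterations, 50 "other" receptors, 10 folds, and strict 0.85 cutoffs for
#' prediction and cross-tissue comparison. Unknown parameter names are
#' rejected.
#'
#' @param ... overrides of the defaults listed above.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    excluded_codes = 4L, min_tpm = 0.1, min_fraction = 0.8, pseudocount = 1,
    contamination = 0.05,
    confounders = c("batch", "ischemic_time", "sex", "age_bracket",
                    "hardy_code"),
    power = "auto", min_module_size = 30, cut_method = "gap",
    cut_height_quantile = 0.8,
    merge_height = 0.25, significance = 0.01,
    pu_iterations = 100, n_other = 50, svm_cost = 1,
    family = "gbt", grid = NULL, n_folds = 10,
    cutoff = 0.85, switch_diff = 0.85, seed = 1L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown))
    stop("unknown pipeline parameters: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

## stage-specific seeds derived from the global one, so stages are
## individually reproducible and independent
stage_seed <- function(seed, stage) {
  offsets <- c(preprocess = 101, pu = 211, classify = 307, explain = 401)
  # double arithmetic, reduced mod 2^31 - 1 to stay a valid integer seed
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Run the full pipeline on one tissue
#'
#' Executes preprocessing, network construction, module enrichment, feature
#' assembly, PU labeling, cross-validated classification of the labeled
#' receptors, final-model fitting, Shapley attribution, and
#' probability-cutoff prediction of the unlabeled receptors.
#'
#' @param expr TPM [expression_matrix()].
#' @param meta sample metadata.
#' @param genesets a `gene_set_collection`.
#' @param receptors receptor catalog (character vector of gene ids).
#' @param metabolic,inflammatory,exclusion positive/exclusion label lists.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every stage artifact is
#'   written as TSV/JSON and a manifest with checksums is emitted.
#' @return a `pipeline_result` list with every stage output and the
#'   manifest.
#' @export
run_pipeline <- function(expr, meta, genesets, receptors, metabolic,
                         inflammatory, exclusion = character(0),
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) message(sprintf(...))

  pp <- preprocess(expr, meta, excluded_codes = config$excluded_codes,
                   min_tpm = config$min_tpm, min_fraction = config$min_fraction,
                   pseudocount = config$pseudocount,
                   contamination = config$contamination,
                   confounders = config$confounders,
                   seed = stage_seed(config$seed, "preprocess"))
  log_stage("preprocess: %d/%d genes kept, %d/%d samples kept",
            pp$counts["genes_kept"], pp$counts["genes_in"],
            pp$counts["samples_kept"], pp$counts["samples_in"])

  net <- build_network(pp$residuals, power = config$power,
                       min_module_size = config$min_module_size,
                       cut_method = config$cut_method,
                       cut_height_quantile = config$cut_height_quantile,
                       merge_height = config$merge_height)
  log_stage("network: power %s, %d modules", format(net$power),
            length(net$partition$sizes))

  enrichment <- enrich_modules(net$partition, genesets)
  heat <- heatmap_matrix(enrichment, config$significance)

  eig_cor <- eigengene_correlation_matrix(net$eigengenes)
  catalog <- intersect(receptors, rownames(pp$residuals))
  fm <- build_feature_matrix(catalog, net$partition, enrichment, eig_cor,
                             net$kme)
  log_stage("features: %d receptors x %d features (%d dropped)",
            nrow(fm$features), ncol(fm$features), nrow(fm$dropped))

  lab <- derive_labels(fm, metabolic, inflammatory, exclusion,
                       catalog = rownames(fm$features),
                       T = config$pu_iterations, K = config$n_other,
                       cost = config$svm_cost,
                       seed = stage_seed(config$seed, "pu"))
  log_stage("labels: %s",
            paste(names(lab$labels$counts), lab$labels$counts,
                  sep = "=", collapse = " "))

  spec <- classifier_spec(config$family, grid = config$grid,
                          seed = stage_seed(config$seed, "classify"))
  cv <- train_eval(fm, lab$labels, spec, n_folds = config$n_folds)
  log_stage("cross-validation (%s): mean accuracy %.3f", config$family,
            cv$mean_accuracy)

  model <- fit_final(fm, lab$labels, config$family, cv$best_params,
                     seed = stage_seed(config$seed, "classify"))
  attribution <- if (config$family == "gbt")
    shap_attribution(model, fm) else NULL

  unlabeled <- names(lab$labels$labels)[lab$labels$labels == "unlabeled"]
  predictions <- if (length(unlabeled))
    predict_unlabeled(model,
                      fm$features[unlabeled, , drop = FALSE],
                      cutoff = config$cutoff) else NULL
  if (!is.null(predictions))
    log_stage("prediction: %d unlabeled receptors, %d pass the %.2f cutoff",
              nrow(predictions), sum(predictions$passes_cutoff),
              config$cutoff)

  result <- structure(list(
    preprocess = pp, network = net, enrichment = enrichment,
    heatmap = heat, features = fm, labeling = lab, cv = cv, model = model,
    attribution = attribution, predictions = predictions,
    config = config), class = "pipeline_result")
  if (!is.null(out_dir)) result$manifest <- write_pipeline(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("receptor-function pipeline result\n")
  cat(sprintf("  genes kept: %d, samples kept: %d\n",
              x$preprocess$counts["genes_kept"],
              x$preprocess$counts["samples_kept"]))
  cat(sprintf("  modules: %d (power %s)\n", length(x$network$partition$sizes),
              format(x$network$power)))
  cat(sprintf("  labels: %s\n",
              paste(names(x$labeling$labels$counts), x$labeling$labels$counts,
                    sep = "=", collapse = " ")))
  cat(sprintf("  CV mean accuracy (%s): %.3f\n", x$cv$family,
              x$cv$mean_accuracy))
  if (!is.null(x$predictions))
    cat(sprintf("  predictions: %d unlabeled, %d above cutoff\n",
                nrow(x$predictions), sum(x$predictions$passes_cutoff)))
  invisible(x)
}

## write stage artifacts and a manifest of parameters + checksums
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    paths[[name]] <<- path
  }
  emit("residuals.tsv",
       function(p) write_expression_tsv(result$preprocess$residuals, p))
  emit("removed_samples.tsv", function(p)
    write_tsv(data.frame(sample_id = result$preprocess$removed_samples), p))
  emit("modules.tsv", function(p)
    write_tsv(data.frame(gene = names(result$network$partition$labels),
                         module = unname(result$network$partition$labels)), p))
  emit("eigengenes.tsv", function(p)
    write_matrix_tsv(result$network$eigengenes$eigengenes, p, "module"))
  emit("kme.tsv", function(p) write_matrix_tsv(result$network$kme, p, "gene"))
  if (!is.null(result$network$power_diagnostics))
    emit("power_diagnostics.tsv",
         function(p) write_tsv(result$network$power_diagnostics, p))
  emit("enrichment.tsv", function(p) write_tsv(result$enrichment, p))
  if (length(result$heatmap$scores))
    emit("heatmap_matrix.tsv",
         function(p) write_matrix_tsv(result$heatmap$scores, p, "module"))
  emit("features.tsv",
       function(p) write_matrix_tsv(result$features$features, p, "receptor"))
  emit("feature_schema.json", function(p)
    jsonlite::write_json(result$features$schema, p))
  emit("oob_scores.tsv", function(p)
    write_tsv(data.frame(receptor = names(result$labeling$oob$scores),
                         mean_oob_score = unname(result$labeling$oob$scores),
                         n_oob = unname(result$labeling$oob$n_oob)), p))
  emit("labels.tsv", function(p)
    write_tsv(data.frame(receptor = names(result$labeling$labels$labels),
                         label = unname(result$labeling$labels$labels),
                         provenance = unname(result$labeling$labels$provenance)),
              p))
  emit("cv_metrics.tsv", function(p) write_tsv(result$cv$metrics$per_class, p))
  emit("misclassified.tsv", function(p) write_tsv(result$cv$misclassified, p))
  emit("cv_result.json", function(p)
    jsonlite::write_json(list(family = result$cv$family,
                              best_params = result$cv$best_params,
                              mean_accuracy = result$cv$mean_accuracy,
                              fold_metrics = result$cv$fold_metrics,
                              macro = result$cv$metrics[c("accuracy",
                                                          "precision",
                                                          "recall", "f1")]),
                         p, auto_unbox = TRUE, digits = NA))
  if (!is.null(result$attribution))
    emit("importance.tsv", function(p)
      write_matrix_tsv(result$attribution$importance, p, "feature"))
  if (!is.null(result$predictions))
    emit("predictions.tsv", function(p) write_tsv(result$predictions, p))

  manifest <- list(
    package_version = as.character(utils::packageVersion("receptorfunc")),
    parameters = unclass(result$config),
    counts = list(genes_kept = unname(result$preprocess$counts["genes_kept"]),
                  samples_kept = unname(result$preprocess$counts["samples_kept"]),
                  modules = length(result$network$partition$sizes),
                  labels = as.list(result$labeling$labels$counts)),
    checksums = as.list(tools::md5sum(unlist(paths))))
  names(manifest$checksums) <- names(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
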
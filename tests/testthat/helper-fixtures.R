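# Shared fixtures: small matrices and a reduced synthetic dataset used by
# several test files. Built once per test run.

tiny_expr <- function(values, stage = "tpm") {
  m <- matrix(values, nrow = length(values) %/% 4, byrow = TRUE)
  dimnames(m) <- list(sprintf("g%d", seq_len(nrow(m))),
                      sprintf("s%d", seq_len(ncol(m))))
  expression_matrix(m, stage)
}

rand_expr <- function(n_genes, n_samples, seed = 1, stage = "tpm",
                      positive = TRUE) {
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  if (positive) v <- abs(v) + 0.2
  dimnames(v) <- list(sprintf("g%03d", seq_len(n_genes)),
                      sprintf("s%03d", seq_len(n_samples)))
  expression_matrix(v, stage)
}

toy_metadata <- function(n, seed = 1, hardy = NULL) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("s%03d", seq_len(n)),
    batch = sample(c("A", "B"), n, replace = TRUE),
    ischemic_time = round(stats::runif(n, 100, 900)),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age_bracket = sample(seq(20, 70, 10), n, replace = TRUE),
    hardy_code = if (is.null(hardy)) sample(0:4, n, replace = TRUE) else hardy,
    stringsAsFactors = FALSE
  )
}

# small synthetic dataset reused across module tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_dataset(synthetic_config(
        n_samples = 100, n_modules = 4, genes_per_module = 60,
        n_background_genes = 80, n_pathways = 12,
        n_receptors_per_class = 12, seed = 21))
    cache
  }
})

# map detected module labels to the planted module they mostly contain
module_map <- function(labels, truth) {
  mods <- sort(unique(labels[labels > 0L]))
  vapply(mods, function(m) {
    as.integer(names(which.max(table(truth[labels == m]))))
  }, integer(1))
}
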
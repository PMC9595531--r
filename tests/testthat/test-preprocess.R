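test_that("death-code filter removes exactly the excluded samples", {
  expr <- rand_expr(5, 10, seed = 2)
  meta <- toy_metadata(10, hardy = c(0, 1, 4, 2, 3, 4, 0, 1, 2, 3))
  out <- filter_samples_by_death(expr, meta)
  expect_equal(ncol(out$expr), 8)
  expect_false(any(out$meta$hardy_code == 4))
  expect_identical(colnames(out$expr), meta$sample_id[meta$hardy_code != 4])

  # empty exclusion set is the identity
  same <- filter_samples_by_death(expr, meta, excluded_codes = integer(0))
  expect_identical(unclass(same$expr), unclass(expr))

  # excluding every code errors explicitly
  expect_error(filter_samples_by_death(expr, meta, excluded_codes = 0:4),
               "no samples remain")

  # unknown sample errors by name
  expr2 <- expr
  colnames(expr2)[1] <- "mystery"
  expect_error(filter_samples_by_death(expression_matrix(unclass(expr2), "tpm"),
                                       meta), "mystery")
})

test_that("gene filter applies the 0.1-TPM / 80% rule inclusively", {
  # 6 genes x 5 samples with a known pass pattern; oracle = per-gene count
  v <- rbind(
    g_all   = c(1, 2, 3, 4, 5),        # 5/5 pass
    g_four  = c(0.05, 1, 1, 1, 1),     # 4/5 = 0.8 -> retained (inclusive)
    g_three = c(0.05, 0.05, 1, 1, 1),  # 3/5 -> dropped
    g_edge  = c(0.1, 0.1, 0.1, 0.1, 0.05),  # values at threshold count
    g_zero  = c(0, 0, 0, 0, 0),        # zero variance -> dropped
    g_const = c(7, 7, 7, 7, 7)         # passes abundance but constant
  )
  colnames(v) <- sprintf("s%d", 1:5)
  expr <- expression_matrix(v, "tpm")
  kept <- rownames(filter_genes(expr))
  oracle <- rownames(v)[vapply(rownames(v), function(g) {
    mean(v[g, ] >= 0.1) >= 0.8 && var(v[g, ]) > 0
  }, logical(1))]
  expect_identical(kept, oracle)
  expect_identical(kept, c("g_all", "g_four", "g_edge"))
  expect_error(filter_genes(log2_transform(expression_matrix(v, "tpm"))),
               "stage")
})

test_that("log2 transform matches a scalar-loop oracle and guards its domain", {
  expect_equal(unclass(log2_transform(tiny_expr(c(0, 1, 3, 7))))[1, ],
               c(s1 = 0, s2 = 1, s3 = 2, s4 = 3))
  expr <- rand_expr(8, 6, seed = 5)
  got <- unclass(log2_transform(expr))
  oracle <- unclass(expr)
  for (i in seq_len(nrow(oracle))) for (j in seq_len(ncol(oracle)))
    oracle[i, j] <- log2(oracle[i, j] + 1)
  expect_equal(got, oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(log2_transform(tiny_expr(c(0, 1, 2, 3)), pseudocount = 0),
               "pseudocount")
  neg <- tiny_expr(c(-1, 1, 2, 3))
  expect_error(log2_transform(neg), "negative")
})

test_that("quantile normalization equalizes distributions with the mean-rank tie rule", {
  # hand-computed: [1,2,3] and [4,5,6] both become [2.5, 3.5, 4.5]
  v <- cbind(s1 = c(1, 2, 3), s2 = c(4, 5, 6))
  rownames(v) <- c("g1", "g2", "g3")
  got <- unclass(quantile_normalize(expression_matrix(v, "log2")))
  expect_equal(unname(got), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)),
               ignore_attr = TRUE)

  # ties: a sample with equal values gets the mean reference at tied ranks
  v2 <- cbind(s1 = c(1, 1, 5), s2 = c(2, 4, 6))
  rownames(v2) <- c("g1", "g2", "g3")
  got2 <- unclass(quantile_normalize(expression_matrix(v2, "log2")))
  ref <- rowMeans(cbind(sort(v2[, 1]), sort(v2[, 2])))  # 1.5, 2.5, 5.5
  expect_equal(unname(got2[, 1]),
               unname(c(mean(ref[1:2]), mean(ref[1:2]), ref[3])))

  # postcondition on random input: sorted columns identical; ranks preserved
  expr <- rand_expr(60, 8, seed = 6, stage = "log2")
  qn <- unclass(quantile_normalize(expr))
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  for (j in 1:8)
    expect_identical(order(qn[, j]), order(unclass(expr)[, j]))

  # single sample is unchanged
  one <- rand_expr(10, 1, seed = 7, stage = "log2")
  expect_equal(unclass(quantile_normalize(one)), unclass(one),
               ignore_attr = TRUE)
})

test_that("quantile normalization agrees with limma on tie-free data", {
  skip_if_not_installed("limma")
  expr <- rand_expr(100, 10, seed = 8, stage = "log2")
  mine <- unclass(quantile_normalize(expr))
  ref <- limma::normalizeQuantiles(unclass(expr), ties = TRUE)
  expect_equal(mine, ref, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("isolation-forest outlier screening recovers planted shifted samples", {
  sim <- generate_dataset(synthetic_config(seed = 7))
  e <- log2_transform(filter_genes(sim$expr))
  planted <- names(sim$truth$outlier)[sim$truth$outlier]
  out <- remove_outlier_samples(e, contamination = 0.05, seed = 31)
  expect_gte(length(intersect(out$removed, planted)),
             ceiling(0.9 * length(planted)))
  # determinism and the zero-contamination identity
  out2 <- remove_outlier_samples(e, contamination = 0.05, seed = 31)
  expect_identical(out$removed, out2$removed)
  none <- remove_outlier_samples(e, contamination = 0)
  expect_length(none$removed, 0)
  expect_error(remove_outlier_samples(e, contamination = 0.6), "< 0.5")
})

test_that("residualization is an exact OLS adjustment", {
  meta <- toy_metadata(40, seed = 10, hardy = rep(0:3, 10))
  set.seed(11)
  v <- matrix(rnorm(6 * 40), 6, 40,
              dimnames = list(sprintf("g%d", 1:6), meta$sample_id))
  # gene exactly linear in ischemic time -> residuals ~ 0
  v[1, ] <- 2 * meta$ischemic_time + 5
  # planted batch effect on gene 2
  v[2, ] <- v[2, ] + 3 * (meta$batch == "B")
  expr <- expression_matrix(v, "qnorm")
  out <- residualize(expr, meta)
  res <- unclass(out$residuals)
  expect_lt(max(abs(res[1, ])), 1e-8)
  # residuals orthogonal to numeric confounders and batch indicator
  expect_lt(max(abs(cor(t(res), meta$ischemic_time))), 1e-8)
  expect_lt(max(abs(cor(t(res), as.numeric(meta$batch == "B")))), 1e-8)
  # coefficients match an independent normal-equations solve
  X <- out$model$design
  beta_oracle <- solve(t(X) %*% X, t(X) %*% v[2, ])
  expect_equal(unname(out$model$coefficients[2, ]),
               unname(drop(beta_oracle)), tolerance = 1e-8)
  # idempotence
  again <- residualize(out$residuals, meta)
  expect_equal(unclass(again$residuals), res, tolerance = 1e-8)
})

test_that("intercept-only residualization mean-centers each gene", {
  meta <- toy_metadata(12, seed = 12)
  expr <- rand_expr(5, 12, seed = 12, stage = "qnorm")
  out <- residualize(expr, meta, confounders = character(0))
  expect_equal(unclass(out$residuals),
               unclass(expr) - rowMeans(unclass(expr)),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("collinear confounder designs are rejected by name", {
  meta <- toy_metadata(20, seed = 13)
  meta$dup_time <- meta$ischemic_time
  expr <- rand_expr(3, 20, seed = 13, stage = "qnorm")
  expect_error(residualize(expr, meta,
                           confounders = c("ischemic_time", "dup_time")),
               "dup_time")
})
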
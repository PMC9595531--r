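# independent scalar oracle for the biweight midcorrelation of two vectors
bicor_oracle <- function(x, y) {
  tw <- function(v) {
    u <- (v - median(v)) / (9 * median(abs(v - median(v))))
    (v - median(v)) * (1 - u^2)^2 * (abs(u) < 1)
  }
  a <- tw(x); b <- tw(y)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

test_that("biweight midcorrelation matches the direct formula and is robust", {
  set.seed(14)
  x <- rnorm(5); y <- rnorm(5)
  m <- rbind(g1 = x, g2 = y, g3 = x, g4 = -x)
  colnames(m) <- sprintf("s%d", 1:5)
  got <- bicor_matrix(m)
  expect_equal(got["g1", "g2"], bicor_oracle(x, y), tolerance = 1e-10)
  expect_equal(got["g1", "g3"], 1, tolerance = 1e-12)
  expect_equal(got["g1", "g4"], -1, tolerance = 1e-12)
  expect_true(isSymmetric(got))
  expect_true(all(abs(got) <= 1))

  # gross outlier: bicor stays closer to the clean relationship than Pearson
  set.seed(15)
  base <- rnorm(20)
  partner <- base + rnorm(20, sd = 0.1)
  spoiled <- base
  spoiled[1] <- 40
  m2 <- rbind(clean = partner, dirty = spoiled)
  colnames(m2) <- sprintf("s%d", 1:20)
  expect_gt(abs(bicor_matrix(m2)["clean", "dirty"]),
            abs(cor(partner, spoiled)))

  expect_error(bicor_matrix(m[, 1:3]), "4 samples")
  # constant gene falls back to correlation 0 with a warning
  m3 <- rbind(g1 = rnorm(6), flat = rep(2, 6))
  colnames(m3) <- sprintf("s%d", 1:6)
  expect_warning(got3 <- bicor_matrix(m3), "constant")
  expect_equal(got3["g1", "flat"], 0)
})

test_that("signed adjacency follows the soft-threshold formula exactly", {
  cm <- matrix(c(1, 1, -1, 0.5,
                 1, 1, 0, 0,
                 -1, 0, 1, 0.2,
                 0.5, 0, 0.2, 1), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  cm <- (cm + t(cm)) / 2
  adj <- signed_adjacency(cm, 14)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_equal(signed_adjacency(matrix(0, 2, 2) + diag(2), 14)[1, 2],
               0.5^14, tolerance = 1e-15)
  # scalar-loop oracle on a random symmetric matrix
  set.seed(16)
  r <- cor(matrix(rnorm(200), 20, 10))
  got <- signed_adjacency(r, 14)
  for (i in 1:5) for (j in 1:5)
    if (i != j) expect_equal(got[i, j], (0.5 * (1 + r[i, j]))^14,
                             tolerance = 1e-12)
  # monotone in cor
  expect_true(all(diff(signed_adjacency(matrix(seq(-1, 1, 0.25), 1), 6)) >= 0))
  expect_error(signed_adjacency(r, -1), "positive")
})

# triple-loop oracle for the topological overlap matrix
tom_oracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 1
  k <- rowSums(a) - 1
  out <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    s <- sum(vapply(setdiff(seq_len(n), c(i, j)),
                    function(u) a[i, u] * a[u, j], numeric(1)))
    out[i, j] <- (s + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  out
}

test_that("TOM matches the triple-loop oracle on random small graphs", {
  # endpoints
  a0 <- diag(3)  # no edges, no shared neighbors
  expect_equal(tom_similarity(a0)$tom[1, 2], 0)
  a1 <- matrix(1, 5, 5)
  expect_true(all(abs(tom_similarity(a1)$tom - 1) < 1e-12))
  # property sweep: random graphs of size 3..6
  for (s in 1:40) {
    set.seed(s)
    n <- sample(3:6, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    got <- tom_similarity(a)$tom
    expect_equal(unname(got), tom_oracle(a), tolerance = 1e-12)
  }
})

test_that("power selection finds scale-free structure and falls back to 14", {
  # planted approximate power-law connectivity: hub-like correlation blocks
  set.seed(17)
  n <- 120; p <- 150
  hubs <- matrix(rnorm(3 * n), 3, n)
  w <- (runif(p))^2  # long-tailed loadings -> heterogeneous connectivity
  m <- w * hubs[sample(1:3, p, replace = TRUE), ] +
    matrix(rnorm(p * n, sd = 0.6), p, n)
  dimnames(m) <- list(sprintf("g%03d", 1:p), sprintf("s%03d", 1:n))
  sel <- pick_power(bicor_matrix(m))
  expect_true(sel$reached_target)
  expect_gte(max(sel$diagnostics$signed_r2, na.rm = TRUE), 0.8)

  # single candidate is returned unconditionally
  one <- pick_power(bicor_matrix(m), candidate_powers = 6)
  expect_equal(one$beta, 6)

  # flat structure: nothing reaches the target -> documented fallback 14
  set.seed(18)
  flat <- matrix(rnorm(40 * 60), 40, 60,
                 dimnames = list(sprintf("g%d", 1:40), sprintf("s%d", 1:60)))
  sel2 <- pick_power(bicor_matrix(flat), candidate_powers = 1:3,
                     target_r2 = 0.999)
  expect_false(sel2$reached_target)
  expect_equal(sel2$beta, 14)
})

test_that("module detection separates planted blocks exactly", {
  # two perfectly separated blocks of 50: within-cor 0.9, between 0
  set.seed(19)
  n <- 60
  f1 <- rnorm(n); f2 <- rnorm(n)
  m <- rbind(sqrt(0.9) * outer(rep(1, 50), f1),
             sqrt(0.9) * outer(rep(1, 50), f2)) +
    matrix(rnorm(100 * n, sd = sqrt(0.1)), 100, n)
  dimnames(m) <- list(sprintf("g%03d", 1:100), sprintf("s%03d", 1:n))
  diss <- tom_similarity(signed_adjacency(bicor_matrix(m), 6))$diss
  part <- detect_modules(diss, min_module_size = 30)
  expect_equal(length(part$sizes), 2)
  truth <- rep(1:2, each = 50)
  expect_equal(mclust::adjustedRandIndex(part$labels, truth), 1)

  # min size larger than any cluster -> everything unassigned, warning
  expect_warning(empty <- detect_modules(diss, min_module_size = 80),
                 "empty partition")
  expect_true(all(empty$labels == 0))
})

test_that("eigengenes summarize modules and orient toward their members", {
  set.seed(20)
  n <- 50
  f <- rnorm(n)
  m <- outer(runif(20, 0.8, 1.2), f) + matrix(rnorm(20 * n, sd = 0.2), 20, n)
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:n))
  labels <- stats::setNames(rep(1L, 20), rownames(m))
  part <- structure(list(labels = labels), class = "module_partition")
  eig <- compute_eigengenes(m, part)
  expect_equal(sum(eig$eigengenes[1, ]^2), 1, tolerance = 1e-10)
  expect_gt(abs(cor(eig$eigengenes[1, ], f)), 0.99)
  # orientation: mean member correlation nonnegative, and stable under
  # negating all member genes
  expect_gte(mean(cor(t(m), eig$eigengenes[1, ])), 0)
  eig_neg <- compute_eigengenes(-m, part)
  expect_gte(mean(cor(t(-m), eig_neg$eigengenes[1, ])), 0)
  # identical genes -> |cor(eigengene, member)| = 1
  dup <- m[rep(1, 5), ]
  rownames(dup) <- sprintf("g%02d", 1:5)
  eig_dup <- compute_eigengenes(dup, structure(list(
    labels = stats::setNames(rep(1L, 5), rownames(dup))),
    class = "module_partition"))
  expect_equal(abs(cor(eig_dup$eigengenes[1, ], dup[1, ])), 1,
               tolerance = 1e-10)
})

test_that("kME is the gene-eigengene correlation for all genes x all modules", {
  sim <- small_sim()
  v <- log2(unclass(sim$expr) + 1)
  truth <- sim$truth$module
  part <- structure(list(labels = truth[truth > 0]),
                    class = "module_partition")
  members <- names(truth)[truth > 0]
  eig <- compute_eigengenes(v[members, ], part)
  kme <- compute_kme(v[members, ], eig)
  expect_equal(dim(kme), c(length(members), 4))
  # loop oracle on a sample of entries
  set.seed(22)
  for (g in sample(members, 10)) for (m in rownames(eig$eigengenes))
    expect_equal(kme[g, m], cor(v[g, ], eig$eigengenes[m, ]),
                 tolerance = 1e-10)
  # own-module kME has nonnegative mean (orientation rule)
  for (m in 1:4)
    expect_gte(mean(kme[names(truth)[truth == m], paste0("ME", m)]), 0)
})

test_that("modules with correlated eigengenes merge to a fixed point", {
  set.seed(23)
  n <- 80
  f <- rnorm(n)
  # three planted groups driven by the same factor (pairwise cor ~0.8),
  # plus one independent group
  g <- rnorm(n)
  mk <- function(base, sz, sd) outer(rep(1, sz), base) +
    matrix(rnorm(sz * n, sd = sd), sz, n)
  m <- rbind(mk(f, 30, 0.5), mk(f, 30, 0.5), mk(f, 30, 0.5), mk(g, 30, 0.5))
  dimnames(m) <- list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:n))
  labels <- stats::setNames(rep(1:4, each = 30), rownames(m))
  part <- structure(list(labels = labels), class = "module_partition")
  merged <- merge_modules(m, part, merge_height = 0.25)
  expect_equal(length(merged$partition$sizes), 2)
  # fixed point: no remaining pair of eigengenes closer than the height
  ec <- cor(t(merged$eigengenes$eigengenes))
  expect_true(all(1 - ec[upper.tri(ec)] >= 0.25))
  # re-running changes nothing
  again <- merge_modules(m, merged$partition, merge_height = 0.25)
  expect_identical(again$partition$labels, merged$partition$labels)

  # weakly correlated modules stay apart
  m2 <- rbind(mk(f, 30, 0.5), mk(g, 30, 0.5))
  dimnames(m2) <- list(sprintf("g%03d", 1:60), sprintf("s%02d", 1:n))
  part2 <- structure(list(labels = stats::setNames(rep(1:2, each = 30),
                                                   rownames(m2))),
                     class = "module_partition")
  kept <- merge_modules(m2, part2, merge_height = 0.25)
  expect_equal(length(kept$partition$sizes), 2)
})
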
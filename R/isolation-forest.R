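# Isolation forest for sample-level anomaly scoring, in the extended
# (random-hyperplane) variant: each node projects the points onto a random
# unit direction and cuts uniformly between the projection extremes, so
# separation that is not axis-aligned in the feature space is still found.
# Trees are grown on subsamples of size psi until full isolation; points in
# a multi-point leaf are credited the average unsuccessful-search length
# c(k). The anomaly score is 2^(-E[h(x)] / c(psi)): points isolated early
# approach 1.

avg_path_length <- function(k) {
  ifelse(k <= 1, 0, 2 * (log(k - 1) + 0.5772156649) - 2 * (k - 1) / k)
}

grow_itree <- function(x, depth, max_depth) {
  n <- nrow(x)
  if (n <= 1L || depth >= max_depth) return(list(leaf = TRUE, size = n))
  w <- stats::rnorm(ncol(x))
  w <- w / sqrt(sum(w^2))
  proj <- drop(x %*% w)
  lo <- min(proj); hi <- max(proj)
  if (hi - lo < .Machine$double.eps^0.5) return(list(leaf = TRUE, size = n))
  cut <- stats::runif(1, lo, hi)
  left <- proj < cut
  list(leaf = FALSE, w = w, cut = cut,
       left = grow_itree(x[left, , drop = FALSE], depth + 1L, max_depth),
       right = grow_itree(x[!left, , drop = FALSE], depth + 1L, max_depth))
}

itree_depth <- function(node, x, depth = 0) {
  if (node$leaf) return(rep(depth + avg_path_length(node$size), nrow(x)))
  out <- numeric(nrow(x))
  left <- drop(x %*% node$w) < node$cut
  if (any(left))
    out[left] <- itree_depth(node$left, x[left, , drop = FALSE], depth + 1)
  if (any(!left))
    out[!left] <- itree_depth(node$right, x[!left, , drop = FALSE], depth + 1)
  out
}

#' Isolation-forest anomaly scores
#'
#' Extended isolation forest (random-hyperplane splits, grown to full
#' isolation) over the rows of `x`.
#'
#' @param x observations x features numeric matrix.
#' @param n_trees number of isolation trees.
#' @param subsample per-tree subsample size (capped at `nrow(x)`); small
#'   subsamples keep clustered anomalies isolatable.
#' @param seed integer seed; scores are deterministic given it.
#' @return anomaly scores in \[0,1\], one per row of `x`; larger = more
#'   anomalous.
#' @export
isolation_forest_scores <- function(x, n_trees = 200, subsample = 64,
                                    seed = 1L) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (exists(".Random.seed", envir = .GlobalEnv)) {
    old_seed <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old_seed, envir = .GlobalEnv))
  }
  set.seed(seed)
  psi <- min(subsample, nrow(x))
  max_depth <- 8L * ceiling(log2(psi))  # loose bound against degeneracy
  depths <- matrix(0, nrow(x), n_trees)
  for (t in seq_len(n_trees)) {
    idx <- sample(nrow(x), psi)
    tree <- grow_itree(x[idx, , drop = FALSE], 0L, max_depth)
    depths[, t] <- itree_depth(tree, x)
  }
  2^(-rowMeans(depths) / avg_path_length(psi))
}
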
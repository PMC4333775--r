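# Independent oracles and small fixtures used across the test files.

# All labelled DAGs on k nodes (adjacency matrices), by brute enumeration of
# every directed graph and filtering on acyclicity. 543 DAGs for k = 4.
enumerate_dags <- function(k) {
  slots <- which(matrix(TRUE, k, k) & !diag(k))
  out <- vector("list", 0L)
  for (code in 0:(2^length(slots) - 1)) {
    bits <- as.integer(intToBits(code))[seq_along(slots)]
    a <- matrix(0L, k, k)
    a[slots] <- bits
    if (restbn::is_acyclic(a)) out[[length(out) + 1L]] <- a
  }
  out
}

# Random weighted DAG: random node permutation, upper-triangular support with
# edge probability 0.5, weights uniform in +/-[0.3, 1].
random_dag <- function(k, seed) {
  set.seed(seed)
  w <- matrix(0, k, k)
  perm <- sample(k)
  ut <- upper.tri(w) & matrix(stats::runif(k * k) < 0.5, k, k)
  w[perm, perm][ut] <- stats::runif(sum(ut), 0.3, 1) *
    sample(c(-1, 1), sum(ut), replace = TRUE)
  restbn::dag_model(paste0("V", seq_len(k)), w)
}

# Family-decomposed Gaussian BIC computed independently through lm():
# ML residual variance (denominator N) of each node on its parents, no
# intercept, penalty (|parents| + 1)/2 * log N.
bic_oracle_lm <- function(parent_list, z) {
  n <- nrow(z)
  sum(vapply(seq_along(parent_list), function(j) {
    p <- parent_list[[j]]
    res <- if (length(p)) stats::lm.fit(z[, p, drop = FALSE], z[, j])$residuals
           else z[, j]
    -(n / 2) * (1 + log(2 * pi * mean(res^2))) -
      ((length(p) + 1) / 2) * log(n)
  }, 0))
}

# Best BIC over all labelled DAGs on ncol(z) nodes (exhaustive search oracle).
exhaustive_best_bic <- function(z) {
  max(vapply(enumerate_dags(ncol(z)), function(a)
    restbn::gaussian_bic(a, z), 0))
}

# Population standardized regression coefficients of each node on its true
# parents, from the SEM's implied covariance: scale Sigma to a correlation
# matrix and solve each family's normal equations.
population_std_coefs <- function(dag) {
  r <- stats::cov2cor(restbn::implied_covariance(dag))
  k <- length(dag$node_names)
  w <- matrix(0, k, k, dimnames = dimnames(dag$weights))
  for (j in seq_len(k)) {
    p <- which(dag$weights[, j] != 0)
    if (length(p)) w[p, j] <- solve(r[p, p, drop = FALSE], r[p, j])
  }
  w
}

# Small grid for rendering tests: 3 mm voxels, origin chosen so voxel centres
# sit on multiples of 3 mm around the origin.
small_grid <- function(n = 15L, vox = 3) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -vox * floor(n / 2)
  restbn::img_grid(rep(n, 3L), aff)
}

# Three toy nodes that fit comfortably inside small_grid().
toy_nodes <- function(radius = 4) {
  list(restbn::node_def("A", c(-9, 0, 0), radius),
       restbn::node_def("B", c(9, 3, -3), radius),
       restbn::node_def("C", c(0, -9, 9), radius))
}

# Deterministic toy recording for the extraction tests.
toy_ts <- function(tt = 40, k = 3, seed = 42, tr = 2) {
  set.seed(seed)
  restbn::ts_matrix(matrix(stats::rnorm(tt * k), tt, k,
                           dimnames = list(NULL, LETTERS[seq_len(k)])),
                    tr = tr)
}
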
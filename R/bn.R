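#' Z-score node time series
#'
#' Centres and scales each column to mean 0 and standard deviation 1, using
#' the population (maximum-likelihood, denominator N) standard deviation.
#' Standardization makes edge weights comparable across subjects and removes
#' the need for intercepts in the per-family regressions.
#'
#' @param x A `ts_matrix` or numeric N x K matrix with N > K.
#' @return Numeric matrix of the same shape with unit-variance columns.
#' @export
standardize <- function(x) {
  if (inherits(x, "ts_matrix")) x <- x$data
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("need more observations than nodes (N > K) to standardize")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, `-`)
  sds <- sqrt(colMeans(xc^2))
  zero <- sds < .Machine$double.eps * 100
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(x)[zero] %||% which(zero), collapse = ", "))
  sweep(xc, 2L, sds, `/`)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Per-family Gaussian BIC scorer backed by the Gram matrix S = X'X, so each
# family score costs a |parents|-sized solve regardless of N. Scores are
# memoised per (target, parent-set).
make_family_scorer <- function(data) {
  s <- crossprod(data)
  n <- nrow(data)
  cache <- new.env(parent = emptyenv())
  function(j, parents) {
    key <- paste0(j, "|", paste(sort(parents), collapse = ","))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    if (length(parents)) {
      spp <- s[parents, parents, drop = FALSE]
      spj <- s[parents, j]
      beta <- tryCatch(solve(spp, spj),
                       error = function(e) stop("singular parent design for node ",
                                                j, call. = FALSE))
      rss <- s[j, j] - sum(spj * beta)
    } else rss <- s[j, j]
    sigma2 <- max(rss / n, 1e-300)
    val <- -(n / 2) * (1 + log(2 * pi * sigma2)) -
      ((length(parents) + 1) / 2) * log(n)
    cache[[key]] <- val
    val
  }
}

# Normalize a structure argument (parent list or adjacency matrix) to a
# parent list of integer indices, validating acyclicity.
as_parent_list <- function(structure, k, node_names = NULL) {
  if (is.matrix(structure)) {
    adj <- structure != 0
    structure <- lapply(seq_len(ncol(adj)), function(j) which(adj[, j]))
  } else {
    structure <- lapply(structure, function(p) {
      if (is.character(p)) match(p, node_names) else as.integer(p)
    })
  }
  if (length(structure) != k) stop("structure must give a parent set per node")
  adj <- matrix(FALSE, k, k)
  for (j in seq_len(k)) {
    if (j %in% structure[[j]]) stop("node ", j, " is its own parent")
    adj[structure[[j]], j] <- TRUE
  }
  if (!is_acyclic(adj)) stop("structure contains a directed cycle")
  structure
}

#' Gaussian BIC score of a DAG structure
#'
#' Decomposable score: for each node j with parent set P_j, the family score
#' is `-(N/2) (1 + log(2 pi sigma_j^2)) - (d_j / 2) log N`, where `sigma_j^2`
#' is the maximum-likelihood (denominator N) residual variance of node j
#' regressed on its parents without intercept and `d_j = |P_j| + 1` counts
#' the regression coefficients plus the variance parameter. Higher is better.
#'
#' @param structure Parent list (one integer/character vector per node) or
#'   adjacency matrix (`A[i, j]` nonzero for edge i -> j). Must be acyclic.
#' @param data N x K numeric matrix, typically from [standardize()].
#' @return The total score (sum of family scores).
#' @export
gaussian_bic <- function(structure, data) {
  data <- as.matrix(data)
  k <- ncol(data)
  pl <- as_parent_list(structure, k, colnames(data))
  scorer <- make_family_scorer(data)
  sum(vapply(seq_len(k), function(j) scorer(j, pl[[j]]), 0))
}

#' Candidate parents of one node via the lasso regularization path
#'
#' Solves the L1-penalized regression of the target column on all other
#' columns along a descending penalty grid, and for each distinct support on
#' the path computes the per-family Gaussian BIC of the least-squares refit.
#' Returns the support at the BIC-optimal penalty. Used to prune the edge
#' space before structure search.
#'
#' @param data N x K standardized matrix.
#' @param target Column index (or name) of the target node.
#' @param lambda_grid Strictly descending positive penalties; the default is
#'   50 log-spaced values from the target's critical penalty (smallest that
#'   zeroes all coefficients) down to 0.01 of it.
#' @return Integer vector of candidate parent column indices (possibly empty).
#' @export
lasso_parent_candidates <- function(data, target, lambda_grid = NULL) {
  data <- as.matrix(data)
  k <- ncol(data)
  if (is.character(target)) target <- match(target, colnames(data))
  stopifnot(length(target) == 1L, target >= 1L, target <= k)
  others <- setdiff(seq_len(k), target)
  if (length(others) == 0L) return(integer(0))
  n <- nrow(data)
  y <- data[, target]
  x <- data[, others, drop = FALSE]
  if (is.null(lambda_grid)) {
    lambda_max <- max(abs(crossprod(x, y))) / n
    if (lambda_max <= 0) return(integer(0))
    lambda_grid <- exp(seq(log(lambda_max), log(0.01 * lambda_max),
                           length.out = 50L))
  }
  if (any(lambda_grid <= 0) || is.unsorted(rev(lambda_grid), strictly = TRUE))
    stop("'lambda_grid' must be strictly descending positive values")
  fit <- glmnet::glmnet(x, y, family = "gaussian", lambda = lambda_grid,
                        standardize = FALSE, intercept = FALSE)
  beta <- as.matrix(fit$beta)
  supports <- unique(lapply(seq_len(ncol(beta)),
                            function(m) others[beta[, m] != 0]))
  supports <- c(list(integer(0)), supports)  # the null model is always eligible
  scorer <- make_family_scorer(data)
  scores <- vapply(supports, function(p) scorer(target, p), 0)
  sort(supports[[which.max(scores)]])
}

# Lasso-path candidate screening for every node.
lasso_candidates_all <- function(data, lambda_grid = NULL) {
  k <- ncol(data)
  cand <- lapply(seq_len(k), function(j)
    lasso_parent_candidates(data, j, lambda_grid))
  names(cand) <- colnames(data)
  cand
}

# Is there a directed path from -> to in adjacency matrix adj (logical)?
has_path <- function(adj, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(adj))
  frontier <- from
  while (length(frontier)) {
    nxt <- which(adj[frontier[1L], ] & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    frontier <- c(frontier[-1L], nxt)
  }
  FALSE
}

#' Hill-climbing DAG structure search under a BIC score
#'
#' Greedy search over DAGs using add / delete / reverse moves restricted to
#' node pairs `(i, j)` with `i` in `candidates[[j]]` or `j` in
#' `candidates[[i]]`. Every move must preserve acyclicity; at each step the
#' single best strictly-improving move is applied. The first climb starts
#' from the empty graph with deterministic tie-breaking (move type add <
#' delete < reverse, then lexicographic (source, target) order); each restart
#' climbs from a seeded random acyclic subgraph of the candidate edge set and
#' breaks exact score ties at random, which is what lets restarts escape the
#' basin the deterministic climb falls into when several edge orientations
#' score identically. The best-scoring structure over all climbs is returned.
#' Deterministic given `seed`.
#'
#' @param data N x K standardized matrix.
#' @param candidates List of candidate-parent index vectors per node
#'   (default: all other nodes, i.e. unrestricted search).
#' @param n_restarts Number of random restarts after the empty-graph climb
#'   (default 20).
#' @param seed Integer seed for the restarts.
#' @return List with `parents` (parent list), `adjacency` (logical matrix),
#'   and `bic` (the attained score).
#' @export
hill_climb_dag <- function(data, candidates = NULL, n_restarts = 20,
                           seed = 1L) {
  data <- as.matrix(data)
  k <- ncol(data)
  if (is.null(candidates)) {
    candidates <- lapply(seq_len(k), function(j) setdiff(seq_len(k), j))
  } else {
    candidates <- lapply(candidates, as.integer)
    if (length(candidates) != k) stop("'candidates' must have one entry per node")
    for (j in seq_len(k))
      if (j %in% candidates[[j]]) stop("a node cannot be its own candidate parent")
  }
  # symmetrized allowed edge slots (i -> j)
  allowed <- matrix(FALSE, k, k)
  for (j in seq_len(k)) allowed[candidates[[j]], j] <- TRUE
  allowed <- (allowed | t(allowed)) & !diag(TRUE, k)
  scorer <- make_family_scorer(data)
  family_total <- function(adj)
    sum(vapply(seq_len(k), function(j) scorer(j, which(adj[, j])), 0))

  # One greedy climb. Moves are enumerated in a fixed order (add, delete,
  # reverse; within each, lexicographic (source, target)), so with
  # deterministic tie-breaking the first improving move of maximal gain wins.
  # Restart climbs break exact score ties at random instead, which diversifies
  # the direction chosen for score-equivalent edges and lets restarts reach
  # other basins of attraction.
  climb <- function(adj, random_ties = FALSE) {
    score <- family_total(adj)
    repeat {
      deltas <- numeric(0)
      moves <- list()
      consider <- function(delta, apply_fn) {
        if (delta > 1e-9) {
          deltas[length(deltas) + 1L] <<- delta
          moves[[length(moves) + 1L]] <<- apply_fn
        }
      }
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (!allowed[i, j] || adj[i, j] || adj[j, i]) next
        if (has_path(adj, j, i)) next  # adding i -> j would close a cycle
        delta <- scorer(j, sort(c(which(adj[, j]), i))) - scorer(j, which(adj[, j]))
        local({ii <- i; jj <- j
          consider(delta, function(a) { a[ii, jj] <- TRUE; a })})
      }
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (!adj[i, j]) next
        delta <- scorer(j, setdiff(which(adj[, j]), i)) - scorer(j, which(adj[, j]))
        local({ii <- i; jj <- j
          consider(delta, function(a) { a[ii, jj] <- FALSE; a })})
      }
      for (i in seq_len(k)) for (j in seq_len(k)) {
        if (!adj[i, j] || !allowed[j, i]) next
        tmp <- adj; tmp[i, j] <- FALSE
        if (has_path(tmp, i, j)) next  # another i ~> j path: reversal cycles
        delta <- (scorer(j, setdiff(which(adj[, j]), i)) - scorer(j, which(adj[, j]))) +
          (scorer(i, sort(c(which(adj[, i]), j))) - scorer(i, which(adj[, i])))
        local({ii <- i; jj <- j
          consider(delta, function(a) { a[ii, jj] <- FALSE; a[jj, ii] <- TRUE; a })})
      }
      if (!length(moves)) break
      ties <- which(deltas >= max(deltas) - 1e-12)
      pick <- if (random_ties && length(ties) > 1L)
        ties[sample.int(length(ties), 1L)] else ties[1L]
      adj <- moves[[pick]](adj)
      score <- score + deltas[pick]
    }
    list(adj = adj, score = score)
  }

  runs <- vector("list", n_restarts + 1L)
  runs[[1L]] <- climb(matrix(FALSE, k, k))
  if (n_restarts > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    slots <- which(allowed, arr.ind = TRUE)
    for (r in seq_len(n_restarts)) {
      # random acyclic subgraph of the candidate set as the restart start
      adj <- matrix(FALSE, k, k)
      if (nrow(slots)) {
        ord <- sample.int(nrow(slots))
        pick <- stats::runif(nrow(slots)) < 0.3
        for (e in ord[pick[ord]]) {
          i <- slots[e, 1L]; j <- slots[e, 2L]
          if (!adj[i, j] && !adj[j, i] && !has_path(adj, j, i)) adj[i, j] <- TRUE
        }
      }
      runs[[r + 1L]] <- climb(adj, random_ties = TRUE)
    }
  }
  scores <- vapply(runs, function(x) x$score, 0)
  best <- runs[[which.max(scores)]]
  parents <- lapply(seq_len(k), function(j) which(best$adj[, j]))
  names(parents) <- colnames(data)
  list(parents = parents, adjacency = best$adj, bic = best$score)
}

#' Maximum-likelihood edge weights for a fixed DAG structure
#'
#' Weight of edge i -> j is the least-squares coefficient of column i in the
#' no-intercept regression of column j on its parents; the residual standard
#' deviation uses the maximum-likelihood (denominator N) variance. Non-edges
#' get weight zero.
#'
#' @param structure Parent list or adjacency matrix (acyclic).
#' @param data N x K standardized matrix with column names.
#' @return A `dag_model` with fitted weights, noise SDs, and the structure's
#'   Gaussian BIC attached.
#' @export
fit_weights_ml <- function(structure, data) {
  data <- as.matrix(data)
  k <- ncol(data)
  node_names <- colnames(data) %||% paste0("V", seq_len(k))
  pl <- as_parent_list(structure, k, node_names)
  s <- crossprod(data)
  n <- nrow(data)
  w <- matrix(0, k, k, dimnames = list(node_names, node_names))
  noise_sd <- numeric(k)
  for (j in seq_len(k)) {
    p <- pl[[j]]
    if (length(p)) {
      beta <- tryCatch(solve(s[p, p, drop = FALSE], s[p, j]),
                       error = function(e) stop("rank-deficient parent design for node ",
                                                node_names[j], call. = FALSE))
      w[p, j] <- beta
      rss <- s[j, j] - sum(s[p, j] * beta)
    } else rss <- s[j, j]
    noise_sd[j] <- sqrt(max(rss / n, 0))
  }
  dag_model(node_names, w, noise_sd = pmax(noise_sd, 1e-12),
            bic = gaussian_bic(pl, data))
}

#' Default configuration of the network learner
#'
#' @param lambda_grid Penalty grid for [lasso_parent_candidates()] (`NULL` =
#'   per-node default).
#' @param n_restarts Hill-climbing restarts (default 20).
#' @param seed Seed for the restart starting points.
#' @param alpha Significance level for [edge_group_stats()] (default 0.05).
#' @return A named list.
#' @export
bn_config <- function(lambda_grid = NULL, n_restarts = 20, seed = 1L,
                      alpha = 0.05) {
  list(lambda_grid = lambda_grid, n_restarts = n_restarts,
       seed = as.integer(seed), alpha = alpha)
}

#' Learn a Gaussian Bayesian network from standardized data
#'
#' Composition of the learning stages: lasso-path candidate-parent screening,
#' BIC-scored hill-climbing restricted to the candidate skeleton, and
#' maximum-likelihood weight estimation. The attained BIC is recorded in the
#' returned model.
#'
#' @param data N x K standardized matrix (see [standardize()]).
#' @param config A [bn_config()] list.
#' @return A `dag_model`.
#' @export
learn_bn <- function(data, config = bn_config()) {
  data <- as.matrix(data)
  cand <- lasso_candidates_all(data, config$lambda_grid)
  hc <- hill_climb_dag(data, candidates = cand,
                       n_restarts = config$n_restarts, seed = config$seed)
  fit_weights_ml(hc$parents, data)
}

#' Group-level Bayesian network for one condition
#'
#' Standardizes each of the condition's recordings individually, concatenates
#' the rows across subjects, and learns a single network from the pooled
#' matrix, so the group model has one weight per edge.
#'
#' @param cohort A `cohort`.
#' @param condition Condition label with at least one recording.
#' @param config A [bn_config()] list.
#' @return A `dag_model` over the cohort's nodes, in cohort node order.
#' @export
group_bn <- function(cohort, condition, config = bn_config()) {
  stopifnot(inherits(cohort, "cohort"))
  recs <- Filter(function(r) r$condition == condition, cohort$recordings)
  if (length(recs) == 0L)
    stop("no recordings for condition '", condition, "'")
  pooled <- do.call(rbind, lapply(recs, function(r) standardize(r$data)))
  learn_bn(pooled, config)
}

#' Per-recording directed-edge feature table
#'
#' Learns a full network from each recording's standardized data and flattens
#' its K x K weight matrix in source-major (row-major) order into one feature
#' row, giving K^2 directed-connectivity features per sample (81 for the
#' packaged nine nodes); absent edges contribute zeros and the diagonal is
#' identically zero.
#'
#' @param cohort A `cohort`.
#' @param config A [bn_config()] list.
#' @return An object of class `feature_table` with fields `matrix`
#'   ((number of recordings) x K^2), `condition`, `subject_id`,
#'   `node_names`, and `feature_key` (source/target per column).
#' @export
subject_feature_table <- function(cohort, config = bn_config()) {
  stopifnot(inherits(cohort, "cohort"))
  nodes <- cohort$node_names
  k <- length(nodes)
  feats <- t(vapply(cohort$recordings, function(r) {
    m <- learn_bn(standardize(r$data), config)
    as.vector(t(m$weights))
  }, numeric(k * k)))
  key <- expand.grid(target = nodes, source = nodes,
                     stringsAsFactors = FALSE)[, c("source", "target")]
  colnames(feats) <- paste0(key$source, "->", key$target)
  structure(
    list(matrix = feats,
         condition = vapply(cohort$recordings, function(r) r$condition, ""),
         subject_id = vapply(cohort$recordings, function(r) r$subject_id, ""),
         node_names = nodes, feature_key = key),
    class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d directed-edge features (%d nodes)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$node_names)))
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  cbind(data.frame(subject_id = x$subject_id, condition = x$condition,
                   stringsAsFactors = FALSE),
        as.data.frame(x$matrix))
}

#' Write a feature table as TSV
#'
#' @param features A `feature_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  utils::write.table(as.data.frame(features), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Cross-subject significance of each directed edge
#'
#' For every off-diagonal edge, a two-sided one-sample t-test of the
#' condition's subject weights against zero; an edge is significant when
#' p < alpha (uncorrected). A column with zero variance has no defined t: it
#' is reported with p = 1 when its mean is zero (edge absent everywhere) and
#' p = 0 when the weights are a nonzero constant.
#'
#' @param features A `feature_table`.
#' @param condition Condition label with at least 3 rows.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with columns `source`, `target`, `mean_weight`,
#'   `t_stat`, `p_value`, `significant`, one row per off-diagonal edge.
#' @export
edge_group_stats <- function(features, condition, alpha = 0.05) {
  stopifnot(inherits(features, "feature_table"))
  rows <- which(features$condition == condition)
  if (length(rows) < 3L)
    stop("need at least 3 recordings in condition '", condition, "'")
  key <- features$feature_key
  off <- which(key$source != key$target)
  res <- lapply(off, function(cidx) {
    v <- features$matrix[rows, cidx]
    if (stats::sd(v) < .Machine$double.eps * 100) {
      tv <- NA_real_
      p <- if (abs(mean(v)) < .Machine$double.eps * 100) 1 else 0
    } else {
      ht <- stats::t.test(v, mu = 0)
      tv <- unname(ht$statistic)
      p <- ht$p.value
    }
    data.frame(source = key$source[cidx], target = key$target[cidx],
               mean_weight = mean(v), t_stat = tv, p_value = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
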
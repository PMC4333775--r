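test_that("standardize gives population z-scores and validates input", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4, mean = 3, sd = 2), 200, 4,
              dimnames = list(NULL, paste0("n", 1:4)))
  z <- standardize(x)
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_lt(max(abs(sqrt(colMeans(z^2)) - 1)), 1e-10)
  expect_equal(standardize(z), z, tolerance = 1e-10)  # idempotent
  x[, 2] <- 5
  expect_error(standardize(x), "n2")
  expect_error(standardize(x[1:3, ]), "N > K")
})

test_that("gaussian_bic matches its closed form and an lm-based oracle", {
  set.seed(2)
  z1 <- standardize(matrix(rnorm(100), 100, 1))
  # empty graph, one standardized node, N = 100:
  # -(N/2)(1 + log 2 pi) - (1/2) log N
  expect_equal(gaussian_bic(list(integer(0)), z1),
               -(100 / 2) * (1 + log(2 * pi)) - 0.5 * log(100),
               tolerance = 1e-9)
  dag <- random_dag(5, seed = 14)
  z <- standardize(simulate_subject(dag, 400, jitter_sd = 0, seed = 3)$data)
  pl <- lapply(1:5, function(j) which(dag$weights[, j] != 0))
  expect_equal(gaussian_bic(pl, z), bic_oracle_lm(pl, z), tolerance = 1e-6)
  # decomposability: total = sum over single-family structures minus the
  # overcounted empty families
  fam <- vapply(1:5, function(j) {
    only_j <- replicate(5, integer(0), simplify = FALSE)
    only_j[[j]] <- pl[[j]]
    gaussian_bic(only_j, z) - gaussian_bic(replicate(5, integer(0),
                                                     simplify = FALSE), z) +
      gaussian_bic(list(integer(0)), z[, j, drop = FALSE])
  }, 0)
  expect_equal(sum(fam), gaussian_bic(pl, z), tolerance = 1e-6)
  expect_error(gaussian_bic(list(2L, 1L), standardize(matrix(rnorm(60), 30, 2))),
               "cycle")
})

test_that("a spurious parent lowers the BIC in nearly all replicates", {
  drops <- vapply(1:40, function(s) {
    set.seed(s)
    z <- standardize(matrix(rnorm(5000 * 2), 5000, 2))
    gaussian_bic(list(integer(0), 1L), z) < gaussian_bic(list(integer(0),
                                                              integer(0)), z)
  }, TRUE)
  expect_gte(mean(drops), 0.95)
})

test_that("lasso-path screening recovers true parents and prunes noise", {
  # pure-noise target: the null support wins
  set.seed(4)
  z <- standardize(matrix(rnorm(5000 * 4), 5000, 4))
  expect_length(lasso_parent_candidates(z, 4), 0)
  # x3 = 0.8 x1 + noise: screening must return exactly {x1}, which the
  # exhaustive subset-BIC oracle over all 2^(K-1) supports confirms
  set.seed(5)
  x <- matrix(rnorm(5000 * 4), 5000, 4)
  x[, 3] <- 0.8 * x[, 1] + rnorm(5000)
  z <- standardize(x)
  got <- lasso_parent_candidates(z, 3)
  subsets <- unlist(lapply(0:3, function(m)
    combn(c(1, 2, 4), m, simplify = FALSE)), recursive = FALSE)
  oracle_scores <- vapply(subsets, function(p) {
    pl <- replicate(4, integer(0), simplify = FALSE)
    pl[[3]] <- as.integer(p)
    gaussian_bic(pl, z)
  }, 0)
  expect_equal(got, as.integer(subsets[[which.max(oracle_scores)]]))
  expect_equal(got, 1L)
  # a grid holding only a super-critical penalty keeps the support empty
  lambda_max <- max(abs(crossprod(z[, -3], z[, 3]))) / nrow(z)
  expect_length(lasso_parent_candidates(z, 3, lambda_grid = 2 * lambda_max), 0)
  expect_error(lasso_parent_candidates(z, 3, lambda_grid = c(0.1, 0.2)),
               "descending")
})

test_that("hill-climbing finds the empty graph on independent noise", {
  set.seed(6)
  z <- standardize(matrix(rnorm(5000 * 5), 5000, 5))
  hc <- hill_climb_dag(z, n_restarts = 5, seed = 1)
  expect_true(all(!hc$adjacency))
  expect_equal(hc$bic, gaussian_bic(replicate(5, integer(0), simplify = FALSE),
                                    z))
})

test_that("hill-climbing returns an acyclic local optimum, deterministically", {
  dag <- random_dag(5, seed = 30)
  z <- standardize(simulate_subject(dag, 800, jitter_sd = 0, seed = 31)$data)
  hc <- hill_climb_dag(z, n_restarts = 10, seed = 2)
  expect_true(is_acyclic(hc$adjacency))
  expect_identical(hill_climb_dag(z, n_restarts = 10, seed = 2)$parents,
                   hc$parents)
  # no single add / delete / reverse move improves the returned structure
  k <- 5
  adj <- hc$adjacency
  deltas <- c()
  for (i in 1:k) for (j in 1:k) {
    if (i == j) next
    if (!adj[i, j] && !adj[j, i]) {
      a2 <- adj; a2[i, j] <- TRUE
      if (is_acyclic(a2)) deltas <- c(deltas, gaussian_bic(a2, z))
    } else if (adj[i, j]) {
      a2 <- adj; a2[i, j] <- FALSE
      deltas <- c(deltas, gaussian_bic(a2, z))
      a3 <- a2; a3[j, i] <- TRUE
      if (is_acyclic(a3)) deltas <- c(deltas, gaussian_bic(a3, z))
    }
  }
  expect_true(all(deltas <= hc$bic + 1e-6))
  # the attained score is never below the empty-graph start
  expect_gte(hc$bic, gaussian_bic(replicate(k, integer(0), simplify = FALSE), z))
})

test_that("candidate restriction confines the learned edges", {
  dag <- random_dag(4, seed = 40)
  z <- standardize(simulate_subject(dag, 600, jitter_sd = 0, seed = 41)$data)
  cand <- list(integer(0), 1L, integer(0), integer(0))  # only 1 -> 2 allowed
  hc <- hill_climb_dag(z, candidates = cand, n_restarts = 3, seed = 1)
  allowed <- matrix(FALSE, 4, 4); allowed[1, 2] <- allowed[2, 1] <- TRUE
  expect_true(all(!hc$adjacency | allowed))
  expect_error(hill_climb_dag(z, candidates = list(1L, 1L, 2L, 3L)),
               "own candidate parent")
})

test_that("ML weights reproduce exact and population coefficients", {
  # noiseless linear relation is interpolated to machine precision
  x1 <- rnorm(50)
  z <- cbind(a = x1, b = 0.7 * x1)
  m <- fit_weights_ml(list(integer(0), 1L), z)
  expect_equal(m$weights["a", "b"], 0.7, tolerance = 1e-12)
  # empty structure: zero weights, unit ML noise on standardized data
  zz <- standardize(matrix(rnorm(500 * 3), 500, 3))
  m0 <- fit_weights_ml(replicate(3, integer(0), simplify = FALSE), zz)
  expect_true(all(m0$weights == 0))
  expect_equal(unname(m0$noise_sd), rep(1, 3), tolerance = 1e-9)
  # large-sample weights match the oracle population standardized
  # coefficients from the implied covariance
  dag <- load_ground_truth("EC")
  zl <- standardize(simulate_subject(dag, 50000, jitter_sd = 0, seed = 8)$data)
  fit <- fit_weights_ml(dag$weights, zl)
  expect_lt(max(abs(fit$weights - population_std_coefs(dag))), 0.02)
})

test_that("learn_bn recovers the generating equivalence class", {
  dag <- load_ground_truth("EC")
  z <- standardize(simulate_subject(dag, 4600, jitter_sd = 0, seed = 1)$data)
  m <- learn_bn(z)
  expect_true(cpdag_equal(m, dag))
  expect_gte(m$bic, gaussian_bic(replicate(9, integer(0), simplify = FALSE), z))
  # independent noise gives the empty model
  set.seed(9)
  z0 <- standardize(matrix(rnorm(5000 * 4), 5000, 4,
                           dimnames = list(NULL, paste0("n", 1:4))))
  expect_true(all(learn_bn(z0)$weights == 0))
})

test_that("group networks pool subjects and keep the cohort node order", {
  ec <- load_ground_truth("EC")
  eo <- load_ground_truth("EO")
  coh <- simulate_cohort(ec, eo, n_subjects = 20, n_timepoints = 230,
                         jitter_sd = 0.1, master_seed = 1)
  m <- group_bn(coh, "EC")
  expect_identical(m$node_names, coh$node_names)
  # the five strong edges shared by both conditions are all recovered
  strong <- rbind(c("SN", "aDMN"), c("SN", "pDMN"), c("HVN", "PVN"),
                  c("PSMN", "PVN"), c("aDMN", "DAN"))
  expect_true(all(m$weights[strong] != 0))
  expect_error(group_bn(coh, "REM"), "no recordings")
})

test_that("subject feature tables have the 81-column directed layout", {
  ec <- load_ground_truth("EC")
  eo <- load_ground_truth("EO")
  coh <- simulate_cohort(ec, eo, n_subjects = 3, n_timepoints = 120,
                         master_seed = 4)
  cfg <- bn_config(n_restarts = 5)
  ft <- subject_feature_table(coh, cfg)
  expect_equal(dim(ft$matrix), c(6, 81))
  # diagonal columns are identically zero
  diag_cols <- which(ft$feature_key$source == ft$feature_key$target)
  expect_length(diag_cols, 9)
  expect_true(all(ft$matrix[, diag_cols] == 0))
  # layout contract: column of (source s, target t) is 9 (s - 1) + t
  s <- "SN"; tg <- "aDMN"
  idx <- 9 * (match(s, coh$node_names) - 1) + match(tg, coh$node_names)
  expect_equal(colnames(ft$matrix)[idx], "SN->aDMN")
  expect_equal(ft$feature_key$source[idx], s)
  expect_equal(ft$feature_key$target[idx], tg)
  # identical recordings give identical feature rows
  r <- coh$recordings[[1]]
  r2 <- r; r2$subject_id <- "clone"
  coh2 <- cohort_dataset(c(coh$recordings[1:2],
                           list(r2, within_cond <- local({
                             x <- coh$recordings[[2]]; x$subject_id <- "clone"; x
                           }))))
  ft2 <- subject_feature_table(coh2, cfg)
  expect_identical(ft2$matrix[1, ], ft2$matrix[3, ])
})

test_that("edge significance handles degenerate columns by the stated rules", {
  ec <- load_ground_truth("EC")
  key <- expand.grid(target = ec$node_names, source = ec$node_names,
                     stringsAsFactors = FALSE)[, c("source", "target")]
  mat <- matrix(0, 20, 81, dimnames = list(NULL,
                paste0(key$source, "->", key$target)))
  set.seed(10)
  mat[, 2] <- 1 + rnorm(20, sd = 1e-4)   # near-constant strong edge
  mat[, 3] <- rnorm(20, sd = 1)          # centred noise
  mat[, 4] <- 0.5                        # exactly constant nonzero
  ft <- structure(list(matrix = mat, condition = rep("EC", 20),
                       subject_id = sprintf("s%02d", 1:20),
                       node_names = ec$node_names, feature_key = key),
                  class = "feature_table")
  st <- edge_group_stats(ft, "EC", alpha = 0.05)
  expect_equal(nrow(st), 72)  # off-diagonal edges only
  all_zero <- st[st$source == key$source[10] & st$target == key$target[10], ]
  expect_equal(all_zero$p_value, 1)
  expect_false(all_zero$significant)
  expect_true(st$significant[st$source == key$source[2] &
                               st$target == key$target[2]])
  expect_equal(st$p_value[st$source == key$source[4] &
                            st$target == key$target[4]], 0)
  # significance flag is exactly p < alpha
  expect_identical(st$significant, st$p_value < 0.05)
  st0 <- edge_group_stats(ft, "EC", alpha = 0)
  expect_false(any(st0$significant))
  ft$condition <- c(rep("EC", 2), rep("EO", 18))
  expect_error(edge_group_stats(ft, "EC"), "at least 3")
})
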
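#' Construct a node time-series recording
#'
#' @param data T x K numeric matrix (timepoints x nodes), with column names.
#' @param subject_id Subject label.
#' @param condition Condition label (`"EC"` or `"EO"` in this package's
#'   experiments, but any label is accepted).
#' @param tr Repetition time in seconds between rows (default 2).
#' @return An object of class `ts_matrix`.
#' @export
ts_matrix <- function(data, subject_id = "s01", condition = "EC", tr = 2) {
  data <- as.matrix(data)
  if (!is.numeric(data) || nrow(data) < 2L)
    stop("'data' must be a numeric matrix with at least 2 timepoints")
  if (any(!is.finite(data))) stop("'data' must be finite")
  if (!is.numeric(tr) || tr <= 0) stop("'tr' must be a positive number")
  structure(
    list(data = data, subject_id = as.character(subject_id),
         condition = as.character(condition), tr = as.numeric(tr)),
    class = "ts_matrix"
  )
}

#' @exportS3Method base::print
print.ts_matrix <- function(x, ...) {
  cat(sprintf("<ts_matrix> subject %s, condition %s: %d timepoints x %d nodes, TR = %gs\n",
              x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Implied covariance of a linear-Gaussian structural equation model
#'
#' For `x = W' x + e` with independent `e_j ~ N(0, noise_sd_j^2)`, the
#' stationary covariance is `(I - W')^{-1} D (I - W')^{-T}` with
#' `D = diag(noise_sd^2)`.
#'
#' @param dag A `dag_model`.
#' @return K x K covariance matrix with node dimnames.
#' @export
implied_covariance <- function(dag) {
  stopifnot(inherits(dag, "dag_model"))
  k <- length(dag$node_names)
  m <- solve(diag(k) - t(dag$weights))
  sigma <- m %*% diag(dag$noise_sd^2, k) %*% t(m)
  dimnames(sigma) <- list(dag$node_names, dag$node_names)
  sigma
}

# Jitter nonzero weights by independent Gaussian perturbations; structure
# (and hence acyclicity) is unchanged.
jitter_weights <- function(weights, jitter_sd) {
  nz <- which(weights != 0)
  if (jitter_sd > 0 && length(nz))
    weights[nz] <- weights[nz] + stats::rnorm(length(nz), 0, jitter_sd)
  weights
}

#' Simulate one subject's recording from a linear-Gaussian SEM
#'
#' Draws subject-specific weights as `dag$weights` plus independent Gaussian
#' perturbations (sd `jitter_sd`) on the nonzero entries only, then generates
#' each time sample independently in topological order as
#' `x_j = sum_i w_ij x_i + e_j`, `e_j ~ N(0, noise_sd_j^2)`. With
#' `ar_coef > 0` the noise of each node is an AR(1) process with that lag-one
#' coefficient, scaled to the same stationary variance, to emulate the
#' temporal autocorrelation of real recordings that the i.i.d. model ignores.
#'
#' @param dag A `dag_model`.
#' @param n_timepoints Number of samples T (>= 2).
#' @param jitter_sd Standard deviation of the per-subject weight perturbation
#'   (default 0.1; 0 disables jitter).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param subject_id,condition Labels attached to the recording.
#' @param tr Repetition time in seconds.
#' @param ar_coef AR(1) coefficient of the node noise processes in `[0, 1)`;
#'   default 0 (independent samples, the model the network learner assumes).
#' @return A `ts_matrix` of dimension `n_timepoints` x K.
#' @export
simulate_subject <- function(dag, n_timepoints, jitter_sd = 0.1, seed = 1L,
                             subject_id = "s01", condition = "EC", tr = 2,
                             ar_coef = 0) {
  stopifnot(inherits(dag, "dag_model"))
  if (!is.numeric(n_timepoints) || n_timepoints < 2L)
    stop("'n_timepoints' must be at least 2")
  if (jitter_sd < 0) stop("'jitter_sd' must be non-negative")
  if (ar_coef < 0 || ar_coef >= 1) stop("'ar_coef' must be in [0, 1)")
  n_timepoints <- as.integer(n_timepoints)
  k <- length(dag$node_names)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  w <- jitter_weights(dag$weights, jitter_sd)
  eps <- matrix(stats::rnorm(n_timepoints * k), n_timepoints, k)
  eps <- sweep(eps, 2L, dag$noise_sd, `*`)
  if (ar_coef > 0) {
    # filter() gives sum phi^i eta_{t-i}; rescale to stationary variance
    eps <- apply(eps, 2L, function(e)
      as.numeric(stats::filter(e, ar_coef, method = "recursive"))) *
      sqrt(1 - ar_coef^2)
  }
  x <- matrix(0, n_timepoints, k)
  for (j in topological_order(w != 0)) {
    parents <- which(w[, j] != 0)
    x[, j] <- eps[, j]
    if (length(parents))
      x[, j] <- x[, j] + x[, parents, drop = FALSE] %*% w[parents, j]
  }
  colnames(x) <- dag$node_names
  ts_matrix(x, subject_id = subject_id, condition = condition, tr = tr)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Construct a cohort dataset
#'
#' @param recordings List of `ts_matrix` objects. Every subject must appear
#'   exactly once per condition and all recordings must share node set and TR.
#' @return An object of class `cohort`.
#' @export
cohort_dataset <- function(recordings) {
  if (!length(recordings) || !all(vapply(recordings, inherits, TRUE, "ts_matrix")))
    stop("'recordings' must be a non-empty list of ts_matrix objects")
  nodes <- colnames(recordings[[1L]]$data)
  trs <- vapply(recordings, function(r) r$tr, 0)
  if (length(unique(trs)) != 1L) stop("all recordings must share the same TR")
  for (r in recordings)
    if (!identical(colnames(r$data), nodes))
      stop("all recordings must share the same node set and order")
  key <- table(vapply(recordings, function(r) r$subject_id, ""),
               vapply(recordings, function(r) r$condition, ""))
  if (any(key != 1L))
    stop("every subject must appear exactly once per condition")
  structure(list(recordings = recordings, node_names = nodes),
            class = "cohort")
}

#' @exportS3Method base::print
print.cohort <- function(x, ...) {
  conds <- vapply(x$recordings, function(r) r$condition, "")
  cat(sprintf("<cohort> %d recordings (%s), %d nodes\n",
              length(x$recordings),
              paste(sprintf("%d %s", as.integer(table(conds)),
                            names(table(conds))), collapse = ", "),
              length(x$node_names)))
  invisible(x)
}

#' Simulate a two-condition cohort
#'
#' Generates `n_subjects` recordings per condition from the two
#' condition-specific ground-truth DAGs. Each recording uses an independently
#' jittered weight draw; per-recording seeds are derived from `master_seed` by
#' seeding R's generator with it and drawing `2 * n_subjects` sub-seeds, so the
#' whole cohort is reproducible from the single master seed.
#'
#' @param dag_ec,dag_eo `dag_model`s sharing the same node names (the two
#'   conditions' ground truths; conventionally EC and EO).
#' @param n_subjects Number of subjects (default 20).
#' @param n_timepoints Samples per recording (default 230, i.e. 240 acquired
#'   volumes minus the 10 discarded at the start).
#' @param jitter_sd Per-subject weight jitter (default 0.1).
#' @param master_seed Integer master seed.
#' @param tr Repetition time in seconds (default 2).
#' @param ar_coef AR(1) noise coefficient passed to [simulate_subject()].
#' @return A `cohort` with `2 * n_subjects` recordings.
#' @export
simulate_cohort <- function(dag_ec, dag_eo, n_subjects = 20,
                            n_timepoints = 230, jitter_sd = 0.1,
                            master_seed = 1L, tr = 2, ar_coef = 0) {
  stopifnot(inherits(dag_ec, "dag_model"), inherits(dag_eo, "dag_model"))
  if (!identical(dag_ec$node_names, dag_eo$node_names))
    stop("the two ground-truth DAGs must share node names and order")
  if (n_subjects < 1L) stop("'n_subjects' must be at least 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(.Machine$integer.max, 2L * n_subjects)
  dags <- list(EC = dag_ec, EO = dag_eo)
  recordings <- vector("list", 2L * n_subjects)
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (ci in 1:2) {
      cond <- names(dags)[ci]
      i <- i + 1L
      recordings[[i]] <- simulate_subject(
        dags[[ci]], n_timepoints, jitter_sd = jitter_sd, seed = seeds[i],
        subject_id = sprintf("s%02d", s), condition = cond, tr = tr,
        ar_coef = ar_coef)
    }
  }
  cohort_dataset(recordings)
}
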
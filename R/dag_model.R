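#' Construct a weighted directed acyclic graph model
#'
#' A `dag_model` holds a linear-Gaussian Bayesian network over a set of named
#' nodes: a K x K weight matrix whose entry `(i, j)` is the coefficient of the
#' directed edge `i -> j` (zero means no edge), a per-node residual standard
#' deviation, and optionally the BIC score under which the structure was
#' selected.
#'
#' @param node_names Character vector of unique node labels (length K).
#' @param weights K x K numeric matrix; `weights[i, j]` is the coefficient of
#'   edge `i -> j`. The diagonal must be zero and the nonzero pattern acyclic.
#' @param noise_sd Numeric vector of K strictly positive residual standard
#'   deviations (recycled if length 1).
#' @param bic Optional numeric score attached to the model.
#' @return An object of class `dag_model`.
#' @export
dag_model <- function(node_names, weights, noise_sd = 1, bic = NULL) {
  node_names <- as.character(node_names)
  k <- length(node_names)
  if (k < 1L) stop("at least one node is required")
  if (anyDuplicated(node_names)) stop("node names must be unique")
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != k || ncol(weights) != k)
    stop("'weights' must be a numeric ", k, " x ", k, " matrix")
  if (any(!is.finite(weights))) stop("'weights' must be finite")
  if (any(diag(weights) != 0)) stop("diagonal of 'weights' must be zero")
  noise_sd <- rep_len(as.numeric(noise_sd), k)
  if (any(!is.finite(noise_sd)) || any(noise_sd <= 0))
    stop("'noise_sd' must be strictly positive")
  dimnames(weights) <- list(node_names, node_names)
  if (is.null(topological_order(weights != 0)))
    stop("the directed graph of nonzero weights contains a cycle")
  structure(
    list(node_names = node_names, weights = weights,
         noise_sd = stats::setNames(noise_sd, node_names), bic = bic),
    class = "dag_model"
  )
}

#' @exportS3Method base::print
print.dag_model <- function(x, ...) {
  ne <- sum(x$weights != 0)
  cat(sprintf("<dag_model> %d nodes, %d directed edges", length(x$node_names), ne))
  if (!is.null(x$bic)) cat(sprintf(", BIC = %.3f", x$bic))
  cat("\n")
  if (ne > 0) {
    e <- dag_edge_list(x)
    print(e, row.names = FALSE)
  }
  invisible(x)
}

#' Edge list of a dag_model
#'
#' @param dag A `dag_model`.
#' @return Data frame with columns `source`, `target`, `weight`, one row per
#'   nonzero edge, ordered by (source, target) node index.
#' @export
dag_edge_list <- function(dag) {
  stopifnot(inherits(dag, "dag_model"))
  idx <- which(dag$weights != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(
    source = dag$node_names[idx[, 1L]],
    target = dag$node_names[idx[, 2L]],
    weight = dag$weights[idx],
    stringsAsFactors = FALSE
  )
}

#' Topological order of a directed graph
#'
#' Kahn's algorithm on a logical/numeric adjacency matrix (`A[i, j]` nonzero
#' means an edge `i -> j`).
#'
#' @param adj Square adjacency matrix.
#' @return Integer vector of node indices in topological order (parents before
#'   children), or `NULL` if the graph has a directed cycle.
#' @export
topological_order <- function(adj) {
  adj <- adj != 0
  k <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  remaining <- rep(TRUE, k)
  while (length(order) < k) {
    ready <- which(remaining & indeg == 0)
    if (length(ready) == 0L) return(NULL)
    v <- ready[1L]
    order <- c(order, v)
    remaining[v] <- FALSE
    indeg <- indeg - adj[v, ]
    indeg[v] <- Inf
  }
  order
}

#' Test a directed graph for acyclicity
#'
#' @param adj Square adjacency (or weight) matrix.
#' @return `TRUE` if the nonzero pattern is a DAG.
#' @export
is_acyclic <- function(adj) !is.null(topological_order(adj))

#' Load a packaged ground-truth network
#'
#' The package ships the two condition-specific directed networks over the nine
#' resting-state network nodes (PVN, HVN, PSMN, VMN, DAN, CEN, aDMN, pDMN, SN)
#' as tab-separated edge lists. This loads one of them as a `dag_model` with
#' unit residual standard deviations.
#'
#' @param condition `"EC"` (eyes closed) or `"EO"` (eyes open).
#' @param noise_sd Residual standard deviation(s) to attach (default 1).
#' @return A `dag_model` over the nine nodes, in the packaged node order.
#' @export
load_ground_truth <- function(condition, noise_sd = 1) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("EC", "EO"))
    stop("unknown condition label: must be \"EC\" or \"EO\"", call. = FALSE)
  fixture <- system.file("extdata",
                         sprintf("bn_edges_%s.tsv", tolower(condition)),
                         package = "restbn")
  if (fixture == "" || !file.exists(fixture))
    stop("ground-truth fixture file not found for condition ", condition,
         call. = FALSE)
  nodes <- read_node_definitions(
    system.file("extdata", "rsn_nodes.tsv", package = "restbn"))
  read_dag_tsv(fixture, node_names = nodes$name, noise_sd = noise_sd)
}

#' Read a DAG from a tab-separated edge list
#'
#' @param path TSV file with header `source  target  weight`.
#' @param node_names Node order for the resulting weight matrix; defaults to
#'   order of first appearance in the file.
#' @param noise_sd Residual standard deviation(s) (default 1).
#' @return A `dag_model`.
#' @export
read_dag_tsv <- function(path, node_names = NULL, noise_sd = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "weight")
  miss <- setdiff(need, names(e))
  if (length(miss)) stop("edge list is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(node_names))
    node_names <- unique(c(rbind(e$source, e$target)))
  bad <- setdiff(unique(c(e$source, e$target)), node_names)
  if (length(bad)) stop("edge list refers to unknown node(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  k <- length(node_names)
  w <- matrix(0, k, k, dimnames = list(node_names, node_names))
  w[cbind(match(e$source, node_names), match(e$target, node_names))] <- e$weight
  dag_model(node_names, w, noise_sd = noise_sd)
}

#' Write a dag_model (optionally with edge statistics) as a TSV edge list
#'
#' @param dag A `dag_model`.
#' @param path Output file.
#' @param stats Optional data frame of per-edge statistics (from
#'   [edge_group_stats()]); matched on `(source, target)` and merged in.
#' @return `path`, invisibly.
#' @export
write_dag_tsv <- function(dag, path, stats = NULL) {
  e <- dag_edge_list(dag)
  if (!is.null(stats)) {
    key <- paste(e$source, e$target)
    skey <- paste(stats$source, stats$target)
    e$p_value <- stats$p_value[match(key, skey)]
    e$significant <- stats$significant[match(key, skey)]
  }
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
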
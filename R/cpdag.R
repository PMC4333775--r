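#' CPDAG (Markov equivalence class) of a DAG
#'
#' Two DAGs are Markov equivalent iff they share the same skeleton and the
#' same v-structures (colliders `i -> k <- j` with `i`, `j` non-adjacent).
#' This returns that characterisation directly: the undirected skeleton edge
#' set and the set of v-structures, which together identify the equivalence
#' class.
#'
#' @param x A `dag_model`, adjacency/weight matrix, or parent list.
#' @param k Number of nodes (needed only for a parent-list input).
#' @return List with `skeleton` (2-column matrix of node index pairs, smaller
#'   index first, sorted) and `vstructures` (3-column matrix `i, k, j` with
#'   `i < j`, sorted).
#' @export
cpdag <- function(x, k = NULL) {
  if (inherits(x, "dag_model")) {
    adj <- x$weights != 0
  } else if (is.matrix(x)) {
    adj <- x != 0
  } else {
    if (is.null(k)) k <- length(x)
    adj <- matrix(FALSE, k, k)
    for (j in seq_len(k)) adj[as.integer(x[[j]]), j] <- TRUE
  }
  if (!is_acyclic(adj)) stop("input graph is not acyclic")
  kk <- nrow(adj)
  und <- adj | t(adj)
  skel <- which(und & upper.tri(und), arr.ind = TRUE)
  skel <- skel[order(skel[, 1L], skel[, 2L]), , drop = FALSE]
  colnames(skel) <- c("a", "b")
  vs <- list()
  for (child in seq_len(kk)) {
    parents <- which(adj[, child])
    if (length(parents) >= 2L) {
      for (a in seq_along(parents)) for (b in seq_along(parents)) {
        if (a < b && !und[parents[a], parents[b]])
          vs[[length(vs) + 1L]] <- c(parents[a], child, parents[b])
      }
    }
  }
  vs <- if (length(vs)) do.call(rbind, vs) else matrix(integer(0), 0L, 3L)
  vs <- vs[order(vs[, 1L], vs[, 2L], vs[, 3L]), , drop = FALSE]
  colnames(vs) <- c("i", "k", "j")
  list(skeleton = skel, vstructures = vs)
}

#' Test two DAGs for Markov equivalence
#'
#' @param x,y DAGs in any form accepted by [cpdag()].
#' @param k Number of nodes for parent-list input.
#' @return `TRUE` iff the two graphs have identical skeletons and
#'   v-structures.
#' @export
cpdag_equal <- function(x, y, k = NULL) {
  a <- cpdag(x, k)
  b <- cpdag(y, k)
  identical(unname(a$skeleton), unname(b$skeleton)) &&
    identical(unname(a$vstructures), unname(b$vstructures))
}

#' Structural Hamming distance between two directed graphs
#'
#' Counts edge slots that differ: an edge present in one graph and absent in
#' the other counts 1, an edge present in both but reversed counts 1.
#'
#' @param x,y DAGs in any form accepted by [cpdag()].
#' @param k Number of nodes for parent-list input.
#' @return Non-negative integer distance.
#' @export
shd <- function(x, y, k = NULL) {
  to_adj <- function(g) {
    if (inherits(g, "dag_model")) return(g$weights != 0)
    if (is.matrix(g)) return(g != 0)
    kk <- k %||% length(g)
    adj <- matrix(FALSE, kk, kk)
    for (j in seq_len(kk)) adj[as.integer(g[[j]]), j] <- TRUE
    adj
  }
  a <- to_adj(x); b <- to_adj(y)
  ua <- a | t(a); ub <- b | t(b)
  skel_diff <- sum((ua != ub)[upper.tri(ua)])
  both <- ua & ub
  rev_diff <- sum((a != b & both)[upper.tri(both)])
  skel_diff + rev_diff
}
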
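#' Read node definitions from a TSV table
#'
#' Expects a tab-separated file with header columns `name`, `x`, `y`, `z`
#' (MNI millimetres) and optionally `radius_mm`; extra columns are carried
#' through untouched. When `radius_mm` is absent, the default 6 mm sphere
#' radius is applied with a notice.
#'
#' @param path TSV file.
#' @param default_radius_mm Radius applied when the column is missing
#'   (default 6).
#' @return Data frame with one row per node, validated (unique names, numeric
#'   finite coordinates, positive radii), plus attribute `"nodes"`: the list
#'   of [node_def()] objects in file order.
#' @export
read_node_definitions <- function(path, default_radius_mm = 6) {
  if (!file.exists(path)) stop("node table not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "x", "y", "z"), names(d))
  if (length(miss))
    stop("node table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(d$name))
    stop("duplicate node name(s): ",
         paste(unique(d$name[duplicated(d$name)]), collapse = ", "),
         call. = FALSE)
  for (cc in c("x", "y", "z")) {
    v <- d[[cc]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("non-numeric or missing coordinate in column '", cc, "'",
           call. = FALSE)
  }
  if (is.null(d$radius_mm)) {
    message("node table has no 'radius_mm' column; using default ",
            default_radius_mm, " mm")
    d$radius_mm <- default_radius_mm
  }
  if (!is.numeric(d$radius_mm) || any(!is.finite(d$radius_mm)) ||
      any(d$radius_mm <= 0))
    stop("'radius_mm' must be positive and finite", call. = FALSE)
  attr(d, "nodes") <- lapply(seq_len(nrow(d)), function(i)
    node_def(d$name[i], c(d$x[i], d$y[i], d$z[i]), d$radius_mm[i]))
  d
}

#' The packaged nine resting-state network node definitions
#'
#' Sphere nodes at the peak MNI coordinates of the nine resting-state
#' networks used throughout the package (primary/high-level visual, primary
#' sensory-motor, ventral motor, dorsal attention, central executive,
#' anterior/posterior default-mode, and salience networks).
#'
#' @param radius_mm Optional radius override applied to every node.
#' @return List of `node_def` objects in the packaged order.
#' @export
packaged_nodes <- function(radius_mm = NULL) {
  d <- read_node_definitions(
    system.file("extdata", "rsn_nodes.tsv", package = "restbn"))
  nodes <- attr(d, "nodes")
  if (!is.null(radius_mm))
    nodes <- lapply(nodes, function(n) node_def(n$name, n$center_mm, radius_mm))
  nodes
}
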
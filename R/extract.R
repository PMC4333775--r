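#' Image grid geometry
#'
#' A grid couples integer voxel dimensions with a voxel-to-millimetre affine.
#' Voxel indices are 0-based in the affine convention: millimetre position of
#' voxel `(i, j, k)` is `affine %*% c(i, j, k, 1)`.
#'
#' @param dim Integer vector of 3 voxel counts.
#' @param affine 4 x 4 voxel-to-mm matrix.
#' @return An object of class `img_grid`.
#' @export
img_grid <- function(dim, affine) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("'dim' must be 3 positive counts")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4 x 4")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("'affine' must be invertible")
  structure(list(dim = dim, affine = affine), class = "img_grid")
}

#' Default MNI-space grid at 3 mm isotropic resolution
#'
#' Covers MNI x in -90..90, y in -126..90, z in -72..108 with 3 mm voxels
#' (61 x 73 x 61), voxel centres on multiples of 3 mm.
#'
#' @return An `img_grid`.
#' @export
default_mni_grid <- function() {
  aff <- diag(c(3, 3, 3, 1))
  aff[1:3, 4L] <- c(-90, -126, -72)
  img_grid(c(61L, 73L, 61L), aff)
}

#' Node definition for a sphere ROI
#'
#' @param name Node label.
#' @param center_mm Numeric length-3 MNI coordinate of the sphere centre (mm).
#' @param radius_mm Sphere radius in mm (> 0).
#' @return An object of class `node_def`.
#' @export
node_def <- function(name, center_mm, radius_mm = 6) {
  if (!is.numeric(center_mm) || length(center_mm) != 3L ||
      any(!is.finite(center_mm)))
    stop("'center_mm' must be 3 finite numbers")
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("'radius_mm' must be positive")
  structure(list(name = as.character(name), center_mm = as.numeric(center_mm),
                 radius_mm = as.numeric(radius_mm)),
            class = "node_def")
}

#' Voxels inside a node's sphere
#'
#' Returns the voxel indices whose centres (mapped through the affine) lie
#' within Euclidean distance `radius_mm` of the node centre. The mask may be
#' clipped by the grid boundary, but an entirely empty mask is an error.
#'
#' @param node A `node_def`.
#' @param grid An `img_grid`.
#' @return Integer matrix with one row per voxel and columns `i, j, k`
#'   (0-based voxel indices).
#' @export
sphere_mask <- function(node, grid) {
  stopifnot(inherits(node, "node_def"), inherits(grid, "img_grid"))
  inv <- solve(grid$affine)
  cvox <- (inv %*% c(node$center_mm, 1))[1:3]
  # candidate bounding box in voxel space, padded by the radius in voxels
  vox_size <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  pad <- ceiling(node$radius_mm / vox_size) + 1L
  rng <- function(d) max(0L, floor(cvox[d] - pad[d])):min(grid$dim[d] - 1L,
                                                          ceiling(cvox[d] + pad[d]))
  if (any(cvox + pad < 0) || any(cvox - pad > grid$dim - 1L))
    stop("sphere mask for node '", node$name, "' is empty: centre outside grid")
  cand <- as.matrix(expand.grid(i = rng(1L), j = rng(2L), k = rng(3L)))
  mm <- cand %*% t(grid$affine[1:3, 1:3])
  mm <- sweep(mm, 2L, grid$affine[1:3, 4L], `+`)
  d2 <- rowSums(sweep(mm, 2L, node$center_mm, `-`)^2)
  keep <- cand[d2 <= node$radius_mm^2 + 1e-9, , drop = FALSE]
  if (nrow(keep) == 0L)
    stop("sphere mask for node '", node$name, "' is empty: centre outside grid")
  storage.mode(keep) <- "integer"
  keep
}

#' Discard initial frames
#'
#' Removes the first `n_discard` timepoints of a recording (rows of a matrix
#' or `ts_matrix`, or volumes of a 4D array), preserving the order of the
#' rest. Recordings typically drop the first frames to let the signal reach
#' equilibrium.
#'
#' @param x Numeric matrix (T x K), `ts_matrix`, or 4D array (T on dim 4).
#' @param n_discard Number of initial frames to drop (`0 <= n_discard < T`).
#' @return The same kind of object with `T - n_discard` frames.
#' @export
discard_initial <- function(x, n_discard = 10) {
  if (n_discard < 0) stop("'n_discard' must be non-negative")
  n_discard <- as.integer(n_discard)
  if (inherits(x, "ts_matrix")) {
    x$data <- discard_initial(x$data, n_discard)
    return(x)
  }
  if (is.matrix(x) || is.data.frame(x)) {
    if (n_discard >= nrow(x))
      stop("'n_discard' (", n_discard, ") must be smaller than T (", nrow(x), ")")
    return(x[seq.int(n_discard + 1L, nrow(x)), , drop = FALSE])
  }
  if (is.array(x) && length(dim(x)) == 4L) {
    if (n_discard >= dim(x)[4L])
      stop("'n_discard' (", n_discard, ") must be smaller than T (", dim(x)[4L], ")")
    return(x[, , , seq.int(n_discard + 1L, dim(x)[4L]), drop = FALSE])
  }
  stop("'x' must be a matrix, ts_matrix, or 4D array")
}

#' Average sphere-ROI time series from a 4D image
#'
#' Column k at time t is the arithmetic mean of the image over the voxels in
#' node k's sphere mask at volume t.
#'
#' @param image 4D numeric array (x, y, z, t).
#' @param nodes List of `node_def`s.
#' @param grid An `img_grid` matching the image's spatial dimensions.
#' @param ... Passed to [ts_matrix()] (subject/condition labels, TR).
#' @return A `ts_matrix` of dimension T x length(nodes).
#' @export
extract_node_series <- function(image, nodes, grid, ...) {
  stopifnot(is.array(image), length(dim(image)) == 4L,
            inherits(grid, "img_grid"))
  if (!all(dim(image)[1:3] == grid$dim))
    stop("image spatial dimensions do not match the grid")
  tt <- dim(image)[4L]
  out <- matrix(NA_real_, tt, length(nodes))
  colnames(out) <- vapply(nodes, function(n) n$name, "")
  nvox <- prod(grid$dim)
  flat <- matrix(image, nrow = nvox, ncol = tt)
  for (k in seq_along(nodes)) {
    m <- sphere_mask(nodes[[k]], grid)
    lin <- 1L + m[, 1L] + grid$dim[1L] * (m[, 2L] + grid$dim[2L] * m[, 3L])
    out[, k] <- colMeans(flat[lin, , drop = FALSE])
  }
  ts_matrix(out, ...)
}

#' Band-pass specification
#'
#' @param f_lo,f_hi Pass-band edges in Hz, `0 <= f_lo < f_hi <= 1/(2 tr)`.
#' @param tr Sampling interval in seconds.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(f_lo = 0.01, f_hi = 0.08, tr = 2) {
  if (tr <= 0) stop("'tr' must be positive")
  nyq <- 1 / (2 * tr)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= nyq + 1e-12))
    stop(sprintf("band must satisfy 0 <= f_lo < f_hi <= Nyquist (%.4g Hz)", nyq))
  structure(list(f_lo = f_lo, f_hi = f_hi, tr = tr), class = "bandpass_spec")
}

#' Ideal band-pass filter of node time series
#'
#' Each column is linearly detrended, then filtered in the frequency domain by
#' an ideal rectangular filter that keeps exactly the discrete frequencies f
#' with `f_lo <= f <= f_hi` (band edges inclusive). Applied independently per
#' column. The operation is a projection, so applying it twice equals applying
#' it once.
#'
#' @param ts A `ts_matrix` or numeric T x K matrix (T >= 8).
#' @param spec A `bandpass_spec`; its `tr` must match the recording's.
#' @return Filtered object of the same kind.
#' @export
bandpass_filter <- function(ts, spec) {
  stopifnot(inherits(spec, "bandpass_spec"))
  if (inherits(ts, "ts_matrix")) {
    if (abs(ts$tr - spec$tr) > 1e-9)
      stop("TR of the band-pass spec does not match the recording")
    ts$data <- bandpass_filter(ts$data, spec)
    return(ts)
  }
  x <- as.matrix(ts)
  tt <- nrow(x)
  if (tt < 8L) stop("at least 8 timepoints are required for filtering")
  x <- detrend_linear(x)
  freqs <- seq.int(0L, tt - 1L) / (tt * spec$tr)
  freqs <- pmin(freqs, 1 / spec$tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= spec$f_lo - 1e-12 & freqs <= spec$f_hi + 1e-12
  bp <- function(m) {
    mf <- stats::mvfft(m)
    mf[!keep, ] <- 0
    Re(stats::mvfft(mf, inverse = TRUE)) / tt
  }
  y <- bp(x)
  # The composite map must be an orthogonal projection (so that filtering is
  # idempotent): remove from the band-limited signal its component along the
  # band-limited image of the linear ramp, which detrending would otherwise
  # re-remove on a second pass. The constant vector needs no such care (it is
  # pure DC and the DC bin is already excluded).
  ramp <- bp(matrix(seq_len(tt) - (tt + 1) / 2, tt, 1))
  nr2 <- sum(ramp^2)
  if (nr2 > 1e-12) y <- y - ramp %*% (crossprod(ramp, y) / nr2)
  y
}

# Remove per-column linear trend (least squares on 1, t).
detrend_linear <- function(x) {
  tt <- nrow(x)
  tc <- seq_len(tt) - (tt + 1) / 2
  x <- sweep(x, 2L, colMeans(x), `-`)
  slope <- crossprod(tc, x) / sum(tc^2)
  x - outer(tc, drop(slope))
}

#' Construct a nuisance confound table
#'
#' Nine columns: global mean, white-matter and CSF signals plus six rigid-body
#' motion parameters (translations in mm, rotations in degrees).
#'
#' @param data T x 9 numeric matrix or data frame. If unnamed, the standard
#'   column names are applied.
#' @return An object of class `confound_table` (a data frame).
#' @export
confound_table <- function(data) {
  data <- as.data.frame(data)
  if (ncol(data) != 9L) stop("a confound table must have exactly 9 columns")
  std <- c("global_mean", "white_matter", "csf",
           "trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  if (is.null(names(data)) || all(grepl("^V[0-9]+$", names(data))))
    names(data) <- std
  if (!all(vapply(data, is.numeric, TRUE))) stop("confounds must be numeric")
  class(data) <- c("confound_table", "data.frame")
  data
}

#' Flag recordings whose head motion exceeds exclusion criteria
#'
#' Checks the six motion columns of a confound table against maximum absolute
#' displacement (mm) and rotation (degrees) thresholds. The flag is reported
#' only; exclusion is the caller's decision.
#'
#' @param confounds A `confound_table`.
#' @param max_mm,max_deg Thresholds (defaults 1 mm, 1 degree).
#' @return `TRUE` if any motion trace exceeds its threshold.
#' @export
motion_exceeds <- function(confounds, max_mm = 1, max_deg = 1) {
  stopifnot(inherits(confounds, "confound_table"))
  trans <- as.matrix(confounds[, c("trans_x", "trans_y", "trans_z")])
  rot <- as.matrix(confounds[, c("rot_x", "rot_y", "rot_z")])
  any(abs(trans) > max_mm) || any(abs(rot) > max_deg)
}

#' Regress nuisance confounds out of node time series
#'
#' Each node column is replaced by its least-squares residual against an
#' intercept plus the confound columns. Collinear confound columns are dropped
#' with a warning before fitting.
#'
#' @param ts A `ts_matrix` or T x K matrix.
#' @param confounds A `confound_table` or T x q numeric matrix with matching
#'   row count.
#' @return Residualized object of the same kind as `ts`.
#' @export
regress_out <- function(ts, confounds) {
  if (inherits(ts, "ts_matrix")) {
    ts$data <- regress_out(ts$data, confounds)
    return(ts)
  }
  x <- as.matrix(ts)
  cf <- as.matrix(as.data.frame(confounds))
  if (nrow(cf) != nrow(x))
    stop("row counts of time series (", nrow(x), ") and confounds (",
         nrow(cf), ") differ")
  design <- cbind(intercept = 1, cf)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop_idx <- qrd$pivot[seq.int(qrd$rank + 1L, ncol(design))]
    warning("dropping collinear confound column(s): ",
            paste(colnames(design)[drop_idx], collapse = ", "))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
    qrd <- qr(design)
  }
  qr.resid(qrd, x)
}

#' Full node-extraction preprocessing pipeline
#'
#' Composition of the preprocessing stages: discard the initial frames, average
#' sphere-ROI series from the image (skipped when the input is already a node
#' matrix), band-pass filter both the node series and the confounds, and
#' regress the confounds out of the node series. Filtering the confounds with
#' the data keeps the regression from reintroducing stop-band energy.
#'
#' @param x 4D array (with `grid` and `nodes` supplied) or T x K node matrix /
#'   `ts_matrix`.
#' @param confounds Optional `confound_table` (or matrix) with T rows (before
#'   discard) or `T - n_discard` rows (already trimmed).
#' @param nodes,grid Node definitions and grid geometry, required for image
#'   input.
#' @param n_discard Initial frames to drop (default 10).
#' @param band `bandpass_spec`, `NULL` to skip filtering, or a length-2 numeric
#'   of band edges in Hz (default `c(0.01, 0.08)`).
#' @param tr Repetition time in seconds, used when `x` is not a `ts_matrix`.
#' @param do_regress Set `FALSE` to skip nuisance regression.
#' @param verbose Emit a per-stage dimension log via `message()`.
#' @param ... Labels passed to [extract_node_series()] for image input.
#' @return A `ts_matrix` of cleaned node time series.
#' @export
preprocess_pipeline <- function(x, confounds = NULL, nodes = NULL, grid = NULL,
                                n_discard = 10, band = c(0.01, 0.08), tr = 2,
                                do_regress = !is.null(confounds),
                                verbose = FALSE, ...) {
  say <- function(...) if (verbose) message(sprintf(...))
  if (is.array(x) && length(dim(x)) == 4L) {
    if (is.null(nodes) || is.null(grid))
      stop("'nodes' and 'grid' are required for image input")
    x <- discard_initial(x, n_discard)
    say("discard: %d volumes remain", dim(x)[4L])
    ts <- extract_node_series(x, nodes, grid, tr = tr, ...)
    say("extract: %d x %d node matrix", nrow(ts$data), ncol(ts$data))
  } else {
    ts <- if (inherits(x, "ts_matrix")) x else ts_matrix(x, tr = tr, ...)
    ts <- discard_initial(ts, n_discard)
    say("discard: %d timepoints remain", nrow(ts$data))
  }
  tt <- nrow(ts$data)
  if (!is.null(confounds)) {
    cf <- as.matrix(as.data.frame(confounds))
    if (nrow(cf) == tt + n_discard) cf <- discard_initial(cf, n_discard)
    if (nrow(cf) != tt)
      stop("confound rows (", nrow(cf), ") match neither T nor T - n_discard")
  }
  if (!is.null(band)) {
    spec <- if (inherits(band, "bandpass_spec")) band
            else bandpass_spec(band[1L], band[2L], tr = ts$tr)
    ts <- bandpass_filter(ts, spec)
    if (!is.null(confounds)) cf <- bandpass_filter(cf, spec)
    say("bandpass: %.3g-%.3g Hz", spec$f_lo, spec$f_hi)
  }
  if (do_regress && !is.null(confounds)) {
    ts <- regress_out(ts, cf)
    say("regress: removed %d confounds", ncol(cf))
  }
  ts
}
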
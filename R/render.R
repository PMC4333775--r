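#' Render node time series into a toy 4D volume
#'
#' Builds a synthetic 4D image in which every voxel inside node k's sphere
#' carries `background noise + ts[t, k]` and all other voxels carry background
#' Gaussian noise only, together with a 9-column synthetic confound table
#' (three tissue signals and six motion traces). The result exercises the
#' sphere-extraction path without any real imaging data.
#'
#' @param ts A `ts_matrix` whose columns match `nodes` in order.
#' @param nodes List of `node_def`s; every sphere must fit inside the grid.
#' @param grid An `img_grid` (default [default_mni_grid()] is usually far
#'   larger than needed; pass a small grid for tests).
#' @param background_sd Standard deviation of the i.i.d. background noise
#'   (0 gives a noiseless image).
#' @param seed Integer seed for background noise and confound traces.
#' @param n_volumes Expected number of volumes; must equal `nrow(ts$data)`
#'   when given (shape guard for callers that know T independently).
#' @param file Optional path; when given, the image is also written as
#'   NIfTI-1 (`.nii` or `.nii.gz`) with the grid affine, and the confounds as
#'   a TSV alongside (same stem, `_confounds.tsv`).
#' @return List with `image` (4D array), `confounds` (`confound_table`), and
#'   `grid`.
#' @export
render_volumes <- function(ts, nodes, grid, background_sd = 1, seed = 1L,
                           n_volumes = NULL, file = NULL) {
  stopifnot(inherits(ts, "ts_matrix"), inherits(grid, "img_grid"))
  tt <- nrow(ts$data)
  if (!is.null(n_volumes) && n_volumes != tt)
    stop("requested volume count (", n_volumes,
         ") does not match the time series length (", tt, ")")
  if (length(nodes) != ncol(ts$data))
    stop("number of nodes must match the number of time-series columns")
  masks <- lapply(nodes, function(n) {
    m <- sphere_mask(n, grid)
    mm <- m %*% t(grid$affine[1:3, 1:3])
    mm <- sweep(mm, 2L, grid$affine[1:3, 4L], `+`)
    # require the whole sphere inside the grid, not just a clipped remnant
    ctr <- n$center_mm
    lo <- (grid$affine %*% c(0, 0, 0, 1))[1:3]
    hi <- (grid$affine %*% c(grid$dim - 1L, 1))[1:3]
    if (any(ctr - n$radius_mm < pmin(lo, hi) - 1e-9) ||
        any(ctr + n$radius_mm > pmax(lo, hi) + 1e-9))
      stop("sphere of node '", n$name, "' extends outside the grid")
    m
  })
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  nvox <- prod(grid$dim)
  flat <- matrix(if (background_sd > 0)
    stats::rnorm(nvox * tt, 0, background_sd) else 0, nvox, tt)
  for (k in seq_along(nodes)) {
    m <- masks[[k]]
    lin <- 1L + m[, 1L] + grid$dim[1L] * (m[, 2L] + grid$dim[2L] * m[, 3L])
    flat[lin, ] <- flat[lin, , drop = FALSE] +
      matrix(ts$data[, k], length(lin), tt, byrow = TRUE)
  }
  image <- array(flat, dim = c(grid$dim, tt))
  cf <- confound_table(cbind(
    matrix(stats::rnorm(tt * 3L), tt, 3L),                 # tissue signals
    apply(matrix(stats::rnorm(tt * 6L, 0, 0.02), tt, 6L), 2L, cumsum)))
  if (!is.null(file)) {
    write_nifti_grid(image, grid, file, tr = ts$tr)
    utils::write.table(cf, sub("\\.nii(\\.gz)?$", "_confounds.tsv", file),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(image = image, confounds = cf, grid = grid)
}

#' Write a 4D array as NIfTI-1 with a grid affine
#'
#' @param image 3D or 4D numeric array.
#' @param grid An `img_grid` supplying the voxel-to-mm affine.
#' @param file Output path (`.nii` or `.nii.gz`).
#' @param tr Repetition time stored in the header (seconds).
#' @return `file`, invisibly.
#' @export
write_nifti_grid <- function(image, grid, file, tr = 2) {
  stopifnot(inherits(grid, "img_grid"))
  vox <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  img <- RNifti::asNifti(image, pixdim = c(vox, tr))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  RNifti::writeNifti(img, file)
  invisible(file)
}

#' Read a NIfTI image together with its grid geometry
#'
#' @param file NIfTI path.
#' @return List with `image` (array) and `grid` (`img_grid` from the stored
#'   sform/qform affine).
#' @export
read_nifti_grid <- function(file) {
  img <- RNifti::readNifti(file)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4L, 4L)
  arr <- as.array(img)
  img_dim <- dim(arr)[1:3]
  list(image = arr, grid = img_grid(img_dim, aff))
}
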
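test_that("sphere masks pick exactly the voxels within the radius", {
  grid <- default_mni_grid()
  # the packaged PVN peak sits exactly on a voxel centre of the 3 mm grid:
  # integer offsets with 9 (i^2 + j^2 + k^2) <= 36 give 33 voxels
  pvn <- node_def("PVN", c(6, -84, -3), 6)
  expect_equal(nrow(sphere_mask(pvn, grid)), 33)
  expect_equal(nrow(sphere_mask(node_def("PVN", c(6, -84, -3), 1), grid)), 1)
})

test_that("masks are nested in radius and contain the nearest voxel", {
  grid <- small_grid()
  ctr <- c(-7, 2, 5)  # off the voxel-centre lattice
  keyize <- function(m) apply(m, 1, paste, collapse = ",")
  masks <- lapply(c(3, 6, 12), function(r)
    sphere_mask(node_def("n", ctr, r), grid))
  expect_true(all(keyize(masks[[1]]) %in% keyize(masks[[2]])))
  expect_true(all(keyize(masks[[2]]) %in% keyize(masks[[3]])))
  expect_true(nrow(masks[[1]]) <= nrow(masks[[2]]))
  nearest <- round((solve(grid$affine) %*% c(ctr, 1))[1:3])
  expect_true(paste(nearest, collapse = ",") %in% keyize(masks[[1]]))
})

test_that("a sphere centred far outside the grid is an explicit error", {
  expect_error(sphere_mask(node_def("far", c(500, 0, 0), 6), small_grid()),
               "far")
})

test_that("initial-frame discard trims matrices and 4D arrays alike", {
  m <- matrix(rnorm(240 * 3), 240, 3)
  expect_equal(nrow(discard_initial(m, 10)), 230)
  expect_equal(discard_initial(m, 10)[1, ], m[11, ])
  expect_identical(discard_initial(m, 0), m)
  expect_error(discard_initial(m, 240), "smaller than")
  a <- array(rnorm(2 * 2 * 2 * 12), c(2, 2, 2, 12))
  expect_equal(dim(discard_initial(a, 5))[4], 7)
  ts <- ts_matrix(m)
  expect_equal(nrow(discard_initial(ts, 10)$data), 230)
})

test_that("noiseless rendering and extraction invert each other", {
  grid <- small_grid()
  nodes <- toy_nodes()
  ts <- toy_ts()
  vol <- render_volumes(ts, nodes, grid, background_sd = 0, seed = 1)
  expect_equal(dim(vol$image)[4], nrow(ts$data))
  got <- extract_node_series(vol$image, nodes, grid, tr = 2)
  expect_equal(unname(got$data), unname(ts$data), tolerance = 1e-12)
})

test_that("extraction averages: constant images and single-voxel masks", {
  grid <- small_grid()
  img <- array(7.5, c(grid$dim, 4))
  got <- extract_node_series(img, toy_nodes(), grid)
  expect_true(all(got$data == 7.5))
  # radius below the voxel size isolates a single voxel
  one <- list(node_def("one", c(0, 0, 0), 1))
  m <- sphere_mask(one[[1]], grid)
  expect_equal(nrow(m), 1)
  img[m[1, 1] + 1, m[1, 2] + 1, m[1, 3] + 1, ] <- c(1, 2, 3, 4)
  expect_equal(unname(extract_node_series(img, one, grid)$data[, 1]),
               c(1, 2, 3, 4))
})

test_that("background voxels carry noise at the requested level", {
  grid <- small_grid(n = 7L)
  nodes <- list(node_def("A", c(0, 0, 0), 3))
  ts <- ts_matrix(matrix(rnorm(1000), 1000, 1, dimnames = list(NULL, "A")))
  vol <- render_volumes(ts, nodes, grid, background_sd = 1, seed = 4)
  mask <- sphere_mask(nodes[[1]], grid)
  outside <- c(1, 1, 1)  # corner voxel, far from the centre sphere
  expect_false(paste(outside - 1, collapse = ",") %in%
                 apply(mask, 1, paste, collapse = ","))
  v <- vol$image[outside[1], outside[2], outside[3], ]
  expect_equal(sd(v), 1, tolerance = 0.1)
  expect_equal(ncol(vol$confounds), 9)
})

test_that("rendering validates sphere fit and volume count", {
  grid <- small_grid(n = 7L)
  ts <- ts_matrix(matrix(rnorm(20), 20, 1, dimnames = list(NULL, "A")))
  expect_error(render_volumes(ts, list(node_def("A", c(8, 0, 0), 6)), grid),
               "outside the grid")
  expect_error(render_volumes(ts, list(node_def("A", c(0, 0, 0), 3)), grid,
                              n_volumes = 19), "does not match")
})

test_that("NIfTI round-trip preserves data and affine", {
  grid <- small_grid(n = 6L)
  arr <- array(rnorm(prod(grid$dim) * 3), c(grid$dim, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_grid(arr, grid, path, tr = 2)
  back <- read_nifti_grid(path)
  expect_equal(back$image, arr, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$grid$affine, grid$affine, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("band-pass keeps the pass band and kills the stop band", {
  tt <- 230; tr <- 2
  t_sec <- seq_len(tt) * tr
  spec <- bandpass_spec(0.01, 0.08, tr)
  rms <- function(x) sqrt(mean(x^2))
  pass <- matrix(sin(2 * pi * 0.04 * t_sec), tt, 1)
  out <- bandpass_filter(pass, spec)
  expect_equal(rms(out) / rms(pass), 1, tolerance = 0.05)
  stopb <- matrix(sin(2 * pi * 0.2 * t_sec), tt, 1)
  expect_lt(rms(bandpass_filter(stopb, spec)) / rms(stopb), 0.05)
  const <- matrix(3, tt, 1)
  expect_lt(max(abs(bandpass_filter(const, spec))), 1e-10)
})

test_that("the ideal filter is a projection (idempotent)", {
  set.seed(8)
  x <- matrix(rnorm(230 * 3), 230, 3)
  spec <- bandpass_spec(0.01, 0.08, 2)
  once <- bandpass_filter(x, spec)
  expect_equal(bandpass_filter(once, spec), once, tolerance = 1e-8)
})

test_that("band specifications are validated", {
  expect_error(bandpass_spec(0.08, 0.01, 2), "f_lo < f_hi")
  expect_error(bandpass_spec(0.01, 0.3, 2), "Nyquist")
  ts <- ts_matrix(matrix(rnorm(60), 30, 2), tr = 3)
  expect_error(bandpass_filter(ts, bandpass_spec(0.01, 0.08, 2)),
               "does not match")
})

test_that("nuisance regression leaves least-squares residuals", {
  set.seed(21)
  tt <- 100
  cf <- confound_table(matrix(rnorm(tt * 9), tt, 9))
  x <- matrix(rnorm(tt * 3), tt, 3)
  x[, 1] <- cf$csf  # a node equal to a confound vanishes
  res <- regress_out(x, cf)
  expect_lt(max(abs(res[, 1])), 1e-8)
  # residuals orthogonal to every confound column
  dots <- crossprod(scale(as.matrix(cf)), scale(res, scale = FALSE))
  expect_lt(max(abs(dots)) / tt, 1e-6)
  expect_error(regress_out(x[1:50, ], cf), "row counts")
})

test_that("orthogonal zero-mean confounds only remove the mean", {
  tt <- 64
  x <- matrix(rnorm(tt), tt, 1)
  # build confounds orthogonal to x and mean-zero via QR complement
  q <- qr.Q(qr(cbind(1, x, matrix(rnorm(tt * 9), tt, 9))))
  cf <- confound_table(q[, 3:11] * 5)
  res <- regress_out(x, cf)
  expect_equal(res, x - mean(x), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("collinear confound columns are dropped with a warning", {
  tt <- 50
  cf <- matrix(rnorm(tt * 9), tt, 9)
  cf[, 9] <- cf[, 1] * 2
  x <- matrix(rnorm(tt * 2), tt, 2)
  expect_warning(res <- regress_out(x, cf), "collinear")
  expect_equal(dim(res), dim(x))
})

test_that("regressing at voxel level then averaging equals the reverse", {
  grid <- small_grid()
  nodes <- toy_nodes()
  ts <- toy_ts(tt = 30)
  vol <- render_volumes(ts, nodes, grid, background_sd = 0.5, seed = 6)
  flat <- matrix(vol$image, prod(grid$dim), 30)
  resid_flat <- regress_out(t(flat), vol$confounds)
  avg_then_reg <- regress_out(extract_node_series(vol$image, nodes, grid)$data,
                              vol$confounds)
  reg_img <- array(t(resid_flat), c(grid$dim, 30))
  reg_then_avg <- extract_node_series(reg_img, nodes, grid)$data
  expect_equal(avg_then_reg, reg_then_avg, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("the preprocessing pipeline composes the stages", {
  grid <- small_grid()
  nodes <- toy_nodes()
  set.seed(31)
  full <- ts_matrix(matrix(rnorm(240 * 3), 240, 3,
                           dimnames = list(NULL, c("A", "B", "C"))))
  vol <- render_volumes(full, nodes, grid, background_sd = 0.2, seed = 2)
  out <- preprocess_pipeline(vol$image, confounds = vol$confounds,
                             nodes = nodes, grid = grid, n_discard = 10)
  expect_equal(dim(out$data), c(230, 3))
  # matrix input with all cleaning disabled is the identity after discard
  m <- full$data
  out2 <- preprocess_pipeline(m, band = NULL, n_discard = 10)
  expect_equal(unname(out2$data), unname(m[11:240, ]))
  # node-order permutation permutes columns and nothing else
  outp <- preprocess_pipeline(vol$image, confounds = vol$confounds,
                              nodes = nodes[c(2, 3, 1)], grid = grid,
                              n_discard = 10)
  expect_equal(outp$data[, c("A", "B", "C")], out$data, tolerance = 1e-10)
})

test_that("head-motion flags report threshold crossings without excluding", {
  tt <- 20
  cf <- confound_table(matrix(0, tt, 9))
  expect_false(motion_exceeds(cf))
  cf$trans_y[5] <- 1.5
  expect_true(motion_exceeds(cf))
  expect_false(motion_exceeds(cf, max_mm = 2))
})
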
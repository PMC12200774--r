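test_that("tensor volume NIfTI round trip preserves components and affine", {
  vol <- random_tensor_volume(shape = c(5L, 6L, 4L), seed = 7)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_volume(vol, path)
  back <- read_tensor_volume(path)
  expect_lt(max(abs(back$tensors - vol$tensors)), 1e-6)
  expect_lt(max(abs(back$affine - vol$affine)), 1e-6)
  fa_mem <- compute_fa(vol)
  fa_file <- compute_fa(back)
  expect_lt(max(abs(fa_mem$values - fa_file$values)), 1e-6)
})

test_that("upper-triangular dialect reads back to canonical order", {
  vol <- random_tensor_volume(shape = c(4L, 4L, 4L), seed = 3)
  p_lower <- withr::local_tempfile(fileext = ".nii.gz")
  p_upper <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_volume(vol, p_lower, component_order = "lower")
  write_tensor_volume(vol, p_upper, component_order = "upper")
  a <- read_tensor_volume(p_lower, component_order = "lower")
  b <- read_tensor_volume(p_upper, component_order = "upper")
  expect_lt(max(abs(a$tensors - b$tensors)), 1e-6)
})

test_that("files with the wrong component count are rejected", {
  arr <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  img <- RNifti::asNifti(arr)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, path)
  expect_error(read_tensor_volume(path), "6 tensor components")
})

test_that("FA matches its closed form and limiting cases", {
  # isotropic
  iso <- const_tensor_volume(c(1e-3, 0, 1e-3, 0, 0, 1e-3))
  expect_equal(max(abs(compute_fa(iso)$values)), 0, tolerance = 1e-12)
  # eigenvalues (2, 1, 1) * 1e-3 -> sqrt(1/6) = 0.40825
  pro <- const_tensor_volume(c(2e-3, 0, 1e-3, 0, 0, 1e-3))
  expect_equal(compute_fa(pro)$values[1], sqrt(1 / 6), tolerance = 1e-10)
  # rank-one limit (1, 0, 0): clamped eigenvalues give FA ~ 1
  lin <- const_tensor_volume(c(1e-3, 0, 0, 0, 0, 0))
  expect_equal(compute_fa(lin)$values[1], 1, tolerance = 1e-6)
  # zero tensor -> FA 0 by convention
  zed <- const_tensor_volume(rep(0, 6))
  expect_equal(compute_fa(zed)$values[1], 0)
})

test_that("MD is the trace third and rotation invariant", {
  v <- const_tensor_volume(c(1e-3, 0, 2e-3, 0, 0, 3e-3))
  expect_equal(compute_md(v)$values[1], 2e-3, tolerance = 1e-15)
  expect_equal(compute_md(const_tensor_volume(rep(0, 6)))$values[1], 0)
  comp <- c(2e-3, 1e-4, 1e-3, -2e-4, 3e-4, 1.5e-3)
  vr <- const_tensor_volume(rotate_tensor6(comp, rz(37)))
  expect_equal(compute_md(vr)$values[1], compute_md(const_tensor_volume(comp))$values[1],
               tolerance = 1e-15)
})

test_that("FA is invariant under a common rotation of all tensors", {
  vol <- random_tensor_volume(seed = 11)
  R <- rz(63) %*% matrix(c(1,0,0, 0,cos(0.4),sin(0.4), 0,-sin(0.4),cos(0.4)), 3, 3)
  rot <- t(apply(vol$tensors, 1, rotate_tensor6, R = R))
  vol_r <- tensor_volume(rot, vol$affine, shape = vol$shape)
  expect_lt(max(abs(compute_fa(vol)$values - compute_fa(vol_r)$values)), 1e-10)
})

test_that("principal eigenvector solves the eigenproblem and is deterministic", {
  v <- const_tensor_volume(c(3e-3, 0, 1e-3, 0, 0, 1e-3))
  e <- principal_eigenvector(v)
  expect_equal(e$vectors[1, ], c(1, 0, 0), tolerance = 1e-12)
  vr <- const_tensor_volume(rotate_tensor6(c(3e-3, 0, 1e-3, 0, 0, 1e-3), rz(90)))
  er <- principal_eigenvector(vr)
  expect_equal(abs(er$vectors[1, ]), c(0, 1, 0), tolerance = 1e-8)
  # residual check on random tensors
  vol <- random_tensor_volume(shape = c(3L, 3L, 3L), seed = 5)
  ev <- principal_eigenvector(vol)
  for (i in seq_len(nrow(vol$tensors))) {
    c6 <- vol$tensors[i, ]
    D <- matrix(c(c6[1], c6[2], c6[4], c6[2], c6[3], c6[5],
                  c6[4], c6[5], c6[6]), 3, 3)
    lam <- max(eigen(D, symmetric = TRUE)$values)
    expect_lt(max(abs(D %*% ev$vectors[i, ] - lam * ev$vectors[i, ])), 1e-8)
  }
})

test_that("FA masks use strict thresholds and are nested", {
  fa <- scalar_volume(c(0.2, 0.3, 0.2, 0.3, 0.2, 0.3, 0.2, 0.3),
                      iso_affine(2, c(2L, 2L, 2L)), c(2L, 2L, 2L))
  m <- make_fa_mask(fa, 0.25)
  expect_identical(m$values, fa$values > 0.25)
  expect_error(make_fa_mask(fa, 0.9), "empty")
  ph <- make_phantom(24, 0.5, 1.0)
  fap <- compute_fa(ph)
  m05 <- make_fa_mask(fap, 0.05)
  m10 <- make_fa_mask(fap, 0.10)
  m25 <- make_fa_mask(fap, 0.25)
  expect_true(all(m25$values <= m10$values))
  expect_true(all(m10$values <= m05$values))
  expect_gt(sum(m05$values), sum(m25$values))
})
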
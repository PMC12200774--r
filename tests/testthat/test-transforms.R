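ref_spec <- function(shape = c(12L, 12L, 12L), spacing = 2) {
  list(shape = shape, affine = iso_affine(spacing, shape))
}

test_that("composing a transform with its inverse yields the zero field", {
  ref <- ref_spec()
  A <- diag(4); A[1:3, 1:3] <- rz(20); A[1:3, 4] <- c(3, -2, 1)
  chain <- transform_chain(affine_transform(A),
                           affine_transform(solve(A)))
  fld <- compose_transforms(chain, ref)
  expect_lt(max(abs(fld$u)), 1e-6)
})

test_that("two pure translations compose to their sum", {
  ref <- ref_spec()
  chain <- transform_chain(affine_transform(istgreg:::t4(c(1, 2, 3))),
                           affine_transform(istgreg:::t4(c(-4, 1, 0.5))))
  fld <- compose_transforms(chain, ref)
  expect_equal(colMeans(fld$u), c(-3, 3, 3.5), tolerance = 1e-10)
  expect_lt(max(abs(sweep(fld$u, 2, c(-3, 3, 3.5)))), 1e-10)
})

test_that("Jacobian maps are exact for identity, rigid and affine maps", {
  ref <- ref_spec()
  expect_lt(max(abs(jacobian_determinant_map(istgreg:::identity_transform(),
                                             ref)$values - 1)), 1e-9)
  R4 <- diag(4); R4[1:3, 1:3] <- rz(33); R4[1:3, 4] <- c(1, 0, -2)
  expect_lt(max(abs(jacobian_determinant_map(affine_transform(R4, dof = 6L),
                                             ref)$values - 1)), 1e-6)
  S4 <- diag(c(1.2, 1, 1, 1))
  expect_lt(max(abs(jacobian_determinant_map(affine_transform(S4),
                                             ref)$values - 1.2)), 1e-6)
  # affine-only chains multiply their linear determinants
  chain <- transform_chain(affine_transform(S4), affine_transform(R4))
  expect_lt(max(abs(jacobian_determinant_map(chain, ref)$values - 1.2)), 1e-6)
})

test_that("identity resampling reproduces the volume in the interior", {
  vol <- random_tensor_volume(shape = c(8L, 8L, 8L), seed = 2)
  out <- apply_transform(vol, istgreg:::identity_transform())
  expect_lt(max(abs(out$tensors - vol$tensors)), 1e-6)
})

test_that("finite-strain reorientation rotates tensors with the map", {
  shape <- c(10L, 10L, 10L)
  vol <- const_tensor_volume(c(2e-3, 0, 1e-3, 0, 0, 1e-3), shape)
  # pull-back by Rz(-90): content rotates +90, x-aligned becomes y-aligned
  A <- diag(4); A[1:3, 1:3] <- rz(-90)
  out <- apply_transform(vol, affine_transform(A, dof = 6L))
  interior <- which(apply(abs(istgreg:::grid_world(shape, vol$affine)), 1,
                          max) < 6)
  expected <- rotate_tensor6(c(2e-3, 0, 1e-3, 0, 0, 1e-3), rz(90))
  for (k in 1:6)
    expect_lt(max(abs(out$tensors[interior, k] - expected[k])), 1e-8)
})

test_that("reorientation preserves eigenvalues so FA commutes with rigid maps", {
  ph <- make_phantom(24, 0.5, 1)
  A <- diag(4); A[1:3, 1:3] <- rz(8); A[1, 4] <- 1.5
  tr <- affine_transform(A, dof = 6L)
  fa_then_move <- apply_transform(compute_fa(ph), tr)
  move_then_fa <- compute_fa(apply_transform(ph, tr))
  md <- compute_md(ph)$values
  interior <- md > 1e-4
  expect_lt(mean(abs(fa_then_move$values[interior] -
                       move_then_fa$values[interior])), 0.02)
})

test_that("warp-then-resample via a composed field matches sequential resampling", {
  ph <- make_phantom(24, 0.5, 1)
  X <- istgreg:::grid_world(ph$shape, ph$affine)
  u <- cbind(1.5 * sin(2 * pi * X[, 2] / 48), 1.2 * cos(2 * pi * X[, 1] / 48),
             0.8 * sin(2 * pi * X[, 3] / 48))
  fld <- displacement_field(u, ph$affine, ph$shape)
  A <- diag(4); A[1:3, 1:3] <- rz(5); A[2, 4] <- 1
  chain <- transform_chain(fld, affine_transform(A, dof = 6L))
  composed <- compose_transforms(chain, ph)
  one_step <- apply_transform(ph, composed, ph)
  two_step <- apply_transform(apply_transform(ph, affine_transform(A, dof = 6L)),
                              fld, ph)
  fa1 <- compute_fa(one_step)$values
  fa2 <- compute_fa(two_step)$values
  interior <- compute_md(one_step)$values > 1e-4
  expect_lt(mean(abs(fa1[interior] - fa2[interior])), 0.02)
})

test_that("affine transforms survive a plain-text round trip", {
  A <- diag(4); A[1:3, 1:3] <- rz(12) %*% diag(c(1.1, 0.9, 1)); A[1:3, 4] <- 1:3
  t1 <- affine_transform(A)
  path <- withr::local_tempfile(fileext = ".txt")
  write_affine(t1, path)
  t2 <- read_affine(path)
  expect_equal(t2$matrix, t1$matrix, tolerance = 1e-12)
})

test_that("transform validation catches malformed inputs", {
  bad <- diag(4); bad[4, 1] <- 1
  expect_error(affine_transform(bad), "affine")
  shear <- diag(4); shear[1, 2] <- 0.3
  expect_error(affine_transform(shear, dof = 6L), "orthogonal")
  expect_silent(affine_transform(shear, dof = 12L))
  expect_error(displacement_field(matrix(Inf, 8, 3), iso_affine(2, c(2L, 2L, 2L)),
                                  c(2L, 2L, 2L)), "finite")
})
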
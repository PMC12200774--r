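# registration unit tests run on a 24-voxel grid so the whole file stays fast;
# full-scale recovery checks live in the acceptance suite

small_phantom <- function() cached("phantom24", make_phantom(24, 0.5, 1.0))

rot_error_deg <- function(M, A) {
  acos(min(1, (sum(diag(t(M[1:3, 1:3]) %*% A[1:3, 1:3])) - 1) / 2)) * 180 / pi
}

test_that("rigid self-registration returns the identity pose", {
  ph <- small_phantom()
  r <- register_rigid(ph, ph)
  expect_lt(rot_error_deg(r$matrix, diag(4)), 0.1)
  expect_lt(sqrt(sum(r$matrix[1:3, 4]^2)), 0.1)  # 0.05 voxel at 2 mm
  expect_equal(r$dof, 6L)
  # linear part orthogonal with det +1
  L <- r$matrix[1:3, 1:3]
  expect_lt(max(abs(t(L) %*% L - diag(3))), 1e-9)
  expect_gt(det(L), 0)
})

test_that("rigid registration recovers a planted rotation and translation", {
  ph <- small_phantom()
  A <- diag(4); A[1:3, 1:3] <- rz(4); A[1, 4] <- 1.5; A[3, 4] <- -1
  fixed <- apply_transform(ph, affine_transform(A, dof = 6L))
  r <- register_rigid(ph, fixed)
  # the 24-voxel grid is deliberately small; sub-degree accuracy at full
  # phantom scale is asserted in the acceptance suite
  expect_lt(rot_error_deg(r$matrix, A), 1)
  expect_lt(sqrt(sum((r$matrix[1:3, 4] - A[1:3, 4])^2)), 0.5)
  # optimizer sanity: cost at the optimum no worse than at the truth
  ctrl <- reg_control()
  fl <- istgreg:::reg_prep(fixed, ctrl)
  ml <- istgreg:::reg_prep(ph, ctrl)
  n <- length(fl)
  c_rec <- istgreg:::affine_cost(r$matrix, fl[[n]], ml[[n]], FALSE,
                                 log(ctrl$metric_floor), ctrl$cost_cap)[1]
  c_true <- istgreg:::affine_cost(A, fl[[n]], ml[[n]], FALSE,
                                  log(ctrl$metric_floor), ctrl$cost_cap)[1]
  expect_lte(c_rec, c_true + 1e-6)
})

test_that("affine registration recovers anisotropic scaling", {
  ph <- small_phantom()
  S <- diag(c(1.08, 1.0, 0.94, 1))
  fixed <- apply_transform(ph, affine_transform(S))
  a <- register_affine(ph, fixed, init = register_rigid(ph, fixed))
  expect_equal(a$dof, 12L)
  sv <- sort(svd(a$matrix[1:3, 1:3])$d)
  expect_lt(max(abs(sv - sort(c(1.08, 1.0, 0.94)))), 0.015)
  expect_lt(abs(det(a$matrix[1:3, 1:3]) / det(S[1:3, 1:3]) - 1), 0.02)
})

test_that("affine self-registration stays at the identity", {
  ph <- small_phantom()
  a <- register_affine(ph, ph)
  expect_lt(max(abs(a$matrix - diag(4))), 0.02)
})

test_that("deformable self-registration returns a near-zero field", {
  ph <- small_phantom()
  fld <- register_deformable(ph, ph, levels = 2)
  expect_lt(max(sqrt(rowSums(fld$u^2))), 0.2)  # 0.1 voxel at 2 mm
  tr <- attr(fld, "cost_trace")
  expect_true(all(diff(tr) <= 1e-12))
})

test_that("deformable registration recovers a smooth planted warp", {
  ph <- small_phantom()
  X <- istgreg:::grid_world(ph$shape, ph$affine)
  u <- cbind(1.6 * sin(2 * pi * X[, 2] / 48), 1.4 * cos(2 * pi * X[, 1] / 48),
             1.2 * sin(2 * pi * X[, 3] / 48))
  fixed <- apply_transform(ph, displacement_field(u, ph$affine, ph$shape))
  fld <- register_deformable(ph, fixed, levels = 3)
  msk <- compute_md(fixed)$values > 1e-4
  rms <- sqrt(mean(rowSums((fld$u - u)^2)[msk]))
  expect_lt(rms, 1)
  # cost trace non-increasing across levels
  expect_true(all(diff(attr(fld, "cost_trace")) <= 1e-12))
  # local invertibility maintained
  jd <- jacobian_determinant_map(fld)
  expect_gt(min(jd$values), 0.1)
})

test_that("scalar-mode registration works on FA maps", {
  ph <- small_phantom()
  fa <- compute_fa(ph)
  A <- diag(4); A[1:3, 1:3] <- rz(3); A[2, 4] <- 1
  fixed <- apply_transform(fa, affine_transform(A, dof = 6L))
  r <- register_rigid(fa, fixed)
  expect_lt(rot_error_deg(r$matrix, A), 1)
  expect_lt(sqrt(sum((r$matrix[1:3, 4] - A[1:3, 4])^2)), 1)
})

test_that("registration starting without overlap is refused", {
  ph <- small_phantom()
  off <- affine_transform(istgreg:::t4(c(500, 0, 0)))
  expect_error(register_affine(ph, ph, init = off), "overlap")
})

test_that("registration is deterministic", {
  ph <- small_phantom()
  A <- diag(4); A[1:3, 1:3] <- rz(2); A[1, 4] <- 1
  fixed <- apply_transform(ph, affine_transform(A, dof = 6L))
  r1 <- register_rigid(ph, fixed)
  r2 <- register_rigid(ph, fixed)
  expect_identical(r1$matrix, r2$matrix)
})
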
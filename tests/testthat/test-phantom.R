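test_that("tract cores reach the requested FA and MD level", {
  for (fa_t in c(0.35, 0.65)) {
    ph <- make_phantom(48, fa_t, 1.0)
    cores <- attr(ph, "cores")
    fa <- compute_fa(ph)$values
    core <- cores$arc | cores$lateral | cores$transverse
    expect_gt(sum(core), 50)
    expect_lt(max(abs(fa[core] - fa_t)), 0.03)
    md <- compute_md(ph)$values
    expect_lt(max(abs(md[core] - 1e-3)), 1e-4)
  }
  expect_error(make_phantom(16, 1.0, 1), "stage_fa")
})

test_that("the crossing region holds near-orthogonal bundle directions", {
  ph <- make_phantom(48, 0.6, 1.0)
  cores <- attr(ph, "cores")
  e1 <- principal_eigenvector(ph)
  lat <- e1$vectors[cores$lateral, , drop = FALSE]
  tra <- e1$vectors[cores$transverse & !cores$crossing, , drop = FALSE]
  # mean absolute angle between the two bundle populations >= 60 degrees
  mean_lat <- colMeans(abs(lat))
  mean_tra <- colMeans(abs(tra))
  ang <- acos(min(1, abs(sum(mean_lat * mean_tra)) /
                    sqrt(sum(mean_lat^2) * sum(mean_tra^2)))) * 180 / pi
  expect_gte(ang, 60)
  expect_gt(sum(cores$crossing), 10)
})

test_that("phantoms and cohorts are bit-reproducible given the seed", {
  p1 <- make_phantom(16, 0.5, 1.0)
  p2 <- make_phantom(16, 0.5, 1.0)
  expect_identical(p1$tensors, p2$tensors)
  spec <- cohort_spec(n_scans = 4L, n_groups = 2L, grid = 16L, seed = 7L)
  c1 <- make_cohort(spec)
  c2 <- make_cohort(spec)
  for (s in names(c1$scans))
    expect_identical(c1$scans[[s]]$tensors, c2$scans[[s]]$tensors)
  expect_identical(c1$ages, c2$ages)
})

test_that("synthetic ages reproduce the planted groups under the age rule", {
  co <- make_cohort(cohort_spec(n_scans = 9L, n_groups = 3L, grid = 16L,
                                seed = 3L))
  p <- partition_by_age(names(co$ages), co$ages)
  expect_equal(unname(p$labels[names(co$groups)]), unname(co$groups))
})

test_that("stronger warps increase pre-registration FA dispersion", {
  base <- cohort_spec(n_scans = 6L, n_groups = 1L, grid = 24L, seed = 11L,
                      rigid_jitter = c(0, 0), noise_sd = 0)
  sig <- sapply(c(0.5, 1.5, 3), function(amp) {
    sp <- base
    sp$warp_amplitude <- amp
    co <- make_cohort(sp)
    fa <- lapply(co$scans, compute_fa)
    mean_fa <- istgreg:::scalar_mean(fa)
    mask <- make_fa_mask(mean_fa, 0.25)
    mean(sigma_fa(fa, mask)$values[mask$values])
  })
  expect_true(all(diff(sig) > 0))
})

test_that("inverse-applying the ground truth realigns scans to the noise floor", {
  spec <- cohort_spec(n_scans = 5L, n_groups = 1L, grid = 24L, seed = 9L,
                      rigid_jitter = c(4, 2), warp_amplitude = 1.5)
  co <- make_cohort(spec)
  # noise-only reference: same spec without misalignment
  spec0 <- spec
  spec0$rigid_jitter <- c(0, 0)
  spec0$warp_amplitude <- 1e-9
  co0 <- make_cohort(spec0)
  realigned <- lapply(names(co$scans), function(s) {
    gt <- co$ground_truth[[s]]
    inv_warp <- invert_displacement_field(gt$warp)
    chain <- transform_chain(affine_transform(solve(gt$rigid), dof = 6L),
                             inv_warp)
    apply_transform(co$scans[[s]], chain, co$scans[[s]])
  })
  sig_of <- function(scans) {
    fa <- lapply(scans, compute_fa)
    mean_fa <- istgreg:::scalar_mean(fa)
    mask <- make_fa_mask(mean_fa, 0.25)
    mean(sigma_fa(fa, mask)$values[mask$values])
  }
  floor_sig <- sig_of(co0$scans)
  realigned_sig <- sig_of(realigned)
  expect_lt(realigned_sig, floor_sig * 1.10 + 0.02)
})

test_that("cohort groups are balanced and recoverable from ground truth", {
  co <- make_cohort(cohort_spec(n_scans = 12L, n_groups = 3L, grid = 16L))
  expect_equal(unname(table(co$groups)), rep(4L, 3L) , ignore_attr = TRUE)
  gts <- sapply(co$ground_truth, function(g) g$group)
  expect_equal(unname(gts), unname(co$groups))
})
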
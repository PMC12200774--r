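test_that("medoid selection minimizes summed distance and centers the target", {
  # rows summing to (10, 4, 9) -> second scan
  m <- matrix(c(0, 3, 7, 3, 0, 1, 7, 1, 0), 3, 3)
  ids <- c("a", "b", "c")
  dimnames(m) <- list(ids, ids)
  d <- structure(list(ids = ids, values = m, normalized = FALSE),
                 class = "distance_matrix")
  ph <- make_phantom(16, 0.4, 1)
  scans <- list(a = ph, b = ph, c = ph)
  sel <- select_initial_target(scans, d)
  expect_equal(sel$id, "b")
  expect_equal(sel$index, 2L)
  # single scan: itself, centering only
  sel1 <- select_initial_target(list(only = ph))
  expect_equal(sel1$id, "only")

  # centering puts the MD-weighted center of mass at the grid center
  off <- ph
  off$affine[1:3, 4] <- off$affine[1:3, 4] + c(4, -6, 2)
  sel_off <- select_initial_target(list(x = off))
  centered <- apply_transform(off, sel_off$centering)
  md <- compute_md(centered)
  X <- istgreg:::grid_world(md$shape, md$affine)
  w <- pmax(md$values, 0)
  com <- colSums(X * w) / sum(w)
  ctr <- istgreg:::apply_affine_points(md$affine,
                                       matrix((md$shape - 1) / 2, 1))[1, ]
  expect_lt(sqrt(sum((com - ctr)^2)), 1)  # 0.5 voxel at 2 mm
})

test_that("a single-scan cohort passes through untouched", {
  ph <- make_phantom(16, 0.5, 1)
  res <- build_template(list(one = ph), ph)
  expect_identical(res$template$tensors, ph$tensors)
  fld <- compose_transforms(res$per_scan_chains$one, ph)
  expect_lt(max(abs(fld$u)), 1e-9)
})

test_that("a cohort of identical scans is a fixed point", {
  ph <- cached("phantom24", make_phantom(24, 0.5, 1.0))
  scans <- list(a = ph, b = ph, c = ph)
  res <- build_template(scans, ph,
                        iters = c(rigid = 1L, affine = 1L, deform = 1L),
                        deform_levels = 2L)
  interior <- compute_md(ph)$values > 1e-4
  fa0 <- compute_fa(ph)$values
  fa1 <- compute_fa(res$template)$values
  expect_lt(mean(abs(fa1[interior] - fa0[interior])), 0.01)
  for (ch in res$per_scan_chains) {
    fld <- compose_transforms(ch, ph)
    expect_lt(mean(sqrt(rowSums(fld$u^2))), 0.3)
  }
  # stage history records non-increasing mean costs per stage sequence
  expect_true(all(c("rigid", "affine", "deform") %in% res$stage_history$stage))
})

test_that("two copies offset by +/-2 mm meet in the middle", {
  ph <- cached("phantom24", make_phantom(24, 0.5, 1.0))
  plus <- affine_transform(istgreg:::t4(c(2, 0, 0)), dof = 6L)
  minus <- affine_transform(istgreg:::t4(c(-2, 0, 0)), dof = 6L)
  a <- apply_transform(ph, plus)
  b <- apply_transform(ph, minus)
  scans <- list(a = a, b = b)
  sel <- select_initial_target(scans, pairwise_scalar_distance(
    lapply(scans, compute_fa)))
  target <- apply_transform(scans[[sel$index]], sel$centering)
  res <- build_template(scans, target,
                        iters = c(rigid = 2L, affine = 0L, deform = 0L))
  tr <- sapply(res$per_scan_chains, function(ch) ch$elements[[1]]$matrix[1, 4])
  # recovered x translations are symmetric about the common center
  expect_lt(abs(sum(tr)), 0.3)
  expect_gt(abs(diff(tr)), 3)  # and actually separate the two copies
})

test_that("istg_run with a single group reduces to one-level construction", {
  ph <- cached("phantom24", make_phantom(24, 0.5, 1.0))
  set.seed(10)
  scans <- list()
  for (i in 1:3) {
    A <- diag(4); A[1:3, 4] <- runif(3, -1.5, 1.5)
    scans[[paste0("s", i)]] <- apply_transform(ph, affine_transform(A, dof = 6L))
  }
  iters <- c(rigid = 1L, affine = 1L, deform = 0L)
  part <- single_partition(names(scans))
  res2 <- istg_run(scans, part, iters = iters, deform_levels = 2L)
  fa <- lapply(scans, compute_fa)
  d0 <- pairwise_scalar_distance(fa)
  sel <- select_initial_target(scans, d0)
  target <- apply_transform(scans[[sel$index]], sel$centering)
  res1 <- build_template(scans, target, iters = iters, deform_levels = 2L)
  expect_lt(max(abs(res2$template$tensors - res1$template$tensors)), 1e-9)
  for (s in names(scans)) {
    f2 <- compose_transforms(res2$per_scan_chains[[s]], res2$template)
    f1 <- compose_transforms(res1$per_scan_chains[[s]], res1$template)
    expect_lt(max(abs(f2$u - f1$u)), 1e-9)
  }
})

test_that("size-1 subgroups pass through level 1 with a warning", {
  ph <- cached("phantom24", make_phantom(24, 0.5, 1.0))
  scans <- list(a = ph, b = apply_transform(ph, affine_transform(istgreg:::t4(c(1, 0, 0)), dof = 6L)),
                c = apply_transform(ph, affine_transform(istgreg:::t4(c(-1, 0, 0)), dof = 6L)))
  part <- istgreg:::new_partition(names(scans), c(1L, 2L, 2L), "manual")
  expect_warning(
    res <- istg_run(scans, part, iters = c(rigid = 1L, affine = 0L, deform = 0L)),
    "size-1")
  expect_s3_class(res, "template_result")
  expect_equal(sort(names(res$per_scan_chains)), c("a", "b", "c"))
})
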
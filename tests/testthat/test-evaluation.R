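full_mask <- function(shape = c(4L, 4L, 4L)) {
  voxel_mask(rep(TRUE, prod(shape)), iso_affine(2, shape), shape, "all")
}

vec_field <- function(v, shape = c(4L, 4L, 4L)) {
  structure(list(vectors = matrix(v, prod(shape), 3, byrow = TRUE),
                 degenerate = rep(FALSE, prod(shape)), shape = shape,
                 affine = iso_affine(2, shape), mask = NULL),
            class = "eigenvector_field")
}

test_that("dyadic coherence hits its closed-form endpoints", {
  m <- full_mask()
  # perfectly aligned
  k1 <- dyadic_coherence(list(vec_field(c(1, 0, 0)), vec_field(c(1, 0, 0)),
                              vec_field(c(1, 0, 0))), m)
  expect_equal(max(abs(k1$values - 1)), 0, tolerance = 1e-10)
  # half along x, half along y: mean dyadic eigenvalues (1/2, 1/2, 0)
  k2 <- dyadic_coherence(list(vec_field(c(1, 0, 0)), vec_field(c(0, 1, 0))), m)
  expect_equal(k2$values[1], 1 - sqrt(0.5), tolerance = 1e-10)
  # scan-order permutation invariance
  k2b <- dyadic_coherence(list(vec_field(c(0, 1, 0)), vec_field(c(1, 0, 0))), m)
  expect_equal(k2$values, k2b$values, tolerance = 1e-12)
})

test_that("dyadic coherence of isotropically random directions is near zero", {
  set.seed(42)
  shape <- c(1L, 1L, 1L)
  m <- full_mask(shape)
  fields <- lapply(1:1000, function(i) {
    v <- rnorm(3)
    vec_field(v / sqrt(sum(v^2)), shape)
  })
  k <- dyadic_coherence(fields, m)
  expect_lt(k$values[1], 0.05)
})

test_that("sigma_fa is the coefficient of variation with n-1 normalization", {
  shape <- c(2L, 1L, 1L)
  m <- full_mask(shape)
  a <- scalar_volume(c(0.4, 0.4), iso_affine(2, shape), shape)
  b <- scalar_volume(c(0.6, 0.6), iso_affine(2, shape), shape)
  s <- sigma_fa(list(a, b), m)
  expect_equal(s$values[1], sd(c(0.4, 0.6)) / 0.5, tolerance = 1e-12)
  expect_equal(s$values[1], 0.2828427, tolerance = 1e-6)
  # identical maps -> 0
  expect_equal(max(sigma_fa(list(a, a, a), m)$values), 0)
  # scale invariance
  a2 <- scalar_volume(a$values * 3, a$affine, shape)
  b2 <- scalar_volume(b$values * 3, b$affine, shape)
  expect_equal(sigma_fa(list(a2, b2), m)$values, s$values, tolerance = 1e-12)
  expect_error(sigma_fa(list(a), m), "at least 2")
})

test_that("NMI behaves at its self, independence and invariance limits", {
  set.seed(13)
  shape <- c(40L, 40L, 40L)
  m <- full_mask(shape)
  a <- scalar_volume(runif(prod(shape)), iso_affine(2, shape), shape)
  expect_equal(nmi(a, a, m), 1, tolerance = 1e-12)
  b <- scalar_volume(runif(prod(shape)), iso_affine(2, shape), shape)
  expect_lt(nmi(a, b, m), 0.05)
  # invariant under a common affine intensity relabeling (bin-preserving)
  a2 <- scalar_volume(3 * a$values + 1, a$affine, shape)
  b2 <- scalar_volume(3 * b$values + 1, b$affine, shape)
  expect_equal(nmi(a2, b2, m), nmi(a, b, m), tolerance = 1e-12)
  const <- scalar_volume(rep(1, prod(shape)), iso_affine(2, shape), shape)
  expect_error(nmi(const, a, m), "constant")
  # the literal joint-over-marginals ratio decreases with similarity
  expect_lt(nmi(a, a, m, variant = "joint_over_sum"),
            nmi(a, b, m, variant = "joint_over_sum"))
})

test_that("jacobian summaries report absolute deviation from unity", {
  shape <- c(3L, 3L, 3L)
  m <- full_mask(shape)
  one <- scalar_volume(rep(1, 27), iso_affine(2, shape), shape)
  js <- jacobian_summary(list(a = one, b = one), m)
  expect_equal(max(abs(js$mean_map$values - 1)), 0)
  expect_equal(max(js$sd_map$values), 0)
  expect_equal(unname(js$abs_dev), c(0, 0))
  j12 <- scalar_volume(rep(1.2, 27), iso_affine(2, shape), shape)
  expect_equal(unname(jacobian_summary(list(j12), m)$abs_dev), 0.2,
               tolerance = 1e-12)
})

test_that("ecdf points follow the step-function definition", {
  e <- ecdf_points(c(3, 1, 2))
  expect_equal(e$value, c(1, 2, 3))
  expect_equal(e$fraction, c(1, 2, 3) / 3)
  expect_equal(e$fraction[1], 1 / 3)
  expect_equal(e$fraction[nrow(e)], 1)
})

test_that("method comparison reproduces pooled-variance textbook values", {
  r <- compare_methods(c(1, 2, 3), c(4, 5, 6), seed = 1)
  expect_equal(r$t_statistic, -3.674235, tolerance = 1e-5)
  expect_equal(r$cohens_d, -3, tolerance = 1e-12)
  expect_equal(r$p_bonferroni, min(1, 3 * r$p_value))
  expect_true(r$d_ci[1] <= r$cohens_d && r$cohens_d <= r$d_ci[2])
  same <- compare_methods(c(1, 2, 3), c(1, 2, 3), seed = 1)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(compare_methods(c(1, 1), c(1, 1)), "pooled variance")
  # deterministic given seed
  r2 <- compare_methods(c(1, 2, 3), c(4, 5, 6), seed = 1)
  expect_identical(r$d_ci, r2$d_ci)
})
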
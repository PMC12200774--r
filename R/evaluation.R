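#' Dyadic coherence of aligned principal eigenvectors
#'
#' For each masked voxel the mean dyadic tensor `<e1 e1^T>` across scans is
#' formed; with its eigenvalues `b1 >= b2 >= b3`,
#' `kappa = 1 - sqrt((b2 + b3) / (2 b1))`. Perfectly co-aligned directions
#' give 1, isotropically scattered directions approach 0. Voxels where the
#' mean dyadic vanishes are removed from the output mask.
#'
#' @param e1_fields list (>= 2) of `eigenvector_field` objects on a common
#'   grid, as returned by [principal_eigenvector()].
#' @param mask a [voxel_mask()].
#' @return a [scalar_volume()] of kappa values (0 outside the mask).
#' @export
dyadic_coherence <- function(e1_fields, mask) {
  stopifnot(length(e1_fields) >= 2L, inherits(mask, "voxel_mask"))
  ref <- e1_fields[[1]]
  idx <- which(mask$values)
  dy <- matrix(0, length(idx), 6)
  for (f in e1_fields) {
    v <- f$vectors[idx, , drop = FALSE]
    dy <- dy + cbind(v[, 1]^2, v[, 1] * v[, 2], v[, 2]^2,
                     v[, 1] * v[, 3], v[, 2] * v[, 3], v[, 3]^2)
  }
  dy <- dy / length(e1_fields)
  ev <- cpp_eig3_batch(dy)$values
  b1 <- ev[, 1]
  kappa <- ifelse(b1 > 1e-12,
                  1 - sqrt(pmax(ev[, 2] + ev[, 3], 0) / (2 * b1)), NA_real_)
  out <- numeric(prod(ref$shape))
  out[idx] <- kappa
  out[is.na(out)] <- 0
  scalar_volume(pmin(pmax(out, 0), 1), ref$affine, ref$shape, unit = "1")
}

#' Normalized standard deviation of FA across scans
#'
#' Voxelwise coefficient of variation: sample standard deviation (n-1
#' denominator) divided by the mean across the aligned FA maps. Voxels whose
#' mean FA is at most 1e-6 are set to 0 (effectively masked out).
#'
#' @param fa_maps list (>= 2) of [scalar_volume()] FA maps on a common grid.
#' @param mask a [voxel_mask()].
#' @return a [scalar_volume()] of sigma_FA values (0 outside the mask).
#' @export
sigma_fa <- function(fa_maps, mask) {
  if (length(fa_maps) < 2L) stopf("need at least 2 FA maps")
  ref <- fa_maps[[1]]
  idx <- which(mask$values)
  X <- vapply(fa_maps, function(m) m$values[idx], numeric(length(idx)))
  mu <- rowMeans(X)
  s <- sqrt(rowSums((X - mu)^2) / (ncol(X) - 1))
  v <- ifelse(mu > 1e-6, s / mu, 0)
  out <- numeric(prod(ref$shape))
  out[idx] <- v
  scalar_volume(out, ref$affine, ref$shape, unit = "1")
}

#' Normalized mutual information between two scalar maps
#'
#' Joint histogram over the masked voxels with `bins` equal-width bins per
#' image spanning each image's masked range. The default variant is the
#' symmetric-uncertainty form `2 I(A;B) / (H(A) + H(B))`, which lies in
#' `[0, 1]` and grows with similarity; the literal joint-over-marginals
#' ratio `H(A,B) / (H(A) + H(B))` (which spans `[0.5, 1]` and shrinks with
#' similarity) is available as `variant = "joint_over_sum"`.
#'
#' @param image,reference [scalar_volume()]s on a common grid.
#' @param mask a [voxel_mask()].
#' @param bins number of histogram bins per image (default 64).
#' @param variant `"symmetric"` (default) or `"joint_over_sum"`.
#' @return a single NMI value.
#' @export
nmi <- function(image, reference, mask, bins = 64L,
                variant = c("symmetric", "joint_over_sum")) {
  variant <- match.arg(variant)
  stopifnot(same_grid(image, reference))
  idx <- which(mask$values)
  a <- image$values[idx]
  b <- reference$values[idx]
  if (diff(range(a)) == 0 || diff(range(b)) == 0)
    stopf("constant image: marginal entropy is zero, NMI undefined")
  bin_of <- function(x) {
    r <- range(x)
    pmin(pmax(floor((x - r[1]) / (r[2] - r[1]) * bins), 0), bins - 1) + 1L
  }
  ia <- bin_of(a); ib <- bin_of(b)
  joint <- matrix(tabulate(ia + bins * (ib - 1L), nbins = bins * bins),
                  bins, bins) / length(ia)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hab <- ent(joint)
  ha <- ent(rowSums(joint))
  hb <- ent(colSums(joint))
  if (variant == "joint_over_sum") return(hab / (ha + hb))
  mi <- ha + hb - hab
  max(0, min(1, 2 * mi / (ha + hb)))
}

#' Summaries of per-scan Jacobian determinant maps
#'
#' @param jac_maps named list of [scalar_volume()] Jacobian maps.
#' @param mask a [voxel_mask()].
#' @return list with `mean_map` and `sd_map` ([scalar_volume()]s across
#'   scans; SD is 0 with a single map) and `abs_dev`, the per-scan
#'   `|mean Jacobian over the mask - 1|`.
#' @export
jacobian_summary <- function(jac_maps, mask) {
  stopifnot(length(jac_maps) >= 1L)
  ref <- jac_maps[[1]]
  X <- vapply(jac_maps, function(m) m$values, numeric(prod(ref$shape)))
  mu <- rowMeans(X)
  s <- if (ncol(X) > 1) sqrt(rowSums((X - mu)^2) / (ncol(X) - 1)) else 0 * mu
  idx <- which(mask$values)
  dev <- apply(X, 2, function(v) abs(mean(v[idx]) - 1))
  names(dev) <- names(jac_maps)
  list(mean_map = scalar_volume(mu, ref$affine, ref$shape, unit = "1"),
       sd_map = scalar_volume(s, ref$affine, ref$shape, unit = "1"),
       abs_dev = dev)
}

#' Empirical cumulative distribution function points
#'
#' @param values non-empty numeric vector.
#' @return data frame of sorted `(value, fraction)` pairs,
#'   `fraction = P(X <= value)`.
#' @export
ecdf_points <- function(values) {
  stopifnot(length(values) >= 1L)
  v <- sort(values)
  data.frame(value = v, fraction = seq_along(v) / length(v))
}

#' Two-sample comparison with effect size
#'
#' Pooled-variance two-sample two-tailed t-test plus Cohen's d
#' (mean difference over pooled SD) with a seeded nonparametric bootstrap
#' 95 percent confidence interval, and a Bonferroni-adjusted p-value for the
#' three pairwise method comparisons.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @param seed integer seed for the bootstrap.
#' @param n_boot bootstrap resamples (default 10000).
#' @return a list of class `comparison_result`: `t_statistic`, `df`,
#'   `p_value`, `p_bonferroni`, `cohens_d`, `d_ci`, `n_per_group`.
#' @export
compare_methods <- function(a, b, seed = 1L, n_boot = 10000L) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) stopf("zero pooled variance")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  boot_d <- with_seed(seed, {
    ia <- matrix(sample.int(length(a), length(a) * n_boot, replace = TRUE),
                 ncol = n_boot)
    ib <- matrix(sample.int(length(b), length(b) * n_boot, replace = TRUE),
                 ncol = n_boot)
    vapply(seq_len(n_boot), function(r) {
      ar <- a[ia[, r]]; br <- b[ib[, r]]
      s2 <- ((length(ar) - 1) * stats::var(ar) +
               (length(br) - 1) * stats::var(br)) /
        (length(ar) + length(br) - 2)
      if (s2 <= 0) return(NA_real_)
      (mean(ar) - mean(br)) / sqrt(s2)
    }, 0)
  })
  ci <- stats::quantile(boot_d, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value,
                 p_bonferroni = min(1, 3 * tt$p.value),
                 cohens_d = d, d_ci = ci,
                 n_per_group = c(length(a), length(b))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("t(%0.f) = %.3f, p = %.3g (Bonferroni %.3g), d = %.3f [%.3f, %.3f]\n",
              x$df, x$t_statistic, x$p_value, x$p_bonferroni, x$cohens_d,
              x$d_ci[1], x$d_ci[2]))
  invisible(x)
}
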
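#' Fractional anisotropy map
#'
#' FA is computed from the eigenvalues of each tensor after clamping them
#' below at the eigenvalue floor (1e-12 mm^2/s):
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, which lies in
#' `[0, 1]`. An all-zero tensor (isotropic after clamping) has FA 0.
#'
#' @param vol a [tensor_volume()].
#' @param mask optional [voxel_mask()]; FA outside the mask is set to 0.
#' @return a [scalar_volume()] with unit `"1"`.
#' @export
compute_fa <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "tensor_volume"))
  fm <- cpp_fa_md(vol$tensors, LAMBDA_FLOOR)
  fa <- fm$fa
  if (!is.null(mask)) fa[!mask$values] <- 0
  scalar_volume(fa, vol$affine, vol$shape, unit = "1")
}

#' Mean diffusivity map
#'
#' MD is the tensor trace divided by 3, in mm^2/s.
#'
#' @inheritParams compute_fa
#' @return a [scalar_volume()] with unit `"mm^2/s"`.
#' @export
compute_md <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "tensor_volume"))
  md <- (vol$tensors[, 1] + vol$tensors[, 3] + vol$tensors[, 6]) / 3
  if (!is.null(mask)) md[!mask$values] <- 0
  scalar_volume(md, vol$affine, vol$shape, unit = "mm^2/s")
}

#' Principal eigenvector field
#'
#' Unit eigenvector of the largest eigenvalue per masked voxel. The sign is
#' made deterministic by forcing the first nonzero component positive (the
#' sign is irrelevant for dyadic-tensor statistics downstream). Voxels whose
#' two leading eigenvalues are nearly equal (`l1 - l2 < 1e-12 * l1`) are
#' flagged in the `degenerate` mask but still receive a vector.
#'
#' @param vol a [tensor_volume()].
#' @param mask a [voxel_mask()] restricting the computation; outside voxels
#'   get the zero vector.
#' @return a list of class `eigenvector_field` with `vectors` (`n x 3`),
#'   `degenerate` (logical), `shape`, `affine` and `mask`.
#' @export
principal_eigenvector <- function(vol, mask = NULL) {
  stopifnot(inherits(vol, "tensor_volume"))
  idx <- mask_indices(mask, vol$shape)
  res <- cpp_principal_eigvec(vol$tensors[idx, , drop = FALSE])
  vec <- matrix(0, nrow(vol$tensors), 3)
  deg <- rep(FALSE, nrow(vol$tensors))
  vec[idx, ] <- res$vectors
  deg[idx] <- res$degenerate
  structure(list(vectors = vec, degenerate = deg, shape = vol$shape,
                 affine = vol$affine, mask = mask),
            class = "eigenvector_field")
}

#' Threshold an FA map into an evaluation mask
#'
#' Strict inequality `FA > threshold`, matching the white-matter evaluation
#' masks built from the cohort-average FA map (thresholds 0.05 whole-brain,
#' 0.1 white matter-enriched, 0.25 white matter-heavy).
#'
#' @param fa a [scalar_volume()] holding an FA map.
#' @param threshold value in `[0, 1]`.
#' @return a [voxel_mask()].
#' @export
make_fa_mask <- function(fa, threshold) {
  stopifnot(inherits(fa, "scalar_volume"), threshold >= 0, threshold <= 1)
  m <- fa$values > threshold
  if (!any(m))
    stopf("FA mask at threshold %.3g is empty", threshold)
  voxel_mask(m, fa$affine, fa$shape,
             provenance = sprintf("FA>%g", threshold))
}
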
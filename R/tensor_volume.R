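#' Diffusion tensor volume
#'
#' A 3-D grid of symmetric 3x3 diffusion tensors, each stored as its 6 unique
#' components in NIfTI lower-triangular order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`
#' (units mm^2/s), together with a 4x4 voxel-to-world affine (RAS+ world frame,
#' 0-based voxel indices). Tensors are expressed in the world frame.
#'
#' @param tensors either an `nx x ny x nz x 6` array or an `n x 6` matrix of
#'   tensor components (voxel index fastest along x).
#' @param affine 4x4 voxel-to-world matrix; must be invertible with last row
#'   `(0, 0, 0, 1)`.
#' @param shape integer vector of 3 grid sizes; required when `tensors` is a
#'   matrix.
#' @param tensor_frame frame the tensors are expressed in, `"world"` (default)
#'   or `"voxel"`.
#' @return an object of class `tensor_volume` with fields `tensors`
#'   (`n x 6` matrix), `shape`, `affine` and `tensor_frame`.
#' @export
tensor_volume <- function(tensors, affine, shape = NULL,
                          tensor_frame = c("world", "voxel")) {
  tensor_frame <- match.arg(tensor_frame)
  if (is.array(tensors) && length(dim(tensors)) == 4L) {
    if (dim(tensors)[4] != 6L)
      stopf("tensor array must have 6 components, got %d", dim(tensors)[4])
    shape <- dim(tensors)[1:3]
    tensors <- matrix(tensors, ncol = 6L)
  }
  if (is.null(shape) || length(shape) != 3L || any(shape < 1L))
    stopf("shape must be 3 positive integers")
  shape <- as.integer(shape)
  if (!is.matrix(tensors) || ncol(tensors) != 6L || nrow(tensors) != prod(shape))
    stopf("tensors must be a prod(shape) x 6 matrix")
  if (!is_affine4(affine))
    stopf("affine must be an invertible 4x4 voxel-to-world matrix")
  structure(list(tensors = tensors, shape = shape, affine = affine,
                 tensor_frame = tensor_frame),
            class = "tensor_volume")
}

#' Scalar volume
#'
#' A 3-D scalar map (FA, MD, Jacobian determinant, ...) on a voxel grid with a
#' voxel-to-world affine.
#'
#' @param values 3-D array or vector of length `prod(shape)`.
#' @param affine 4x4 voxel-to-world matrix.
#' @param shape grid sizes, required when `values` is a vector.
#' @param unit text unit label (`"1"` for FA, `"mm^2/s"` for MD).
#' @return an object of class `scalar_volume`.
#' @export
scalar_volume <- function(values, affine, shape = NULL, unit = "1") {
  if (is.array(values) && length(dim(values)) == 3L) {
    shape <- dim(values)
    values <- as.vector(values)
  }
  if (is.null(shape) || length(shape) != 3L)
    stopf("shape must be 3 positive integers")
  shape <- as.integer(shape)
  if (length(values) != prod(shape))
    stopf("values length %d does not match shape", length(values))
  if (!is_affine4(affine))
    stopf("affine must be an invertible 4x4 voxel-to-world matrix")
  structure(list(values = as.numeric(values), shape = shape, affine = affine,
                 unit = unit),
            class = "scalar_volume")
}

#' Voxel mask
#'
#' @param values logical 3-D array or vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @param shape grid sizes, required when `values` is a vector.
#' @param provenance free-text description of how the mask was derived.
#' @return an object of class `voxel_mask`.
#' @export
voxel_mask <- function(values, affine, shape = NULL, provenance = "") {
  if (is.array(values) && length(dim(values)) == 3L) {
    shape <- dim(values)
    values <- as.vector(values)
  }
  shape <- as.integer(shape)
  if (length(values) != prod(shape))
    stopf("mask length does not match shape")
  structure(list(values = as.logical(values), shape = shape, affine = affine,
                 provenance = provenance),
            class = "voxel_mask")
}

#' @export
print.tensor_volume <- function(x, ...) {
  cat(sprintf("<tensor_volume> %s voxels, spacing %s mm, frame %s\n",
              paste(x$shape, collapse = "x"),
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                    collapse = "x"),
              x$tensor_frame))
  invisible(x)
}

#' @export
print.scalar_volume <- function(x, ...) {
  rng <- range(x$values)
  cat(sprintf("<scalar_volume> %s voxels, unit '%s', range [%.4g, %.4g]\n",
              paste(x$shape, collapse = "x"), x$unit, rng[1], rng[2]))
  invisible(x)
}

#' @export
print.voxel_mask <- function(x, ...) {
  cat(sprintf("<voxel_mask> %s voxels, %d set (%s)\n",
              paste(x$shape, collapse = "x"), sum(x$values), x$provenance))
  invisible(x)
}

# internal: check two volumes share grid and affine
same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < tol
}

mask_indices <- function(mask, shape) {
  if (is.null(mask)) return(seq_len(prod(shape)))
  if (!identical(mask$shape, as.integer(shape)))
    stopf("mask shape does not match volume shape")
  which(mask$values)
}
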
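#' Read a tensor volume from NIfTI
#'
#' Reads a NIfTI image with 6 values per voxel (stored as a 4th dimension or a
#' 5th-dimension vector intent) and permutes the components into the canonical
#' lower-triangular order `(Dxx, Dxy, Dyy, Dxz, Dyz, Dzz)`.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param component_order component-order dialect of the file: `"lower"`
#'   (NIfTI lower-triangular, canonical) or `"upper"` (DTI-TK-style
#'   `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`).
#' @return a [tensor_volume()].
#' @export
read_tensor_volume <- function(path, component_order = c("lower", "upper")) {
  component_order <- match.arg(component_order)
  img <- RNifti::readNifti(path)
  arr <- unclass(img)
  d <- dim(arr)
  if (length(d) == 5L && d[4] == 1L) {
    d <- d[-4]
    dim(arr) <- d
  }
  if (length(d) != 4L || d[4] != 6L)
    stopf("expected 6 tensor components per voxel, got dims [%s]",
          paste(dim(img), collapse = ", "))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (!is_affine4(aff))
    stopf("file affine is not invertible")
  if (component_order == "upper") {
    # (xx, xy, xz, yy, yz, zz) -> (xx, xy, yy, xz, yz, zz)
    arr <- arr[, , , c(1L, 2L, 4L, 3L, 5L, 6L), drop = FALSE]
  }
  tensor_volume(array(arr, dim = d), aff)
}

#' Write a tensor volume to NIfTI
#'
#' @param vol a [tensor_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param component_order dialect to write, see [read_tensor_volume()].
#' @return invisibly, `path`.
#' @export
write_tensor_volume <- function(vol, path,
                                component_order = c("lower", "upper")) {
  component_order <- match.arg(component_order)
  stopifnot(inherits(vol, "tensor_volume"))
  tens <- vol$tensors
  if (component_order == "upper")
    tens <- tens[, c(1L, 2L, 4L, 3L, 5L, 6L), drop = FALSE]
  arr <- array(tens, c(vol$shape, 6L))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar volume from NIfTI
#' @param path input path.
#' @param unit unit label to attach.
#' @return a [scalar_volume()].
#' @export
read_scalar_volume <- function(path, unit = "1") {
  img <- RNifti::readNifti(path)
  arr <- unclass(img)
  if (length(dim(arr)) != 3L)
    stopf("expected a 3-D scalar image")
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  scalar_volume(array(arr, dim(arr)), aff, unit = unit)
}

#' Write a scalar volume (or mask) to NIfTI
#' @param vol a [scalar_volume()] or [voxel_mask()] (masks written as uint8).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scalar_volume <- function(vol, path) {
  if (inherits(vol, "voxel_mask")) {
    arr <- array(as.integer(vol$values), vol$shape)
    img <- RNifti::asNifti(arr, datatype = "uint8")
  } else {
    arr <- array(vol$values, vol$shape)
    img <- RNifti::asNifti(arr)
  }
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
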
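#' Affine spatial transform
#'
#' A 4x4 world-to-world map. Transforms in this package are stored as
#' resampling (pull-back) maps: they send coordinates of the space an image
#' is being resampled onto (the reference/template side) to coordinates of
#' the space the data comes from. This is the convention used for warps by
#' the major registration toolkits, and it makes [jacobian_determinant_map()]
#' report the determinant of the map exactly as given.
#'
#' @param matrix 4x4 matrix with last row `(0, 0, 0, 1)`.
#' @param dof 6 (rigid: the linear part must be a proper rotation) or 12.
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(matrix, dof = 12L) {
  if (!is_affine4(matrix)) stopf("not a valid 4x4 affine matrix")
  dof <- as.integer(dof)
  if (!dof %in% c(6L, 12L)) stopf("dof must be 6 or 12")
  L <- matrix[1:3, 1:3]
  if (dof == 6L) {
    if (max(abs(t(L) %*% L - diag(3))) > 1e-6 || det(L) < 0)
      stopf("a 6-dof transform must have an orthogonal linear part with det +1")
  }
  structure(list(matrix = matrix, dof = dof), class = "affine_transform")
}

#' Dense displacement field
#'
#' Per-voxel 3-vector displacement in world mm on a reference grid; the map
#' is `x -> x + u(x)` (pull-back convention, see [affine_transform()]).
#'
#' @param u `n x 3` matrix or `nx x ny x nz x 3` array of displacements (mm).
#' @param affine 4x4 voxel-to-world matrix of the reference grid.
#' @param shape grid sizes, required when `u` is a matrix.
#' @param provenance free text (e.g. subdivision level history).
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, affine, shape = NULL, provenance = "") {
  if (is.array(u) && length(dim(u)) == 4L) {
    shape <- dim(u)[1:3]
    u <- matrix(u, ncol = 3L)
  }
  shape <- as.integer(shape)
  if (!is.matrix(u) || ncol(u) != 3L || nrow(u) != prod(shape))
    stopf("u must be a prod(shape) x 3 matrix of world-mm displacements")
  if (any(!is.finite(u))) stopf("displacements must be finite")
  if (!is_affine4(affine)) stopf("invalid reference affine")
  structure(list(u = u, shape = shape, affine = affine,
                 provenance = provenance),
            class = "displacement_field")
}

#' Ordered chain of spatial transforms
#'
#' Elements are listed reference-side first: evaluating the chain at a
#' reference-space point applies the first element, then the second, ...,
#' ending in the native space of the scan the chain belongs to. A typical
#' chain from groupwise registration is `(deformable field, affine)`.
#'
#' @param ... `affine_transform` and/or `displacement_field` objects.
#' @return an object of class `transform_chain`.
#' @export
transform_chain <- function(...) {
  elems <- list(...)
  if (length(elems) == 1L && is.list(elems[[1]]) &&
      !inherits(elems[[1]], c("affine_transform", "displacement_field")))
    elems <- elems[[1]]
  ok <- vapply(elems, inherits, TRUE,
               what = c("affine_transform", "displacement_field"))
  if (length(elems) == 0L || !all(ok))
    stopf("chain elements must be affine transforms or displacement fields")
  structure(list(elements = elems), class = "transform_chain")
}

as_chain <- function(t) {
  if (inherits(t, "transform_chain")) t
  else if (inherits(t, c("affine_transform", "displacement_field")))
    transform_chain(list(t))
  else stopf("not a transform")
}

identity_transform <- function() affine_transform(diag(4), dof = 6L)

# evaluate the chain's pull-back at world points (n x 3)
chain_map_points <- function(chain, pts) {
  for (el in chain$elements) {
    if (inherits(el, "affine_transform")) {
      pts <- apply_affine_points(el$matrix, pts)
    } else {
      vox <- world_to_voxel(el$affine, pts)
      disp <- cpp_resample_channels(el$u, el$shape, vox, rep(0, 3), FALSE)
      pts <- pts + disp
    }
  }
  pts
}

#' Collapse a transform chain to a single dense displacement field
#'
#' Samples the functional composition of all chain elements on the reference
#' grid and returns it as one displacement field (so a native scan can be
#' interpolated exactly once).
#'
#' @param chain a [transform_chain()] (or a single transform).
#' @param reference a volume or list with `shape` and `affine` defining the
#'   output grid.
#' @return a [displacement_field()] on the reference grid.
#' @export
compose_transforms <- function(chain, reference) {
  chain <- as_chain(chain)
  X <- grid_world(reference$shape, reference$affine)
  P <- chain_map_points(chain, X)
  displacement_field(P - X, reference$affine, reference$shape,
                     provenance = "composed chain")
}

#' Jacobian determinant map of a transform
#'
#' Per-voxel determinant of the spatial Jacobian of the composed map on the
#' reference grid (central finite differences, one-sided at the boundary).
#' Values above 1 indicate local expansion, below 1 compression, exactly 1 no
#' volume change; a rigid map gives 1 everywhere and a pure affine the
#' constant determinant of its linear part.
#'
#' @param t a [transform_chain()], [affine_transform()] or
#'   [displacement_field()].
#' @param reference output grid (`shape` + `affine`); defaults to the field's
#'   own grid when `t` is a displacement field.
#' @return a [scalar_volume()] of determinants (unit `"1"`).
#' @export
jacobian_determinant_map <- function(t, reference = NULL) {
  if (inherits(t, "displacement_field") && is.null(reference))
    reference <- t
  if (is.null(reference)) stopf("reference grid required")
  fld <- if (inherits(t, "displacement_field") &&
             identical(t$shape, as.integer(reference$shape)) &&
             max(abs(t$affine - reference$affine)) < 1e-9) t
         else compose_transforms(t, reference)
  jd <- cpp_jacdet(fld$u, fld$shape, solve(reference$affine[1:3, 1:3]))
  scalar_volume(jd, reference$affine, reference$shape, unit = "1")
}

#' Resample a volume through a transform chain
#'
#' The chain is collapsed to a single dense map and the volume is
#' interpolated exactly once on the reference grid. Tensor volumes are
#' interpolated componentwise on matrix logarithms (guaranteeing positive
#' definite output) and each interpolated tensor is reoriented by the
#' finite-strain rotation extracted from the local Jacobian of the composed
#' map, so eigenvalues (hence FA and MD) are preserved up to interpolation.
#' Out-of-field voxels receive the isotropic floor tensor (scalars: 0).
#'
#' @param vol a [tensor_volume()] or [scalar_volume()].
#' @param t a [transform_chain()] or single transform.
#' @param reference output grid (`shape` + `affine`); defaults to `vol`'s.
#' @return a volume of the same class as `vol` on the reference grid.
#' @export
apply_transform <- function(vol, t, reference = NULL) {
  if (is.null(reference)) reference <- vol
  chain <- as_chain(t)
  X <- grid_world(reference$shape, reference$affine)
  P <- chain_map_points(chain, X)
  vox <- world_to_voxel(vol$affine, P)
  if (inherits(vol, "scalar_volume")) {
    out <- cpp_resample_channels(matrix(vol$values, ncol = 1), vol$shape,
                                 vox, 0, FALSE)
    return(scalar_volume(out[, 1], reference$affine, reference$shape,
                         unit = vol$unit))
  }
  stopifnot(inherits(vol, "tensor_volume"))
  J <- world_map_jacobian(P, reference$shape, reference$affine)
  rr <- cpp_reorient_rotations(J)
  if (any(rr$bad)) {
    idx <- which(rr$bad)[1]
    v <- arrayInd(idx, reference$shape) - 1L
    stopf("non-invertible local Jacobian at voxel (%d, %d, %d)",
          v[1], v[2], v[3])
  }
  logD <- cpp_tensor_log(vol$tensors, LAMBDA_FLOOR)
  out <- cpp_resample_tensor(logD, vol$shape, vox, rr$rot,
                             TRUE, LAMBDA_FLOOR)
  tensor_volume(out, reference$affine, shape = reference$shape)
}

#' Write an affine transform as a plain-text 4x4 matrix
#' @param t an `affine_transform`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_affine <- function(t, path) {
  stopifnot(inherits(t, "affine_transform"))
  utils::write.table(t$matrix, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a plain-text 4x4 affine transform
#' @param path input path.
#' @param dof degrees of freedom label (6 or 12).
#' @return an `affine_transform`.
#' @export
read_affine <- function(path, dof = 12L) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  affine_transform(m, dof = dof)
}
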
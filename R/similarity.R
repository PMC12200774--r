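#' Pairwise scalar-map distances
#'
#' Euclidean distance between every pair of scalar maps on a common grid:
#' `d(A, B) = sqrt(sum_v (A(v) - B(v))^2)` over the masked voxels, the
#' root-sum-of-squares distance between FA (or MD) maps of rigidly
#' pre-aligned scans.
#'
#' @param maps named list of [scalar_volume()]s sharing shape and affine.
#' @param mask optional [voxel_mask()]; defaults to the whole grid.
#' @return an object of class `distance_matrix` with fields `ids`, `values`
#'   (symmetric, zero diagonal) and `normalized = FALSE`.
#' @export
pairwise_scalar_distance <- function(maps, mask = NULL) {
  if (length(maps) < 2L)
    stopf("need at least 2 maps, got %d", length(maps))
  ids <- names(maps)
  if (is.null(ids)) ids <- sprintf("scan%02d", seq_along(maps))
  ref <- maps[[1]]
  for (m in maps) {
    stopifnot(inherits(m, "scalar_volume"))
    if (!same_grid(m, ref))
      stopf("maps do not share a common grid/affine")
  }
  idx <- mask_indices(mask, ref$shape)
  X <- vapply(maps, function(m) m$values[idx], numeric(length(idx)))
  d <- as.matrix(stats::dist(t(X)))
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, values = d, normalized = FALSE),
            class = "distance_matrix")
}

#' Normalize a distance matrix to (0, 1]
#'
#' The default mode divides by the largest pairwise distance, mapping the
#' off-diagonal entries into `(0, 1]` while preserving ratios; the reciprocal
#' similarity weights then stay within a sane dynamic range. A `"minmax"`
#' mode maps `(d - d_min) / (d_max - d_min)` instead; because that sends the
#' closest pair to 0, its result is clamped below at `eps = 1e-6`, which
#' hands that single pair a reciprocal weight of order `1/eps` and lets one
#' edge dominate the whole similarity graph - it is provided for
#' completeness, but modularity clustering should use the default.
#'
#' @param d an unnormalized `distance_matrix` over at least 2 scans.
#' @param method `"max"` (default) or `"minmax"`.
#' @return the normalized `distance_matrix` (off-diagonal entries in
#'   `[eps, 1]`).
#' @export
normalize_distances <- function(d, method = c("max", "minmax")) {
  method <- match.arg(method)
  stopifnot(inherits(d, "distance_matrix"))
  if (isTRUE(d$normalized))
    stopf("distance matrix is already normalized")
  eps <- 1e-6
  up <- upper.tri(d$values)
  rng <- range(d$values[up])
  v <- d$values
  if (rng[2] <= 0 || (method == "minmax" && diff(rng) <= 0)) {
    warning("all pairs are equidistant; normalized distances set to 1")
    v[up | t(up)] <- 1
  } else {
    v <- if (method == "max") v / rng[2]
         else (v - rng[1]) / (rng[2] - rng[1])
    v <- pmax(v, eps)
    diag(v) <- 0
  }
  structure(list(ids = d$ids, values = v, normalized = TRUE),
            class = "distance_matrix")
}

#' Similarity index graph
#'
#' Combines normalized FA and MD distances into edge weights
#' `s(A, B) = 1 / d_FA(A, B) + 1 / d_MD(A, B)`; the most dissimilar pair
#' (both distances 1) has weight 2, and weights grow as either normalized
#' distance shrinks.
#'
#' @param dfa_norm,dmd_norm normalized `distance_matrix` objects over the
#'   same scan identifiers.
#' @return an object of class `similarity_graph` with fields `ids`, `weights`
#'   (symmetric, zero diagonal) and `total_weight` (sum of all entries, the
#'   `2m` of modularity).
#' @export
similarity_index <- function(dfa_norm, dmd_norm) {
  stopifnot(inherits(dfa_norm, "distance_matrix"),
            inherits(dmd_norm, "distance_matrix"))
  if (!isTRUE(dfa_norm$normalized) || !isTRUE(dmd_norm$normalized))
    stopf("both distance matrices must be normalized")
  if (!identical(dfa_norm$ids, dmd_norm$ids))
    stopf("scan identifiers do not match between the FA and MD matrices")
  w <- 1 / dfa_norm$values + 1 / dmd_norm$values
  diag(w) <- 0
  if (any(!is.finite(w)))
    stopf("non-finite similarity weights (were the distances clamped?)")
  structure(list(ids = dfa_norm$ids, weights = w, total_weight = sum(w)),
            class = "similarity_graph")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d scans%s\n", length(x$ids),
              if (isTRUE(x$normalized)) ", normalized" else ""))
  invisible(x)
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph> %d scans, total weight %.4g\n",
              length(x$ids), x$total_weight))
  invisible(x)
}

#' Write a distance matrix or similarity graph as CSV
#'
#' The CSV has a header row of scan identifiers and one row per scan.
#'
#' @param x a `distance_matrix` or `similarity_graph`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_pairwise_csv <- function(x, path) {
  v <- if (inherits(x, "similarity_graph")) x$weights else x$values
  utils::write.csv(as.data.frame(v), path, row.names = FALSE)
  invisible(path)
}
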
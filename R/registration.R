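#' Registration engine settings
#'
#' Controls for the deterministic multi-resolution pattern-search optimizer
#' and the hierarchical piecewise-affine deformable stage. All defaults are
#' engine choices; nothing in the optimizer uses random numbers, so a given
#' (moving, fixed, control) triple always produces the same transform.
#'
#' @param pyramid integer downsampling factors, coarse to fine.
#' @param step_rot initial rotation step (radians).
#' @param step_trans_vox initial translation step, in voxels of the current
#'   pyramid level.
#' @param step_scale,step_shear initial log-scale / shear steps (affine).
#' @param min_rot,min_trans_vox convergence steps at the finest level.
#' @param mask_frac,mask_quantile the cost is evaluated where the fixed
#'   volume's MD (FA in scalar mode) exceeds `mask_frac` times its
#'   `mask_quantile` quantile over positive voxels, excluding background.
#' @param mask_dilate binary-dilation passes applied to the foreground mask
#'   so a shell of background voxels constrains the brain boundary.
#' @param trans_trust maximum translation (mm per axis) away from the
#'   center-of-mass initialization that rigid/affine optimization may
#'   explore; whole-brain alignment should not stray several mm from a
#'   matched center of mass, and the bound excludes partial-overlap basins
#'   of the cost surface.
#' @param cost_cap robust cap on the per-voxel squared log-tensor difference
#'   (tensor metric only). Tissue-level differences stay quadratic while
#'   tissue-against-background mismatches saturate, so gross misalignment is
#'   measured by non-overlap volume rather than being dominated by the
#'   boundary contrast; this keeps rigid alignment of differently-sized
#'   brains unimodal in translation.
#' @param max_sweeps pattern-search sweep limit per resolution level.
#' @param deform_step_trans,deform_step_lin initial block translation (mm)
#'   and linear-deviation steps of the deformable stage.
#' @param deform_halvings number of step halvings per block fit.
#' @param deform_penalty weight tying each block's corner displacements to
#'   zero increment (relative to the block cost at identity).
#' @param deform_max_sweeps pattern-search sweep limit per block fit.
#' @param min_block_vox blocks with fewer foreground voxels are left at the
#'   identity increment.
#' @param jac_floor minimum allowed local Jacobian determinant; increments
#'   are halved until the composed field stays above it.
#' @return a list of class `reg_control`.
#' @export
reg_control <- function(pyramid = c(4L, 2L, 1L),
                        step_rot = 0.04, step_trans_vox = 2,
                        step_scale = 0.04, step_shear = 0.04,
                        min_rot = 5e-4, min_trans_vox = 0.02,
                        mask_frac = 0.1, mask_quantile = 0.95,
                        mask_dilate = 0L,
                        metric_floor = 1e-4, cost_cap = 3, trans_trust = 4,
                        max_sweeps = 40L,
                        deform_step_trans = 1.0, deform_step_lin = 0.03,
                        deform_halvings = 2L, deform_penalty = 0.05,
                        deform_max_sweeps = 12L,
                        min_block_vox = 12L, jac_floor = 0.1) {
  structure(as.list(environment()), class = "reg_control")
}

# deterministic greedy coordinate pattern search with step halving
pattern_search <- function(par, fn, steps, min_steps, max_sweeps = 40L,
                           shrink = 0.5) {
  f0 <- fn(par)
  n_eval <- 1L
  sweeps <- 0L
  repeat {
    improved <- FALSE
    for (i in seq_along(par)) {
      for (s in c(1, -1)) {
        cand <- par
        cand[i] <- cand[i] + s * steps[i]
        fc <- fn(cand)
        n_eval <- n_eval + 1L
        if (fc < f0 - abs(f0) * 1e-12) {
          par <- cand
          f0 <- fc
          improved <- TRUE
          break
        }
      }
    }
    sweeps <- sweeps + 1L
    if (!improved) {
      if (all(steps <= min_steps + 1e-300)) break
      steps <- pmax(steps * shrink, min_steps)
    }
    if (sweeps >= max_sweeps) break
  }
  list(par = par, value = f0, evals = n_eval)
}

is_scalar_mode <- function(vol) inherits(vol, "scalar_volume")

# per-volume pyramid: foreground mask, masked values/coords, center of mass.
# Tensor values are carried through the pyramid in linear space (block means)
# and converted per level to clamped matrix logarithms: the registration
# metric is the squared Frobenius difference of log-tensors (log-Euclidean),
# matching the log-space interpolation and averaging used everywhere else.
# The metric floor (default 1e-4 mm^2/s) keeps the near-zero background from
# dominating the cost through its logarithm.
reg_prep <- function(vol, control) {
  scalar <- is_scalar_mode(vol)
  vals <- if (scalar) matrix(vol$values, ncol = 1) else vol$tensors
  lev_data <- list(list(values = vals, dim = vol$shape, affine = vol$affine))
  max_down <- max(as.integer(round(log2(control$pyramid))))
  cur <- lev_data[[1]]
  if (max_down > 0) {
    for (l in seq_len(max_down)) {
      ds <- cpp_downsample2(cur$values, cur$dim)
      aff <- cur$affine
      aff[1:3, 4] <- aff[1:3, 4] + aff[1:3, 1:3] %*% rep(0.5, 3)
      aff[1:3, 1:3] <- 2 * aff[1:3, 1:3]
      cur <- list(values = ds$values, dim = as.integer(ds$dim), affine = aff)
      lev_data[[l + 1L]] <- cur
    }
  }
  levels <- lapply(control$pyramid, function(f) {
    d <- lev_data[[as.integer(round(log2(f))) + 1L]]
    fg <- if (scalar) d$values[, 1]
          else (d$values[, 1] + d$values[, 3] + d$values[, 6]) / 3
    pos <- fg[fg > 1e-15]
    thr <- if (length(pos)) control$mask_frac *
      stats::quantile(pos, control$mask_quantile, names = FALSE) else 0
    fgm <- fg > thr
    if (!any(fgm)) stopf("empty foreground mask in registration pyramid")
    fidx <- which(fgm)
    fvox <- arrayInd(fidx, d$dim) - 1
    w <- fg[fidx]
    com <- colSums(apply_affine_points(d$affine, fvox) * w) / sum(w)
    # include a background shell so the cost also constrains the boundary
    midx <- which(dilate_mask(fgm, d$dim, control$mask_dilate))
    vox <- arrayInd(midx, d$dim) - 1
    storage.mode(vox) <- "double"
    lv <- if (scalar) d$values
          else cpp_tensor_log(d$values, control$metric_floor)
    list(values = lv, dim = d$dim, affine = d$affine,
         coords = vox, fixvals = lv[midx, , drop = FALSE],
         com = com, spacing = mean(sqrt(colSums(d$affine[1:3, 1:3]^2))))
  })
  levels
}

# cost of a world pull-back affine M between prepared pyramid levels;
# out-of-field samples count as background (the metric-floor log tensor)
affine_cost <- function(M, fix_lev, mov_lev, scalar, oob_diag = log(1e-4),
                        cap = Inf) {
  V <- solve(mov_lev$affine) %*% M %*% fix_lev$affine
  if (scalar) {
    cpp_cost_scalar(mov_lev$values[, 1], mov_lev$dim, fix_lev$fixvals[, 1],
                    fix_lev$coords, V)
  } else {
    R <- t(polar_rotation(solve(M[1:3, 1:3])))
    cpp_cost_tensor(mov_lev$values, mov_lev$dim, fix_lev$fixvals,
                    fix_lev$coords, V, R, oob_diag, cap)
  }
}

rigid_matrix <- function(p, cf, cm) {
  t4(cm + p[4:6]) %*% lin4(rot3(p[1], p[2], p[3])) %*% t4(-cf)
}

affine_increment <- function(p, cf) {
  Sh <- diag(3)
  Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  L <- rot3(p[1], p[2], p[3]) %*% Sh %*% diag(exp(p[7:9]))
  t4(cf + p[4:6]) %*% lin4(L) %*% t4(-cf)
}

#' Rigid (6-dof) tensor or scalar registration
#'
#' Minimizes the mean squared Frobenius difference between the fixed tensors
#' and the transformed-and-reoriented moving tensors (mean squared intensity
#' difference for scalar volumes) over the fixed-side foreground mask, with a
#' multi-resolution pyramid and a deterministic pattern search over 3 Euler
#' angles and 3 translations. The returned transform is the pull-back map
#' (fixed/reference world coordinates to moving world coordinates); its
#' `cost` attribute holds the final masked cost.
#'
#' The search is initialized by matching the foreground centers of mass.
#'
#' @param moving,fixed two [tensor_volume()]s (tensor metric) or two
#'   [scalar_volume()]s (scalar/FA metric).
#' @param control a [reg_control()].
#' @param prep_moving,prep_fixed precomputed internal pyramids for the two
#'   volumes (from repeated registrations against the same volume, as in
#'   template building); computed on the fly when `NULL`.
#' @return an `affine_transform` with `dof = 6`.
#' @export
register_rigid <- function(moving, fixed, control = reg_control(),
                           prep_moving = NULL, prep_fixed = NULL) {
  scalar <- is_scalar_mode(fixed)
  stopifnot(is_scalar_mode(moving) == scalar)
  fl <- if (is.null(prep_fixed)) reg_prep(fixed, control) else prep_fixed
  ml <- if (is.null(prep_moving)) reg_prep(moving, control) else prep_moving
  cf <- fl[[length(fl)]]$com
  cm <- ml[[length(ml)]]$com
  p <- rep(0, 6)
  oobd <- log(control$metric_floor)
  cap <- control$cost_cap
  ov <- affine_cost(rigid_matrix(p, cf, cm), fl[[1]], ml[[1]], scalar, oobd,
                    cap)
  if (ov[2] < 0.05)
    stopf("no overlap between volumes after center-of-mass initialization")
  # exhaustive coarse translation search around the center-of-mass start:
  # cross-stage cost surfaces can hold secondary basins that a purely local
  # descent walks into
  tt <- control$trans_trust
  fn1 <- function(q) affine_cost(rigid_matrix(q, cf, cm),
                                 fl[[1]], ml[[1]], scalar, oobd, cap)[1]
  gstep <- min(fl[[1]]$spacing / 2, tt / 2)
  offs <- expand.grid(x = c(-2, -1, 0, 1, 2) * gstep,
                      y = c(-2, -1, 0, 1, 2) * gstep,
                      z = c(-2, -1, 0, 1, 2) * gstep)
  gcosts <- apply(offs, 1, function(o) fn1(c(0, 0, 0, o)))
  p[4:6] <- as.numeric(offs[which.min(gcosts), ])
  for (l in seq_along(fl)) {
    fine <- l == length(fl)
    sp <- fl[[l]]$spacing
    fn <- function(q) {
      if (any(abs(q[4:6]) > tt)) return(Inf)
      affine_cost(rigid_matrix(q, cf, cm),
                  fl[[l]], ml[[l]], scalar, oobd, cap)[1]
    }
    if (l > 1L && fn(numeric(6)) < fn(p)) p <- numeric(6)
    steps <- c(rep(control$step_rot, 3), rep(control$step_trans_vox * sp, 3))
    mins <- c(rep(if (fine) control$min_rot else control$step_rot / 8, 3),
              rep((if (fine) control$min_trans_vox else 0.25) * sp, 3))
    res <- pattern_search(p, fn, steps, mins, control$max_sweeps)
    p <- res$par
  }
  out <- affine_transform(rigid_matrix(p, cf, cm), dof = 6L)
  attr(out, "cost") <- res$value
  out
}

#' Affine (12-dof) tensor or scalar registration
#'
#' As [register_rigid()] with 12 parameters (3 rotations, 3 translations,
#' 3 log-scales, 3 shears), optimized as an increment composed onto `init`
#' (typically the rigid result).
#'
#' @inheritParams register_rigid
#' @param init an `affine_transform` to start from; identity when `NULL`.
#' @return an `affine_transform` with `dof = 12`.
#' @export
register_affine <- function(moving, fixed, init = NULL,
                            control = reg_control(),
                            prep_moving = NULL, prep_fixed = NULL) {
  scalar <- is_scalar_mode(fixed)
  stopifnot(is_scalar_mode(moving) == scalar)
  fl <- if (is.null(prep_fixed)) reg_prep(fixed, control) else prep_fixed
  ml <- if (is.null(prep_moving)) reg_prep(moving, control) else prep_moving
  cf <- fl[[length(fl)]]$com
  M0 <- if (is.null(init)) diag(4) else init$matrix
  p <- rep(0, 12)
  oobd <- log(control$metric_floor)
  cap <- control$cost_cap
  ov <- affine_cost(M0, fl[[1]], ml[[1]], scalar, oobd, cap)
  if (ov[2] < 0.05)
    stopf("no overlap between volumes at the initial transform")
  tt <- control$trans_trust
  for (l in seq_along(fl)) {
    fine <- l == length(fl)
    sp <- fl[[l]]$spacing
    fn <- function(q) {
      if (any(abs(q[4:6]) > tt)) return(Inf)
      affine_cost(M0 %*% affine_increment(q, cf),
                  fl[[l]], ml[[l]], scalar, oobd, cap)[1]
    }
    if (l > 1L && fn(numeric(12)) < fn(p)) p <- numeric(12)
    steps <- c(rep(control$step_rot, 3), rep(control$step_trans_vox * sp, 3),
               rep(control$step_scale, 3), rep(control$step_shear, 3))
    mins <- c(rep(if (fine) control$min_rot else control$step_rot / 8, 3),
              rep((if (fine) control$min_trans_vox else 0.25) * sp, 3),
              rep(if (fine) 1e-3 else control$step_scale / 8, 6))
    res <- pattern_search(p, fn, steps, mins, control$max_sweeps)
    p <- res$par
  }
  out <- affine_transform(M0 %*% affine_increment(p, cf), dof = 12L)
  attr(out, "cost") <- res$value
  out
}

# resample a value field (same grid as the fixed volume) through x -> x + u;
# tensor-mode fields are log-tensors, reoriented per voxel by the
# finite-strain rotation (rotation congruence commutes with the matrix log)
warp_on_grid <- function(mov_values, shape, affine, X, u, scalar,
                         oob_diag = log(1e-4)) {
  P <- X + u
  vox <- world_to_voxel(affine, P)
  if (scalar) {
    list(values = cpp_resample_channels(mov_values, shape, vox, 0, FALSE))
  } else {
    J <- world_map_jacobian(P, shape, affine)
    rr <- cpp_reorient_rotations(J)
    list(values = cpp_resample_tensor(mov_values, shape, vox, rr$rot,
                                      FALSE, exp(oob_diag)))
  }
}

frob_cost <- function(a, b, cap = Inf) {
  d <- a - b
  if (ncol(d) == 1L) return(mean(d^2))
  d2 <- d[, 1]^2 + d[, 3]^2 + d[, 6]^2 +
    2 * (d[, 2]^2 + d[, 4]^2 + d[, 5]^2)
  mean(pmin(d2, cap))
}

#' Hierarchical piecewise-affine deformable registration
#'
#' The image domain is split into `2^L` uniform blocks per axis at level
#' `L = 1, ..., levels`; each block fits a local affine increment against the
#' currently-warped moving image on the tensor Frobenius cost (scalar cost in
#' scalar mode) with a quadratic penalty tying its corner displacements to
#' zero. Block transforms are blended by a trilinear partition of unity into
#' a continuous displacement increment, composed onto the accumulated field.
#' Increments are halved until the composed field's local Jacobian
#' determinant stays above `control$jac_floor`, and an increment is only
#' accepted if it lowers the masked cost, so the per-level cost trace is
#' non-increasing.
#'
#' @param moving,fixed volumes on the same grid (affinely pre-aligned).
#' @param levels number of subdivision levels (default 3: 2, 4, 8 blocks
#'   per axis).
#' @param control a [reg_control()].
#' @param init_field optional [displacement_field()] to start from.
#' @return a [displacement_field()] on the fixed grid, with attributes
#'   `cost_trace` (cost after each level) and `cost` (final cost).
#' @export
register_deformable <- function(moving, fixed, levels = 3L,
                                control = reg_control(), init_field = NULL) {
  scalar <- is_scalar_mode(fixed)
  stopifnot(is_scalar_mode(moving) == scalar)
  if (!same_grid(moving, fixed))
    stopf("deformable registration expects both volumes on one grid")
  shape <- fixed$shape
  aff <- fixed$affine
  n <- prod(shape)
  fixlin <- if (scalar) matrix(fixed$values, ncol = 1) else fixed$tensors
  movlin <- if (scalar) matrix(moving$values, ncol = 1) else moving$tensors
  oobd <- log(control$metric_floor)
  fixvals <- if (scalar) fixlin
             else cpp_tensor_log(fixlin, control$metric_floor)
  movvals <- if (scalar) movlin
             else cpp_tensor_log(movlin, control$metric_floor)
  fg <- if (scalar) fixlin[, 1]
        else (fixlin[, 1] + fixlin[, 3] + fixlin[, 6]) / 3
  pos <- fg[fg > 1e-15]
  thr <- if (length(pos)) control$mask_frac *
    stats::quantile(pos, control$mask_quantile, names = FALSE) else 0
  fgm <- fg > thr
  if (!any(fgm)) stopf("empty foreground mask")
  midx <- which(dilate_mask(fgm, shape, control$mask_dilate))
  X <- grid_world(shape, aff)
  invA <- solve(aff)
  u <- if (is.null(init_field)) matrix(0, n, 3) else init_field$u
  Li <- solve(aff[1:3, 1:3])

  field_cost <- function(u_) {
    w <- warp_on_grid(movvals, shape, aff, X, u_, scalar, oobd)
    frob_cost(w$values[midx, , drop = FALSE], fixvals[midx, , drop = FALSE],
              control$cost_cap)
  }
  cost_trace <- field_cost(u)
  vox_idx <- arrayInd(seq_len(n), shape) - 1L

  for (L in seq_len(levels)) {
    nb <- 2L^L
    warped <- warp_on_grid(movvals, shape, aff, X, u, scalar, oobd)$values
    bs <- shape / nb
    block_of <- pmin(floor(vox_idx[, 1] / bs[1]), nb - 1) +
      nb * (pmin(floor(vox_idx[, 2] / bs[2]), nb - 1) +
              nb * pmin(floor(vox_idx[, 3] / bs[3]), nb - 1))
    params <- matrix(0, nb^3, 12)  # global form: t'(3) then Ldev(9)
    blk_mask <- split(midx, block_of[midx])
    for (bkey in names(blk_mask)) {
      bidx <- blk_mask[[bkey]]
      if (length(bidx) < control$min_block_vox) next
      b <- as.integer(bkey)
      bv <- c(b %% nb, (b %/% nb) %% nb, b %/% (nb * nb))
      lo <- bv * bs
      hi <- pmin((bv + 1) * bs, shape) - 1
      corners <- as.matrix(expand.grid(c(lo[1], hi[1]), c(lo[2], hi[2]),
                                       c(lo[3], hi[3])))
      cw <- apply_affine_points(aff, corners)
      cb <- colMeans(cw)
      diag2 <- sum((apply(cw, 2, max) - apply(cw, 2, min))^2) + 1e-12
      coords <- vox_idx[bidx, , drop = FALSE]
      storage.mode(coords) <- "double"
      bfix <- fixvals[bidx, , drop = FALSE]
      V0 <- invA %*% diag(4) %*% aff
      c0 <- if (scalar)
        cpp_cost_scalar(warped[, 1], shape, bfix[, 1], coords, V0)[1]
      else cpp_cost_tensor(warped, shape, bfix, coords, V0, diag(3), oobd,
                           control$cost_cap)[1]
      pen_w <- control$deform_penalty * (c0 + 1e-300) / diag2
      steps <- c(rep(control$deform_step_trans, 3),
                 rep(control$deform_step_lin, 9))
      mins <- steps / 2^control$deform_halvings
      res <- cpp_fit_block(warped, shape, scalar, bfix, coords, aff,
                           matrix(cb, 1), cw, steps, mins,
                           control$deform_max_sweeps, pen_w, oobd,
                           control$cost_cap)
      q <- res$par
      Ldev <- matrix(q[4:12], 3, 3)
      tb <- q[1:3] - Ldev %*% cb
      params[b + 1L, ] <- c(tb, as.vector(Ldev))
    }
    # blend: trilinear interpolation of the global-form block parameters
    ccoord <- cbind((vox_idx[, 1] + 0.5) / bs[1] - 0.5,
                    (vox_idx[, 2] + 0.5) / bs[2] - 0.5,
                    (vox_idx[, 3] + 0.5) / bs[3] - 0.5)
    pint <- cpp_resample_channels(params, rep(nb, 3L), ccoord,
                                  rep(0, 12), TRUE)
    u_inc <- cbind(
      pint[, 1] + pint[, 4] * X[, 1] + pint[, 7] * X[, 2] + pint[, 10] * X[, 3],
      pint[, 2] + pint[, 5] * X[, 1] + pint[, 8] * X[, 2] + pint[, 11] * X[, 3],
      pint[, 3] + pint[, 6] * X[, 1] + pint[, 9] * X[, 2] + pint[, 12] * X[, 3])
    for (try in seq_len(10L)) {
      vox_new <- world_to_voxel(aff, X + u_inc)
      u_new <- u_inc + cpp_resample_channels(u, shape, vox_new, rep(0, 3),
                                             TRUE)
      jd <- cpp_jacdet(u_new, shape, Li)
      if (min(jd) > control$jac_floor) break
      u_inc <- u_inc / 2
    }
    if (min(jd) <= 0)
      stopf("negative Jacobian determinant after step damping")
    new_cost <- field_cost(u_new)
    if (new_cost <= cost_trace[length(cost_trace)]) {
      u <- u_new
      cost_trace <- c(cost_trace, new_cost)
    } else {
      cost_trace <- c(cost_trace, cost_trace[length(cost_trace)])
    }
  }
  out <- displacement_field(u, aff, shape,
                            provenance = sprintf("piecewise-affine levels 1..%d",
                                                 levels))
  attr(out, "cost_trace") <- cost_trace
  attr(out, "cost") <- cost_trace[length(cost_trace)]
  out
}
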
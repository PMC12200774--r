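#' Select the initial target scan and its centering translation
#'
#' Picks the medoid — the scan minimizing the summed distance to all others
#' (ties broken by lowest index) — and computes the translation that places
#' its intensity (MD-weighted, FA-weighted for scalars) center of mass at the
#' center of its grid. This automates the conventional manual choice of a
#' clean-contrast scan nudged to a standard origin.
#'
#' @param scans named list of [tensor_volume()]s (or [scalar_volume()]s).
#' @param d a `distance_matrix` over the scan ids (ignored for one scan).
#' @return a list with `id`, `index`, and `centering` (an
#'   `affine_transform` holding the pull-back translation).
#' @export
select_initial_target <- function(scans, d = NULL) {
  stopifnot(length(scans) >= 1L)
  ids <- names(scans)
  if (is.null(ids)) ids <- sprintf("scan%02d", seq_along(scans))
  if (length(scans) == 1L) {
    idx <- 1L
  } else {
    stopifnot(inherits(d, "distance_matrix"))
    sums <- rowSums(d$values[ids, ids, drop = FALSE])
    idx <- unname(which.min(sums))
  }
  vol <- scans[[idx]]
  w <- if (is_scalar_mode(vol)) vol$values
       else (vol$tensors[, 1] + vol$tensors[, 3] + vol$tensors[, 6]) / 3
  w <- pmax(w, 0)
  X <- grid_world(vol$shape, vol$affine)
  com <- colSums(X * w) / sum(w)
  ctr <- apply_affine_points(vol$affine, matrix((vol$shape - 1) / 2, 1))[1, ]
  # pull-back: resampling the scan through this translation puts its center
  # of mass at the grid center
  centering <- affine_transform(t4(com - ctr), dof = 6L)
  list(id = ids[idx], index = idx, centering = centering)
}

log_euclidean_mean <- function(vols) {
  acc <- 0
  for (v in vols) acc <- acc + cpp_tensor_log(v$tensors, LAMBDA_FLOOR)
  ref <- vols[[1]]
  tensor_volume(cpp_tensor_exp(acc / length(vols)), ref$affine,
                shape = ref$shape)
}

euclidean_mean_tensor <- function(vols) {
  acc <- 0
  for (v in vols) acc <- acc + v$tensors
  ref <- vols[[1]]
  tensor_volume(acc / length(vols), ref$affine, shape = ref$shape)
}

scalar_mean <- function(vols) {
  acc <- 0
  for (v in vols) acc <- acc + v$values
  ref <- vols[[1]]
  scalar_volume(acc / length(vols), ref$affine, ref$shape, unit = ref$unit)
}

average_volumes <- function(vols, averaging = "log_euclidean") {
  if (is_scalar_mode(vols[[1]])) scalar_mean(vols)
  else if (averaging == "euclidean") euclidean_mean_tensor(vols)
  else log_euclidean_mean(vols)
}

#' Groupwise template construction (align, average, repeat)
#'
#' Runs the three-stage schedule rigid -> affine -> deformable. Within a
#' stage, each iteration registers every scan to the current target,
#' resamples it, and replaces the target with the voxelwise log-Euclidean
#' mean (scalar mean in scalar mode) of the aligned scans. The affine stage
#' is initialized from the rigid transforms and the deformable stage from
#' the affine-aligned scans; each scan's chain records the final transforms.
#'
#' A single-scan input is its own template with an identity chain.
#'
#' @param scans named list of volumes (all tensor or all scalar).
#' @param target initial target volume (e.g. the centered medoid).
#' @param iters named iteration counts per stage,
#'   `c(rigid = 2, affine = 2, deform = 2)`; improvements beyond two
#'   iterations are typically negligible.
#' @param control a [reg_control()].
#' @param deform_levels subdivision levels of the deformable stage.
#' @param averaging `"log_euclidean"` (default) or `"euclidean"` tensor
#'   averaging.
#' @param level label stored on the result.
#' @return a list of class `template_result`: `template`, `per_scan_chains`
#'   (named list of [transform_chain()]s), `aligned` (scans resampled into
#'   template space), `stage_history` (data frame of stage, iteration, mean
#'   cost) and `level`.
#' @export
build_template <- function(scans, target,
                           iters = c(rigid = 2L, affine = 2L, deform = 2L),
                           control = reg_control(), deform_levels = 3L,
                           averaging = "log_euclidean",
                           level = "initial_target") {
  ids <- names(scans)
  if (is.null(ids)) ids <- sprintf("scan%02d", seq_along(scans))
  names(scans) <- ids
  if (length(scans) == 1L) {
    chains <- list(transform_chain(identity_transform()))
    names(chains) <- ids
    return(structure(list(template = scans[[1]], per_scan_chains = chains,
                          aligned = scans,
                          stage_history = data.frame(stage = character(),
                                                     iteration = integer(),
                                                     mean_cost = numeric()),
                          level = level),
                     class = "template_result"))
  }
  it <- function(nm, default) {
    v <- iters[[nm]]
    if (is.null(v) || is.na(v)) default else as.integer(v)
  }
  hist <- list()
  affines <- stats::setNames(vector("list", length(scans)), ids)
  fields <- stats::setNames(vector("list", length(scans)), ids)
  cur <- target
  # native scans never change: build their registration pyramids once
  preps <- lapply(scans, reg_prep, control = control)

  for (i in seq_len(it("rigid", 2L))) {
    costs <- numeric(0)
    tprep <- reg_prep(cur, control)
    for (s in ids) {
      affines[[s]] <- register_rigid(scans[[s]], cur, control,
                                     prep_moving = preps[[s]],
                                     prep_fixed = tprep)
      costs <- c(costs, attr(affines[[s]], "cost"))
    }
    aligned <- lapply(ids, function(s)
      apply_transform(scans[[s]], affines[[s]], cur))
    cur <- average_volumes(aligned)
    hist[[length(hist) + 1L]] <- data.frame(stage = "rigid", iteration = i,
                                            mean_cost = mean(costs))
  }
  for (i in seq_len(it("affine", 2L))) {
    costs <- numeric(0)
    tprep <- reg_prep(cur, control)
    for (s in ids) {
      affines[[s]] <- register_affine(scans[[s]], cur, init = affines[[s]],
                                      control = control,
                                      prep_moving = preps[[s]],
                                      prep_fixed = tprep)
      costs <- c(costs, attr(affines[[s]], "cost"))
    }
    aligned <- lapply(ids, function(s)
      apply_transform(scans[[s]], affines[[s]], cur))
    cur <- average_volumes(aligned)
    hist[[length(hist) + 1L]] <- data.frame(stage = "affine", iteration = i,
                                            mean_cost = mean(costs))
  }
  for (i in seq_len(it("deform", 2L))) {
    costs <- numeric(0)
    for (s in ids) {
      pre <- apply_transform(scans[[s]], affines[[s]], cur)
      fields[[s]] <- register_deformable(pre, cur, levels = deform_levels,
                                         control = control,
                                         init_field = fields[[s]])
      costs <- c(costs, attr(fields[[s]], "cost"))
    }
    aligned <- lapply(ids, function(s)
      apply_transform(scans[[s]],
                      transform_chain(fields[[s]], affines[[s]]), cur))
    cur <- average_volumes(aligned)
    hist[[length(hist) + 1L]] <- data.frame(stage = "deform", iteration = i,
                                            mean_cost = mean(costs))
  }
  chains <- lapply(ids, function(s) {
    if (is.null(fields[[s]])) transform_chain(affines[[s]])
    else transform_chain(fields[[s]], affines[[s]])
  })
  names(chains) <- ids
  aligned <- lapply(ids, function(s) apply_transform(scans[[s]], chains[[s]],
                                                     cur))
  names(aligned) <- ids
  structure(list(template = cur, per_scan_chains = chains, aligned = aligned,
                 stage_history = do.call(rbind, hist), level = level),
            class = "template_result")
}

#' @export
print.template_result <- function(x, ...) {
  cat(sprintf("<template_result> level '%s', %d scans, %d stage iterations\n",
              x$level, length(x$per_scan_chains), nrow(x$stage_history)))
  invisible(x)
}

#' Two-level groupwise registration via intermediate subgroup templates
#'
#' Level 1 builds a template per subgroup of the partition
#' ([build_template()] with the centered subgroup medoid as initial target);
#' level 2 runs the same construction over the subgroup templates.
#' Each scan's final chain is the composition of its level-1 chain with its
#' subgroup's level-2 chain, and every native scan is resampled exactly once
#' into the final space through the composed chain. Size-1 subgroups pass
#' their scan through level 1 untouched (with a warning): the subgroup
#' template is the scan itself.
#'
#' @param scans named list of [tensor_volume()]s.
#' @param partition a `scan_partition` covering all scan ids.
#' @param d optional `distance_matrix` over the scan ids used for medoid
#'   selection; computed from FA maps when `NULL` (scans must then share a
#'   grid).
#' @param iters,control,deform_levels,averaging as in [build_template()].
#' @return a `template_result` with `level = "final"`, per-scan composed
#'   chains and the scans aligned into the final space; also carries the
#'   `partition` and the per-subgroup level-1 results in `subgroups`.
#' @export
istg_run <- function(scans, partition, d = NULL,
                     iters = c(rigid = 2L, affine = 2L, deform = 2L),
                     control = reg_control(), deform_levels = 3L,
                     averaging = "log_euclidean") {
  ids <- names(scans)
  stopifnot(inherits(partition, "scan_partition"))
  if (!all(ids %in% partition$ids))
    stopf("partition does not cover all scans")
  if (is.null(d)) {
    fa_maps <- lapply(scans, compute_fa)
    d <- pairwise_scalar_distance(fa_maps)
  }
  groups <- partition_groups(partition)
  if (any(lengths(groups) == 0L)) stopf("empty subgroup")
  if (any(lengths(groups) == 1L))
    warning("size-1 subgroup: the scan passes through level 1 as its own template")

  lvl1 <- lapply(groups, function(gids) {
    sub <- scans[gids]
    tgt <- select_initial_target(sub, d)
    target <- apply_transform(sub[[tgt$index]], tgt$centering)
    build_template(sub, target, iters = iters, control = control,
                   deform_levels = deform_levels, averaging = averaging,
                   level = "subgroup")
  })
  templates <- lapply(lvl1, function(r) r$template)
  names(templates) <- sprintf("subgroup%02d", seq_along(templates))

  if (length(templates) == 1L) {
    lvl2_chains <- list(transform_chain(identity_transform()))
    names(lvl2_chains) <- names(templates)
    final_template <- templates[[1]]
    lvl2_hist <- NULL
  } else {
    fa_t <- lapply(templates, compute_fa)
    d2 <- pairwise_scalar_distance(fa_t)
    tgt2 <- select_initial_target(templates, d2)
    target2 <- apply_transform(templates[[tgt2$index]], tgt2$centering)
    lvl2 <- build_template(templates, target2, iters = iters,
                           control = control, deform_levels = deform_levels,
                           averaging = averaging, level = "final")
    lvl2_chains <- lvl2$per_scan_chains
    final_template <- lvl2$template
    lvl2_hist <- lvl2$stage_history
  }

  chains <- stats::setNames(vector("list", length(ids)), ids)
  for (g in seq_along(groups)) {
    gname <- names(templates)[g]
    for (s in groups[[g]]) {
      chains[[s]] <- transform_chain(c(lvl2_chains[[gname]]$elements,
                                       lvl1[[g]]$per_scan_chains[[s]]$elements))
    }
  }
  aligned <- lapply(ids, function(s)
    apply_transform(scans[[s]], chains[[s]], final_template))
  names(aligned) <- ids
  hist_parts <- lapply(seq_along(lvl1), function(g) {
    h <- lvl1[[g]]$stage_history
    if (nrow(h)) h$stage <- paste0("L1.g", g - 1L, ".", h$stage)
    h
  })
  if (!is.null(lvl2_hist) && nrow(lvl2_hist)) {
    lvl2_hist$stage <- paste0("L2.", lvl2_hist$stage)
    hist_parts <- c(hist_parts, list(lvl2_hist))
  }
  hist <- do.call(rbind, hist_parts)
  structure(list(template = final_template, per_scan_chains = chains,
                 aligned = aligned, stage_history = hist, level = "final",
                 partition = partition, subgroups = lvl1),
            class = "template_result")
}
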
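#' Single tensor-field brain phantom
#'
#' An ellipsoidal "brain" of isotropic tensors (MD about 1.0e-3 mm^2/s)
#' containing three tract systems with prolate (cigar-shaped) tensors of the
#' requested FA oriented along the local tract tangent: a midline arc
#' emulating the corpus callosum, two straight lateral bundles running
#' anterior-posterior, and a transverse bundle that crosses them (the
#' crossing region therefore contains principal directions about 90 degrees
#' apart). Background outside the ellipsoid is the isotropic floor tensor.
#' `stage_scale` scales the whole geometry, emulating global growth between
#' maturation stages; `stage_fa` sets the tract FA, emulating progressive
#' myelination.
#'
#' For a prolate tensor with mean diffusivity m, eigenvalues are
#' `m(1 + 2 delta), m(1 - delta), m(1 - delta)` with
#' `delta = FA / sqrt(3 - 2 FA^2)`, which reproduces the requested FA
#' exactly; FA targets must be below 1 for positive eigenvalues.
#'
#' Tract/tissue boundaries are softened by a small Gaussian partial-volume
#' blur (in linear tensor space, which preserves positive definiteness), as
#' in real tensor maps; tract cores are unaffected and recorded in the
#' `cores` attribute (logical masks `arc`, `lateral`, `transverse`,
#' `crossing`) before blurring.
#'
#' @param grid integer grid size (scalar or length 3); default 48, 2 mm
#'   isotropic voxels centered on the world origin.
#' @param stage_fa tract FA target in (0, 1).
#' @param stage_scale global geometry scale factor.
#' @param seed integer seed (reserved for randomized variants; the base
#'   phantom is deterministic).
#' @param spacing voxel size in mm.
#' @param edge_smoothness partial-volume blur SD in voxels (0 disables).
#' @return a [tensor_volume()] with a `cores` attribute.
#' @export
make_phantom <- function(grid = 48L, stage_fa = 0.5, stage_scale = 1,
                         seed = 0L, spacing = 2, edge_smoothness = 0.6) {
  if (length(grid) == 1L) grid <- rep(grid, 3L)
  grid <- as.integer(grid)
  if (stage_fa <= 0 || stage_fa >= 1)
    stopf("stage_fa must be in (0, 1) for positive eigenvalues")
  aff <- diag(c(spacing, spacing, spacing, 1))
  aff[1:3, 4] <- -(grid - 1) / 2 * spacing
  X <- grid_world(grid, aff)
  n <- nrow(X)
  fov <- grid * spacing
  sc <- stage_scale

  md <- 1.0e-3
  delta <- stage_fa / sqrt(3 - 2 * stage_fa^2)
  l_par <- md * (1 + 2 * delta)
  l_perp <- md * (1 - delta)

  tensors <- matrix(0, n, 6)
  tensors[, c(1, 3, 6)] <- LAMBDA_FLOOR

  radii <- 0.42 * fov * c(0.85, 1.0, 0.8) * sc
  inside <- (X[, 1] / radii[1])^2 + (X[, 2] / radii[2])^2 +
    (X[, 3] / radii[3])^2 <= 1

  # tract geometry (shared by the tract painters, the texture clearance
  # zone and the core masks). Deep tract positions scale sub-linearly with
  # global brain growth (dampening factor 0.4), as white-matter cores grow
  # less than the cortical envelope; this also keeps cross-stage rigid
  # alignment well-posed instead of tempting it to lock onto one displaced
  # bundle.
  sct <- 1 + 0.4 * (sc - 1)
  tube <- 0.055 * mean(fov) * sct   # tract tube radius, mm
  r_arc <- 0.22 * fov[2] * sct
  z_c <- -0.05 * fov[3] * sct
  rad <- sqrt(X[, 2]^2 + (X[, 3] - z_c)^2)
  arc_ok <- inside & (X[, 3] - z_c) >= -0.3 * r_arc
  x_lat <- 0.22 * fov[1] * sct
  z_lat <- -0.12 * fov[3] * sct
  y_cross <- -0.08 * fov[2] * sct
  margin <- 1.9
  zone <- (arc_ok & abs(X[, 1]) <= margin * 1.3 * tube &
             abs(rad - r_arc) <= margin * tube) |
    (sqrt((X[, 1] - x_lat)^2 + (X[, 3] - z_lat)^2) <= margin * tube) |
    (sqrt((X[, 1] + x_lat)^2 + (X[, 3] - z_lat)^2) <= margin * tube) |
    (sqrt((X[, 2] - y_cross)^2 + (X[, 3] - z_lat)^2) <= margin * tube)

  # smooth deterministic tissue texture (gray/white/CSF-like MD variation)
  # so deformation is observable away from the tracts as well; the pattern
  # is stationary across maturation stages, emulating the developmental
  # stability of diffusion contrast that motivates tensor-based alignment.
  # Tissue in the clearance zone around the tracts stays uniform so
  # partial-volume bleed cannot distort tract-core FA or MD.
  tex <- 1 + 0.35 * sin(2 * pi * X[, 1] / 31) * sin(2 * pi * X[, 2] / 37) +
    0.25 * sin(2 * pi * X[, 2] / 23 + 1) * sin(2 * pi * X[, 3] / 29 + 2)
  # fine-scale contrast that rotates between two fixed patterns as the
  # maturation stage advances (regional myelination progress): coarse
  # structure stays stationary, so global pose-finding across stages is
  # unaffected, but fine-scale correspondence between different stages is
  # genuinely ambiguous - the regime in which one-level groupwise
  # registration of a heterogeneous cohort degrades. Mixing two
  # incommensurate patterns (rather than phase-shifting one) ensures no
  # rigid shift can map one stage's fine contrast onto another's.
  p1 <- sin(2 * pi * X[, 1] / 13) * sin(2 * pi * X[, 2] / 11 + 1) *
    sin(2 * pi * X[, 3] / 17 + 2)
  p2 <- sin(2 * pi * X[, 1] / 12 + 2) * sin(2 * pi * X[, 2] / 16 + 1) *
    sin(2 * pi * X[, 3] / 10)
  wmix <- (stage_fa - 0.35) / 0.3 * pi / 2
  tex <- tex + 0.22 * (cos(wmix) * p1 + sin(wmix) * p2)
  tex[zone] <- 1
  tensors[inside, 1] <- md * tex[inside]
  tensors[inside, 3] <- md * tex[inside]
  tensors[inside, 6] <- md * tex[inside]

  set_tract <- function(tensors, sel, dirs) {
    # prolate tensor l_perp*I + (l_par - l_perp) * d d^T per voxel
    d1 <- dirs[, 1]; d2 <- dirs[, 2]; d3 <- dirs[, 3]
    dl <- l_par - l_perp
    tensors[sel, 1] <- l_perp + dl * d1^2
    tensors[sel, 2] <- dl * d1 * d2
    tensors[sel, 3] <- l_perp + dl * d2^2
    tensors[sel, 4] <- dl * d1 * d3
    tensors[sel, 5] <- dl * d2 * d3
    tensors[sel, 6] <- l_perp + dl * d3^2
    tensors
  }
  # midline arc (corpus callosum-like), in the y-z plane near x = 0
  sel_arc <- arc_ok & abs(X[, 1]) <= 1.3 * tube & abs(rad - r_arc) <= tube
  dirs <- cbind(0, -(X[sel_arc, 3] - z_c), X[sel_arc, 2])
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-12)
  tensors <- set_tract(tensors, sel_arc, dirs)

  # two lateral bundles, straight along y
  sel_lat <- rep(FALSE, n)
  for (sgn in c(-1, 1)) {
    sel <- inside &
      sqrt((X[, 1] - sgn * x_lat)^2 + (X[, 3] - z_lat)^2) <= tube &
      abs(X[, 2]) <= 0.36 * fov[2] * sct
    sel_lat <- sel_lat | sel
    tensors <- set_tract(tensors, sel,
                         matrix(rep(c(0, 1, 0), each = sum(sel)), ncol = 3))
  }

  # transverse bundle along x, crossing the laterals
  sel_tr <- inside &
    sqrt((X[, 2] - y_cross)^2 + (X[, 3] - z_lat)^2) <= tube &
    abs(X[, 1]) <= 0.3 * fov[1] * sct
  tensors <- set_tract(tensors, sel_tr,
                       matrix(rep(c(1, 0, 0), each = sum(sel_tr)), ncol = 3))

  # paired ventricle-like CSF structures: bright isotropic MD near the
  # center, the dominant landmark of real MD maps; they anchor the global
  # pose during rigid alignment across maturation stages. A clearance margin
  # keeps CSF (and its partial-volume bleed) away from the tract tubes.
  md_csf <- 2.8e-3
  for (sgn in c(-1, 1)) {
    vc <- c(sgn * 0.07, 0.03, 0.03) * fov * sc
    vr <- c(4.5, 13, 6.5) * sc
    vsel <- ((X[, 1] - vc[1]) / vr[1])^2 + ((X[, 2] - vc[2]) / vr[2])^2 +
      ((X[, 3] - vc[3]) / vr[3])^2 <= 1
    vsel <- vsel & !zone
    tensors[vsel, c(1, 3, 6)] <- md_csf
    tensors[vsel, c(2, 4, 5)] <- 0
  }


  # core masks sit well inside each tube, away from the arc's cut ends, the
  # crossing and the brain boundary, so partial-volume effects cannot reach
  cores <- list(
    arc = arc_ok & abs(X[, 1]) <= 0.5 * tube & abs(rad - r_arc) <= 0.3 * tube &
      (X[, 3] - z_c) >= 0.3 * r_arc,
    lateral = sel_lat &
      pmin(sqrt((X[, 1] - x_lat)^2 + (X[, 3] - z_lat)^2),
           sqrt((X[, 1] + x_lat)^2 + (X[, 3] - z_lat)^2)) <= 0.3 * tube &
      !sel_tr & abs(X[, 2] - y_cross) > 2 * tube &
      abs(X[, 2]) <= 0.25 * fov[2] * sct,
    transverse = sel_tr & abs(X[, 1] - x_lat) > 2 * tube &
      abs(X[, 1] + x_lat) > 2 * tube &
      sqrt((X[, 2] - y_cross)^2 + (X[, 3] - z_lat)^2) <= 0.3 * tube,
    crossing = sel_tr & sel_lat)

  if (edge_smoothness > 0)
    tensors <- smooth_field(tensors, grid, edge_smoothness)
  out <- tensor_volume(tensors, aff, shape = grid)
  attr(out, "cores") <- cores
  out
}

#' Cohort specification for the synthetic phantom generator
#'
#' Defaults emulate a longitudinal infant cohort at desk scale: three
#' maturation stages differing in tract FA (progressive myelination) and in
#' global size (growth), per-scan rigid misalignment, smooth random warps
#' (individual morphology), and tensor-valued noise.
#'
#' @param n_scans number of scans.
#' @param n_groups number of maturation-stage subgroups.
#' @param grid grid size (scalar or length 3), default 48 at 2 mm.
#' @param stage_fa per-group tract FA targets.
#' @param stage_scale per-group global scale factors.
#' @param stage_morph amplitude (mm) of the smooth stage-specific
#'   non-affine shape difference. Each stage's anatomy is deformed by a
#'   fixed smooth field (a stage-dependent mixture of two low-frequency
#'   basis fields, vanishing near the center so the ventricle pose anchors
#'   stay put); brain shape matures non-affinely between stages, which is
#'   the regime where aligning everything to one mixed average degrades.
#' @param rigid_jitter max rotation (degrees) and translation (mm),
#'   `c(rot_deg, trans_mm)`.
#' @param warp_amplitude max smooth-warp displacement (mm). The default
#'   (2.5 mm) is large enough that registration quality, not the noise
#'   floor, drives the evaluation metrics, while staying below the ~4 mm
#'   between-stage boundary displacement implied by the scale steps, so the
#'   planted stage structure remains present in the image-similarity
#'   signal - the generator's contract.
#' @param warp_smoothness Gaussian smoothing length of the random warp (mm).
#' @param noise_sd SD of additive Gaussian noise on log-tensor components.
#' @param seed integer master seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_scans = 12L, n_groups = 3L, grid = 48L,
                        stage_fa = c(0.35, 0.50, 0.65),
                        stage_scale = c(0.90, 1.00, 1.10),
                        stage_morph = 2.5,
                        rigid_jitter = c(5, 3), warp_amplitude = 2.5,
                        warp_smoothness = 12, noise_sd = 0.05, seed = 42L) {
  stopifnot(n_groups <= n_scans, all(stage_fa > 0 & stage_fa < 1),
            stage_morph >= 0, warp_amplitude >= 0, warp_smoothness > 0,
            noise_sd >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

# separable Gaussian smoothing of a voxel field (n x k), sigma in voxels
smooth_field <- function(F, shape, sigma_vox) {
  arr <- array(F, c(shape, ncol(F)))
  r <- max(1L, ceiling(3 * sigma_vox))
  kern <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    # circularly-safe edge-replicated 1-D convolution
    nv <- length(v)
    vp <- c(rep(v[1], r), v, rep(v[nv], r))
    stats::filter(vp, kern, sides = 2)[(r + 1):(r + nv)]
  }
  for (c4 in seq_len(ncol(F)))
    for (ax in 1:3) {
      a <- arr[, , , c4]
      a <- apply(a, setdiff(1:3, ax), pad_conv)
      if (ax == 2) a <- aperm(array(a, shape[c(2, 1, 3)]), c(2, 1, 3))
      if (ax == 3) a <- aperm(array(a, shape[c(3, 1, 2)]), c(2, 3, 1))
      arr[, , , c4] <- array(a, shape)
    }
  matrix(arr, ncol = ncol(F))
}

#' Generate a synthetic longitudinal phantom cohort
#'
#' Scans are assigned to maturation-stage groups (balanced by default); each
#' scan is its stage's phantom carried through a known random rigid
#' misalignment composed with a known smooth random warp (Gaussian-filtered
#' white displacement fields scaled to `warp_amplitude`), resampled once
#' with full tensor reorientation, and perturbed by seeded Gaussian noise on
#' its log-tensor components. Synthetic ages are drawn per group from the
#' disjoint ranges [0,3), [3,6) and [6,8) months, so age-based and
#' similarity-based clustering can be compared against the planted groups.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `scans` (named list of [tensor_volume()]s),
#'   `ground_truth` (per scan: group label, the applied pull-back rigid
#'   matrix, the applied warp [displacement_field()], noise seed) and
#'   `ages` (named vector, months).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  grid <- if (length(spec$grid) == 1L) rep(spec$grid, 3L) else spec$grid
  grid <- as.integer(grid)
  group_of <- rep(seq_len(spec$n_groups), length.out = spec$n_scans)
  group_of <- sort(group_of)
  bases <- lapply(seq_len(spec$n_groups), function(g) {
    ph <- make_phantom(grid, spec$stage_fa[g], spec$stage_scale[g])
    if (spec$stage_morph > 0) {
      Xg <- grid_world(ph$shape, ph$affine)
      fovg <- ph$shape * sqrt(colSums(ph$affine[1:3, 1:3]^2))
      radg <- 0.42 * fovg * c(0.85, 1.0, 0.8) * spec$stage_scale[g]
      r_rel <- sqrt((Xg[, 1] / radg[1])^2 + (Xg[, 2] / radg[2])^2 +
                      (Xg[, 3] / radg[3])^2)
      ramp <- pmin(1, pmax(0, (r_rel - 0.25) / 0.5))
      F1 <- cbind(sin(2 * pi * Xg[, 2] / 75 + 0.4),
                  sin(2 * pi * Xg[, 3] / 65 + 1.2),
                  sin(2 * pi * Xg[, 1] / 70 + 2.0))
      F2 <- cbind(sin(2 * pi * Xg[, 3] / 60 + 2.2),
                  sin(2 * pi * Xg[, 1] / 85 + 0.7),
                  sin(2 * pi * Xg[, 2] / 55 + 1.5))
      th <- (g - 1) * pi / 2 / max(1L, spec$n_groups - 1L)
      W <- (cos(th) * F1 + sin(th) * F2) * ramp
      mx <- max(sqrt(rowSums(W^2)))
      if (mx > 0) W <- W * (spec$stage_morph / mx)
      ph <- apply_transform(ph, displacement_field(W, ph$affine, ph$shape,
                                                   provenance = "stage morph"),
                            ph)
    }
    ph
  })
  ref <- bases[[1]]
  X <- grid_world(ref$shape, ref$affine)
  n <- nrow(X)
  age_lo <- c(0, 3, 6)
  age_hi <- c(3, 6, 8)

  ids <- sprintf("scan%02d", seq_len(spec$n_scans))
  scans <- list()
  gt <- list()
  ages <- numeric(spec$n_scans)
  names(ages) <- ids
  sigma_vox <- spec$warp_smoothness / mean(sqrt(colSums(ref$affine[1:3, 1:3]^2)))

  for (s in seq_len(spec$n_scans)) {
    g <- group_of[s]
    scan_seed <- spec$seed * 1000L + s
    out <- with_seed(scan_seed, {
      ang <- runif(3, -1, 1) * spec$rigid_jitter[1] * pi / 180
      tr <- runif(3, -1, 1) * spec$rigid_jitter[2]
      A <- t4(tr) %*% lin4(rot3(ang[1], ang[2], ang[3]))
      w <- matrix(rnorm(n * 3), n, 3)
      w <- smooth_field(w, grid, sigma_vox)
      mx <- max(sqrt(rowSums(w^2)))
      if (mx > 0) w <- w * (spec$warp_amplitude / mx)
      fld <- displacement_field(w, ref$affine, grid,
                                provenance = "synthetic warp")
      chain <- transform_chain(fld, affine_transform(A, dof = 6L))
      vol <- apply_transform(bases[[g]], chain, ref)
      if (spec$noise_sd > 0) {
        logD <- cpp_tensor_log(vol$tensors, LAMBDA_FLOOR)
        logD <- logD + matrix(rnorm(length(logD), sd = spec$noise_sd),
                              nrow(logD), 6)
        vol <- tensor_volume(cpp_tensor_exp(logD), vol$affine,
                             shape = vol$shape)
      }
      age <- runif(1, age_lo[g], age_hi[g])
      list(vol = vol, rigid = A, warp = fld, age = age, ang = ang, tr = tr)
    })
    scans[[ids[s]]] <- out$vol
    ages[s] <- out$age
    gt[[ids[s]]] <- list(group = g - 1L, rigid = out$rigid, warp = out$warp,
                         angles = out$ang, translation = out$tr,
                         noise_seed = scan_seed)
  }
  list(scans = scans, ground_truth = gt, ages = ages,
       groups = stats::setNames(group_of - 1L, ids), spec = spec)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `v(x) + u(x + v(x)) = 0`, so that composing the two fields
#' cancels to interpolation accuracy; used to realign phantom scans by the
#' recorded ground-truth transforms.
#'
#' @param fld a [displacement_field()].
#' @param n_iter fixed-point iterations (default 20).
#' @return a [displacement_field()] on the same grid.
#' @export
invert_displacement_field <- function(fld, n_iter = 20L) {
  X <- grid_world(fld$shape, fld$affine)
  v <- -fld$u
  for (i in seq_len(n_iter)) {
    vox <- world_to_voxel(fld$affine, X + v)
    v <- -cpp_resample_channels(fld$u, fld$shape, vox, rep(0, 3), TRUE)
  }
  displacement_field(v, fld$affine, fld$shape, provenance = "inverted field")
}
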
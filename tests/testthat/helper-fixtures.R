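# shared fixtures; expensive objects are built once per test run

iso_affine <- function(spacing = 2, shape = c(4L, 4L, 4L)) {
  a <- diag(c(spacing, spacing, spacing, 1))
  a[1:3, 4] <- -(shape - 1) / 2 * spacing
  a
}

# constant-tensor volume from 6 components
const_tensor_volume <- function(comp6, shape = c(4L, 4L, 4L), spacing = 2) {
  tensor_volume(matrix(comp6, prod(shape), 6, byrow = TRUE),
                iso_affine(spacing, shape), shape = shape)
}

# random PSD tensor field (deterministic given seed)
random_tensor_volume <- function(shape = c(6L, 6L, 6L), seed = 1,
                                 scale = 1e-3) {
  set.seed(seed)
  n <- prod(shape)
  tens <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    A <- matrix(rnorm(9), 3, 3)
    D <- scale * (crossprod(A) / 3 + diag(3) * 0.1)
    tens[i, ] <- c(D[1, 1], D[1, 2], D[2, 2], D[1, 3], D[2, 3], D[3, 3])
  }
  tensor_volume(tens, iso_affine(2, shape), shape = shape)
}

rotate_tensor6 <- function(comp6, R) {
  D <- matrix(c(comp6[1], comp6[2], comp6[4],
                comp6[2], comp6[3], comp6[5],
                comp6[4], comp6[5], comp6[6]), 3, 3)
  Dr <- R %*% D %*% t(R)
  c(Dr[1, 1], Dr[1, 2], Dr[2, 2], Dr[1, 3], Dr[2, 3], Dr[3, 3])
}

rz <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# brute-force maximum modularity over all partitions of n <= 8 nodes
all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (j in seq_along(p)) {
      q <- p
      q[[j]] <- c(q[[j]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

matrix_modularity <- function(W, labels, gamma = 1) {
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (c in unique(labels)) {
    m <- labels == c
    q <- q + sum(W[m, m]) / two_m - gamma * (sum(k[m]) / two_m)^2
  }
  q
}

brute_force_best_q <- function(W, gamma = 1) {
  best <- -Inf
  for (p in all_partitions(nrow(W))) {
    lab <- integer(nrow(W))
    for (j in seq_along(p)) lab[p[[j]]] <- j
    best <- max(best, matrix_modularity(W, lab, gamma))
  }
  best
}

sim_graph_from_matrix <- function(W, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("n%02d", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)
  structure(list(ids = ids, weights = W, total_weight = sum(W)),
            class = "similarity_graph")
}

two_cliques_graph <- function() {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1; W[4:6, 4:6] <- 1
  diag(W) <- 0
  sim_graph_from_matrix(W)
}

# cached expensive fixtures -------------------------------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# the packaged default heterogeneous cohort (n = 12, 3 stages, seed 42)
default_cohort <- function() cached("cohort", make_cohort(cohort_spec()))

# rigid pre-alignment of the default cohort to the centered medoid plus the
# similarity graph built from the pre-aligned FA/MD maps
cohort_similarity <- function() cached("similarity", {
  co <- default_cohort()
  scans <- co$scans
  fa <- lapply(scans, compute_fa)
  d0 <- pairwise_scalar_distance(fa)
  tgt <- select_initial_target(scans, d0)
  target <- apply_transform(scans[[tgt$index]], tgt$centering)
  pre <- lapply(scans, function(s)
    apply_transform(s, register_rigid(s, target), target))
  d_fa <- normalize_distances(pairwise_scalar_distance(lapply(pre, compute_fa)))
  d_md <- normalize_distances(pairwise_scalar_distance(lapply(pre, compute_md)))
  list(graph = similarity_index(d_fa, d_md), pre = pre, target = target,
       d0 = d0)
})

# the full method-comparison experiment on the default cohort
cohort_experiment <- function() cached("experiment", {
  co <- default_cohort()
  run_experiment(co$scans,
                 methods = c("fa-onelevel", "tensor-onelevel",
                             "istg-louvain", "istg-age"),
                 ages = co$ages,
                 iters = c(rigid = 1L, affine = 1L, deform = 1L),
                 deform_levels = 3L, cluster_seed = 1L)
})
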
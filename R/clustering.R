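#' Louvain community detection on a similarity graph
#'
#' Greedy weighted-modularity maximization in two alternating phases: local
#' node moves (each node is reassigned to the neighbouring community with the
#' largest modularity gain, staying put on ties) and community aggregation
#' (communities collapse into super-nodes and the procedure repeats on the
#' aggregated graph). Iteration stops when the best available gain falls
#' below `gain_tol`. The node visit order is shuffled by `seed`, which fully
#' determines the result.
#'
#' @param g a [similarity_index()] graph.
#' @param resolution resolution parameter `gamma` of the modularity null
#'   term (default 1).
#' @param gain_tol minimum modularity gain to keep iterating (default 1e-9).
#' @param seed integer seed for the node visit order.
#' @return an object of class `scan_partition` with 0-based contiguous
#'   subgroup labels, `method = "louvain"`, and the achieved `modularity`.
#' @export
louvain_partition <- function(g, resolution = 1, gain_tol = 1e-9, seed = 1L) {
  stopifnot(inherits(g, "similarity_graph"))
  W <- g$weights
  n <- nrow(W)
  if (n < 2L) stopf("need at least 2 nodes")
  if (max(abs(W - t(W))) > 1e-8) stopf("similarity weights must be symmetric")
  labels <- with_seed(seed, louvain_core(W, resolution, gain_tol))
  part <- new_partition(g$ids, labels, method = "louvain",
                        resolution = resolution)
  part$modularity <- modularity(g, part, resolution)
  part
}

# Louvain on a raw weight matrix; returns 1-based labels per node.
# W may carry self-loops on the diagonal (aggregated graphs do).
louvain_core <- function(W, resolution, gain_tol) {
  n0 <- nrow(W)
  node_of <- seq_len(n0)   # original node -> current super-node
  repeat {
    n <- nrow(W)
    k <- rowSums(W)        # weighted degree incl. self-loops
    two_m <- sum(k)
    if (two_m <= 0) return(rep(1L, n0))
    lab <- seq_len(n)
    sigma_tot <- k
    moved_any <- FALSE
    move_tol <- max(gain_tol / n, 1e-13)
    passes <- 0L
    repeat {
      pass_gain <- 0
      order_ <- sample.int(n)
      for (i in order_) {
        ci <- lab[i]
        # link weights from i to each community (excluding the self edge)
        wi <- W[i, ]
        wi[i] <- 0
        s_to <- tapply_sum(wi, lab, n_levels = n)
        sigma_tot[ci] <- sigma_tot[ci] - k[i]
        gains <- s_to - resolution * k[i] * sigma_tot / two_m
        gains_q <- gains / (two_m / 2)
        best <- which.max(gains_q)
        if (gains_q[best] > gains_q[ci] + move_tol && best != ci) {
          pass_gain <- pass_gain + (gains_q[best] - gains_q[ci])
          lab[i] <- best
          sigma_tot[best] <- sigma_tot[best] + k[i]
          moved_any <- TRUE
        } else {
          sigma_tot[ci] <- sigma_tot[ci] + k[i]
        }
      }
      passes <- passes + 1L
      if (pass_gain < gain_tol || passes >= 100L) break
    }
    lab <- match(lab, sort(unique(lab)))
    if (!moved_any || length(unique(lab)) == n) {
      return(lab[node_of])
    }
    # aggregation phase: communities become nodes, internal weight -> self-loop
    nc <- max(lab)
    A <- matrix(0, nc, nc)
    for (c1 in seq_len(nc)) {
      m1 <- lab == c1
      for (c2 in c1:nc) {
        m2 <- lab == c2
        A[c1, c2] <- A[c2, c1] <- sum(W[m1, m2, drop = FALSE])
      }
    }
    node_of <- lab[node_of]
    W <- A
  }
}

tapply_sum <- function(x, group, n_levels) {
  out <- numeric(n_levels)
  agg <- vapply(split(x, factor(group, levels = seq_len(n_levels))), sum, 0)
  out[seq_len(n_levels)] <- agg
  out
}

#' Weighted Newman-Girvan modularity
#'
#' `Q = sum_c [ S_in_c / 2m - gamma * (S_tot_c / 2m)^2 ]`, where `S_in_c` is
#' the total weight of edges inside community `c` (each counted twice),
#' `S_tot_c` the total weighted degree of its nodes and `2m` the total graph
#' weight.
#'
#' @param g a [similarity_index()] graph.
#' @param labels a `scan_partition` covering all of `g`'s ids.
#' @param resolution resolution parameter `gamma`.
#' @return the modularity value.
#' @export
modularity <- function(g, labels, resolution = 1) {
  stopifnot(inherits(g, "similarity_graph"),
            inherits(labels, "scan_partition"))
  lab <- labels$labels[g$ids]
  if (any(is.na(lab)))
    stopf("partition does not cover all graph nodes")
  W <- g$weights
  two_m <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (c in unique(lab)) {
    m <- lab == c
    q <- q + sum(W[m, m]) / two_m - resolution * (sum(k[m]) / two_m)^2
  }
  q
}

new_partition <- function(ids, labels1, method, resolution = NA_real_) {
  labels1 <- match(labels1, sort(unique(labels1)))  # contiguous from 1
  lab <- as.integer(labels1) - 1L
  names(lab) <- ids
  structure(list(ids = ids, labels = lab, method = method,
                 modularity = NA_real_, resolution = resolution),
            class = "scan_partition")
}

#' Partition scans by chronological age
#'
#' Half-open binning at the given cutoffs (defaults 3 and 6 months):
#' `[0, 3)`, `[3, 6)`, `[6, Inf)`; a scan aged exactly at a cutoff falls in
#' the older bin. Empty bins are dropped with a warning and labels
#' re-compacted.
#'
#' @param ids scan identifiers.
#' @param ages named numeric vector, age in months per id.
#' @param cutoffs increasing cutoff ages in months.
#' @return a `scan_partition` with `method = "age"`.
#' @export
partition_by_age <- function(ids, ages, cutoffs = c(3, 6)) {
  a <- ages[ids]
  if (any(is.na(a)))
    stopf("missing age for: %s", paste(ids[is.na(a)], collapse = ", "))
  if (any(a < 0)) stopf("ages must be >= 0")
  bin <- findInterval(a, cutoffs) + 1L
  if (length(unique(bin)) < length(cutoffs) + 1L)
    warning("empty age bins dropped; subgroup indices re-compacted")
  new_partition(ids, bin, method = "age")
}

#' Trivial single-group partition
#' @param ids scan identifiers (at least one).
#' @return a `scan_partition` labelling every scan 0, `method = "single"`.
#' @export
single_partition <- function(ids) {
  stopifnot(length(ids) >= 1L)
  new_partition(ids, rep(1L, length(ids)), method = "single")
}

#' @export
print.scan_partition <- function(x, ...) {
  cat(sprintf("<scan_partition> %d scans, %d subgroups (%s)%s\n",
              length(x$ids), length(unique(x$labels)), x$method,
              if (is.finite(x$modularity))
                sprintf(", Q = %.4f", x$modularity) else ""))
  invisible(x)
}

#' Subgroup membership as a list of id vectors
#' @param p a `scan_partition`.
#' @return list of character vectors, one per subgroup index.
#' @export
partition_groups <- function(p) {
  stopifnot(inherits(p, "scan_partition"))
  split(p$ids, p$labels[p$ids])
}

#' Write a partition as a two-column CSV (id, label)
#' @param p a `scan_partition`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_partition_csv <- function(p, path) {
  utils::write.csv(data.frame(id = p$ids, label = p$labels[p$ids]),
                   path, row.names = FALSE)
  invisible(path)
}
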
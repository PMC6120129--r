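# Independent oracles and fixture builders used across the suite.
# All oracles deliberately use different algorithms from the package code
# (Floyd-Warshall instead of BFS, exhaustive enumeration instead of Prim).

# Random spanning tree on n nodes (random attachment), as a weighted_network
# plus its known edge list.
random_tree_network <- function(n, weights = NULL) {
  stopifnot(n >= 2)
  parent <- c(NA, vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1)))
  if (is.null(weights)) weights <- stats::runif(n - 1L, 0.5, 5)
  W <- matrix(0, n, n)
  for (i in 2:n) {
    W[i, parent[i]] <- weights[i - 1L]
    W[parent[i], i] <- weights[i - 1L]
  }
  list(net = weighted_network(W),
       edges = cbind(pmin(2:n, parent[-1]), pmax(2:n, parent[-1])))
}

# Random connected weighted graph (rejection sampling on connectivity).
random_connected_network <- function(n, p = 0.5) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    pres <- stats::rbinom(sum(ut), 1, p)
    W[ut] <- pres * stats::runif(sum(ut), 0.2, 8)
    W <- W + t(W)
    if (connected_oracle(W > 0)) return(weighted_network(W))
  }
}

# Connectivity via matrix powers of the adjacency (independent of BFS code).
connected_oracle <- function(adj) {
  n <- nrow(adj)
  reach <- diag(n) + adj
  for (k in seq_len(n)) reach <- (reach %*% reach > 0) + 0
  all(reach > 0)
}

# Exhaustive minimum spanning tree: enumerate all (n-1)-subsets of present
# edges, keep those forming a spanning tree, minimize total cost 1/w.
brute_force_mst_cost <- function(net) {
  W <- unclass(net)
  n <- nrow(W)
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  m <- nrow(idx)
  stopifnot(m >= n - 1)
  best <- Inf
  for (comb in utils::combn(m, n - 1L, simplify = FALSE)) {
    adj <- matrix(FALSE, n, n)
    for (k in comb) {
      adj[idx[k, 1], idx[k, 2]] <- TRUE
      adj[idx[k, 2], idx[k, 1]] <- TRUE
    }
    if (connected_oracle(adj)) {
      cost <- sum(1 / W[cbind(idx[comb, 1], idx[comb, 2])])
      if (cost < best) best <- cost
    }
  }
  best
}

# All-pairs hop distances by Floyd-Warshall on the tree's adjacency.
floyd_warshall_hops <- function(tree) {
  n <- tree$n
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(tree$edges))) {
    D[tree$edges$from[k], tree$edges$to[k]] <- 1
    D[tree$edges$to[k], tree$edges$from[k]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

# Betweenness oracle: enumerate the unique path of every unordered pair by
# depth-first search and count interior passages.
path_enum_betweenness <- function(tree) {
  n <- tree$n
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(tree$edges))) {
    adj[tree$edges$from[k], tree$edges$to[k]] <- TRUE
    adj[tree$edges$to[k], tree$edges$from[k]] <- TRUE
  }
  find_path <- function(from, to) {
    stack <- list(from)
    seen <- logical(n); seen[from] <- TRUE
    prev <- integer(n)
    while (length(stack) > 0) {
      u <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (u == to) break
      for (v in which(adj[u, ] & !seen)) {
        seen[v] <- TRUE; prev[v] <- u
        stack[[length(stack) + 1L]] <- v
      }
    }
    path <- to
    while (path[1] != from) path <- c(prev[path[1]], path)
    path
  }
  counts <- numeric(n)
  for (j in seq_len(n - 1)) for (k in (j + 1):n) {
    interior <- setdiff(find_path(j, k), c(j, k))
    counts[interior] <- counts[interior] + 1
  }
  counts / ((n - 1) * (n - 2) / 2)
}

# Path and star networks with controllable weights.
path_network <- function(weights) {
  n <- length(weights) + 1L
  W <- matrix(0, n, n)
  for (i in seq_along(weights)) {
    W[i, i + 1L] <- weights[i]
    W[i + 1L, i] <- weights[i]
  }
  weighted_network(W)
}

star_network <- function(n, hub_weight = 10, other_weight = NULL) {
  W <- matrix(0, n, n)
  W[1, 2:n] <- hub_weight
  W[2:n, 1] <- hub_weight
  if (!is.null(other_weight)) {
    for (i in 2:(n - 1)) for (j in (i + 1):n) {
      W[i, j] <- other_weight
      W[j, i] <- other_weight
    }
  }
  weighted_network(W)
}

# Straight-tube tensor phantom along x: atlas with two end regions, a
# single-voxel-thick suprathreshold tube of exactly `n_tube` voxels.
straight_tube_phantom <- function(n_tube = 26L, pad = 2L,
                                  ad = 1.7e-3, rd = 0.3e-3) {
  vs <- 0.2
  nx <- n_tube + 2L * pad
  dims <- c(nx, 5L, 5L)
  labels <- array(0L, dim = dims)
  yz <- 3L  # tube row (1-based index), center y = z = 0.5 mm
  labels[(pad + 1L):(pad + 3L), yz, yz] <- 1L          # start region
  labels[(pad + n_tube - 2L):(pad + n_tube), yz, yz] <- 2L  # end region
  atlas <- atlas_volume(labels, vs)
  x0 <- (pad + 0.5) * vs
  x1 <- (pad + n_tube - 0.5) * vs
  ymid <- (yz - 0.5) * vs
  bundle <- bundle_spec(1L, 2L, rbind(c(x0, ymid, ymid), c(x1, ymid, ymid)),
                        radius = 0.09, axial_diffusivity = ad,
                        radial_diffusivity = rd)
  tensors <- make_bundle_tensor_field(atlas, list(bundle),
                                      background_diffusivity = 0.3e-3)
  eig <- eigen_decompose(tensors)
  fa <- fa_map(eig)
  dirs <- array(eig$vectors[, , , , 1L], dim = c(dims, 3L))
  list(atlas = atlas, tensors = tensors, fa = fa, dirs = dirs,
       tube_mask = fa$data >= 0.15, n_tube = n_tube, pad = pad, vs = vs,
       mid_point = c((pad + n_tube / 2) * vs, ymid, ymid))
}
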
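#' Weighted structural network
#'
#' A structural network is the graph S = (N, W): named nodes (atlas regions)
#' and a symmetric non-negative weight matrix with zero diagonal, where w_ij
#' counts the (normalized) streamlines connecting regions i and j.
#'
#' @param W numeric square matrix; symmetric within 1e-12, non-negative,
#'   zero diagonal.
#' @param nodes node names (defaults to existing dimnames or N1..Nn).
#' @return matrix of class `weighted_network`.
#' @export
weighted_network <- function(W, nodes = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  stopifnot(n == ncol(W))
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  if (any(W < 0)) stop("weights must be non-negative")
  if (any(diag(W) != 0)) stop("diagonal (self-connections) must be zero")
  if (is.null(nodes)) {
    nodes <- rownames(W)
    if (is.null(nodes)) nodes <- paste0("N", seq_len(n))
  }
  stopifnot(length(nodes) == n, !anyDuplicated(nodes))
  dimnames(W) <- list(nodes, nodes)
  class(W) <- c("weighted_network", "matrix", "array")
  W
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network: %d nodes, %d edges, density %.3f>\n",
              nrow(x), sum(x[upper.tri(x)] > 0), network_density(x)))
  invisible(x)
}

#' Build a weighted network from streamline endpoints and atlas labels
#'
#' Two regions are connected by a streamline iff its two terminal points fall
#' in voxels carrying the two (distinct) region labels; w_ij sums the
#' normalization weights of all such streamlines. Streamlines with either
#' endpoint in background, or with both endpoints in the same region
#' (self-connections), contribute nothing.
#'
#' @param tractogram a [tractogram] (normalized weights used if present,
#'   else unit weights).
#' @param atlas an [atlas_volume] in the same coordinate frame.
#' @param regions region table defining the node set and order.
#' @return a [weighted_network] over the region names.
#' @export
build_network <- function(tractogram, atlas, regions = region_table()) {
  stopifnot(inherits(tractogram, "tractogram"),
            inherits(atlas, "atlas_volume"))
  if (max(abs(tractogram$voxel_size - atlas$voxel_size)) > 1e-9) {
    stop("tractogram and atlas voxel sizes differ: coordinate frame mismatch")
  }
  n <- nrow(regions)
  W <- matrix(0, n, n)
  dims <- dim(atlas$labels)
  vs <- atlas$voxel_size
  w <- tractogram$weights
  if (is.null(w)) w <- rep(1, tractogram$n_retained)
  for (k in seq_along(tractogram$streamlines)) {
    sl <- tractogram$streamlines[[k]]
    ends <- sl[c(1L, nrow(sl)), , drop = FALSE]
    v <- floor(sweep(ends, 2, vs, "/"))
    if (any(v < 0) || any(sweep(v, 2, dims, ">="))) next
    l1 <- atlas$labels[v[1, 1] + 1L, v[1, 2] + 1L, v[1, 3] + 1L]
    l2 <- atlas$labels[v[2, 1] + 1L, v[2, 2] + 1L, v[2, 3] + 1L]
    if (l1 > 0L && l2 > 0L && l1 != l2) {
      W[l1, l2] <- W[l1, l2] + w[k]
      W[l2, l1] <- W[l2, l1] + w[k]
    }
  }
  weighted_network(W, regions$name)
}

#' Network density
#'
#' Fraction of existing edges over the N(N-1)/2 possible undirected edges
#' (self-connections excluded).
#'
#' @param net a [weighted_network].
#' @return scalar in \[0, 1\].
#' @export
network_density <- function(net) {
  n <- nrow(net)
  if (n < 2L) stop("density is undefined for networks with fewer than 2 nodes")
  sum(net[upper.tri(net)] > 0) / (n * (n - 1) / 2)
}

#' Binarize a network
#'
#' All positive connection weights are set to one.
#'
#' @param net a [weighted_network].
#' @return a binary [weighted_network].
#' @export
binarize <- function(net) {
  weighted_network((unclass(net) > 0) + 0, rownames(net))
}

#' Group prevalence of connections
#'
#' Per edge, the fraction of subjects in which the connection exists
#' (mean of the binarized matrices).
#'
#' @param nets list of [weighted_network]s over one node set.
#' @return a [weighted_network] of prevalences in \[0, 1\].
#' @export
group_prevalence <- function(nets) {
  stopifnot(length(nets) >= 1L)
  nodes <- rownames(nets[[1]])
  for (nt in nets) {
    if (!identical(rownames(nt), nodes)) stop("networks have mixed node sets")
  }
  acc <- Reduce(`+`, lapply(nets, function(nt) unclass(binarize(nt))))
  weighted_network(acc / length(nets), nodes)
}

#' Extract the flagged sub-network
#'
#' Principal submatrix over the regions carrying a flag (by default the 16
#' sensorimotor regions), node order preserved.
#'
#' @param net a [weighted_network] over the full region set.
#' @param regions region table.
#' @param flag name of a logical column of `regions` (default "sensorimotor").
#' @return a [weighted_network] over the flagged regions.
#' @export
extract_subnetwork <- function(net, regions = region_table(),
                               flag = "sensorimotor") {
  sel <- regions$name[regions[[flag]]]
  missing <- setdiff(sel, rownames(net))
  if (length(missing) > 0) {
    stop("flagged nodes missing from network: ", paste(missing, collapse = ", "))
  }
  weighted_network(unclass(net)[sel, sel, drop = FALSE], sel)
}
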
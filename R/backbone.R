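#' Minimum spanning tree backbone of a weighted network
#'
#' Extracts the network backbone: the spanning tree minimizing the total
#' connectivity cost, where the cost of an edge is the inverse of its weight
#' (strong connections are cheap, so the tree retains the strongest
#' connections). Computed with the Prim--Jarnik algorithm. Among equal-cost
#' candidate edges the lexicographically smallest node pair (i, j), i < j, is
#' chosen, which makes the returned tree deterministic; the total cost is
#' tie-free by optimality.
#'
#' @param net a [weighted_network]; the graph over its positive-weight edges
#'   must be connected.
#' @param on_disconnected "error" (default) or "largest_component", which
#'   restricts the tree to the largest connected component and records a
#'   warning.
#' @return object of class `tree_backbone`: list with `nodes` (names),
#'   `edges` (data.frame `from`, `to` (node indices, from < to), `weight`,
#'   `cost = 1/weight`) and `n`.
#' @export
minimum_spanning_tree <- function(net,
                                  on_disconnected = c("error",
                                                      "largest_component")) {
  on_disconnected <- match.arg(on_disconnected)
  W <- unclass(net)
  nodes <- rownames(W)
  comp <- graph_components(W > 0)
  keep <- seq_len(nrow(W))
  if (max(comp) > 1L) {
    sizes <- tabulate(comp)
    if (on_disconnected == "error") {
      stop(sprintf("network is disconnected (component sizes: %s)",
                   paste(sort(sizes, decreasing = TRUE), collapse = ", ")))
    }
    warning(sprintf("restricting to largest component (%d of %d nodes)",
                    max(sizes), nrow(W)))
    keep <- which(comp == which.max(sizes))
    W <- W[keep, keep, drop = FALSE]
    nodes <- nodes[keep]
  }
  n <- nrow(W)
  edges <- prim_jarnik(W)
  structure(list(nodes = nodes, edges = edges, n = n),
            class = "tree_backbone")
}

# Prim–Jarnik on cost = 1/weight with lexicographic tie-breaking.
# W: symmetric non-negative matrix, positive-weight graph assumed connected.
prim_jarnik <- function(W) {
  n <- nrow(W)
  if (n == 1L) {
    return(data.frame(from = integer(0), to = integer(0),
                      weight = numeric(0), cost = numeric(0)))
  }
  C <- ifelse(W > 0, 1 / W, Inf)
  diag(C) <- Inf
  in_tree <- logical(n)
  best_cost <- rep(Inf, n)
  best_from <- rep(NA_integer_, n)
  in_tree[1L] <- TRUE
  relax <- function(u) {
    for (v in which(!in_tree)) {
      cuv <- C[u, v]
      if (cuv < best_cost[v] ||
          (cuv == best_cost[v] && !is.na(best_from[v]) &&
           edge_lex_less(u, v, best_from[v], v))) {
        best_cost[v] <<- cuv
        best_from[v] <<- u
      }
    }
  }
  relax(1L)
  from <- integer(n - 1L); to <- integer(n - 1L); wt <- numeric(n - 1L)
  for (k in seq_len(n - 1L)) {
    cand <- which(!in_tree & best_cost == min(best_cost[!in_tree]))
    if (!is.finite(min(best_cost[!in_tree]))) {
      stop("internal error: graph disconnected inside Prim-Jarnik")
    }
    # among equal-cost frontier edges pick the lexicographically smallest pair
    if (length(cand) > 1L) {
      pick <- cand[1L]
      for (v in cand[-1L]) {
        if (edge_lex_less(best_from[v], v, best_from[pick], pick)) pick <- v
      }
    } else pick <- cand
    in_tree[pick] <- TRUE
    from[k] <- min(best_from[pick], pick)
    to[k] <- max(best_from[pick], pick)
    wt[k] <- W[best_from[pick], pick]
    relax(pick)
  }
  data.frame(from = from, to = to, weight = wt, cost = 1 / wt)
}

edge_lex_less <- function(a1, a2, b1, b2) {
  ai <- min(a1, a2); aj <- max(a1, a2)
  bi <- min(b1, b2); bj <- max(b1, b2)
  ai < bi || (ai == bi && aj < bj)
}

# Connected components of a logical adjacency matrix (BFS labelling).
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.tree_backbone <- function(x, ...) {
  cat(sprintf("<tree_backbone: %d nodes, %d edges, total cost %.4g>\n",
              x$n, nrow(x$edges), sum(x$edges$cost)))
  invisible(x)
}

# Adjacency list of a tree_backbone.
tree_adjacency <- function(tree) {
  adj <- vector("list", tree$n)
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$from[k]; j <- tree$edges$to[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# All-pairs hop distances along the unique tree paths (BFS from every node).
tree_hop_distances <- function(tree) {
  n <- tree$n
  adj <- tree_adjacency(tree)
  D <- matrix(NA_integer_, n, n)
  for (s in seq_len(n)) {
    d <- rep(NA_integer_, n)
    d[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in adj[[u]]) if (is.na(d[v])) {
        d[v] <- d[u] + 1L
        queue <- c(queue, v)
      }
    }
    D[s, ] <- d
  }
  D
}

#' Betweenness centrality on a tree backbone
#'
#' On a tree every node pair has exactly one path, so betweenness of node i
#' reduces to the fraction of unordered pairs \{j, k\} (both distinct from i)
#' whose unique path passes through i, normalized by (n-1)(n-2)/2 to lie in
#' \[0, 1\]. Computed by removing i and counting pairs split across the
#' resulting components.
#'
#' @param tree a `tree_backbone` with at least 3 nodes.
#' @return named numeric vector of nodal betweenness values.
#' @export
tree_betweenness <- function(tree) {
  n <- tree$n
  if (n < 3L) stop("betweenness is undefined for trees with fewer than 3 nodes")
  adj <- tree_adjacency(tree)
  bc <- numeric(n)
  total_pairs <- (n - 1) * (n - 2) / 2
  for (i in seq_len(n)) {
    # component sizes of the forest after deleting node i: one BFS per neighbor
    sizes <- vapply(adj[[i]], function(s) {
      seen <- logical(n)
      seen[c(i, s)] <- TRUE
      queue <- s
      cnt <- 1L
      while (length(queue) > 0L) {
        u <- queue[1L]; queue <- queue[-1L]
        for (v in adj[[u]]) if (!seen[v]) {
          seen[v] <- TRUE
          cnt <- cnt + 1L
          queue <- c(queue, v)
        }
      }
      cnt
    }, integer(1))
    through <- (sum(sizes)^2 - sum(sizes^2)) / 2  # cross-component pairs
    bc[i] <- through / total_pairs
  }
  names(bc) <- tree$nodes
  bc
}

#' Nodal strength on a tree backbone
#'
#' Sum of the original connection weights (not costs) of the tree edges
#' incident to each node.
#'
#' @param tree a `tree_backbone`.
#' @return named numeric vector.
#' @export
tree_strength <- function(tree) {
  s <- numeric(tree$n)
  for (k in seq_len(nrow(tree$edges))) {
    i <- tree$edges$from[k]; j <- tree$edges$to[k]; w <- tree$edges$weight[k]
    s[i] <- s[i] + w
    s[j] <- s[j] + w
  }
  names(s) <- tree$nodes
  s
}

#' Degrees and leaf number of a tree backbone
#'
#' @param tree a `tree_backbone`.
#' @return list with `degree` (named integer vector) and `n_leaf` (number of
#'   nodes with exactly one connection).
#' @export
tree_degree_and_leaf_number <- function(tree) {
  deg <- integer(tree$n)
  for (k in seq_len(nrow(tree$edges))) {
    deg[tree$edges$from[k]] <- deg[tree$edges$from[k]] + 1L
    deg[tree$edges$to[k]] <- deg[tree$edges$to[k]] + 1L
  }
  names(deg) <- tree$nodes
  list(degree = deg, n_leaf = sum(deg == 1L))
}

#' Tree diameter (hops)
#'
#' Largest hop distance between any two tree nodes; ranges from 2 (star) to
#' n - 1 (path) for n >= 3.
#'
#' @param tree a `tree_backbone` with at least 2 nodes.
#' @return integer diameter.
#' @export
tree_diameter <- function(tree) {
  if (tree$n < 2L) stop("diameter undefined for a single-node tree")
  max(tree_hop_distances(tree))
}

#' Nodal eccentricity and its network mean
#'
#' A node's eccentricity is its largest hop distance to any other tree node;
#' it decreases as the node becomes more central. The network-level value is
#' the mean over nodes. The maximum nodal eccentricity equals the diameter.
#'
#' @param tree a `tree_backbone` with at least 2 nodes.
#' @return list with `eccentricity` (named vector) and `mean_eccentricity`.
#' @export
tree_eccentricity <- function(tree) {
  if (tree$n < 2L) stop("eccentricity undefined for a single-node tree")
  D <- tree_hop_distances(tree)
  ecc <- apply(D, 1, max)
  names(ecc) <- tree$nodes
  list(eccentricity = ecc, mean_eccentricity = mean(ecc))
}

#' Kappa: width of the tree degree distribution
#'
#' Kappa = <k^2> / <k> over the tree degrees; high values indicate heavy
#' reliance on hub nodes (vulnerability to hub damage).
#'
#' @param tree a `tree_backbone`.
#' @return scalar kappa.
#' @export
kappa_metric <- function(tree) {
  deg <- tree_degree_and_leaf_number(tree)$degree
  mean(deg^2) / mean(deg)
}

#' All backbone metrics for one network
#'
#' Convenience wrapper: extracts the MST and computes every nodal and
#' network-level metric.
#'
#' @param net a connected [weighted_network].
#' @return list with `tree`, `nodal` (data.frame: node, degree, strength,
#'   betweenness, eccentricity) and `network` (data.frame: n_leaf, diameter,
#'   mean_eccentricity, kappa, mean_betweenness, mean_strength).
#' @export
backbone_metrics <- function(net) {
  tree <- minimum_spanning_tree(net)
  dl <- tree_degree_and_leaf_number(tree)
  bc <- tree_betweenness(tree)
  st <- tree_strength(tree)
  ec <- tree_eccentricity(tree)
  list(
    tree = tree,
    nodal = data.frame(node = tree$nodes, degree = unname(dl$degree),
                       strength = unname(st), betweenness = unname(bc),
                       eccentricity = unname(ec$eccentricity)),
    network = data.frame(n_leaf = dl$n_leaf,
                         diameter = tree_diameter(tree),
                         mean_eccentricity = ec$mean_eccentricity,
                         kappa = kappa_metric(tree),
                         mean_betweenness = mean(bc),
                         mean_strength = mean(st))
  )
}

#' Backbone metric table for a cohort
#'
#' For every subject, computes MST metrics of the full network and of the
#' sensorimotor sub-network. The sensorimotor MST is extracted from the
#' 16-node sub-network itself, not pruned from the full-network MST. Subjects
#' whose (sub-)network is disconnected are excluded and reported in the
#' `"excluded"` attribute.
#'
#' @param cohort list of subjects, each a list with elements `network`
#'   (a [weighted_network]), `group` and `subject` (id); a bare list of
#'   networks is also accepted.
#' @param regions region table used for sub-network extraction.
#' @param scopes which network scopes to analyze.
#' @return list with `network` and `nodal` data.frames carrying subject,
#'   group and scope columns.
#' @export
backbone_metric_table <- function(cohort, regions = region_table(),
                                  scopes = c("total", "sensorimotor")) {
  net_rows <- list(); nodal_rows <- list(); excluded <- character(0)
  for (s in seq_along(cohort)) {
    subj <- cohort[[s]]
    if (inherits(subj, "weighted_network")) {
      subj <- list(network = subj, group = NA_character_, subject = s)
    }
    for (scope in scopes) {
      net <- if (scope == "sensorimotor") {
        extract_subnetwork(subj$network, regions)
      } else subj$network
      m <- tryCatch(backbone_metrics(net), error = function(e) e)
      if (inherits(m, "error")) {
        excluded <- c(excluded,
                      sprintf("subject %s [%s]: %s", subj$subject, scope,
                              conditionMessage(m)))
        next
      }
      net_rows[[length(net_rows) + 1L]] <-
        cbind(data.frame(subject = subj$subject, group = subj$group,
                         scope = scope), m$network)
      nodal_rows[[length(nodal_rows) + 1L]] <-
        cbind(data.frame(subject = subj$subject, group = subj$group,
                         scope = scope), m$nodal)
    }
  }
  out <- list(network = do.call(rbind, net_rows),
              nodal = do.call(rbind, nodal_rows))
  attr(out, "excluded") <- excluded
  out
}

#' Group prevalence of MST connections
#'
#' Per edge, the fraction of subjects whose MST backbone contains that edge
#' (binarized individual MST matrices averaged).
#'
#' @param nets list of [weighted_network]s over one node set.
#' @return a [weighted_network] of MST-edge prevalences.
#' @export
group_mst_prevalence <- function(nets) {
  stopifnot(length(nets) >= 1L)
  nodes <- rownames(nets[[1]])
  mst_bin <- lapply(nets, function(nt) {
    if (!identical(rownames(nt), nodes)) stop("networks have mixed node sets")
    tree <- minimum_spanning_tree(nt)
    B <- matrix(0, nrow(nt), ncol(nt))
    for (k in seq_len(nrow(tree$edges))) {
      i <- match(tree$nodes[tree$edges$from[k]], nodes)
      j <- match(tree$nodes[tree$edges$to[k]], nodes)
      B[i, j] <- 1; B[j, i] <- 1
    }
    B
  })
  weighted_network(Reduce(`+`, mst_bin) / length(nets), nodes)
}
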
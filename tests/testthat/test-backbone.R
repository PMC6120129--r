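test_that("the MST minimizes total inverse-weight cost on worked examples", {
  # two nodes: the single edge, cost 1/5
  W2 <- matrix(c(0, 5, 5, 0), 2, 2)
  t2 <- minimum_spanning_tree(weighted_network(W2))
  expect_equal(nrow(t2$edges), 1)
  expect_equal(sum(t2$edges$cost), 0.2)
  # four-node complete graph with known optimum
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- 4; W4[1, 3] <- 1; W4[1, 4] <- 1
  W4[2, 3] <- 3; W4[2, 4] <- 1; W4[3, 4] <- 2
  W4 <- W4 + t(W4)
  t4 <- minimum_spanning_tree(weighted_network(W4))
  expect_equal(sum(t4$edges$cost), 13 / 12)
  got <- t4$edges[order(t4$edges$from, t4$edges$to), c("from", "to")]
  expect_equal(unname(as.matrix(got)), rbind(c(1L, 2L), c(2L, 3L), c(3L, 4L)))
  # every tree cost is exactly the inverse weight
  expect_equal(t4$edges$cost, 1 / t4$edges$weight)
  # a connected 42-node network yields 41 edges
  net42 <- make_network_cohort(cohort_spec(n_control = 1, n_stroke = 1,
                                           seed = 5))[[1]]$network
  expect_equal(nrow(minimum_spanning_tree(net42)$edges), 41)
})

test_that("Prim-Jarnik equals exhaustive spanning-tree enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(4:7, 1)
    net <- random_connected_network(n, p = 0.6)
    t_mine <- minimum_spanning_tree(net)
    expect_equal(nrow(t_mine$edges), n - 1)
    expect_equal(sum(t_mine$edges$cost), brute_force_mst_cost(net),
                 tolerance = 1e-12)
  }
})

test_that("the MST cost agrees with an independent Kruskal implementation", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (rep in 1:25) {
    net <- random_connected_network(sample(5:12, 1), p = 0.5)
    g <- igraph::graph_from_adjacency_matrix(unclass(net), mode = "undirected",
                                             weighted = TRUE)
    ref <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
    ref_cost <- sum(1 / igraph::E(ref)$weight)
    expect_equal(sum(minimum_spanning_tree(net)$edges$cost), ref_cost,
                 tolerance = 1e-12)
  }
})

test_that("disconnected networks error or fall back to the largest component", {
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  W[4, 5] <- W[5, 4] <- 1
  net <- weighted_network(W)
  expect_error(minimum_spanning_tree(net), "component sizes: 3, 2")
  expect_warning(t_lc <- minimum_spanning_tree(net, "largest_component"),
                 "largest component")
  expect_equal(t_lc$n, 3)
  expect_equal(nrow(t_lc$edges), 2)
})

test_that("tree betweenness matches path enumeration and the star/path forms", {
  # star: hub carries every path, leaves none
  star <- minimum_spanning_tree(star_network(7))
  bc <- tree_betweenness(star)
  expect_equal(unname(bc[1]), 1)
  expect_equal(unname(bc[2:7]), rep(0, 6))
  # path a-b-c-d: bc(b) = 2/3, bc(a) = 0
  pth <- minimum_spanning_tree(path_network(c(4, 3, 2)))
  bcp <- tree_betweenness(pth)
  expect_equal(unname(bcp), c(0, 2 / 3, 2 / 3, 0))
  # random trees against the exhaustive path-enumeration oracle
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    tr <- minimum_spanning_tree(random_tree_network(n)$net)
    expect_equal(unname(tree_betweenness(tr)), path_enum_betweenness(tr),
                 tolerance = 1e-12)
  }
  expect_error(tree_betweenness(minimum_spanning_tree(
    weighted_network(matrix(c(0, 1, 1, 0), 2, 2)))), "fewer than 3")
})

test_that("tree strength sums original incident weights", {
  t2 <- minimum_spanning_tree(weighted_network(matrix(c(0, 5, 5, 0), 2, 2)))
  expect_equal(unname(tree_strength(t2)), c(5, 5))
  star <- minimum_spanning_tree(star_network(6, hub_weight = 1))
  expect_equal(unname(tree_strength(star)), c(5, rep(1, 5)))
  pth <- minimum_spanning_tree(path_network(c(4, 3, 2)))
  expect_equal(unname(tree_strength(pth)), c(4, 7, 5, 2))
})

test_that("degrees, leaf number and kappa satisfy the closed forms", {
  pth <- minimum_spanning_tree(path_network(c(1, 1, 1)))
  dl <- tree_degree_and_leaf_number(pth)
  expect_equal(dl$n_leaf, 2)
  expect_equal(kappa_metric(pth), 5 / 3)  # degrees 1,2,2,1
  star42 <- minimum_spanning_tree(star_network(42))
  expect_equal(tree_degree_and_leaf_number(star42)$n_leaf, 41)
  star5 <- minimum_spanning_tree(star_network(5))
  expect_equal(kappa_metric(star5), 2.5)  # degrees 4,1,1,1,1
  # star kappa exceeds path kappa from n = 5 on
  for (n in c(5, 8, 12)) {
    ks <- kappa_metric(minimum_spanning_tree(star_network(n)))
    kp <- kappa_metric(minimum_spanning_tree(path_network(rep(1, n - 1))))
    expect_gt(ks, kp)
  }
})

test_that("diameter and eccentricity agree with Floyd-Warshall", {
  star <- minimum_spanning_tree(star_network(9))
  expect_equal(tree_diameter(star), 2)
  ecc <- tree_eccentricity(star)
  expect_equal(unname(ecc$eccentricity), c(1, rep(2, 8)))
  pth <- minimum_spanning_tree(path_network(rep(1, 7)))
  expect_equal(tree_diameter(pth), 7)
  p4 <- minimum_spanning_tree(path_network(c(1, 1, 1)))
  e4 <- tree_eccentricity(p4)
  expect_equal(unname(e4$eccentricity), c(3, 2, 2, 3))
  expect_equal(e4$mean_eccentricity, 2.5)
  set.seed(31)
  for (rep in 1:40) {
    tr <- minimum_spanning_tree(random_tree_network(sample(4:8, 1))$net)
    Do <- floyd_warshall_hops(tr)
    expect_equal(tree_diameter(tr), max(Do))
    expect_equal(unname(tree_eccentricity(tr)$eccentricity),
                 unname(apply(Do, 1, max)))
  }
})

test_that("tree metric identities hold on random trees", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:9, 1)
    tr <- minimum_spanning_tree(random_tree_network(n)$net)
    dl <- tree_degree_and_leaf_number(tr)
    expect_equal(sum(dl$degree), 2 * (n - 1))        # handshake
    expect_gte(dl$n_leaf, 2)
    expect_lte(dl$n_leaf, n - 1)
    d <- tree_diameter(tr)
    expect_equal(max(tree_eccentricity(tr)$eccentricity), d)
    expect_gte(d, 2); expect_lte(d, n - 1)
    # maximal leaf number iff minimal diameter (star)
    expect_equal(dl$n_leaf == n - 1, d == 2)
  }
})

test_that("the MST edge set is invariant under monotone weight transforms", {
  edge_set <- function(tree) {
    e <- tree$edges[order(tree$edges$from, tree$edges$to), c("from", "to")]
    unname(as.matrix(e))
  }
  set.seed(23)
  for (rep in 1:20) {
    net <- random_connected_network(sample(5:9, 1), p = 0.6)
    base <- edge_set(minimum_spanning_tree(net))
    for (f in list(function(w) w^2, function(w) 3 * w, function(w) exp(w))) {
      Wt <- unclass(net)
      Wt[Wt > 0] <- f(Wt[Wt > 0])
      expect_equal(edge_set(minimum_spanning_tree(weighted_network(Wt))),
                   base)
    }
  }
})

test_that("the cohort metric table covers both scopes for all 18 subjects", {
  cohort <- make_network_cohort(cohort_spec(seed = 17))
  mt <- backbone_metric_table(cohort)
  expect_equal(nrow(mt$network), 18 * 2)
  expect_identical(sort(unique(mt$network$scope)),
                   c("sensorimotor", "total"))
  expect_equal(nrow(mt$nodal), 18 * (42 + 16))
  expect_length(attr(mt, "excluded"), 0)
  # identical subjects give identical rows
  same <- list(cohort[[1]], cohort[[1]])
  mt2 <- backbone_metric_table(same)
  tot <- mt2$network[mt2$network$scope == "total", ]
  expect_equal(tot$kappa, rep(tot$kappa[1], 2))
  expect_equal(tot$n_leaf, rep(tot$n_leaf[1], 2))
  # the 4-node worked example's metrics appear in the table
  W4 <- matrix(0, 4, 4)
  W4[1, 2] <- 4; W4[2, 3] <- 3; W4[3, 4] <- 2
  W4 <- W4 + t(W4)
  mt4 <- backbone_metric_table(list(weighted_network(W4)), scopes = "total")
  expect_equal(mt4$network$n_leaf, 2)
  expect_equal(mt4$network$diameter, 3)
  expect_equal(mt4$network$kappa, 5 / 3)
  expect_equal(mt4$network$mean_eccentricity, 2.5)
  expect_equal(mt4$nodal$strength, c(4, 7, 5, 2))
  # disconnected subjects are excluded and reported
  Wd <- matrix(0, 4, 4); Wd[1, 2] <- Wd[2, 1] <- 1
  mtd <- backbone_metric_table(list(weighted_network(Wd)), scopes = "total")
  expect_length(attr(mtd, "excluded"), 1)
  expect_null(mtd$network)
})

test_that("MST prevalence is the mean of binarized MST matrices", {
  net <- random_connected_network(6)
  prev <- group_mst_prevalence(list(net, net, net))
  vals <- unclass(prev)[upper.tri(prev)]
  expect_true(all(vals %in% c(0, 1)))
  expect_equal(sum(vals), 5)  # n - 1 ones when all MSTs identical
  set.seed(40)
  nets <- replicate(6, random_connected_network(7), simplify = FALSE)
  pm <- unclass(group_mst_prevalence(nets))
  expect_true(all(pm >= 0 & pm <= 1))
  expect_true(all(diag(pm) == 0))
  expect_lt(max(abs(pm - t(pm))), 1e-15)
})
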
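tri <- function(wab, wbc, wac) {
  mir_network(
    c("a", "b", "c"),
    data.frame(
      from = c("a", "b", "a"), to = c("b", "c", "c"),
      rho = c(wab, wbc, wac)
    )
  )
}

test_that("network construction enforces its structural invariants", {
  expect_error(
    mir_network("a", data.frame(from = "a", to = "a", rho = 0.5)),
    "self-edges"
  )
  expect_error(
    mir_network(c("a", "b"), data.frame(
      from = c("a", "b"), to = c("b", "a"), rho = c(0.5, 0.6)
    )),
    "one edge"
  )
  expect_error(
    mir_network(c("a", "b"), data.frame(from = "a", to = "b", rho = 0)),
    "weights"
  )
  net <- mir_network(c("a", "b"), data.frame(from = "a", to = "b", rho = -0.7))
  expect_equal(net$edges$sign, "-")
})

test_that("path distances are sums of inverse weights with tie-aware counts", {
  e <- mir_network(c("a", "b"), data.frame(from = "a", to = "b", rho = 0.5))
  expect_equal(path_distance(e, "a", "b"), list(distance = 2, n_shortest_paths = 1))
  # direct edge 1/0.25 = 4 ties the two-hop route 2 + 2
  t1 <- tri(0.5, 0.5, 0.25)
  expect_equal(path_distance(t1, "a", "c"), list(distance = 4, n_shortest_paths = 2))
  disc <- mir_network(c("a", "b", "c"), data.frame(from = "a", to = "b", rho = 1))
  pd <- path_distance(disc, "a", "c")
  expect_equal(pd$distance, Inf)
  expect_equal(pd$n_shortest_paths, 0)
  expect_equal(path_distance(disc, "a", "a")$distance, 0)
  expect_error(path_distance(disc, "a", "zz"), "unknown node")
})

test_that("weighted degree follows the selected weight mode", {
  star <- mir_network(
    c("h", "x", "y", "z"),
    data.frame(from = "h", to = c("x", "y"), rho = c(0.5, 0.7))
  )
  expect_equal(weighted_degree(star, "z"), 0)
  expect_equal(weighted_degree(star, "h"), 1.2)
  star_inv <- mir_network(
    star$nodes, star$edges[, c("from", "to", "rho")],
    weight_mode = "inverse_abs"
  )
  expect_equal(weighted_degree(star_inv, "h"), 2 + 1 / 0.7, tolerance = 1e-12)
})

test_that("betweenness matches hand-computable topologies", {
  path3 <- mir_network(
    c("a", "b", "c"),
    data.frame(from = c("a", "b"), to = c("b", "c"), rho = c(0.5, 0.5))
  )
  expect_equal(betweenness(path3, "b"), 1)
  expect_equal(betweenness(path3, "a"), 0)
  expect_equal(unname(betweenness(tri(0.5, 0.5, 0.5))), rep(0, 3))
  star5 <- mir_network(
    c("h", "l1", "l2", "l3", "l4"),
    data.frame(from = "h", to = c("l1", "l2", "l3", "l4"), rho = 0.6)
  )
  b <- betweenness(star5)
  expect_equal(unname(b["h"]), 1)
  expect_equal(unname(b[c("l1", "l2", "l3", "l4")]), rep(0, 4))
  # fewer than 3 nodes: 0 by convention
  e2 <- mir_network(c("a", "b"), data.frame(from = "a", to = "b", rho = 0.9))
  expect_equal(unname(betweenness(e2)), c(0, 0))
})

test_that("betweenness is invariant to rescaling all edge weights", {
  for (seed in 1:10) {
    net <- random_network(7, p = 0.5, seed = seed)
    if (nrow(net$edges) == 0) next
    scaled <- net
    scaled$edges$rho <- net$edges$rho * 0.5
    expect_equal(betweenness(scaled), betweenness(net), tolerance = 1e-9)
  }
})

test_that("Zhang-Horvath clustering matches the closed formula", {
  expect_equal(unname(zhang_clustering(tri(1, 1, 1))), rep(1, 3))
  # open wedge: no closing edge, coefficient 0
  wedge <- mir_network(
    c("a", "b", "c"),
    data.frame(from = c("a", "a"), to = c("b", "c"), rho = c(0.5, 0.5))
  )
  expect_equal(zhang_clustering(wedge, "a"), 0)
  # hand evaluation: w_vj = w_vk = 0.5, w_jk = 0.8 -> 0.4 / 0.5 = 0.8
  expect_equal(zhang_clustering(tri(0.5, 0.5, 0.8), "b"), 0.8, tolerance = 1e-12)
})

test_that("unit-weight Zhang clustering equals the unweighted coefficient", {
  for (seed in 1:50) {
    net <- random_network(sample(4:8, 1), p = 0.5, seed = seed)
    net$edges$rho <- rep(1, nrow(net$edges))
    A <- (net_weights(net) > 0) * 1
    expect_equal(unname(zhang_clustering(net)), bf_unweighted_clustering(A),
      tolerance = 1e-12
    )
  }
})

test_that("the average weighted clustering coefficient behaves as defined", {
  expect_equal(average_weighted_clustering(tri(1, 1, 1)), 1)
  iso <- mir_network(c("a", "b", "c"))
  expect_equal(average_weighted_clustering(iso), 0)
  expect_error(average_weighted_clustering(mir_network(character(0))), "no nodes")
  # two disjoint triangles, uniform weights 1 and 0.5: brute-force evaluation
  two_tri <- mir_network(
    c("a", "b", "c", "x", "y", "z"),
    data.frame(
      from = c("a", "b", "a", "x", "y", "x"),
      to = c("b", "c", "c", "y", "z", "z"),
      rho = c(1, 1, 1, 0.5, 0.5, 0.5)
    )
  )
  cw <- c(rep(1, 3), rep(0.5, 3)) # uniform triangle of weight w has c_w = w
  wdeg <- c(rep(2, 3), rep(1, 3))
  expect_equal(average_weighted_clustering(two_tri), mean(cw), tolerance = 1e-12)
  expect_equal(
    average_weighted_clustering(two_tri, node_weight = "degree"),
    sum(cw * wdeg) / sum(wdeg),
    tolerance = 1e-12
  )
})

test_that("node removal ranks triangle members over pendants", {
  net <- mir_network(
    c("a", "b", "c", "p"),
    data.frame(
      from = c("a", "b", "a", "c"), to = c("b", "c", "c", "p"),
      rho = c(0.9, 0.9, 0.9, 0.4)
    )
  )
  rr <- robustness_ranking(net)
  expect_setequal(rr$feature_id, net$nodes)
  # removing a triangle vertex hurts cohesion more than removing the pendant
  expect_lt(
    rr$awcc_without[rr$feature_id == "a"],
    rr$awcc_without[rr$feature_id == "p"]
  )
  expect_equal(rr$feature_id[4], "p")
  # removing an isolated node: remaining average under unit weights,
  # strictly unchanged under degree weights (zero-weight node)
  iso_net <- mir_network(c("a", "b", "c", "i"), tri(1, 1, 1)$edges)
  rr2 <- robustness_ranking(iso_net)
  expect_equal(
    rr2$awcc_without[rr2$feature_id == "i"],
    average_weighted_clustering(tri(1, 1, 1))
  )
  rr3 <- robustness_ranking(iso_net, node_weight = "degree")
  expect_equal(
    rr3$awcc_without[rr3$feature_id == "i"],
    average_weighted_clustering(iso_net, node_weight = "degree")
  )
})

test_that("maximal cliques come from adjacency alone", {
  k4 <- mir_network(
    letters[1:4],
    data.frame(
      from = c("a", "a", "a", "b", "b", "c"),
      to = c("b", "c", "d", "c", "d", "d"),
      rho = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
    )
  )
  cl <- find_cliques(k4)
  expect_length(cl, 1)
  expect_equal(cl[[1]], letters[1:4])
  expect_length(find_cliques(mir_network(letters[1:5])), 0)
})

test_that("graph metrics agree with exhaustive oracles on random graphs", {
  for (seed in 1:60) {
    n <- sample(4:8, 1)
    net <- random_network(n, p = 0.45, seed = seed)
    W <- net_weights(net)
    expect_equal(unname(betweenness(net)), bf_betweenness(W), tolerance = 1e-9)
    A <- (W > 0) * 1
    got <- find_cliques(net, min_size = 3)
    want <- lapply(bf_max_cliques(A, 3), function(S) net$nodes[S])
    expect_setequal(
      vapply(got, paste, "", collapse = ","),
      vapply(want, function(s) paste(sort(s), collapse = ","), "")
    )
    u <- sample(n, 1)
    v <- sample(setdiff(seq_len(n), u), 1)
    got_pd <- path_distance(net, net$nodes[u], net$nodes[v])
    want_pd <- bf_path_distance(W, u, v)
    expect_equal(got_pd$distance, want_pd$distance, tolerance = 1e-9)
    expect_equal(got_pd$n_shortest_paths, want_pd$n_shortest_paths)
  }
})

test_that("distances agree with an independent Dijkstra implementation", {
  for (seed in 1:20) {
    net <- random_network(8, p = 0.4, seed = seed + 500)
    g <- as_igraph(net)
    if (igraph::ecount(g) == 0) next
    ref <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    got <- sapply(net$nodes, function(v) {
      sapply(net$nodes, function(u) path_distance(net, u, v)$distance)
    })
    expect_equal(unname(got[net$nodes, net$nodes]), unname(ref[net$nodes, net$nodes]),
      tolerance = 1e-9
    )
  }
})

test_that("correlation networks keep significant Spearman edges only", {
  # two features with identical ordering: rho = 1, edge present
  set.seed(4)
  base <- stats::rnorm(20, 7, 1)
  tum <- rbind(base, base + 3, stats::rnorm(20), stats::rnorm(20))
  nor <- matrix(stats::rnorm(80, 7, 1), 4, 20)
  st <- make_study(tum, nor)
  net <- build_network(st, c("f01", "f02"), alpha = 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$rho, 1)
  # alpha = 0: no edge survives
  net0 <- build_network(st, c("f01", "f02", "f03"), alpha = 0)
  expect_equal(nrow(net0$edges), 0)
  expect_length(net0$nodes, 3)
  # constant feature: node kept, edges skipped, warning emitted
  tum2 <- tum
  tum2[4, ] <- 5
  st2 <- make_study(tum2, nor)
  expect_warning(
    net2 <- build_network(st2, c("f01", "f04"), alpha = 0.5),
    "constant"
  )
  expect_true("f04" %in% net2$nodes)
  expect_equal(nrow(net2$edges), 0)
  expect_error(build_network(st, c("f01", "nope")), "absent")
})

test_that("a planted correlation clique is recovered from tumour samples", {
  hits <- vapply(1:20, function(seed) {
    cfg <- generator_config(50, 10,
      module_plan = list(list(features = 1:4, rho = 0.8)), seed = seed
    )
    st <- generate_paired_cohort(cfg)
    net <- build_network(st, st$feature_ids, alpha = 0.05, tissue = "tumor")
    cl <- find_cliques(net, min_size = 3)
    any(vapply(cl, function(s) all(sprintf("miR-%03d", 1:4) %in% s), logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("centrality reports and graph files round-trip", {
  net <- tri(0.9, 0.8, 0.7)
  rep <- centrality_report(net)
  expect_setequal(rep$feature_id, net$nodes)
  expect_setequal(rep$degree_rank, 1:3)
  d <- withr::local_tempdir()
  write_edge_list(net, file.path(d, "edges.tsv"))
  net2 <- read_edge_list(file.path(d, "edges.tsv"), nodes = net$nodes)
  expect_equal(net2$edges$rho, net$edges$rho, tolerance = 1e-9)
  write_network_graphml(net, file.path(d, "net.graphml"))
  g <- igraph::read_graph(file.path(d, "net.graphml"), format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::E(g)$rho), sort(net$edges$rho), tolerance = 1e-6)
})
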
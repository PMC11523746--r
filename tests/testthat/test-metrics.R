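test_that("transitivity matches worked examples and exhaustive enumeration", {
  expect_equal(transitivity_global(gen_complete(9)), 1)
  expect_equal(transitivity_global(gen_complete(27)), 1)
  expect_equal(transitivity_global(gen_square_lattice(5, 5)), 0)
  tri_pendant <- neuron_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                    c("a", "d")))
  expect_equal(transitivity_global(tri_pendant), 0.6)  # 1 triangle, 5 triads
  for (s in 1:15) {
    g <- rand_fixture(12, 0.25, s)
    expect_equal(transitivity_global(g), oracle_transitivity(g))
    expect_equal(transitivity_global(g),
                 ifelse(is.nan(igraph::transitivity(g)), 0,
                        igraph::transitivity(g)))
    expect_identical(transitivity_global(g) == 0, oracle_triangles(g) == 0L)
  }
})

test_that("square clustering reproduces hand-derived values and the set oracle", {
  c4 <- gen_square_lattice(2, 2)
  expect_equal(unname(square_clustering(c4)), rep(1, 4))
  star <- neuron_graph(cbind("hub", c("a", "b", "c")))
  expect_equal(square_clustering(star, "hub")[["hub"]], 0)
  lat3 <- gen_square_lattice(3, 3)
  expect_equal(square_clustering(lat3, "g2_2")[["g2_2"]], 0.2)
  expect_equal(square_clustering_mean(lat3), (4 / 3 + 4 / 4 + 0.2) / 9)
  path <- neuron_graph(cbind(letters[1:4], letters[2:5]))
  expect_equal(square_clustering_mean(path), 0)
  expect_error(square_clustering(lat3, "zz"), "unknown node")
  expect_error(square_clustering_mean(neuron_graph(NULL)), "empty")
  for (s in 1:12) {
    g <- rand_fixture(9, 0.35, s)
    got <- square_clustering(g)
    for (v in igraph::V(g)$name) {
      expect_equal(got[[v]], oracle_square_clustering(g, v))
    }
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("spectral bipartivity is 1 exactly for two-colorable graphs", {
  for (n in 3:9) expect_equal(spectral_bipartivity(gen_square_lattice(n, n)), 1)
  expect_equal(spectral_bipartivity(gen_complete(3)), 0.8429, tolerance = 1e-4)
  expect_equal(round(spectral_bipartivity(gen_complete(9)), 2), 0.50)
  expect_error(spectral_bipartivity(neuron_graph(NULL)), "empty")
  for (s in 1:200) {
    g <- rand_fixture(sample(4:12, 1), stats::runif(1, 0.1, 0.5), s)
    b <- spectral_bipartivity(g)
    expect_true(b > 0 && b <= 1)
    expect_identical(abs(b - 1) < 1e-12, oracle_bipartite(g))
  }
  # bipartivity of complete graphs decreases monotonically toward 0.5
  bk <- vapply(3:30, function(n) spectral_bipartivity(gen_complete(n)), 0)
  expect_true(all(diff(bk) < 0))
  expect_gt(min(bk), 0.5)
})

test_that("average path length matches small cases and the igraph oracle", {
  expect_equal(avg_path_length(neuron_graph(cbind("a", "b"))), 1)
  expect_equal(avg_path_length(neuron_graph(rbind(c("a", "b"), c("b", "c")))), 4 / 3)
  expect_equal(avg_path_length(gen_complete(17)), 1)
  two <- neuron_graph(rbind(c("a", "b"), c("c", "d")))
  expect_error(avg_path_length(two), "connected component")
  for (s in 1:10) {
    g <- gen_random(12, 0.4, s)
    comp <- subgraph_of(g, graph_components(g)[[1]])
    if (igraph::vcount(comp) < 2) next
    expect_equal(avg_path_length(comp), igraph::mean_distance(comp))
  }
})

test_that("mean local triangle clustering matches examples and igraph", {
  expect_equal(triangle_clustering_mean(gen_complete(10)), 1)
  expect_equal(triangle_clustering_mean(gen_square_lattice(4, 4)), 0)
  tri_pendant <- neuron_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                                    c("a", "d")))
  # per-node: two pure triangle nodes 1, the attachment node 2*1/(3*2) = 1/3,
  # the pendant 0
  expect_equal(triangle_clustering_mean(tri_pendant), (1 / 3 + 1 + 1 + 0) / 4)
  for (s in 1:10) {
    g <- rand_fixture(11, 0.3, s)
    expect_equal(triangle_clustering_mean(g),
                 igraph::transitivity(g, type = "localaverage", isolates = "zero"))
  }
})

test_that("degree-preserving randomization keeps the degree sequence", {
  k8 <- gen_complete(8)
  ref <- random_reference(k8, seed = 3)
  expect_true(igraph::identical_graphs(ref, k8))  # no legal swap exists
  for (s in 1:6) {
    g <- rand_fixture(14, 0.3, s)
    r1 <- random_reference(g, seed = s + 100)
    expect_equal(sort(igraph::degree(r1)[igraph::V(g)$name]),
                 sort(igraph::degree(g)))
    expect_equal(igraph::ecount(r1), igraph::ecount(g))
    r2 <- random_reference(g, seed = s + 100)
    expect_equal(igraph::as_edgelist(r1), igraph::as_edgelist(r2))
  }
  expect_error(random_reference(neuron_graph(cbind("a", "b"))), "2 edges")
})

test_that("sigma follows the calibration conventions and is reproducible", {
  for (n in c(3, 6, 9)) {
    expect_equal(small_world_sigma(gen_square_lattice(n, n), seed = 1), 0)
  }
  expect_equal(small_world_sigma(gen_complete(12), seed = 1), 1)
  g <- gen_small_world(20, 4, 0.2, seed = 4)
  expect_identical(small_world_sigma(g, seed = 9), small_world_sigma(g, seed = 9))
  expect_error(small_world_sigma(gen_complete(3)), "4 nodes")
  two <- neuron_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a"), c("x", "y")))
  expect_error(small_world_sigma(two), "disconnected")
})

test_that("small-world graphs score high sigma; rewired rings score lower", {
  # rewired rings (triangle-rich, short paths) are small-world-like
  hits <- sum(vapply(1:20, function(s) {
    g <- gen_small_world(27, 6, 0.1, seed = s)
    comp <- subgraph_of(g, graph_components(g)[[1]])
    small_world_sigma(comp, seed = s) > 1
  }, TRUE))
  expect_gt(hits, 10)
  # at matched seeds, the p = 0 ring beats its fully rewired counterpart
  wins <- sum(vapply(1:50, function(s) {
    ring <- gen_small_world(20, 4, 0, seed = s)
    rewired <- gen_small_world(20, 4, 1, seed = s)
    comp <- subgraph_of(rewired, graph_components(rewired)[[1]])
    s_ring <- small_world_sigma(ring, seed = s)
    s_rew <- if (igraph::vcount(comp) >= 4) small_world_sigma(comp, seed = s) else 0
    s_ring > s_rew
  }, TRUE))
  expect_gte(wins, 40)
})

test_that("all metrics are invariant under node relabeling", {
  g <- rand_fixture(12, 0.35, 77)
  h <- permute_names(g, 42)
  expect_equal(transitivity_global(h), transitivity_global(g))
  expect_equal(square_clustering_mean(h), square_clustering_mean(g))
  expect_equal(spectral_bipartivity(h), spectral_bipartivity(g))
  expect_equal(triangle_clustering_mean(h), triangle_clustering_mean(g))
  cg <- subgraph_of(g, graph_components(g)[[1]])
  ch <- subgraph_of(h, graph_components(h)[[1]])
  if (igraph::vcount(cg) >= 2) {
    expect_equal(avg_path_length(ch), avg_path_length(cg))
  }
})
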
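test_that("criteria carry the calibrated bands and validate their shape", {
  crit <- grid_criteria()
  expect_equal(crit$transitivity_band, c(0, 0.20))
  expect_equal(crit$bipartivity_band, c(0.80, 1.0))
  expect_equal(crit$sigma_band, c(0, 0.50))
  expect_equal(crit$min_component_nodes, 36)
  expect_equal(crit$min_window_nodes, 4)
  expect_error(grid_criteria(transitivity_band = c(0.3, 0.1)), "lo <= hi")
  expect_output(print(crit), "transitivity")
})

test_that("components below the minimum neuron count are excluded", {
  small <- gen_random(35, 0.3, 1)  # connected w.h.p., 35 < 36
  res <- component_filter(small)
  if (length(graph_components(small)[[1]]) < 36) expect_false(res$accepted)
  ok <- component_filter(gen_square_lattice(6, 6))
  expect_true(ok$accepted)
  expect_equal(ok$size, 36L)
  big <- igraph::as_edgelist(gen_random(40, 0.3, 2))
  small2 <- igraph::as_edgelist(gen_random(10, 0.5, 3))
  two <- neuron_graph(rbind(matrix(paste0("a", big), ncol = 2),
                            matrix(paste0("b", small2), ncol = 2)))
  res2 <- component_filter(two, grid_criteria(min_component_nodes = 36))
  expect_true(res2$accepted)
  expect_equal(res2$size, 40L)
  expect_equal(res2$component_sizes[1:2], c(40L, 10L))
  empty <- component_filter(neuron_graph(NULL))
  expect_false(empty$accepted)
  expect_equal(empty$size, 0L)
})

test_that("window records carry the metric suite; classification is inclusive", {
  rec <- score_window(gen_square_lattice(4, 4), sigma_seed = 1)
  expect_equal(rec$transitivity, 0)
  expect_equal(rec$bipartivity, 1)
  expect_equal(rec$sigma, 0)
  expect_true(classify_window(rec))
  k5 <- score_window(gen_complete(5), sigma_seed = 1)
  expect_equal(k5$transitivity, 1)
  expect_lt(k5$bipartivity, 0.8)
  expect_equal(k5$sigma, 1)
  expect_false(classify_window(k5))
  tri <- score_window(gen_complete(3), sigma_seed = 1)
  expect_true(is.na(tri$sigma))  # below minimum window size: unflaggable
  expect_false(classify_window(tri))
  boundary <- data.frame(n_nodes = 10L, n_edges = 12L, transitivity = 0.20,
                         square_clustering = 0.1, bipartivity = 0.80, sigma = 0.50)
  expect_true(classify_window(boundary))
  trian <- data.frame(n_nodes = 30L, n_edges = 60L, transitivity = 0.49,
                      square_clustering = 0.15, bipartivity = 0.65, sigma = 2.0)
  expect_false(classify_window(trian))
})

test_that("scanning flags every lattice window and no complete-graph window", {
  lat <- gen_square_lattice(6, 6)
  wins <- scan_windows(lat, seed = 1)
  expect_length(wins, 36L)
  expect_true(all(vapply(wins, `[[`, TRUE, "flagged")))
  # flagged windows re-satisfy the bands post hoc
  for (w in wins[1:5]) {
    expect_true(classify_window(w$metrics, grid_criteria()))
    expect_equal(w$members, ego_window(lat, w$center))
  }
  k9 <- gen_complete(9)
  wins9 <- scan_windows(k9, seed = 1)
  expect_length(wins9, 9L)
  expect_false(any(vapply(wins9, `[[`, TRUE, "flagged")))
})

test_that("overlap clustering groups windows chained by shared nodes", {
  mk <- function(center, members) {
    list(center = center, members = members,
         metrics = data.frame(n_nodes = length(members)), flagged = TRUE)
  }
  res <- overlap_clusters(list(mk("w1", c("1", "2", "3")),
                               mk("w2", c("3", "4", "5")),
                               mk("w3", c("7", "8"))))
  expect_length(res$clusters, 1L)
  expect_equal(res$clusters[[1]]$node_union, as.character(1:5))
  expect_equal(res$clusters[[1]]$n_windows, 2L)
  expect_length(res$singletons, 1L)
  expect_equal(res$singletons[[1]]$center, "w3")
  empty <- overlap_clusters(list())
  expect_length(empty$clusters, 0L)
  expect_length(empty$singletons, 0L)
  # a pure lattice scan collapses into one cluster of all windows
  lat <- gen_square_lattice(6, 6)
  flagged <- Filter(function(w) w$flagged, scan_windows(lat, seed = 1))
  oc <- overlap_clusters(flagged)
  expect_length(oc$clusters, 1L)
  expect_equal(oc$clusters[[1]]$n_windows, 36L)
})

test_that("grid-ness scoring is the covered-node fraction with percent reporting", {
  comp278 <- neuron_graph(NULL, nodes = paste0("n", 1:278))
  clusters <- list(list(node_union = paste0("n", 1:60), n_windows = 2L))
  expect_equal(gridness_percent(gridness_score(comp278, clusters)), 22)
  comp41 <- neuron_graph(NULL, nodes = paste0("n", 1:41))
  cl41 <- list(list(node_union = paste0("n", 1:36), n_windows = 2L))
  expect_equal(gridness_percent(gridness_score(comp41, cl41)), 88)
  expect_equal(gridness_score(comp41, list()), 0)
  # monotone non-decreasing in the cluster set
  more <- c(cl41, list(list(node_union = paste0("n", 37:40), n_windows = 2L)))
  expect_gte(gridness_score(comp41, more), gridness_score(comp41, cl41))
  expect_error(gridness_score(neuron_graph(NULL), list()), "empty")
  expect_error(gridness_score(comp41, list(list(node_union = "zz"))), "subsets")
})

test_that("the full scan recovers a planted lattice window and is deterministic", {
  h <- gen_hybrid(4, 4, generator_spec("random", n = 30, p = 0.2), 2, seed = 11)
  rep1 <- grid_scan(h$graph, grid_criteria(min_component_nodes = 20), seed = 11)
  flagged_centers <- rep1$windows$center[rep1$windows$flagged]
  expect_gte(sum(flagged_centers %in% h$planted), 1L)
  rep2 <- grid_scan(h$graph, grid_criteria(min_component_nodes = 20), seed = 11)
  expect_identical(rep1$windows, rep2$windows)
  expect_identical(rep1$flagged_nodes, rep2$flagged_nodes)
  expect_identical(rep1$gridness_percent, rep2$gridness_percent)
  # a rejected network produces an empty but well-formed report
  tiny <- grid_scan(gen_square_lattice(3, 3), seed = 1)
  expect_false(tiny$accepted)
  expect_equal(tiny$gridness_percent, 0L)
  expect_equal(tiny$n_windows, 0L)
})
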
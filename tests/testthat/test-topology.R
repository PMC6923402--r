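test_that("degree counts distinct interaction partners", {
  triangle <- net_from_edges(c("A", "B", "C"), c("B", "C", "A"))
  expect_equal(degrees(triangle)$degree, c(2, 2, 2))

  star <- net_from_edges(c(rep("H", 15), sprintf("S%02d", 16:25)),
                         c(sprintf("S%02d", 1:15), rep("H", 10)))
  d <- degrees(star)
  expect_equal(d$degree[d$node == "H"], 25)

  loop <- net_from_edges("A", "A")
  expect_equal(degrees(loop)$degree, 2)
})

test_that("hubs returns exactly ceiling(fraction * N) nodes, ties cut by id", {
  star <- net_from_edges(rep("H", 9), paste0("S", 1:9))
  h <- hubs(star, 0.10)  # N = 10 -> k = 1
  expect_equal(h$members, "H")

  # all degrees equal: the lexicographically smallest node is kept
  ring <- net_from_edges(paste0("N", 1:10), paste0("N", c(2:10, 1)))
  expect_equal(hubs(ring, 0.10)$members, "N1")
  expect_length(hubs(ring, 0.45)$members, 5)
  expect_error(hubs(ring, 0), "fraction")
})

test_that("directed domination covers a node and its out-neighbors", {
  net <- net_from_edges(c("A", "A", "B"), c("B", "C", "C"))
  expect_equal(dominated_by(net, "A"), c("A", "B", "C"))
  expect_equal(dominated_by(net, "C"), "C")  # sink covers only itself
  expect_error(dominated_by(net, "Z"), "unknown")

  loop <- net_from_edges(c("A", "A"), c("A", "B"))
  expect_equal(dominated_by(loop, "A"), c("A", "B"))
})

test_that("MDS solves small structured instances exactly", {
  star <- net_from_edges(rep("A", 3), c("B", "C", "D"))
  s <- compute_mds(star, mode = "exact")
  expect_equal(s$members, "A")
  expect_equal(s$exactness, "exact")

  path4 <- net_from_edges(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(length(compute_mds(path4, mode = "exact")$members),
               brute_force_mds_size(path4))
  expect_equal(length(compute_mds(path4, mode = "exact")$members), 2)
})

test_that("every in-degree-0 node is forced into the MDS; greedy never beats exact", {
  set.seed(11)
  for (rep in 1:20) {
    net <- random_digraph(8, 0.25)
    exact <- compute_mds(net, mode = "exact")
    greedy <- compute_mds(net, mode = "greedy")
    expect_lte(length(exact$members), length(greedy$members))
    expect_equal(greedy$exactness, "heuristic")
    arcs <- unique(net$edges[c("source", "target")])
    sources_only <- setdiff(net$nodes$id, arcs$target)
    expect_true(all(sources_only %in% exact$members))
    expect_true(all(sources_only %in% greedy$members))
  }
})

test_that("topology results are invariant to edge-list permutation", {
  syn <- generate_synthetic(synthetic_spec(
    n_tfs = 10, n_genes = 60, n_mirnas = 4, seed = 3))
  net <- syn$truth$planted_subnetwork
  set.seed(5)
  perm <- regulatory_network(
    net$edges[sample(nrow(net$edges)), , drop = FALSE])
  expect_identical(hubs(net), hubs(perm))
  expect_identical(compute_mds(net), compute_mds(perm))
  expect_identical(compute_mcds(net), compute_mcds(perm))
})

test_that("largest weakly connected component, with the stated tie rule", {
  two <- net_from_edges(c("A", "A", "B", "B", "X", "X"),
                        c("B", "C", "D", "E", "Y", "Z"))
  lcc <- largest_connected_component(two)
  expect_equal(node_ids(lcc), c("A", "B", "C", "D", "E"))

  connected <- net_from_edges(c("A", "B"), c("B", "C"))
  expect_identical(largest_connected_component(connected), connected)

  # equal sizes: the component holding the smallest id wins
  tie <- net_from_edges(c("A", "B"), c("Z", "C"))
  expect_equal(node_ids(largest_connected_component(tie)), c("A", "Z"))
})

test_that("MCDS output dominates the LCC and induces a connected subgraph", {
  star <- net_from_edges(rep("A", 3), c("B", "C", "D"))
  expect_equal(compute_mcds(star)$members, "A")

  path4 <- net_from_edges(c("A", "B", "C"), c("B", "C", "D"))
  s <- compute_mcds(path4)
  expect_gte(length(s$members), 2)
  und <- und_adjacency_idx(path4)
  idx <- match(s$members, path4$nodes$id)
  expect_true(subset_connected(und, idx))
  out_adj <- out_adjacency_idx(path4)
  expect_true(covers_all(out_adj, idx, 4))
})

test_that("MCDS heuristic is valid and no smaller than the brute-force optimum", {
  set.seed(23)
  for (rep in 1:15) {
    net <- random_connected_digraph(8)
    s <- compute_mcds(net)
    idx <- match(s$members, net$nodes$id)
    expect_true(covers_all(out_adjacency_idx(net), idx, 8))
    expect_true(subset_connected(und_adjacency_idx(net), idx))
    expect_gte(length(s$members), brute_force_min_cds_size(net))
    # connectivity is an extra constraint on top of domination
    expect_gte(length(s$members),
               length(compute_mds(net, mode = "exact")$members))
  }
})
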
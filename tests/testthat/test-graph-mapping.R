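toy_chain <- function(lengths, closed = FALSE) {
  # horizontal chain with prescribed segment lengths (synthetic, for unit use)
  xs <- cumsum(c(0, lengths))
  sketchlayout:::new_chain(cbind(xs, 0), closed = closed)
}

test_that("pruning drops exactly the degree-one fringe, in one pass", {
  c5 <- make_graph("cycle", 5)
  expect_setequal(igraph::V(prune_graph(c5))$name, igraph::V(c5)$name)

  p4 <- igraph::make_graph(~ a - b, b - c, c - d)
  pr <- prune_graph(p4)
  expect_setequal(igraph::V(pr)$name, c("b", "c"))
  expect_equal(igraph::ecount(pr), 1)

  star <- igraph::make_graph(~ hub - s1, hub - s2, hub - s3, hub - s4, hub - s5)
  pr <- prune_graph(star)  # hub survives: no error
  expect_identical(igraph::V(pr)$name, "hub")

  expect_error(prune_graph(igraph::make_graph(~ a - b)),
               "no multi-degree core")
  expect_equal(igraph::vcount(prune_graph(igraph::make_graph(~ a - b),
                                          keep_all = TRUE)), 2)
})

test_that("the cycle heuristic recovers full rings and rejects short cycles", {
  c20 <- prune_graph(make_graph("cycle", 20))
  cyc <- find_long_cycle(c20, tau = ceiling(2 * sqrt(20)), seed = 1)
  expect_equal(length(cyc$nodes), 20)
  expect_equal(cyc$kind, "cycle")
  expect_equal(unname(cyc$parent[cyc$nodes[1]]), cyc$nodes[20])

  tree <- prune_graph(make_graph("tree", 30, seed = 3))
  expect_null(find_long_cycle(tree, tau = 3, seed = 1))

  # two triangles joined by a bridge: longest simple cycle is 3 < tau
  g <- igraph::make_graph(~ a - b, b - c, c - a, c - d, d - e, e - f, f - d)
  expect_equal(oracle_longest_cycle(g), 3)
  expect_null(find_long_cycle(g, tau = 5, seed = 1))
})

test_that("cycle recovery holds across ring sizes with the tau rule", {
  for (n in c(9, 17, 33, 60)) {
    pr <- prune_graph(make_graph("cycle", n))
    tau <- ceiling(2 * sqrt(n))
    cyc <- find_long_cycle(pr, tau = tau, seed = n)
    expect_equal(length(cyc$nodes), n, info = paste("C", n))
  }
})

test_that("heuristic cycles are valid and never beat exhaustive search", {
  for (seed in 1:15) {
    n <- 5 + (seed %% 6)
    g <- random_connected_graph(seed, n)
    truth <- oracle_longest_cycle(g)
    cyc <- find_long_cycle(g, tau = 3, seed = seed)
    if (!is.null(cyc)) {
      m <- length(cyc$nodes)
      expect_lte(m, truth)
      # validity: consecutive members (and the wrap) are edges
      pairs <- cbind(cyc$nodes, cyc$nodes[c(2:m, 1)])
      for (r in seq_len(m)) {
        expect_true(igraph::are_adjacent(g, pairs[r, 1], pairs[r, 2]))
      }
    } else {
      succeed()  # heuristic may miss cycles; it must never invent one
    }
  }
})

test_that("BFS double sweep starts at a far node and respects level order", {
  pr <- prune_graph(igraph::make_graph(~ a - b, b - c, c - d))  # path b-c
  s <- bfs_double_sweep(pr, seed = 1)
  expect_setequal(s$nodes, c("b", "c"))
  expect_equal(unname(s$parent[s$nodes[2]]), s$nodes[1])
  expect_true(is.na(s$parent[s$nodes[1]]))

  c4 <- make_graph("cycle", 4)
  s4 <- bfs_double_sweep(prune_graph(c4), seed = 7)
  expect_length(s4$nodes, 4)
  # distances from the start must be non-decreasing along the visit order
  d <- as.integer(igraph::distances(c4, v = s4$nodes[1])[1, s4$nodes])
  expect_true(all(diff(d) >= 0))

  single <- igraph::make_graph(~ hub - s1, hub - s2)
  ss <- bfs_double_sweep(prune_graph(single), seed = 1)
  expect_identical(ss$nodes, "hub")
  expect_true(is.na(ss$parent["hub"]))
})

test_that("double sweep maps only the largest component and reports the rest", {
  g <- igraph::disjoint_union(igraph::make_ring(6), igraph::make_ring(3))
  igraph::V(g)$name <- paste0("m", 1:9)
  expect_warning(s <- bfs_double_sweep(g, seed = 1), "largest component")
  expect_length(s$nodes, 6)
  expect_length(attr(s, "excluded"), 3)
})

test_that("largest-remainder apportionment matches the worked cases", {
  expect_identical(largest_remainder(c(30, 10), 8), c(6L, 2L))
  expect_identical(largest_remainder(c(10, 10, 10), 10), c(4L, 3L, 3L))
  expect_identical(largest_remainder(c(5), 7), 7L)
})

test_that("distribution conserves nodes and preserves order", {
  set.seed(99)
  for (trial in 1:200) {
    nseg <- sample(1:8, 1)
    lens <- runif(nseg, 0.5, 40)
    nn <- sample(1:50, 1)
    ch <- toy_chain(lens)
    sq <- node_sequence(paste0("x", seq_len(nn)), kind = "path")
    mp <- distribute_nodes(ch, sq)
    expect_equal(sum(attr(mp, "counts")), nn)
    expect_identical(mp$node, sq$nodes)          # concatenation order
    expect_true(!is.unsorted(mp$seg))
  }
})

test_that("anchor positions sit evenly inside their segments", {
  ch <- toy_chain(10)
  sq1 <- node_sequence("a")
  tp <- target_positions(ch, distribute_nodes(ch, sq1))
  expect_equal(c(tp$x, tp$y), c(5, 0))

  sq3 <- node_sequence(c("a", "b", "c"))
  tp3 <- target_positions(ch, distribute_nodes(ch, sq3))
  expect_equal(tp3$x, c(2.5, 5.0, 7.5))

  # closed square chain, 8 nodes: all anchors on the perimeter
  sq <- sketchlayout:::new_chain(
    cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)), closed = TRUE)
  mp <- distribute_nodes(sq, node_sequence(paste0("n", 1:8), kind = "cycle"))
  tp <- target_positions(sq, mp)
  on_perimeter <- abs(tp$x) < 1e-9 | abs(tp$x - 10) < 1e-9 |
    abs(tp$y) < 1e-9 | abs(tp$y - 10) < 1e-9
  expect_true(all(on_perimeter))
})

test_that("sequence choice requires both a closed chain and a long cycle", {
  closed <- sketchlayout:::new_chain(
    cbind(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0)), closed = TRUE)
  open <- toy_chain(c(10, 10))
  c16 <- prune_graph(make_graph("cycle", 16))
  tree <- prune_graph(make_graph("tree", 30, seed = 2))
  expect_equal(choose_sequence(c16, closed, seed = 1)$kind, "cycle")
  expect_equal(choose_sequence(c16, open, seed = 1)$kind, "path")
  expect_equal(choose_sequence(tree, closed, seed = 1)$kind, "path")
})
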
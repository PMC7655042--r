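test_that("adjacency matrices read back exactly what was written", {
  m <- rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0))
  g <- weighted_digraph(m, labels = c("a", "b", "c"))
  expect_equal(n_nodes(g), 3L)
  expect_equal(n_edges(g), 3L)
  expect_equal(unname(out_degree(g)), c(1L, 1L, 1L))
  expect_equal(unname(in_degree(g)), c(1L, 1L, 1L))

  for (sep in c(",", "\t")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_adjacency(g, path, sep = sep)
    g2 <- read_adjacency(path)
    expect_identical(g2$labels, g$labels)
    expect_identical(g2$weights, g$weights)
    # byte-identical re-write
    path2 <- withr::local_tempfile(fileext = ".csv")
    write_adjacency(g2, path2, sep = sep)
    expect_identical(readLines(path), readLines(path2))
  }

  # unlabeled, fractional weights survive with full precision
  w <- matrix(c(0, 0.0136, 1 / 3, 0), 2, 2)
  gu <- weighted_digraph(w, labels = c("x", "y"))
  path <- withr::local_tempfile()
  write_adjacency(gu, path, labels = FALSE)
  expect_equal(read_adjacency(path)$weights, gu$weights,
               ignore_attr = TRUE)
})

test_that("matrix reader rejects malformed input with located errors", {
  path <- withr::local_tempfile()
  writeLines(c("0,1,0", "1,0,1"), path)
  expect_error(read_adjacency(path), "non-square")

  writeLines(c("0,1", "-1,0"), path)
  expect_error(read_adjacency(path), "negative weight.*\\(2, 1\\)")

  writeLines(c("0,1", "oops,0"), path)
  expect_error(read_adjacency(path), "unparseable.*oops")

  writeLines(c("0,1", "NaN,0"), path)
  expect_error(read_adjacency(path), "NaN")
})

test_that("transpose flag swaps source/target orientation", {
  path <- withr::local_tempfile()
  writeLines(c(",a,b", "a,0,1", "b,0,0"), path)
  g <- read_adjacency(path)
  gt <- read_adjacency(path, transpose = TRUE)
  expect_identical(gt$weights, t(g$weights))
  expect_equal(unname(out_degree(g)), c(1L, 0L))
  expect_equal(unname(out_degree(gt)), c(0L, 1L))
})

test_that("edge lists build the expected graph, summing duplicates", {
  path <- withr::local_tempfile()
  writeLines(c("a,b", "b,c", "c,a"), path)
  g <- read_edge_list(path)
  expect_identical(g$weights, cycle3()$weights)

  # duplicate rows sum weights: two 0.5 rows give one edge of weight 1
  writeLines(c("source,target,weight", "a,b,0.5", "a,b,0.5"), path)
  g2 <- read_edge_list(path)
  expect_equal(n_edges(g2), 1L)
  expect_equal(g2$weights["a", "b"], 1.0)

  # empty rows with an explicit universe
  writeLines(character(0), path)
  g3 <- read_edge_list(path, nodes = c("a", "b"))
  expect_equal(n_nodes(g3), 2L)
  expect_equal(n_edges(g3), 0L)

  writeLines(c("a,b,-2"), path)
  expect_error(read_edge_list(path), "negative weight")
  writeLines(c("a"), path)
  expect_error(read_edge_list(path), "malformed")
  writeLines(c("a,b", "c,d"), path)
  expect_error(read_edge_list(path, nodes = c("a", "b")), "outside")
})

test_that("edge-list writer round-trips through the reader", {
  set.seed(71)
  g <- connectome_like_fixture(12, 0.3, self_loop_rate = 0.25, seed = 4)
  path <- withr::local_tempfile()
  write_edge_list(g, path)
  g2 <- read_edge_list(path, nodes = g$labels)
  expect_identical(g2$weights, g$weights)
})

test_that("thresholding keeps the boundary, is idempotent and monotone", {
  g <- graph_from_edges(3L, list(c(1, 2, 0.01), c(2, 3, 0.0136),
                                 c(3, 1, 0.5)))
  gt <- threshold_edges(g, 0.0136)
  expect_equal(n_edges(gt), 2L)                     # boundary edge kept
  expect_equal(gt$weights["b", "c"], 0.0136)
  expect_equal(gt$weights["a", "b"], 0)

  expect_identical(threshold_edges(g, 0)$weights, g$weights)  # identity
  expect_equal(n_edges(threshold_edges(g, 1)), 0L)  # all removed, N kept
  expect_equal(n_nodes(threshold_edges(g, 1)), 3L)
  expect_error(threshold_edges(g, -0.1), "nonnegative")

  set.seed(8)
  for (i in 1:5) {
    W <- matrix(stats::runif(49), 7, 7) * (matrix(stats::runif(49), 7, 7) < 0.5)
    gr <- weighted_digraph(W)
    w1 <- stats::runif(1, 0, 0.8); w2 <- w1 + stats::runif(1, 0, 0.2)
    t1 <- threshold_edges(gr, w1)
    expect_identical(threshold_edges(t1, w1)$weights, t1$weights)
    expect_true(all(threshold_edges(gr, w2)$weights <= (t1$weights > 0) * 1))
  }
})

test_that("self-loop stripping zeroes only the diagonal", {
  g <- graph_from_edges(3L, list(c(1, 2), c(2, 2), c(3, 1)))
  gs <- strip_self_loops(g)
  expect_equal(n_edges(gs), 2L)
  expect_equal(gs$weights["b", "b"], 0)
  expect_identical(strip_self_loops(cycle3())$weights, cycle3()$weights)

  gl <- graph_from_edges(2L, list(c(1, 1), c(2, 2)))
  expect_equal(n_edges(strip_self_loops(gl)), 0L)
})

test_that("active-core restriction removes exactly sources and sinks", {
  chain <- path_graph(3)
  core <- restrict_to_active_core(chain)            # single pass
  expect_identical(core$labels, "p2")
  expect_equal(n_edges(core), 0L)

  expect_identical(restrict_to_active_core(cycle3())$weights,
                   cycle3()$weights)

  empty <- restrict_to_active_core(chain, iterate = TRUE)
  expect_equal(n_nodes(empty), 0L)

  set.seed(31)
  for (i in 1:10) {
    g <- connectome_like_fixture(15, 0.12)
    s <- network_summary(g)
    core <- restrict_to_active_core(g)
    srcs <- g$labels[in_degree(g) == 0]
    snks <- g$labels[out_degree(g) == 0]
    expect_setequal(setdiff(g$labels, core$labels), union(srcs, snks))
    fix <- restrict_to_active_core(g, iterate = TRUE)
    expect_true(all(in_degree(fix) > 0) && all(out_degree(fix) > 0))
  }
})

test_that("network summary matches brute-force recounts", {
  s <- network_summary(cycle3())
  expect_equal(s$n_nodes, 3L)
  expect_equal(s$n_edges, 3L)
  expect_equal(s$density, 0.5)
  expect_equal(s$n_source_nodes, 0L)
  expect_equal(s$n_sink_nodes, 0L)

  lone <- weighted_digraph(matrix(0, 1, 1), labels = "solo")
  s1 <- network_summary(lone)
  expect_equal(unlist(s1[c("n_nodes", "n_edges", "n_source_nodes",
                           "n_sink_nodes")]),
               c(n_nodes = 1L, n_edges = 0L, n_source_nodes = 1L,
                 n_sink_nodes = 1L))

  set.seed(99)
  for (i in 1:10) {
    g <- connectome_like_fixture(20, stats::runif(1, 0.05, 0.4),
                                 self_loop_rate = stats::runif(1))
    W <- g$weights
    s <- network_summary(g)
    expect_equal(s$n_edges, sum(W > 0))
    expect_equal(s$n_self_loops, sum(diag(W) > 0))
    expect_equal(s$n_source_nodes, sum(colSums(W > 0) == 0))
    expect_equal(s$n_sink_nodes, sum(rowSums(W > 0) == 0))
    expect_equal(s$density, (sum(W > 0) - sum(diag(W) > 0)) / (20 * 19))
  }
})
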
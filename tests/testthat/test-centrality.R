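test_that("degree centrality counts distinct partners", {
  star <- igraph::make_star(8, mode = "undirected", center = 1)
  igraph::V(star)$name <- paste0("s", 1:8)
  cent <- node_centrality(star)
  expect_equal(cent$degree[cent$node == "s1"], 7L)

  k2 <- edge_list_network("u", "v")
  expect_equal(node_centrality(k2)$degree, c(1L, 1L))

  fix <- node_centrality(make_figure1_fixture())
  expect_equal(fix$degree[fix$node == "5"], 5L)
  expect_equal(sum(fix$degree), 2L * igraph::ecount(make_figure1_fixture()))
})

test_that("normalized betweenness matches hand values on canonical graphs", {
  p3 <- edge_list_network(c("a", "b"), c("b", "c"))
  cent <- node_centrality(p3)
  expect_equal(cent$betweenness[cent$node == "b"], 1)
  expect_equal(cent$betweenness[cent$node == "a"], 0)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("k", 1:4)
  expect_equal(node_centrality(k4)$betweenness, rep(0, 4))

  fix <- node_centrality(make_figure1_fixture())
  expect_equal(fix$betweenness[fix$node == "2"], 0)
  # hand-derived: node 5 lies on 21.5 pair-path fractions out of 36 pairs
  expect_equal(fix$betweenness[fix$node == "5"], 21.5 / 36, tolerance = 1e-12)
})

test_that("betweenness agrees with exhaustive path enumeration on small graphs", {
  for (seed in 1:12) {
    n <- sample(4:8, 1)
    g <- random_connected_gnp(n, 0.45, seed)
    cent <- node_centrality(g)
    expect_equal(stats::setNames(cent$betweenness, cent$node),
                 oracle_betweenness(g)[cent$node], tolerance = 1e-12)
    # degree-1 nodes never sit between a pair
    leafs <- cent$node[cent$degree == 1L]
    expect_true(all(cent$betweenness[cent$node %in% leafs] == 0))
    expect_true(all(cent$betweenness >= 0 & cent$betweenness <= 1))
  }
})

test_that("disconnected and degenerate inputs are handled", {
  g <- edge_list_network(c("a", "x"), c("b", "y"))
  expect_error(node_centrality(g), "largest connected component")
  expect_equal(node_centrality(edge_list_network("u", "v"))$betweenness,
               c(0, 0))
})

test_that("weights follow (d*b)^(-gamma) with the zero-betweenness floor", {
  # 10-node table so the default floor (0.5/36) sits below every positive b
  cent <- data.frame(node = letters[1:10],
                     degree = c(4L, rep(2L, 9)),
                     betweenness = c(0.25, rep(0.1, 9)))
  expect_equal(unname(compute_weights(cent, gamma = 0)$weights), rep(1, 10))
  expect_equal(unname(compute_weights(cent, gamma = 1)$weights["a"]), 1)

  # floored node: n = 10 table, eps = 0.5/36
  cent10 <- data.frame(node = as.character(1:10), degree = rep(2L, 10),
                       betweenness = rep(0, 10))
  w <- compute_weights(cent10, gamma = 1)
  expect_equal(w$betweenness_floor, 0.5 / 36)
  expect_equal(unname(w$weights[1]), (2 * 0.5 / 36)^(-1))
  expect_true(all(is.finite(w$weights) & w$weights > 0))

  expect_error(compute_weights(cent, gamma = -0.1), "non-negative")
})

test_that("weights are monotone in gamma and rank nodes by d*b", {
  g <- make_figure1_fixture()
  cent <- node_centrality(g)
  gammas <- c(0.1, 0.3, 0.6, 1)
  ws <- lapply(gammas, function(gm) compute_weights(cent, gamma = gm))
  floorv <- ws[[1]]$betweenness_floor
  db <- cent$degree * pmax(cent$betweenness, floorv)
  for (j in seq_along(db)) {
    wj <- vapply(ws, function(w) unname(w$weights[cent$node[j]]), 0)
    if (db[j] > 1) expect_true(all(diff(wj) < 0))
    if (db[j] < 1) expect_true(all(diff(wj) > 0))
  }
  # ascending weight order == descending d*b order, any gamma > 0
  for (w in ws) {
    expect_equal(order(unname(w$weights[cent$node])), order(-db))
  }
  # order preservation: b_j >= b_k > 0 and d_j >= d_k => w_j <= w_k
  w <- ws[[2]]$weights[cent$node]
  for (j in seq_along(db)) {
    for (k in seq_along(db)) {
      if (cent$betweenness[j] >= cent$betweenness[k] &&
          cent$betweenness[k] > 0 && cent$degree[j] >= cent$degree[k]) {
        expect_lte(w[j], w[k])
      }
    }
  }
})

test_that("centrality tables export as 12-digit TSV", {
  g <- make_figure1_fixture()
  cent <- node_centrality(g)
  w <- compute_weights(cent, gamma = 0.05)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_centrality_table(cent, w, f)
  tab <- utils::read.delim(f, colClasses = c(node = "character"))
  expect_equal(names(tab), c("node", "degree", "betweenness", "weight"))
  expect_equal(tab$weight[tab$node == "5"],
               unname(signif(w$weights["5"], 12)))
})
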
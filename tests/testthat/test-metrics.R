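path_graph <- function() {
  W <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  W["a", "b"] <- W["b", "a"] <- 1
  W["b", "c"] <- W["c", "b"] <- 1
  W
}

test_that("strength, lengths and clustering have their closed-form values", {
  W <- matrix(0, 4, 4, dimnames = list(paste0("V", 1:4), paste0("V", 1:4)))
  W[1, 2] <- W[2, 1] <- 0.5
  expect_equal(unname(node_strength(W)), c(0.5, 0.5, 0, 0))
  expect_equal(unname(node_strength(matrix(0, 3, 3))), rep(0, 3))
  L <- edge_lengths(W)
  expect_equal(L[1, 2], 2)
  expect_equal(L[1, 3], Inf)
  expect_equal(diag(L), rep(0, 4), ignore_attr = TRUE)
  expect_equal(edge_lengths(diag(0, 2) + 1 - diag(2))[1, 2], 1)

  # triangle with equal weights: clustering 1 everywhere; path: all zero
  tri <- matrix(0.7, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient(tri)), rep(1, 3))
  expect_equal(unname(clustering_coefficient(path_graph())), rep(0, 3))
})

test_that("shortest paths on the unit path graph and disconnected pairs", {
  sp <- shortest_paths(edge_lengths(path_graph()))
  expect_equal(sp$distances["a", "c"], 2)
  expect_equal(extract_path(sp, "a", "c"), c("a", "b", "c"))
  W <- path_graph(); W["b", "c"] <- W["c", "b"] <- 0
  sp2 <- shortest_paths(edge_lengths(W))
  expect_equal(sp2$distances["a", "c"], Inf)
  expect_null(extract_path(sp2, "a", "c"))
  expect_error(shortest_paths(matrix(-1, 2, 2)), "negative")
})

test_that("tied geodesics reconstruct to the lexicographically smallest path", {
  # diamond: 1-2-4 and 1-3-4 both length 2; canonical path goes through 2
  W <- matrix(0, 4, 4, dimnames = list(paste0("V", 1:4), paste0("V", 1:4)))
  for (e in list(c(1, 2), c(1, 3), c(2, 4), c(3, 4)))
    W[e[1], e[2]] <- W[e[2], e[1]] <- 1
  sp <- shortest_paths(edge_lengths(W))
  expect_equal(extract_path(sp, "V1", "V4"), c("V1", "V2", "V4"))
})

test_that("betweenness has its combinatorial values on path and star graphs", {
  expect_equal(unname(betweenness_centrality(edge_lengths(path_graph()))),
               c(0, 1, 0))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(betweenness_centrality(edge_lengths(star))),
               c(6, 0, 0, 0, 0))  # all C(4,2) leaf pairs go via the center
})

test_that("closeness matches the (n-1)/sum convention and handles isolates", {
  sp <- shortest_paths(edge_lengths(path_graph()))
  cc <- closeness_centrality(sp)
  expect_equal(unname(cc), c(2 / 3, 1, 2 / 3))
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  expect_message(cc2 <- closeness_centrality(edge_lengths(W)), "disconnected")
  expect_equal(unname(cc2)[3], 0)
  # component scaling: r = 1 of n - 1 = 2 -> (1/2) * (1/1)
  expect_equal(unname(cc2)[1], 0.5)
})

test_that("all metrics equal independent oracles on random weighted graphs", {
  set.seed(50)
  for (rep in 1:20) {
    n <- sample(5:12, 1)
    W <- random_weight_matrix(n, density = runif(1, 0.25, 0.7))
    L <- edge_lengths(W)
    expect_equal(unname(node_strength(W)), oracle_strength(W))
    expect_equal(unname(clustering_coefficient(W)), oracle_clustering(W),
                 tolerance = 1e-10)
    sp <- shortest_paths(L)
    expect_equal(unname(sp$distances), unname(oracle_distances(W)),
                 tolerance = 1e-10)
    expect_equal(unname(betweenness_centrality(L)), oracle_betweenness(W),
                 tolerance = 1e-8)
    suppressMessages(
      expect_equal(unname(closeness_centrality(sp)), oracle_closeness(W),
                   tolerance = 1e-10))
  }
})

test_that("measures are equivariant under node relabeling", {
  set.seed(51)
  W <- random_weight_matrix(8, 0.5)
  perm <- sample(8)
  Wp <- W[perm, perm]
  expect_equal(unname(node_strength(Wp)), unname(node_strength(W))[perm])
  expect_equal(unname(clustering_coefficient(Wp)),
               unname(clustering_coefficient(W))[perm])
  expect_equal(unname(betweenness_centrality(edge_lengths(Wp))),
               unname(betweenness_centrality(edge_lengths(W)))[perm])
})

test_that("positive rescaling preserves clustering and centrality order", {
  set.seed(52)
  W <- random_weight_matrix(9, 0.5)
  c_scaled <- 3.7
  expect_equal(node_strength(W * c_scaled), node_strength(W) * c_scaled)
  expect_equal(clustering_coefficient(W * c_scaled), clustering_coefficient(W))
  expect_equal(order(betweenness_centrality(edge_lengths(W * c_scaled))),
               order(betweenness_centrality(edge_lengths(W))))
  expect_equal(order(closeness_centrality(edge_lengths(W * c_scaled))),
               order(closeness_centrality(edge_lengths(W))))
})

test_that("hub detection counts top ranks across at least two measures", {
  mk_table <- function(s, b, c) data.frame(
    node = paste0("V", seq_along(s)), strength = s, betweenness = b,
    closeness = c, stringsAsFactors = FALSE)
  # 24 nodes: cutoff rank is round(0.2 * 24) = 5
  s <- 24:1
  tab <- mk_table(s, s, s)
  expect_equal(detect_hubs(tab), paste0("V", 1:5))
  # rank 5, 6, 6 across the three measures: only one measure in the top 5
  s2 <- c(24:1); b2 <- s2; c2 <- s2
  s2[5] <- 20.5  # V5: rank 5 in strength
  b2[5] <- 18.5; b2[6] <- 19.5  # V5 rank 6 in betweenness
  c2[5] <- 18.5; c2[6] <- 19.5  # and rank 6 in closeness
  expect_false("V5" %in% detect_hubs(mk_table(s2, b2, c2)))
  # a node ranked first everywhere is always a hub
  expect_true("V1" %in% detect_hubs(mk_table(s, s, s), min_measures = 3))

  # counting oracle on random tables
  set.seed(53)
  for (rep in 1:10) {
    p <- sample(6:24, 1)
    tab <- mk_table(runif(p), runif(p), runif(p))
    r_star <- round(0.2 * p)
    hubs <- detect_hubs(tab)
    manual <- tab$node[sapply(seq_len(p), function(i) {
      sum(vapply(c("strength", "betweenness", "closeness"), function(m)
        sum(tab[[m]] > tab[[m]][i]) + 1 <= r_star, TRUE)) >= 2
    })]
    expect_equal(hubs, manual)
  }
})

test_that("centrality table carries ranks, hub flags and valid clustering", {
  set.seed(54)
  W <- random_weight_matrix(10, 0.5)
  net <- ising_network(W, rep(0, 10))
  tab <- centrality_table(net)
  expect_equal(tab$strength, unname(rowSums(W)))
  expect_true(all(tab$clustering >= 0 & tab$clustering <= 1))
  expect_equal(tab$rank_strength, rank(-tab$strength, ties.method = "min"))
  expect_equal(tab$node[tab$is_hub], detect_hubs(tab))
})
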
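test_that("density, level and efficiency match their closed forms", {
  empty <- spatial_network(matrix(0L, 5, 5))
  expect_equal(network_density(empty), 0)
  expect_equal(network_density(complete_net(5)), 1)
  expect_warning(expect_true(is.na(network_level(empty))), "no ties")

  # 31 regions, 255 connected pairs -> 255/465
  set.seed(30)
  a <- matrix(0L, 31, 31)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  sel <- pairs[sample(nrow(pairs), 255), ]
  a[sel] <- 1L
  expect_equal(network_density(spatial_network(a)), 255 / 465)

  # level: reciprocated vs one-way pairs
  expect_equal(network_level(complete_net(4)), 0)
  expect_equal(network_level(star_net(5, "out")), 1)
  a2 <- matrix(0L, 6, 6)
  a2[1, 2] <- a2[2, 1] <- a2[1, 3] <- a2[3, 1] <- a2[1, 4] <- a2[4, 1] <- 1L
  a2[2, 3] <- a2[2, 4] <- a2[2, 5] <- a2[2, 6] <- a2[3, 5] <- a2[3, 6] <- a2[4, 6] <- 1L
  expect_equal(network_level(spatial_network(a2)), 0.7)  # alpha=3, beta=7

  # efficiency: spanning tree -> 1, complete -> 0, printed arithmetic
  expect_equal(network_efficiency(path_net(5)), 1)
  expect_equal(network_efficiency(complete_net(5)), 0)
  a3 <- matrix(0L, 31, 31)
  sel3 <- pairs[sample(nrow(pairs), 297), ]
  a3[sel3] <- 1L
  expect_equal(network_efficiency(spatial_network(a3)), 1 - 267 / 435)
})

test_that("degree centrality counts in and out ties over 2L-2", {
  net <- star_net(5, "mutual")
  expect_equal(unname(degree_centrality(net)[1]), 1)
  a <- matrix(0L, 4, 4); a[1, 2] <- 1L
  expect_equal(unname(degree_centrality(spatial_network(a))[3]), 0)
  expect_equal(unname(degree_centrality(path_net(3))[2]), 0.5)
})

test_that("betweenness matches closed forms on stars and complete graphs", {
  expect_equal(betweenness_centrality(complete_net(6))$raw, rep(0, 6))
  b <- betweenness_centrality(star_net(5, "mutual"))
  expect_equal(b$raw[1], 6)          # all C(4,2) pairs route via the center
  expect_equal(b$normalized[1], 1)
  expect_equal(b$raw[-1], rep(0, 4))
})

test_that("closeness matches closed forms on stars and paths", {
  cl <- closeness_centrality(star_net(5, "mutual"))
  expect_equal(cl$normalized[1], 1)
  cl3 <- closeness_centrality(path_net(3))  # symmetrized path
  expect_equal(cl3$normalized[1], 2 / 3)
  expect_equal(cl3$normalized[2], 1)
})

test_that("isolates get distance-L closeness with a warning", {
  a <- matrix(0L, 4, 4); a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- 1L
  expect_warning(cl <- closeness_centrality(spatial_network(a)), "unreachable")
  expect_equal(cl$normalized[4], 3 / 12)   # three unreachable at distance 4
})

test_that("centralities equal brute-force oracles on random digraphs", {
  set.seed(31)
  for (case in 1:50) {
    n <- sample(4:8, 1)
    net <- random_digraph(n, runif(1, 0.15, 0.5))
    a <- net$adjacency
    b <- betweenness_centrality(net)
    expect_equal(b$raw, oracle_betweenness_raw(a), tolerance = 1e-10)
    cl <- suppressWarnings(closeness_centrality(net))
    expect_equal(cl$normalized, oracle_closeness_norm(a), tolerance = 1e-12)
    os <- oracle_summary(a)
    expect_equal(network_density(net), os$density)
    expect_equal(suppressWarnings(network_level(net)), os$level)
    expect_equal(network_efficiency(net), os$efficiency)
  }
})

test_that("normalized centralities stay in [0,1]; ties only help degree", {
  set.seed(32)
  for (case in 1:20) {
    net <- random_digraph(sample(4:9, 1), 0.3)
    ct <- suppressWarnings(centrality_table(net))
    expect_true(all(ct$degree >= 0 & ct$degree <= 1))
    expect_true(all(ct$betweenness >= 0 & ct$betweenness <= 1))
    expect_true(all(ct$closeness > 0 & ct$closeness <= 1))
    # add one missing directed tie: endpoints' degree never decreases
    zero <- which(net$adjacency == 0 & row(net$adjacency) != col(net$adjacency))
    if (length(zero) > 0) {
      a2 <- net$adjacency
      a2[zero[1]] <- 1L
      d2 <- degree_centrality(spatial_network(a2))
      expect_true(all(d2 >= degree_centrality(net)))
    }
  }
})

test_that("out/in centralization summarizes sender-receiver asymmetry", {
  sym <- star_net(6, "mutual")
  sh <- network_share_summary(sym)
  expect_equal(sh$out_share, sh$in_share)
  src <- star_net(6, "out")
  sh2 <- network_share_summary(src)
  expect_equal(sh2$out_share, 1)       # one pure source, maximal asymmetry
  expect_lt(sh2$in_share, 0.2)
  # matches direct recomputation on a random digraph
  set.seed(33)
  net <- random_digraph(7, 0.4)
  a <- net$adjacency
  sh3 <- network_share_summary(net)
  expect_equal(sh3$out_share, sum(max(rowSums(a)) - rowSums(a)) / 36)
})

test_that("network_summary bundles consistent counts", {
  set.seed(34)
  net <- random_digraph(10, 0.3)
  s <- suppressWarnings(network_summary(net))
  expect_equal(s$bidirectional_pairs + s$unidirectional_pairs,
               s$connected_pairs)
  expect_equal(s$directed_ties, 2 * s$bidirectional_pairs + s$unidirectional_pairs)
  expect_equal(s$density, network_density(net))
})
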
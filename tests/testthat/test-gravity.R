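make_regions <- function(P, G, ids = sprintf("R%d", seq_along(P))) {
  validate_region_table(data.frame(
    region_id = ids, population = P, gdp = G, gdp_per_capita = G / P))
}

test_that("traditional gravity follows the inverse-square mass law", {
  D <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(unname(traditional_gravity(c(1, 1), c(1, 1), D)),
               matrix(c(0, 1, 1, 0), 2))
  X1 <- traditional_gravity(c(2, 3), c(5, 7), D)
  X2 <- traditional_gravity(c(2, 3), c(5, 7), 2 * D)
  expect_equal(X2, X1 / 4)
  # 3-region hand oracle
  P <- c(2, 3, 4); G <- c(5, 6, 7)
  D3 <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3)
  X <- traditional_gravity(P, G, D3, lambda = 0.5)
  for (e in 1:3) for (f in 1:3) {
    expected <- if (e == f) 0 else 0.5 * P[e] * G[e] * P[f] * G[f] / D3[e, f]^2
    expect_equal(unname(X[e, f]), expected)
  }
  expect_error(traditional_gravity(c(0, 1), c(1, 1), D), "positive")
})

test_that("modified gravity matches its formula cell by cell", {
  set.seed(20)
  n <- 4
  P <- runif(n, 1e6, 5e7)
  g <- runif(n, 1e3, 1e5)
  regions <- validate_region_table(data.frame(
    region_id = sprintf("R%d", 1:n), population = P, gdp = P * g,
    gdp_per_capita = g))
  N <- runif(n, 0.1, 0.9)
  D <- as.matrix(dist(matrix(runif(2 * n), n))) * 100
  dimnames(D) <- list(regions$region_id, regions$region_id)
  gm <- modified_gravity(regions, N, D)
  G <- P * g
  for (e in 1:n) for (f in 1:n) {
    expected <- if (e == f) 0 else
      N[e] / (N[e] + N[f]) * (P[e] * N[e] * G[e])^(1 / 3) *
      (P[f] * N[f] * G[f])^(1 / 3) * abs(g[e] - g[f]) / D[e, f]
    expect_equal(unname(gm$X[e, f]), expected, tolerance = 1e-12)
  }
  # share matrix: lambda_ef + lambda_fe = 1 off-diagonal
  off <- row(gm$lambda) != col(gm$lambda)
  expect_equal(unname((gm$lambda + t(gm$lambda))[off]), rep(1, sum(off)))
})

test_that("modified gravity limits: equal capacity and equal income", {
  regions <- make_regions(c(1e6, 1e6), c(1e9, 1e9))
  D <- matrix(c(0, 10, 10, 0), 2,
              dimnames = list(c("R1", "R2"), c("R1", "R2")))
  gm <- modified_gravity(regions, c(0.5, 0.5), D)
  expect_equal(unname(gm$lambda[1, 2]), 0.5)
  # equal per-capita GDP: economic-distance term collapses to the eps floor
  expect_lt(gm$X[1, 2] / (1e6 * 0.5 * 1e9)^(2 / 3), 1e-6)
  bad <- regions; bad$gdp_per_capita <- c(-1, 1)
  expect_error(validate_region_table(bad), "gdp_per_capita")
  expect_error(modified_gravity(regions, c(0, 0.5), D), "positive")
})

test_that("modified gravity equals a naive double-loop oracle at n = 10", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 10
    P <- rlnorm(n, 17, 0.5); g <- rlnorm(n, 10, 0.5)
    regions <- validate_region_table(data.frame(
      region_id = sprintf("R%02d", 1:n), population = P, gdp = P * g,
      gdp_per_capita = g))
    N <- runif(n, 0.05, 1)
    D <- as.matrix(dist(matrix(runif(2 * n), n))) * 500
    dimnames(D) <- list(regions$region_id, regions$region_id)
    gm <- modified_gravity(regions, N, D)
    oracle <- matrix(0, n, n)
    G <- P * g
    for (e in 1:n) for (f in 1:n) {
      if (e != f) {
        oracle[e, f] <- N[e] / (N[e] + N[f]) *
          (P[e] * N[e] * G[e])^(1 / 3) * (P[f] * N[f] * G[f])^(1 / 3) *
          abs(g[e] - g[f]) / D[e, f]
      }
    }
    expect_equal(unname(gm$X), oracle, tolerance = 1e-12)
  }
})

test_that("binarization follows the mean critical point with >= ties", {
  X <- matrix(5, 4, 4); diag(X) <- 0
  net <- binarize_gravity(X)
  expect_equal(sum(net$adjacency), 12)      # constant matrix: complete

  X0 <- matrix(0, 4, 4)
  expect_equal(sum(binarize_gravity(X0)$adjacency), 0)

  # one dominant entry per row survives under row_mean
  Xd <- matrix(1, 5, 5); diag(Xd) <- 0
  Xd[1, 2] <- 100
  net_d <- binarize_gravity(Xd, "row_mean")
  expect_equal(unname(net_d$adjacency[1, ]), c(0, 1, 0, 0, 0))
  expect_equal(unname(rowSums(net_d$adjacency)[2:5]), rep(4, 4))

  expect_error(binarize_gravity(-X), "nonnegative")
})

test_that("row-mean binarization is scale invariant; rules differ sensibly", {
  set.seed(22)
  X <- matrix(rlnorm(100, 0, 1.5), 10); diag(X) <- 0
  for (rule in c("row_mean", "col_mean", "grand_mean")) {
    n1 <- binarize_gravity(X, rule)
    n2 <- binarize_gravity(X * 37.5, rule)
    expect_identical(n1$adjacency, n2$adjacency)
  }
  # col_mean thresholds the transposed problem
  expect_identical(binarize_gravity(t(X), "col_mean")$adjacency,
                   t(binarize_gravity(X, "row_mean")$adjacency))
})

test_that("spatial_network rejects malformed adjacency", {
  expect_error(spatial_network(matrix(2, 2, 2)), "0/1")
  expect_error(spatial_network(diag(3)), "self-ties")
  expect_error(spatial_network(matrix(0, 2, 3)), "square")
})
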
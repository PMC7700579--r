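# Independent brute-force oracles for the network statistics, deliberately
# computed by different routes than the package (matrix powers and explicit
# path enumeration instead of BFS accumulation).

# Geodesic distances via powers of the adjacency matrix: d(i,j) is the
# smallest k with (A^k)[i,j] > 0.
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pk <- diag(n)
  for (k in seq_len(n - 1)) {
    pk <- pk %*% a
    newly <- pk > 0 & !is.finite(d)
    d[newly] <- k
  }
  d
}

# All geodesics from j to k by depth-limited path enumeration; returns the
# list of geodesics (each a vector of vertices including endpoints).
oracle_geodesics <- function(a, j, k, d) {
  if (!is.finite(d) || d == 0) return(list())
  paths <- list()
  walk <- function(path, v, left) {
    if (left == 0) {
      if (v == k) paths[[length(paths) + 1]] <<- path
      return(invisible(NULL))
    }
    for (w in which(a[v, ] == 1)) {
      if (!(w %in% path)) walk(c(path, w), w, left - 1)
    }
  }
  walk(j, j, d)
  paths
}

# Raw betweenness by explicit geodesic enumeration: half the ordered-pair
# sum of (geodesics through q) / (all geodesics).
oracle_betweenness_raw <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  raw <- numeric(n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k || !is.finite(d[j, k])) next
      paths <- oracle_geodesics(a, j, k, d[j, k])
      if (length(paths) == 0) next
      inner <- lapply(paths, function(p) p[-c(1, length(p))])
      for (q in seq_len(n)) {
        if (q == j || q == k) next
        thru <- sum(vapply(inner, function(p) q %in% p, logical(1)))
        raw[q] <- raw[q] + thru / length(paths) / 2
      }
    }
  }
  raw
}

# Normalized closeness on the symmetrized graph, unreachable distance = n.
oracle_closeness_norm <- function(a) {
  n <- nrow(a)
  sym <- ((a + t(a)) > 0) * 1
  d <- oracle_distances(sym)
  d[!is.finite(d)] <- n
  (n - 1) / rowSums(d)
}

# Density / level / efficiency by explicit double loops over pairs.
oracle_summary <- function(a) {
  n <- nrow(a)
  s <- alpha <- beta <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- a[i, j] + a[j, i]
      if (k > 0) s <- s + 1
      if (k == 2) alpha <- alpha + 1
      if (k == 1) beta <- beta + 1
    }
  }
  maxpairs <- n * (n - 1) / 2
  list(density = s / maxpairs,
       level = if (alpha + beta > 0) beta / (alpha + beta) else NA_real_,
       efficiency = min(max(1 - (s - (n - 1)) / (maxpairs - (n - 1)), 0), 1))
}

# Permutation enumerator independent of the package's recursive generator:
# successive insertion of the next element into every slot.
oracle_permutations <- function(n) {
  perms <- list(1L)
  for (k in 2:n) {
    out <- list()
    for (p in perms) {
      for (pos in 0:(k - 1)) {
        out[[length(out) + 1]] <- append(p, k, after = pos)
      }
    }
    perms <- out
  }
  perms
}

# Adjusted Rand index between two labelings.
ari <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  ex <- si * sj / choose(n, 2)
  (sij - ex) / ((si + sj) / 2 - ex)
}

# Random digraph helper.
random_digraph <- function(n, p = 0.3) {
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  diag(a) <- 0
  spatial_network(a)
}
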
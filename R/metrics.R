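#' Tie counts of a directed network
#'
#' Returns the directed tie count, the number of connected unordered pairs
#' `s_pairs`, and its split into reciprocated (`alpha`) and one-way (`beta`)
#' pairs. The pair count is the `s` entering density and efficiency, whose
#' denominators are over unordered pairs t(t-1)/2.
#'
#' @param net A [spatial_network].
#' @return List with `directed_ties`, `s_pairs`, `alpha`, `beta`, `t`.
#' @export
tie_counts <- function(net) {
  a <- net$adjacency
  up <- upper.tri(a)
  both <- a[up] + t(a)[up]          # per unordered pair: 0, 1 or 2 ties
  list(directed_ties = sum(a),
       s_pairs = sum(both > 0),
       alpha = sum(both == 2),
       beta = sum(both == 1),
       t = nrow(a))
}

#' Network density
#'
#' NI = s / (t(t-1)/2) with s the number of connected unordered pairs, so
#' the value lies in \[0, 1\]; 1 means every pair of regions is correlated
#' in at least one direction.
#'
#' @param net A [spatial_network].
#' @return Scalar density.
#' @export
network_density <- function(net) {
  tc <- tie_counts(net)
  if (tc$t < 2) stop("density needs at least two regions")
  tc$s_pairs / (tc$t * (tc$t - 1) / 2)
}

#' Network level (hierarchy)
#'
#' NR = 1 - alpha/(alpha + beta) = beta/(alpha + beta): the share of
#' connected pairs that are one-way. 1 when no tie is reciprocated
#' (maximally asymmetric accessibility), 0 when all are.
#'
#' @param net A [spatial_network].
#' @return Scalar in \[0, 1\], or NA (with a warning) for an empty network.
#' @export
network_level <- function(net) {
  tc <- tie_counts(net)
  if (tc$alpha + tc$beta == 0) {
    warning("network has no ties; level undefined")
    return(NA_real_)
  }
  tc$beta / (tc$alpha + tc$beta)
}

#' Network efficiency
#'
#' NE = 1 - (s - (t-1)) / (t(t-1)/2 - (t-1)): redundancy of connected pairs
#' beyond the spanning-tree minimum t-1, rescaled so a tree scores 1 and the
#' complete graph 0. Below the spanning-tree minimum the printed formula
#' exceeds 1; the value is clamped into \[0, 1\].
#'
#' @param net A [spatial_network].
#' @return Scalar efficiency.
#' @export
network_efficiency <- function(net) {
  tc <- tie_counts(net)
  if (tc$t < 3) stop("efficiency needs at least three regions")
  ne <- 1 - (tc$s_pairs - (tc$t - 1)) /
    (tc$t * (tc$t - 1) / 2 - (tc$t - 1))
  min(max(ne, 0), 1)
}

#' Degree centrality
#'
#' PC_i = (out-degree + in-degree) / (2L - 2): total tie involvement scaled
#' by its maximum (reciprocal ties with every other region), so values lie
#' in \[0, 1\].
#'
#' @param net A [spatial_network].
#' @return Named vector of degree centralities.
#' @export
degree_centrality <- function(net) {
  a <- net$adjacency
  L <- nrow(a)
  if (L < 2) stop("need at least two regions")
  (rowSums(a) + colSums(a)) / (2 * L - 2)
}

#' Betweenness centrality
#'
#' Fraction of geodesics between other regions passing through each region,
#' on the directed graph. For every ordered reachable pair (j, k) the
#' contribution of q is s_jk(q)/s_jk (geodesics through q over all
#' geodesics); the raw score halves the ordered-pair sum so a symmetric
#' network reproduces the classic unordered count, and the normalized score
#' applies the factor 2/(L^2 - 3L + 2).
#'
#' @param net A [spatial_network].
#' @return Data frame with columns `region_id`, `raw`, `normalized`.
#' @export
betweenness_centrality <- function(net) {
  a <- net$adjacency
  L <- nrow(a)
  sp <- shortest_path_counts(a)
  d <- sp$dist
  sig <- sp$sigma
  raw <- numeric(L)
  for (q in seq_len(L)) {
    tot <- 0
    for (j in seq_len(L)) {
      if (j == q) next
      for (k in seq_len(L)) {
        if (k == q || k == j) next
        if (is.finite(d[j, k]) && d[j, q] + d[q, k] == d[j, k]) {
          tot <- tot + sig[j, q] * sig[q, k] / sig[j, k]
        }
      }
    }
    raw[q] <- tot / 2
  }
  normalized <- if (L > 2) raw * 2 / (L^2 - 3 * L + 2) else rep(0, L)
  data.frame(region_id = rownames(a), raw = raw, normalized = normalized,
             row.names = NULL)
}

#' Closeness centrality
#'
#' Computed on the symmetrized graph (a tie in either direction connects a
#' pair). Raw score is 1 over the sum of geodesic distances to all other
#' regions; the normalized score (L-1)/sum(d) is the headline value in
#' (0, 1\]. Unreachable pairs are assigned distance L (the node count), with
#' a warning.
#'
#' @param net A [spatial_network].
#' @return Data frame with columns `region_id`, `raw`, `normalized`.
#' @export
closeness_centrality <- function(net) {
  a <- net$adjacency
  L <- nrow(a)
  sym <- ((a + t(a)) > 0) * 1L
  d <- shortest_path_counts(sym)$dist
  unreach <- !is.finite(d) & row(d) != col(d)
  if (any(unreach)) {
    warning("unreachable region pairs: distance set to node count ", L)
    d[unreach] <- L
  }
  dsum <- rowSums(d)                # diagonal contributes 0
  data.frame(region_id = rownames(a), raw = 1 / dsum,
             normalized = (L - 1) / dsum, row.names = NULL)
}

#' Combined centrality table
#'
#' Per-region degree, betweenness (raw and normalized) and closeness (raw
#' and normalized), mirroring the per-province centrality table layout.
#'
#' @param net A [spatial_network].
#' @return A data.frame, one row per region.
#' @export
centrality_table <- function(net) {
  a <- net$adjacency
  btw <- betweenness_centrality(net)
  cls <- closeness_centrality(net)
  data.frame(region_id = rownames(a),
             out_degree = rowSums(a),
             in_degree = colSums(a),
             degree = degree_centrality(net),
             betweenness_raw = btw$raw,
             betweenness = btw$normalized,
             closeness_raw = cls$raw,
             closeness = cls$normalized,
             row.names = NULL)
}

#' Out/in degree network centralization
#'
#' Freeman-style centralization sum(max(c) - c_i) / (L-1)^2 computed
#' separately on out- and in-degrees. A symmetric network yields equal
#' shares; a pure source star maximizes the out-share. Descriptive summary
#' only: the aggregation behind published out/in percentages of this kind
#' is not standardized.
#'
#' @param net A [spatial_network].
#' @return List with `out_share` and `in_share` in \[0, 1\].
#' @export
network_share_summary <- function(net) {
  a <- net$adjacency
  L <- nrow(a)
  outd <- rowSums(a)
  ind <- colSums(a)
  list(out_share = sum(max(outd) - outd) / (L - 1)^2,
       in_share = sum(max(ind) - ind) / (L - 1)^2)
}

#' Whole-network summary
#'
#' @param net A [spatial_network].
#' @return List with density, level, efficiency, tie counts and shares.
#' @export
network_summary <- function(net) {
  tc <- tie_counts(net)
  shares <- network_share_summary(net)
  list(node_count = tc$t,
       directed_ties = tc$directed_ties,
       connected_pairs = tc$s_pairs,
       bidirectional_pairs = tc$alpha,
       unidirectional_pairs = tc$beta,
       density = network_density(net),
       level = network_level(net),
       efficiency = network_efficiency(net),
       out_centralization = shares$out_share,
       in_centralization = shares$in_share)
}

# All-pairs geodesic distances and counts by per-source BFS with layer
# accumulation (sigma[s, v] = number of distinct shortest s->v paths).
shortest_path_counts <- function(a) {
  n <- nrow(a)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  adj <- lapply(seq_len(n), function(i) which(a[i, ] == 1))
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!is.finite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  diag(dist) <- 0
  list(dist = dist, sigma = sigma)
}
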
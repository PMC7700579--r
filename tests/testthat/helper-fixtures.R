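# Reference 2018 block table: sizes and directed tie counts between four
# blocks of 31 regions (intra ties; off-block ties sent; off-block received).
table3_counts <- function() {
  data.frame(
    block = 1:4,
    size = c(8, 7, 7, 9),
    intra = c(17, 22, 15, 19),
    off_sent = c(44, 43, 37, 22),
    off_recv = c(29, 38, 44, 35)
  )
}

# A concrete 31-node digraph + partition realizing the reference block
# counts exactly. The inter-block flow matrix below has row sums equal to
# off_sent and column sums equal to off_recv; cells are placed
# deterministically inside each block pair.
table3_network <- function() {
  tc <- table3_counts()
  sizes <- tc$size
  assignment <- rep(1:4, sizes)
  n <- sum(sizes)
  members <- split(seq_len(n), assignment)
  flow <- matrix(c(0, 20, 14, 10,
                   15, 0, 18, 10,
                   10, 12, 0, 15,
                   4, 6, 12, 0), 4, 4, byrow = TRUE)
  stopifnot(identical(rowSums(flow), as.numeric(tc$off_sent)),
            identical(colSums(flow), as.numeric(tc$off_recv)))
  a <- matrix(0L, n, n)
  fill <- function(from, to, count) {
    cells <- expand.grid(i = from, j = to)
    cells <- cells[cells$i != cells$j, ]
    stopifnot(count <= nrow(cells))
    for (r in seq_len(count)) a[cells$i[r], cells$j[r]] <<- 1L
  }
  for (b in 1:4) fill(members[[b]], members[[b]], tc$intra[b])
  for (b1 in 1:4) {
    for (b2 in 1:4) {
      if (b1 != b2) fill(members[[b1]], members[[b2]], flow[b1, b2])
    }
  }
  list(net = spatial_network(a), assignment = assignment)
}

# Small named digraphs used across metric tests.
path_net <- function(k) {
  a <- matrix(0L, k, k)
  for (i in seq_len(k - 1)) a[i, i + 1] <- 1L
  spatial_network(a)
}

star_net <- function(k, mode = c("mutual", "out")) {
  mode <- match.arg(mode)
  a <- matrix(0L, k, k)
  a[1, 2:k] <- 1L
  if (mode == "mutual") a[2:k, 1] <- 1L
  spatial_network(a)
}

complete_net <- function(k) {
  a <- matrix(1L, k, k)
  diag(a) <- 0L
  spatial_network(a)
}
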
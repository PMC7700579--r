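#' Traditional spatial gravity model
#'
#' Bilateral interaction strength X_ef = lambda * P_e G_e * P_f G_f / D_ef^2:
#' economic "mass" attenuated by the square of geographic distance. Provided
#' for comparison with [modified_gravity()]; symmetric by construction.
#'
#' @param P Strictly positive population vector.
#' @param G Strictly positive GDP vector.
#' @param D Distance matrix (symmetric, zero diagonal, positive off-diagonal).
#' @param lambda Scalar constant (default 1).
#' @return Symmetric nonnegative matrix with zero diagonal.
#' @export
traditional_gravity <- function(P, G, D, lambda = 1) {
  D <- validate_distance_matrix(as.matrix(D))
  n <- length(P)
  if (length(G) != n || nrow(D) != n) stop("dimension mismatch")
  if (any(P <= 0) || any(G <= 0)) stop("P and G must be strictly positive")
  mass <- P * G
  X <- lambda * outer(mass, mass) / D^2
  diag(X) <- 0
  dimnames(X) <- dimnames(D)
  X
}

#' Modified gravity model for capacity spillover
#'
#' Directed interaction strength between regions e and f:
#' \deqn{X_{ef} = \frac{N_e}{N_e+N_f}\,(P_e N_e G_e)^{1/3} (P_f N_f G_f)^{1/3}
#'   \frac{|g_e - g_f|}{D_{ef}}}
#' where P is year-end population, G real GDP, g per-capita GDP and N the
#' entropy-weight capacity score. The share factor lambda_ef = N_e/(N_e+N_f)
#' makes the matrix asymmetric: the higher-capacity region projects the
#' stronger pull. Identical per-capita GDP would annihilate a cell, so the
#' gap is floored at `eps_frac * mean(g)`.
#'
#' @param regions A `region_table` data.frame (see [read_region_table()]).
#' @param N Strictly positive capacity vector, one per region.
#' @param D Distance matrix over the same regions.
#' @param eps_frac Relative floor for the per-capita GDP gap.
#' @return A `gravity_matrix` list: `X` (n x n, zero diagonal) and `lambda`
#'   (the share matrix, lambda + t(lambda) = 1 off-diagonal).
#' @export
modified_gravity <- function(regions, N, D, eps_frac = 1e-9) {
  D <- validate_distance_matrix(as.matrix(D))
  P <- regions$population
  G <- regions$gdp
  g <- regions$gdp_per_capita
  n <- length(P)
  if (length(N) != n || nrow(D) != n) stop("dimension mismatch")
  if (any(P <= 0) || any(G <= 0) || any(g <= 0) || any(N <= 0)) {
    stop("population, gdp, gdp_per_capita and capacity must be strictly positive")
  }
  lam <- outer(N, N, function(a, b) a / (a + b))
  mass <- (P * N * G)^(1 / 3)
  gap <- abs(outer(g, g, "-"))
  gap <- pmax(gap, eps_frac * mean(g))
  X <- lam * outer(mass, mass) * gap / D
  diag(X) <- 0
  diag(lam) <- 0
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(regions$region_id)
  dimnames(X) <- dimnames(lam) <- list(ids, ids)
  structure(list(X = X, lambda = lam), class = "gravity_matrix")
}

#' Directed spatial correlation network
#'
#' Thin container for a binary directed adjacency matrix over labeled
#' regions. Entries are 0/1 with a structurally zero diagonal.
#'
#' @param adjacency Square 0/1 matrix.
#' @param region_ids Region labels (default: rownames).
#' @param year Optional year tag.
#' @return An object of class `spatial_network`.
#' @export
spatial_network <- function(adjacency, region_ids = rownames(adjacency),
                            year = NA) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency entries must be 0/1")
  if (any(diag(a) != 0)) stop("self-ties are not allowed")
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(a)))
  storage.mode(a) <- "integer"
  dimnames(a) <- list(region_ids, region_ids)
  structure(list(adjacency = a, region_ids = region_ids, year = year),
            class = "spatial_network")
}

#' @export
print.spatial_network <- function(x, ...) {
  cat("spatial_network:", length(x$region_ids), "regions,",
      sum(x$adjacency), "directed ties",
      if (!is.na(x$year)) paste0("(year ", x$year, ")") else "", "\n")
  invisible(x)
}

#' Binarize a gravity matrix at its mean critical point
#'
#' Each cell of the real-valued gravity matrix is compared with a critical
#' value derived from matrix means: the mean of the cell's row (default,
#' sender-relative), of its column, or of the whole matrix. Cells at or
#' above the critical value become directed ties (the tie case keeps the 1).
#' Means are taken over off-diagonal cells only; the diagonal is structural.
#'
#' @param X A `gravity_matrix` or plain nonnegative square matrix.
#' @param rule Critical-point rule: "row_mean" (default), "col_mean",
#'   "grand_mean".
#' @param year Optional year tag carried into the network.
#' @return A [spatial_network].
#' @export
binarize_gravity <- function(X, rule = c("row_mean", "col_mean", "grand_mean"),
                             year = NA) {
  rule <- match.arg(rule)
  if (inherits(X, "gravity_matrix")) X <- X$X
  X <- as.matrix(X)
  if (any(X < 0)) stop("gravity matrix must be nonnegative")
  n <- nrow(X)
  off <- row(X) != col(X)
  crit <- switch(rule,
    row_mean = matrix(rowSums(X) / (n - 1), n, n),
    col_mean = matrix(colSums(X) / (n - 1), n, n, byrow = TRUE),
    grand_mean = matrix(mean(X[off]), n, n)
  )
  # a zero gravity cell is "no interaction" even when the row mean is zero
  a <- (X >= crit & X > 0) * 1L
  diag(a) <- 0L
  spatial_network(a, region_ids = rownames(X), year = year)
}
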
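#' Min-max standardization of an indicator panel
#'
#' Rescales every indicator column to \[0, 1\] by the extreme-difference
#' (range) method, removing unit effects before entropy weighting. A constant
#' column carries no range information and maps to all zeros.
#'
#' @param panel An [indicator_panel] or a nonnegative numeric matrix
#'   (regions in rows, indicators in columns).
#' @return A numeric matrix of the same shape with entries in \[0, 1\].
#' @export
standardize_minmax <- function(panel) {
  x <- panel_values(panel)
  out <- apply(x, 2L, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) rep(0, length(v)) else (v - min(v)) / rng
  })
  out <- matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  out
}

#' Column proportions of a standardized matrix
#'
#' Converts each column to proportions y_ij = x_ij / sum_i(x_ij), the form
#' entered into the information-entropy computation. An all-zero column
#' (a degenerate, constant indicator) is left at zero.
#'
#' @param std A nonnegative matrix, typically the output of
#'   [standardize_minmax()].
#' @return Matrix of the same shape; every nonzero column sums to 1.
#' @export
column_proportions <- function(std) {
  std <- as.matrix(std)
  if (any(std < 0)) stop("column_proportions() requires a nonnegative matrix")
  cs <- colSums(std)
  y <- sweep(std, 2L, ifelse(cs > 0, cs, 1), "/")
  dimnames(y) <- dimnames(std)
  y
}

#' Information entropy of one indicator column
#'
#' Computes e_j = -k * sum_i y_ij * ln(y_ij) with k = 1/ln(n), using the
#' continuity convention 0 * ln(0) = 0. An all-zero proportion column carries
#' no information and is assigned entropy 1.
#'
#' @param y Nonnegative proportion vector summing to 0 or 1.
#' @param n Number of samples (regions); must be >= 2 so k is defined.
#' @return Scalar entropy in \[0, 1\].
#' @export
indicator_entropy <- function(y, n = length(y)) {
  if (n < 2) stop("entropy undefined for n < 2 (k = 1/ln(n))")
  if (any(y < 0)) stop("proportions must be nonnegative")
  s <- sum(y)
  if (s == 0) return(1)
  if (abs(s - 1) > 1e-8) stop("proportion column must sum to 1 (or be all zero)")
  terms <- ifelse(y > 0, y * log(y), 0)
  e <- -sum(terms) / log(n)
  # guard against tiny negative round-off at the uniform limit
  min(max(e, 0), 1)
}

#' Indicator weights from entropies
#'
#' Difference coefficients g_j = 1 - e_j are normalized into weights
#' omega_j = g_j / sum(g_j). Indicators at maximum entropy (no variation)
#' receive exactly zero weight.
#'
#' @param e Vector of column entropies in \[0, 1\].
#' @return Weight vector summing to 1.
#' @export
weights_from_entropy <- function(e) {
  if (any(e < -1e-12 | e > 1 + 1e-12)) stop("entropies must lie in [0, 1]")
  g <- 1 - e
  if (sum(g) <= 0) stop("no discriminating indicator: all entropies equal 1")
  g / sum(g)
}

#' Composite capacity scores
#'
#' Weighted sum A_i = sum_j omega_j x_ij over the standardized panel. With
#' standardized values in \[0, 1\] and weights summing to 1, scores lie in
#' \[0, 1\].
#'
#' @param std Standardized matrix (regions x indicators).
#' @param w Weight vector of length ncol(std).
#' @return Numeric score vector, one per region.
#' @export
capacity_scores <- function(std, w) {
  std <- as.matrix(std)
  if (ncol(std) != length(w)) stop("weights length must match indicator count")
  drop(std %*% w)
}

#' Entropy-weight capacity evaluation
#'
#' End-to-end composite scoring of a region-by-indicator panel: min-max
#' standardization, column proportions, information entropies, difference
#' coefficients, weights, and composite capacity scores.
#'
#' @param panel An [indicator_panel] or nonnegative numeric matrix.
#' @return A `capacity_result` list with elements `weights`, `entropies`,
#'   `diff_coeffs`, `scores`, `standardized`.
#' @examples
#' m <- matrix(rlnorm(62), 31, 2, dimnames = list(paste0("R", 1:31), c("a", "b")))
#' res <- capacity_index(m)
#' sum(res$weights) # 1
#' @export
capacity_index <- function(panel) {
  x <- panel_values(panel)
  if (nrow(x) < 2) stop("need at least two regions")
  std <- standardize_minmax(x)
  y <- column_proportions(std)
  e <- apply(y, 2L, indicator_entropy, n = nrow(x))
  w <- weights_from_entropy(e)
  structure(
    list(
      weights = w,
      entropies = e,
      diff_coeffs = 1 - e,
      scores = stats::setNames(capacity_scores(std, w), rownames(x)),
      standardized = std
    ),
    class = "capacity_result"
  )
}

#' @export
print.capacity_result <- function(x, ...) {
  cat("Entropy-weight capacity evaluation\n")
  cat("  regions:   ", length(x$scores), "\n")
  cat("  indicators:", length(x$weights), "\n")
  cat("  weights:   ", paste(signif(x$weights, 3), collapse = " "), "\n")
  cat("  score range:", signif(min(x$scores), 3), "-", signif(max(x$scores), 3), "\n")
  invisible(x)
}

# Extract the numeric value matrix from a panel-like object.
panel_values <- function(panel) {
  if (inherits(panel, "indicator_panel")) return(panel$values)
  x <- as.matrix(panel)
  if (!is.numeric(x)) stop("panel values must be numeric")
  if (any(x < 0)) stop("panel values must be nonnegative")
  x
}
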
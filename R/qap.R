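#' Node-attribute difference matrix
#'
#' Absolute-difference dissimilarity M\[i, j\] = |v_i - v_j|: the standard
#' way a nodal covariate enters a QAP against a relational matrix.
#' Symmetric with zero diagonal.
#'
#' @param values Numeric vector, one value per region.
#' @param region_ids Optional labels (default: names of `values`).
#' @param log Take log of values before differencing (requires positives).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
difference_matrix <- function(values, region_ids = names(values), log = FALSE) {
  if (anyNA(values)) stop("missing region value at position ",
                          which(is.na(values))[1])
  if (log) {
    if (any(values <= 0)) stop("log differencing requires positive values")
    values <- base::log(values)
  }
  m <- abs(outer(values, values, "-"))
  diag(m) <- 0
  if (!is.null(region_ids)) dimnames(m) <- list(region_ids, region_ids)
  m
}

#' QAP correlation between two square matrices
#'
#' Observed Pearson correlation over all off-diagonal cells (both (i,j) and
#' (j,i): the network is directed) between the relational matrix `R` and a
#' covariate matrix `M`, with a permutation null built by relabeling the
#' nodes of `M` — permuting its rows and columns simultaneously — `n_perm`
#' times. The one-tailed p-value uses the add-one estimator
#' (#\{r_perm >= r_obs\} + 1)/(n_perm + 1); exhaustive mode enumerates all
#' n! relabelings instead (identity included, no add-one).
#'
#' @param R A [spatial_network] or square numeric matrix.
#' @param M Square numeric covariate matrix.
#' @param n_perm Number of random relabelings (default 8000).
#' @param seed Optional integer seed for reproducibility.
#' @param exhaustive Enumerate all permutations (requires n <= 7).
#' @return A `qap_result` list: `r_obs`, `n_perm`, `p_one_tailed`,
#'   `p_two_tailed`, `perm_sd`, `perm_min`, `perm_max`, `perm_dist`, `seed`.
#' @export
qap_correlation <- function(R, M, n_perm = 8000, seed = NULL,
                            exhaustive = FALSE) {
  if (inherits(R, "spatial_network")) R <- R$adjacency
  R <- as.matrix(R); M <- as.matrix(M)
  n <- nrow(R)
  if (any(dim(M) != dim(R)) || nrow(R) != ncol(R)) {
    stop("matrices must be square and conformable")
  }
  off <- row(R) != col(R)
  rv <- R[off]
  if (stats::sd(rv) == 0 || stats::sd(M[off]) == 0) {
    stop("degenerate matrix: zero variance over off-diagonal cells")
  }
  r_obs <- stats::cor(rv, M[off])
  if (exhaustive) {
    if (n > 7) stop("exhaustive enumeration limited to n <= 7")
    perms <- all_permutations(n)
    r_perm <- vapply(perms, function(p) {
      stats::cor(rv, M[p, p][off])
    }, numeric(1))
    n_used <- length(perms)
    p_one <- mean(r_perm >= r_obs - 1e-12)
    p_two <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  } else {
    if (n_perm < 1) stop("n_perm must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      stats::cor(rv, M[p, p][off])
    }, numeric(1))
    n_used <- n_perm
    p_one <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_perm + 1)
    p_two <- (sum(abs(r_perm) >= abs(r_obs) - 1e-12) + 1) / (n_perm + 1)
  }
  structure(list(r_obs = r_obs, n_perm = n_used,
                 p_one_tailed = p_one, p_two_tailed = p_two,
                 perm_sd = stats::sd(r_perm), perm_min = min(r_perm),
                 perm_max = max(r_perm), perm_dist = r_perm,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "qap_result")
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf(
    "QAP correlation: r = %.4f (one-tailed p = %.4f, two-tailed p = %.4f, %d permutations)\n",
    x$r_obs, x$p_one_tailed, x$p_two_tailed, x$n_perm))
  invisible(x)
}

#' QAP correlation table over a covariate set
#'
#' Runs [qap_correlation()] of the network against every covariate and
#' assembles the classic report: correlation coefficient, one- and
#' two-tailed significance, and the permutation distribution's standard
#' deviation, minimum and maximum.
#'
#' @param R A [spatial_network] or square matrix.
#' @param covariates Either a named list of square difference matrices, or a
#'   region-by-factor data.frame/matrix of nodal values (each column is
#'   turned into a difference matrix).
#' @param n_perm Permutations per covariate.
#' @param seed Base seed; covariate i uses seed + i - 1.
#' @param log Log-transform nodal values before differencing.
#' @return A data.frame of class `qap_table`, one row per covariate.
#' @export
qap_table <- function(R, covariates, n_perm = 8000, seed = NULL, log = FALSE) {
  mats <- covariate_matrices(covariates, log = log)
  rows <- lapply(seq_along(mats), function(i) {
    res <- qap_correlation(R, mats[[i]], n_perm = n_perm,
                           seed = if (is.null(seed)) NULL else seed + i - 1)
    data.frame(factor = names(mats)[i],
               r = res$r_obs,
               p_one_tailed = res$p_one_tailed,
               p_two_tailed = res$p_two_tailed,
               perm_sd = res$perm_sd,
               perm_min = res$perm_min,
               perm_max = res$perm_max)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qap_table", class(out))
  out
}

# Normalize covariate input into a named list of square matrices.
covariate_matrices <- function(covariates, log = FALSE) {
  if (is.list(covariates) && !is.data.frame(covariates)) {
    if (is.null(names(covariates))) stop("covariate list must be named")
    return(covariates)
  }
  df <- as.data.frame(covariates)
  ids <- if ("region_id" %in% names(df)) {
    ids <- as.character(df$region_id)
    df <- df[setdiff(names(df), "region_id")]
    ids
  } else {
    rownames(df)
  }
  mats <- lapply(df, difference_matrix, region_ids = ids, log = log)
  names(mats) <- names(df)
  mats
}

# All permutations of 1..n in lexicographic order (n small).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(first, rest[p])
    }
  }
  out
}
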
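#' Construct an indicator panel
#'
#' A panel couples a nonnegative region-by-indicator value matrix with region
#' and indicator identifiers. Regions are kept in first-appearance order; all
#' downstream matrices share that order.
#'
#' @param values Nonnegative numeric matrix (regions x indicators).
#' @param region_ids Unique region labels (default: rownames).
#' @param indicator_ids Indicator labels (default: colnames).
#' @return An object of class `indicator_panel`.
#' @export
indicator_panel <- function(values, region_ids = rownames(values),
                            indicator_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(region_ids)) region_ids <- paste0("R", seq_len(nrow(values)))
  if (is.null(indicator_ids)) indicator_ids <- paste0("I", seq_len(ncol(values)))
  if (anyDuplicated(region_ids)) {
    stop("duplicate region_id: ", region_ids[duplicated(region_ids)][1])
  }
  if (!is.numeric(values)) stop("panel values must be numeric")
  bad <- which(values < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("negative value at region '%s', indicator '%s'",
                 region_ids[bad[1, 1]], indicator_ids[bad[1, 2]]))
  }
  dimnames(values) <- list(region_ids, indicator_ids)
  structure(list(values = values, region_ids = region_ids,
                 indicator_ids = indicator_ids),
            class = "indicator_panel")
}

#' @export
print.indicator_panel <- function(x, ...) {
  cat("indicator_panel:", length(x$region_ids), "regions x",
      length(x$indicator_ids), "indicators\n")
  invisible(x)
}

#' Read a region-by-indicator panel from CSV
#'
#' Expects a header row with a `region_id` column followed by numeric
#' indicator columns. Parse failures name the offending row/column.
#'
#' @param path Path to a comma-separated file.
#' @return An [indicator_panel].
#' @export
read_indicator_panel <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"region_id" %in% names(df)) stop("missing column 'region_id' in ", path)
  ids <- as.character(df$region_id)
  vals <- df[setdiff(names(df), "region_id")]
  if (ncol(vals) < 1) stop("no indicator columns in ", path)
  for (cn in names(vals)) {
    v <- suppressWarnings(as.numeric(vals[[cn]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d (region '%s'), column '%s'",
                   i, ids[i], cn))
    }
    vals[[cn]] <- v
  }
  indicator_panel(as.matrix(vals), region_ids = ids,
                  indicator_ids = names(vals))
}

#' Read a region metadata table from CSV
#'
#' Columns: `region_id`, optional `region_name`, `population`, `gdp`,
#' `gdp_per_capita`, optional planar `x_coord`/`y_coord` (synthetic runs).
#' All numeric fields must be strictly positive.
#'
#' @param path Path to a comma-separated file.
#' @return A data.frame of class `region_table`.
#' @export
read_region_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_region_table(df)
}

#' Validate a region metadata table
#'
#' @param df A data.frame with region_id, population, gdp, gdp_per_capita.
#' @return The validated data.frame, classed `region_table`.
#' @export
validate_region_table <- function(df) {
  need <- c("region_id", "population", "gdp", "gdp_per_capita")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$region_id)) {
    stop("duplicate region_id: ", df$region_id[duplicated(df$region_id)][1])
  }
  for (cn in c("population", "gdp", "gdp_per_capita")) {
    v <- df[[cn]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      stop("column '", cn, "' must be strictly positive and finite")
    }
  }
  class(df) <- unique(c("region_table", class(df)))
  df
}

#' Read a labeled distance matrix from CSV
#'
#' First column holds region ids, header row repeats them. The matrix must be
#' symmetric with zero diagonal and strictly positive off-diagonal entries.
#'
#' @param path Path to a comma-separated file.
#' @return A validated numeric matrix with dimnames.
#' @export
read_distance_matrix <- function(path) {
  m <- read_labeled_matrix(path)
  validate_distance_matrix(m)
}

#' Validate a distance matrix
#'
#' @param m Square numeric matrix.
#' @param tol Symmetry tolerance.
#' @return The matrix, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_distance_matrix <- function(m, tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (any(!is.finite(m))) stop("distance matrix has non-finite entries")
  if (any(m < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(m)) > 0)) stop("distance matrix diagonal must be zero")
  if (max(abs(m - t(m))) > tol * max(1, max(abs(m)))) {
    stop("distance matrix must be symmetric")
  }
  off <- m[row(m) != col(m)]
  if (any(off <= 0)) stop("off-diagonal distances must be strictly positive")
  m
}

#' Write / read a labeled square matrix as CSV
#'
#' The storage dialect for all square artifacts: a header row of region ids
#' and an id first column. `write_labeled_matrix` followed by
#' `read_labeled_matrix` is the identity (up to numeric printing, which uses
#' full precision).
#'
#' @param m Square numeric matrix with dimnames.
#' @param path Destination/source file path.
#' @return `read_labeled_matrix` returns the matrix; the writer returns the
#'   path invisibly.
#' @export
write_labeled_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("R", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  # %.17g guarantees doubles survive the text round trip bit-exactly
  fm <- matrix(sprintf("%.17g", m), nrow(m), dimnames = dimnames(m))
  df <- data.frame(region_id = rownames(m),
                   as.data.frame(fm, check.names = FALSE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labeled_matrix
#' @export
read_labeled_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("matrix cells must be numeric in ", path)
  rownames(m) <- ids
  if (!identical(colnames(m), ids)) {
    if (!setequal(colnames(m), ids)) stop("row/column labels disagree in ", path)
    m <- m[, ids, drop = FALSE]
  }
  m
}

#' Write a spatial network's adjacency matrix to CSV
#'
#' @param net A [spatial_network].
#' @param path Destination path.
#' @export
write_adjacency <- function(net, path) {
  stopifnot(inherits(net, "spatial_network"))
  write_labeled_matrix(net$adjacency, path)
}

#' Read an adjacency matrix CSV back into a spatial network
#'
#' @param path Source path.
#' @param year Optional year tag.
#' @return A [spatial_network].
#' @export
read_adjacency <- function(path, year = NA) {
  m <- read_labeled_matrix(path)
  spatial_network(m, year = year)
}

#' Write a directed edge list (TSV)
#'
#' One `source<TAB>target<TAB>weight` line per directed tie. Weights come
#' from the gravity matrix when supplied, else 1.
#'
#' @param net A [spatial_network].
#' @param path Destination path.
#' @param weights Optional square matrix of tie weights.
#' @export
write_edge_list <- function(net, path, weights = NULL) {
  stopifnot(inherits(net, "spatial_network"))
  a <- net$adjacency
  idx <- which(a == 1, arr.ind = TRUE)
  w <- if (is.null(weights)) rep(1, nrow(idx)) else weights[idx]
  df <- data.frame(source = rownames(a)[idx[, 1]],
                   target = colnames(a)[idx[, 2]],
                   weight = w)
  df <- df[order(df$source, df$target), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a JSON run report
#'
#' Serializes any list of pipeline results (weights, scores, metrics, block
#' table, QAP table, configuration echo) as pretty-printed JSON.
#'
#' @param results A list.
#' @param path Destination path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Assemble a run configuration
#'
#' Collects every tunable the pipeline consumes, with the defaults used
#' throughout the package. Validated on construction.
#'
#' @param years Years to process (synthetic runs).
#' @param binarize_rule One of "row_mean", "col_mean", "grand_mean".
#' @param concor_depth Maximum CONCOR split depth (>= 1).
#' @param concor_tol CONCOR convergence criterion in (0, 1).
#' @param n_perm QAP permutation count (>= 1).
#' @param seed Integer RNG seed.
#' @param out_dir Output directory or NA for in-memory runs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(years = 2018, binarize_rule = "row_mean",
                       concor_depth = 2, concor_tol = 0.2,
                       n_perm = 8000, seed = 1L, out_dir = NA) {
  binarize_rule <- match.arg(binarize_rule,
                             c("row_mean", "col_mean", "grand_mean"))
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (concor_depth < 1) stop("concor_depth must be >= 1")
  structure(list(years = years, binarize_rule = binarize_rule,
                 concor_depth = concor_depth, concor_tol = concor_tol,
                 n_perm = n_perm, seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}
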
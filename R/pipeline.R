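#' Run the full analysis pipeline
#'
#' Executes the five analysis stages in order — entropy-weight scoring,
#' modified gravity, mean critical-point binarization, network metrics,
#' CONCOR blockmodel with roles, QAP correlation — either on supplied
#' inputs or on a synthetic dataset, one independent cross-section per
#' year. Deterministic given the seed in `config`.
#'
#' @param config A [run_config()].
#' @param data Either a `synthetic_data` object, or a list with elements
#'   `regions`, `panels` (named list of panels by year), `distances` and
#'   optionally `covariates`. NULL generates synthetic data from the
#'   config's seed and years.
#' @param stages Character subset of
#'   c("score", "network", "metrics", "blocks", "qap") to run.
#' @return A `pipeline_report`: per-year results plus a trend table of
#'   density/level/efficiency by year and a config echo.
#' @export
run_pipeline <- function(config = run_config(), data = NULL,
                         stages = c("score", "network", "metrics",
                                    "blocks", "qap")) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(data)) {
    data <- generate_synthetic(synthetic_spec(years = config$years,
                                              seed = config$seed))
  }
  years <- intersect(as.character(config$years), names(data$panels))
  if (length(years) == 0) stop("no requested year present in the panel data")

  per_year <- list()
  trend <- NULL
  for (yr in years) {
    res <- list(year = as.numeric(yr))
    panel <- data$panels[[yr]]

    cap <- capacity_index(panel)
    if ("score" %in% stages) {
      res$weights <- as.list(cap$weights)
      res$scores <- as.list(cap$scores)
    }

    net <- NULL
    if (any(c("network", "metrics", "blocks", "qap") %in% stages)) {
      N <- pmax(cap$scores, 1e-6)
      grav <- modified_gravity(data$regions, N, data$distances)
      X <- grav$X
      if (!is.null(data$block_assignment) && !is.null(data$spec)) {
        # synthetic runs carry their plant through the pipeline
        X <- apply_block_boost(X, data$block_assignment,
                               data$spec$block_boost)
      }
      net <- binarize_gravity(X, rule = config$binarize_rule, year = yr)
      res$network <- list(rule = config$binarize_rule,
                          directed_ties = sum(net$adjacency))
    }
    if ("metrics" %in% stages) {
      res$summary <- network_summary(net)
      res$centrality <- centrality_table(net)
      trend <- rbind(trend, data.frame(year = as.numeric(yr),
                                       density = res$summary$density,
                                       level = res$summary$level,
                                       efficiency = res$summary$efficiency))
    }
    if ("blocks" %in% stages) {
      part <- concor(net, depth = config$concor_depth,
                     tolerance = config$concor_tol)
      res$blocks <- block_characteristics(net, part)
      res$block_assignment <- as.list(part$assignment)
    }
    if ("qap" %in% stages && !is.null(data$covariates)) {
      res$qap <- qap_table(net, data$covariates, n_perm = config$n_perm,
                           seed = config$seed)
    }
    per_year[[yr]] <- res
  }

  report <- structure(list(config = unclass(config), years = per_year,
                           trend = trend),
                      class = "pipeline_report")
  if (!is.na(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report_to_json(report),
                 file.path(config$out_dir, "report.json"))
  }
  report
}

#' Run metrics only on a provided adjacency matrix
#'
#' @param net A [spatial_network].
#' @return List with the network summary and centrality table.
#' @export
metrics_only <- function(net) {
  list(summary = network_summary(net), centrality = centrality_table(net))
}

# Flatten a pipeline_report into JSON-serializable plain lists.
report_to_json <- function(report) {
  yrs <- lapply(report$years, function(res) {
    if (!is.null(res$centrality)) res$centrality <- as.data.frame(res$centrality)
    if (!is.null(res$blocks)) res$blocks <- as.data.frame(res$blocks)
    if (!is.null(res$qap)) res$qap <- as.data.frame(res$qap)
    res
  })
  list(config = report$config, years = yrs, trend = report$trend)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", length(x$years), "year(s)\n")
  if (!is.null(x$trend)) print(x$trend, row.names = FALSE)
  invisible(x)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `score`, `network`, `metrics`,
#' `blocks`, `qap`, `validate` and `run`. Flags are `--name value` pairs;
#' see the package README for the per-command flags. Called by the
#' `inst/cli/agglomnet.R` wrapper script.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the result object of the subcommand.
#' @export
agglomnet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: agglomnet <simulate|score|network|metrics|blocks|qap|validate|run> [--flag value ...]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- parse_flags(args[-1])
  get_opt <- function(name, default = NULL) {
    if (!is.null(opt[[name]])) opt[[name]] else default
  }
  result <- switch(cmd,
    simulate = {
      spec <- synthetic_spec(
        n_regions = as.numeric(get_opt("n-regions", 31)),
        years = seq(as.numeric(get_opt("from", 2004)),
                    as.numeric(get_opt("to", 2018))),
        seed = as.integer(get_opt("seed", 1)))
      sdata <- generate_synthetic(spec)
      out <- get_opt("out", "synthetic")
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(sdata$regions, file.path(out, "regions.csv"),
                       row.names = FALSE, quote = FALSE)
      write_labeled_matrix(sdata$distances, file.path(out, "dist.csv"))
      utils::write.csv(sdata$covariates, file.path(out, "covariates.csv"),
                       row.names = FALSE, quote = FALSE)
      for (yr in names(sdata$panels)) {
        p <- sdata$panels[[yr]]
        utils::write.csv(data.frame(region_id = p$region_ids, p$values,
                                    check.names = FALSE),
                         file.path(out, paste0("panel_", yr, ".csv")),
                         row.names = FALSE, quote = FALSE)
      }
      message("synthetic data written to ", out)
      sdata
    },
    score = {
      panel <- read_indicator_panel(get_opt("panel"))
      res <- capacity_index(panel)
      write_report(list(weights = as.list(res$weights),
                        entropies = as.list(res$entropies),
                        scores = as.list(res$scores)),
                   get_opt("out", "capacity.json"))
      res
    },
    network = {
      regions <- read_region_table(get_opt("regions"))
      D <- read_distance_matrix(get_opt("dist"))
      cap <- jsonlite::read_json(get_opt("capacity"), simplifyVector = TRUE)
      N <- unlist(cap$scores)
      grav <- modified_gravity(regions, pmax(N, 1e-6), D)
      net <- binarize_gravity(grav, rule = get_opt("rule", "row_mean"))
      write_adjacency(net, get_opt("out", "net.csv"))
      gpath <- get_opt("gravity-out", "gravity.csv")
      write_labeled_matrix(grav$X, gpath)
      net
    },
    metrics = {
      net <- read_adjacency(get_opt("net"))
      res <- metrics_only(net)
      write_report(list(summary = res$summary,
                        centrality = res$centrality),
                   get_opt("out", "metrics.json"))
      utils::write.csv(res$centrality,
                       get_opt("table-out", "centrality.csv"),
                       row.names = FALSE)
      res
    },
    blocks = {
      net <- read_adjacency(get_opt("net"))
      part <- concor(net, depth = as.numeric(get_opt("depth", 2)),
                     tolerance = as.numeric(get_opt("tol", 0.2)))
      bc <- block_characteristics(net, part)
      write_report(list(assignment = as.list(part$assignment),
                        blocks = as.data.frame(bc)),
                   get_opt("out", "blocks.json"))
      bc
    },
    qap = {
      net <- read_adjacency(get_opt("net"))
      cov <- utils::read.csv(get_opt("covariates"),
                             stringsAsFactors = FALSE)
      tab <- qap_table(net, cov,
                       n_perm = as.numeric(get_opt("nperm", 8000)),
                       seed = as.integer(get_opt("seed", 1)))
      write_report(as.data.frame(tab), get_opt("out", "qap.json"))
      tab
    },
    validate = {
      ok <- TRUE
      if (!is.null(opt$panel)) {
        tryCatch(read_indicator_panel(opt$panel),
                 error = function(e) { ok <<- FALSE; message("panel: ", conditionMessage(e)) })
      }
      if (!is.null(opt$dist)) {
        tryCatch(read_distance_matrix(opt$dist),
                 error = function(e) { ok <<- FALSE; message("dist: ", conditionMessage(e)) })
      }
      if (!is.null(opt$regions)) {
        tryCatch(read_region_table(opt$regions),
                 error = function(e) { ok <<- FALSE; message("regions: ", conditionMessage(e)) })
      }
      message(if (ok) "all inputs valid" else "validation FAILED")
      ok
    },
    run = {
      cfg <- run_config(
        years = seq(as.numeric(get_opt("from", 2004)),
                    as.numeric(get_opt("to", 2018))),
        binarize_rule = get_opt("rule", "row_mean"),
        concor_depth = as.numeric(get_opt("depth", 2)),
        concor_tol = as.numeric(get_opt("tol", 0.2)),
        n_perm = as.numeric(get_opt("nperm", 8000)),
        seed = as.integer(get_opt("seed", 1)),
        out_dir = get_opt("out", "run_output"))
      run_pipeline(cfg)
    },
    stop("unknown command: ", cmd)
  )
  invisible(result)
}

# Parse "--name value" pairs into a named list.
parse_flags <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got: ", args[i])
    name <- sub("^--", "", args[i])
    if (i + 1 > length(args)) stop("flag --", name, " needs a value")
    opt[[name]] <- args[i + 1]
    i <- i + 2
  }
  opt
}
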
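# End-to-end reproducible runs: configuration, synthetic study simulation,
# stage orchestration, file outputs, and a run manifest.

#' Simulate a synthetic survey study
#'
#' Writes (or returns) a raw survey table with the package's default
#' structure: `n` older respondents with validated ages drawn from a
#' truncated normal (mean 80.5, SD 10, range 65-109), a diabetes-diagnosis
#' flag set, and the 17 ordinal items sampled from the default two-community
#' true network through the latent-Gaussian threshold model with the
#' default right-skewed marginals.
#'
#' @param n Number of respondents (default 1685).
#' @param seed Master seed.
#' @param missing_rate Per-cell missingness rate (default 0: a
#'   complete-case extract).
#' @param net True network (default [make_true_network()] with the seed).
#' @param thresholds Threshold matrix (default calibrated set).
#' @param path Optional CSV output path.
#' @return The raw survey table (invisibly if written to `path`).
#' @export
simulate_study <- function(n = 1685, seed = 1, missing_rate = 0,
                           net = make_true_network(seed = seed),
                           thresholds = default_thresholds(),
                           path = NULL) {
  R <- true_covariance(net)
  tab <- sample_ordinal(R, thresholds, n, seed = sub_seed(seed, 1, 300))
  age <- with_seed(sub_seed(seed, 2, 300), {
    a <- numeric(0)
    while (length(a) < n) {
      cand <- rnorm(2 * n, 80.5, 10)
      a <- c(a, cand[cand >= 65 & cand <= 109])
    }
    round(a[seq_len(n)], 1)
  })
  tab <- data.frame(participant_id = tab$participant_id,
                    age = age, dm_diagnosed = 1L,
                    tab[, -1, drop = FALSE], check.names = FALSE)
  if (missing_rate > 0)
    tab <- inject_missing(tab, missing_rate, seed = sub_seed(seed, 3, 300))
  if (!is.null(path)) {
    write_survey_csv(tab, path)
    return(invisible(tab))
  }
  tab
}

#' Build a run configuration
#'
#' Every field has a default, so `run_config()` alone describes a valid
#' fully synthetic run.
#'
#' @param input Path to a survey CSV, or `NULL` to simulate.
#' @param n Synthetic sample size (used when `input` is `NULL`).
#' @param seed Master seed for simulation and all bootstraps.
#' @param missing_rate Synthetic per-cell missingness rate.
#' @param gamma EBIC hyperparameter.
#' @param n_points Penalty path length.
#' @param B Bootstrap samples; `B = 0` skips the stability stage.
#' @param alpha Difference-test significance level.
#' @param drop_grid Case-dropping proportions.
#' @param min_age Eligibility age threshold.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(input = NULL, n = 1685, seed = 1, missing_rate = 0,
                       gamma = 0.5, n_points = 100, B = 1000,
                       alpha = 0.05, drop_grid = seq(0.05, 0.75, by = 0.05),
                       min_age = 65, out_dir = "symptomnet_out") {
  structure(list(input = input, n = n, seed = seed,
                 missing_rate = missing_rate, gamma = gamma,
                 n_points = n_points, B = B, alpha = alpha,
                 drop_grid = drop_grid, min_age = min_age,
                 out_dir = out_dir),
            class = "run_config")
}

write_table <- function(df, dir, file) {
  path <- file.path(dir, file)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

#' Export a network to GraphML
#'
#' @param net A `symptom_network` or `true_network`.
#' @param path Output `.graphml` path.
#' @export
export_graphml <- function(net, path) {
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$community <- unname(net$communities[net$node_names])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

network_edge_table <- function(net) {
  W <- net$weights
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  data.frame(node_a = net$node_names[ut[, 1]],
             node_b = net$node_names[ut[, 2]],
             weight = W[ut])
}

#' Run the full analysis pipeline
#'
#' Executes eligibility filtering, scale scoring and descriptives, network
#' estimation, centrality, and (when `B > 0`) the bootstrap stability
#' stage, writing all tabular outputs and a JSON manifest to
#' `config$out_dir`. With an identical configuration and seed, all numeric
#' outputs are byte-identical across runs.
#'
#' @param config A [run_config()].
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  manifest <- list(config = unclass(config), seed = config$seed,
                   version = as.character(utils::packageVersion("symptomnet")))
  run <- function(what, expr) {
    stage <- what
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  raw <- run("input", {
    if (is.null(config$input)) {
      tab <- simulate_study(n = config$n, seed = config$seed,
                            missing_rate = config$missing_rate)
      write_survey_csv(tab, file.path(config$out_dir, "survey.csv"))
      tab
    } else read_survey_csv(config$input)
  })
  manifest$rows_input <- nrow(raw)

  eligible <- run("filter", filter_eligible(raw, min_age = config$min_age))
  manifest$exclusions <- as.list(attr(eligible, "exclusions"))
  manifest$rows_eligible <- nrow(eligible)

  run("screening", {
    desc <- describe_items(eligible)
    write_table(desc, config$out_dir, "descriptives.csv")
    scores <- score_scales(eligible)
    prev <- prevalence(scores)
    manifest$prevalence <- as.list(prev)
    manifest$cronbach_alpha <- list(
      cesd = cronbach_alpha(eligible[cesd_items()]),
      gad = cronbach_alpha(eligible[gad_items()]))
  })

  net <- run("estimation",
             select_network(eligible, gamma = config$gamma,
                            n_points = config$n_points))
  manifest$lambda_selected <- net$lambda
  manifest$ebic <- net$ebic
  manifest$edge_count <- edge_count(net)
  run("estimation", {
    write_table(network_edge_table(net), config$out_dir, "edge_list.csv")
    write_table(net$path, config$out_dir, "lambda_path.csv")
    export_graphml(net, file.path(config$out_dir, "network.graphml"))
  })

  run("centrality", {
    ct <- centrality_table(net)
    write_table(ct, config$out_dir, "nodes.csv")
  })

  if (config$B > 0) {
    run("stability", {
      eb <- edge_bootstrap(eligible, B = config$B, seed = config$seed,
                           gamma = config$gamma, n_points = config$n_points)
      boot_tab <- data.frame(edge = names(eb$estimate),
                             estimate = unname(eb$estimate),
                             lower = eb$lower, upper = eb$upper,
                             B = eb$B, failures = eb$failures)
      write_table(boot_tab, config$out_dir, "boot_edges.csv")

      nz <- which(eb$estimate != 0)
      dt <- difference_test_matrix(eb$draws, alpha = config$alpha,
                                   subset = nz)
      colnames(dt) <- rownames(dt) <- names(eb$estimate)[nz]
      dt_long <- data.frame(
        edge_a = rep(rownames(dt), times = ncol(dt)),
        edge_b = rep(colnames(dt), each = nrow(dt)),
        significant = as.vector(dt))
      dt_long <- dt_long[dt_long$edge_a < dt_long$edge_b, ]
      write_table(dt_long, config$out_dir, "edge_diff_tests.csv")

      cs <- lapply(c(EI = "EI", BEI = "BEI"), function(stat) {
        cd <- case_dropping(eligible, statistic = stat,
                            proportions = config$drop_grid, B = config$B,
                            seed = config$seed, gamma = config$gamma,
                            n_points = config$n_points)
        list(cs = cs_coefficient(cd), drop = cd)
      })
      cs_tab <- data.frame(statistic = names(cs),
                           cs_coefficient = vapply(cs, function(x) x$cs, 0))
      write_table(cs_tab, config$out_dir, "cs_coefficients.csv")
      manifest$cs <- stats::setNames(lapply(cs, function(x) x$cs),
                                      names(cs))
    })
  } else {
    manifest$stability <- "skipped (B = 0)"
  }

  manifest$timestamp <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
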
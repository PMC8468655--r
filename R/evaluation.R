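#' Average shortest-path length among selected spreaders (LS)
#'
#' Mean hop distance over all unordered pairs of spreaders; larger values
#' mean a better-scattered seed set. Pairs lying in different components
#' are excluded from both numerator and denominator, and the number of
#' excluded pairs is reported.
#'
#' @param graph An undirected [igraph::graph].
#' @param spreaders Character vector of at least two nodes, or a spreader
#'   tibble with a `node` column.
#' @return A one-row tibble: `ls` (NA if every pair is disconnected),
#'   `n_pairs` (pairs used), `n_excluded` (disconnected pairs).
#' @examples
#' g <- toy_fixtures()$c4
#' avg_spreader_distance(g, c("a", "b", "c"))
#' @export
avg_spreader_distance <- function(graph, spreaders) {
  if (is.data.frame(spreaders)) spreaders <- spreaders$node
  spreaders <- unique(as.character(spreaders))
  if (length(spreaders) < 2) {
    abort("need at least two spreaders to compute LS")
  }
  spreaders <- check_nodes(graph, spreaders)
  d <- igraph::distances(graph, v = spreaders, to = spreaders,
                         algorithm = "unweighted")
  up <- d[upper.tri(d)]
  finite <- is.finite(up)
  tibble::tibble(
    ls = if (any(finite)) mean(up[finite]) else NA_real_,
    n_pairs = sum(finite),
    n_excluded = sum(!finite)
  )
}

#' Combine any ranking metric with the community-distribution strategy
#'
#' The "starred" variant of a benchmark metric: spreaders are allocated to
#' communities proportionally to size and the metric is then used within
#' each community instead of globally. For score-type metrics the globally
#' computed score table is used with per-community top selection; for the
#' iterative rankers (VoteRank, HybridRank, IKS) the ranker runs on each
#' community's induced subgraph with that community's allocation. With the
#' gravity k-shell score this is exactly [pbsi_select()].
#'
#' @param graph An undirected [igraph::graph].
#' @param membership A membership tibble covering the graph.
#' @param p_total Number of spreaders.
#' @param scores A precomputed score tibble (`node`, `score`), or `NULL`
#'   to use `metric`.
#' @param metric Metric name (see [rank_nodes()]) used when `scores` is
#'   `NULL`.
#' @inheritParams rank_nodes
#' @return A spreader tibble (`node`, `community`, `score`, `rank`).
#' @export
combined_variant <- function(graph, membership, p_total, scores = NULL,
                             metric = "deg", radius = 3L, alpha = 1,
                             sir = NULL) {
  membership <- partition_from_membership(graph, membership)
  plan <- allocate_spreaders(membership, p_total)
  if (is.null(scores) && metric %in% c("vr", "hc", "iks")) {
    picked <- purrr::pmap(
      list(plan$community, plan$n_spreaders),
      function(com, p) {
        if (p == 0) return(NULL)
        members <- membership$node[membership$community == com]
        sub <- igraph::induced_subgraph(graph, members)
        sel <- select_top_nodes(sub, metric, p)
        dplyr::mutate(sel, community = com)
      }
    )
    out <- dplyr::bind_rows(picked)
    return(out[, c("node", "community", "score", "rank")])
  }
  if (is.null(scores)) {
    scores <- rank_nodes(graph, metric, radius = radius, alpha = alpha,
                         sir = sir)
  }
  select_spreaders(membership, scores, plan)
}

#' Profit of the community-distributed variant of a metric
#'
#' `delta = fss_combined / fss_simple`; values above 1 mean the
#' distribution strategy improved the metric.
#'
#' @param fss_combined,fss_simple Mean final spreading scopes of the
#'   combined ("starred") and simple variants.
#' @return The ratio.
#' @export
profit <- function(fss_combined, fss_simple) {
  if (any(fss_simple <= 0)) abort("fss_simple must be positive")
  fss_combined / fss_simple
}

#' Aggregate profits over a simple-vs-combined FSS table
#'
#' Takes a tidy table with one row per (network, method) and the FSS of the
#' simple and combined variants, and returns per-cell profits plus the
#' average profit (mean of `delta - 1`, as a percentage) with and without
#' the simulation-based TSA method.
#'
#' @param fss_table A tibble with columns `network`, `method`,
#'   `fss_simple`, `fss_combined`.
#' @return A list with `cells` (the table plus a `delta` column) and
#'   `summary`, a tibble of `aggregation` / `avg_profit_pct`.
#' @export
profit_summary <- function(fss_table) {
  cells <- dplyr::mutate(fss_table,
                         delta = profit(.data$fss_combined,
                                        .data$fss_simple))
  no_tsa <- dplyr::filter(cells, .data$method != "tsa")
  summary <- tibble::tibble(
    aggregation = c("all_methods", "excluding_tsa"),
    avg_profit_pct = c(100 * mean(cells$delta - 1),
                       100 * mean(no_tsa$delta - 1))
  )
  list(cells = cells, summary = summary)
}

#' Published benchmark final-spreading-scope table
#'
#' The bundled reference benchmark results: mean FSS reached by eight
#' seed-selection methods (betweenness, closeness, degree, HybridRank,
#' VoteRank, indirect spreading strength, improved k-shell, true spreading
#' ability), each in its simple and community-distributed ("starred")
#' variant, on eight public networks (SIR with `mu = 1`, `beta = 0.13`,
#' as many seeds as Louvain communities). Used for profit aggregation
#' examples and arithmetic cross-checks.
#'
#' @return A tibble with columns `network`, `method`, `fss_simple`,
#'   `fss_combined`.
#' @export
reference_fss <- function() {
  path <- system.file("extdata", "benchmark_fss.tsv", package = "pbsi")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Published network summary table
#'
#' Bundled summary statistics of nine public real networks commonly used in
#' spreader-identification benchmarks: node and edge counts, reported mean
#' degree, mean shortest path, clustering coefficient, maximum k-shell and
#' Louvain community count.
#'
#' @return A tibble with columns `network`, `n_nodes`, `n_edges`,
#'   `avg_degree`, `avg_path`, `clustering`, `ks_max`, `n_communities`.
#' @export
reference_networks <- function() {
  path <- system.file("extdata", "network_summary.tsv", package = "pbsi")
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Run a simple-vs-combined spreading experiment grid
#'
#' For every combination of spreading rate, seed-set size, method and
#' variant, selects the seed set once, estimates the mean final spreading
#' scope over `runs` SIR replicates, and computes the seed-scatter metric
#' LS. Output is one tidy row per cell.
#'
#' @param graph An undirected [igraph::graph].
#' @param betas Numeric vector of transmission probabilities.
#' @param rhos Integer vector of seed-set sizes.
#' @param methods Character vector of metric names (see [rank_nodes()]).
#' @param variants Subset of `c("simple", "combined")`.
#' @param membership Optional ground-truth membership tibble; detected with
#'   Louvain (seeded) when `NULL` and a combined variant is requested.
#' @param mu Recovery probability.
#' @param runs SIR replicates per cell.
#' @param seed Root seed (selection, detection and simulation all derive
#'   from it).
#' @param radius,alpha Passed to the rankers.
#' @return A tibble of class `pbsi_grid` with columns `method`, `variant`,
#'   `beta`, `rho`, `fss_mean`, `fss_se`, `ls`, `runs`.
#' @export
run_grid <- function(graph, betas, rhos, methods = c("gksw", "deg"),
                     variants = c("simple", "combined"), membership = NULL,
                     mu = 1, runs = 100L, seed = 1L, radius = 3L,
                     alpha = 1) {
  stopifnot(length(betas) > 0, length(rhos) > 0,
            all(betas >= 0 & betas <= 1))
  variants <- match.arg(variants, several.ok = TRUE)
  if ("combined" %in% variants && is.null(membership)) {
    membership <- detect_communities(graph, seed = seed)
  }
  base_sir <- sir_config(beta = 0, mu = mu, runs = runs, seed = seed)
  cells <- tidyr::expand_grid(method = methods, variant = variants,
                              rho = as.integer(rhos))
  seed_sets <- purrr::pmap(cells, function(method, variant, rho) {
    if (variant == "simple") {
      select_top_nodes(graph, method, rho, radius = radius, alpha = alpha,
                       sir = base_sir)$node
    } else {
      combined_variant(graph, membership, rho, metric = method,
                       radius = radius, alpha = alpha, sir = base_sir)$node
    }
  })
  cells$ls <- vapply(seed_sets, function(s) {
    if (length(s) < 2) return(NA_real_)
    avg_spreader_distance(graph, s)$ls
  }, numeric(1))
  cells$cell_id <- seq_len(nrow(cells))
  out <- tidyr::expand_grid(cells, beta = betas)
  res <- purrr::pmap(
    list(out$beta, out$cell_id, seq_len(nrow(out))),
    function(beta, idx, i) {
      cfg <- sir_config(beta = beta, mu = mu, runs = runs,
                        seed = seed + i)
      fss_mean(graph, seed_sets[[idx]], cfg)
    }
  )
  out$fss_mean <- vapply(res, `[[`, numeric(1), "fss_mean")
  out$fss_se <- vapply(res, `[[`, numeric(1), "fss_se")
  out$runs <- as.integer(runs)
  out <- out[, c("method", "variant", "beta", "rho", "fss_mean", "fss_se",
                 "ls", "runs")]
  class(out) <- c("pbsi_grid", class(out))
  out
}
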
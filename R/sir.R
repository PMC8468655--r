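#' SIR simulation configuration
#'
#' @param beta Transmission probability per contact, in `[0, 1]`.
#' @param mu Recovery probability per step, in `(0, 1]` (default 1: each
#'   node is infectious for exactly one step).
#' @param runs Number of independent replicates for ensemble estimates.
#' @param seed Root RNG seed; each replicate derives its own reproducible
#'   stream from it.
#' @param max_steps Safety cap on the number of steps (default `10 * n`,
#'   resolved at run time); only binding for `mu` near 0.
#' @param contact Contact rule: `"single"` (default; each infected node
#'   contacts one uniformly random neighbour per step) or `"all"` (an
#'   independent transmission attempt to every susceptible neighbour, the
#'   textbook network-SIR rule). Note that under `"single"` with `mu = 1`
#'   the mean number of secondary infections is at most `beta`, so
#'   outbreaks are always subcritical; `"all"` is provided for comparison
#'   with that regime.
#' @return A list of class `sir_config`.
#' @export
sir_config <- function(beta, mu = 1, runs = 100L, seed = 1L,
                       max_steps = NULL, contact = c("single", "all")) {
  stopifnot(beta >= 0, beta <= 1, mu > 0, mu <= 1, runs >= 1)
  structure(list(beta = beta, mu = mu, runs = as.integer(runs),
                 seed = as.integer(seed), max_steps = max_steps,
                 contact = match.arg(contact)),
            class = "sir_config")
}

#' Run one realisation of the discrete-time SIR contact process
#'
#' All nodes start susceptible except the seed set, which starts infected.
#' At each step, every currently infected node contacts one of its
#' neighbours uniformly at random; if that neighbour is susceptible it
#' becomes infected with probability `beta` (infectious from the next step).
#' Simultaneously, every node that was infected at the start of the step
#' recovers with probability `mu`. The process stops when no infected nodes
#' remain; the final spreading scope (FSS) equals the number of recovered
#' nodes at termination.
#'
#' Note the contact rule: one random neighbour per infected node per step,
#' not an independent transmission attempt to every neighbour.
#'
#' @param graph An undirected [igraph::graph].
#' @param seeds Character vector of seed nodes (distinct, present in the
#'   graph) or a spreader tibble with a `node` column.
#' @param config An [sir_config()].
#' @param seed Optional RNG seed for this single run (defaults to
#'   `config$seed`).
#' @return An object of class `sir_result`: a list with `fss`, `steps`,
#'   `n_seeds`, and a per-step `trajectory` tibble (`t`, `new_infected`,
#'   `ss`, `n_s`, `n_i`, `n_r`). See [tidy()] and [glance()] methods.
#' @examples
#' g <- toy_fixtures()$path3
#' sir_run(g, "b", sir_config(beta = 1), seed = 42)
#' @export
sir_run <- function(graph, seeds, config, seed = NULL) {
  if (is.data.frame(seeds)) seeds <- seeds$node
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0) abort("seed set must be non-empty")
  seeds <- check_nodes(graph, seeds)
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(seed, sir_run_impl(graph, seeds, config))
}

sir_run_impl <- function(graph, seeds, config) {
  n <- igraph::vcount(graph)
  nodes <- node_names(graph)
  adj <- adjacency_index(graph)
  max_steps <- config$max_steps %||% (10L * n)
  # 0 = susceptible, 1 = infected, 2 = recovered
  status <- integer(n)
  status[match(seeds, nodes)] <- 1L
  new_infected <- integer(0)
  n_s <- integer(0); n_i <- integer(0); n_r <- integer(0)
  t <- 0L
  while (any(status == 1L) && t < max_steps) {
    t <- t + 1L
    infected <- which(status == 1L)
    # contacts resolved from the step-start state
    newly <- integer(0)
    for (i in infected) {
      nb <- adj[[i]]
      if (length(nb) == 0) next
      if ((config$contact %||% "single") == "single") {
        target <- nb[sample.int(length(nb), 1L)]
        if (status[target] == 0L && !(target %in% newly) &&
            runif(1) < config$beta) {
          newly <- c(newly, target)
        }
      } else {
        sus <- nb[status[nb] == 0L & !(nb %in% newly)]
        if (length(sus) > 0) {
          newly <- c(newly, sus[runif(length(sus)) < config$beta])
        }
      }
    }
    # simultaneous recovery of step-start infected
    recovering <- infected[runif(length(infected)) < config$mu]
    status[recovering] <- 2L
    status[newly] <- 1L  # infectious from the next step
    new_infected <- c(new_infected, length(newly))
    n_s <- c(n_s, sum(status == 0L))
    n_i <- c(n_i, sum(status == 1L))
    n_r <- c(n_r, sum(status == 2L))
  }
  if (any(status == 1L)) {
    warn("sir_run reached max_steps with infected nodes remaining")
  }
  fss <- length(seeds) + sum(new_infected)
  structure(list(
    fss = fss,
    steps = t,
    n_seeds = length(seeds),
    trajectory = tibble::tibble(
      t = seq_len(t),
      new_infected = new_infected,
      ss = length(seeds) + new_infected,
      n_s = n_s, n_i = n_i, n_r = n_r
    )
  ), class = "sir_result")
}

#' @export
print.sir_result <- function(x, ...) {
  cat("<sir_result> fss =", x$fss, "| steps =", x$steps,
      "| seeds =", x$n_seeds, "\n")
  invisible(x)
}

#' Tidiers for SIR results
#'
#' `tidy()` returns the per-step trajectory (`t`, `new_infected`, `ss` the
#' spreading scope `|seeds| + I(t)`, and the three compartment counts);
#' `glance()` returns a one-row summary.
#'
#' @param x An `sir_result`.
#' @param ... Unused.
#' @method tidy sir_result
#' @export
tidy.sir_result <- function(x, ...) x$trajectory

#' @rdname tidy.sir_result
#' @method glance sir_result
#' @export
glance.sir_result <- function(x, ...) {
  tibble::tibble(fss = x$fss, steps = x$steps, n_seeds = x$n_seeds)
}

#' Ensemble mean final spreading scope
#'
#' Runs `config$runs` independent SIR replicates and returns the mean and
#' standard error of the final spreading scope. Replicate streams are
#' derived from the root seed, so replicate `r` is reproducible in
#' isolation.
#'
#' @inheritParams sir_run
#' @return A one-row tibble: `fss_mean`, `fss_se`, `runs`, `n_seeds`.
#' @export
fss_mean <- function(graph, seeds, config) {
  if (is.data.frame(seeds)) seeds <- seeds$node
  seeds <- unique(as.character(seeds))
  seeds <- check_nodes(graph, seeds)
  rep_seeds <- withr::with_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, config$runs))
  fss <- vapply(rep_seeds, function(s) {
    withr::with_seed(s, sir_run_impl(graph, seeds, config))$fss
  }, numeric(1))
  tibble::tibble(
    fss_mean = mean(fss),
    fss_se = if (length(fss) > 1) sd(fss) / sqrt(length(fss)) else 0,
    runs = config$runs,
    n_seeds = length(seeds)
  )
}

#' Epidemic threshold of a network
#'
#' The degree-based mean-field estimate `<k> / <k^2>`, with both moments
#' over all nodes. Spreading rates slightly above this threshold produce
#' system-wide outbreaks on uncorrelated networks.
#'
#' @param graph An undirected [igraph::graph] with at least one edge.
#' @return A single number.
#' @examples
#' epidemic_threshold(toy_fixtures()$star5)  # 1.6 / 4 = 0.4
#' @export
epidemic_threshold <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    abort("epidemic threshold undefined for an edgeless graph")
  }
  k <- as.numeric(igraph::degree(graph))
  mean(k) / mean(k^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
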
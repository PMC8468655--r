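#' Degree, closeness and betweenness score tables
#'
#' Classical centralities as tidy score tables. Closeness of node `u` is
#' `1 / sum of distances` from `u`; on disconnected graphs the sum runs over
#' `u`'s component only, and a singleton component scores 0 by convention.
#' Betweenness uses the unordered-pair convention ([igraph::betweenness()]);
#' the ordered-pair variant differs only by a global factor 2 and cannot
#' change a ranking.
#'
#' @param graph An undirected [igraph::graph].
#' @return A tibble with columns `node`, `score`.
#' @name classic_scores
NULL

#' @rdname classic_scores
#' @export
degree_scores <- function(graph) {
  d <- node_degrees(graph)
  tibble::tibble(node = d$node, score = d$degree)
}

#' @rdname classic_scores
#' @export
closeness_scores <- function(graph) {
  cc <- suppressWarnings(igraph::closeness(graph, mode = "all"))
  cc[!is.finite(cc)] <- 0  # singleton components
  tibble::tibble(node = node_names(graph), score = as.numeric(cc))
}

#' @rdname classic_scores
#' @export
betweenness_scores <- function(graph) {
  b <- igraph::betweenness(graph, directed = FALSE)
  tibble::tibble(node = node_names(graph), score = as.numeric(b))
}

#' VoteRank seed selection
#'
#' Iterative voting: every node starts with voting ability 1; a node's
#' voting score is the summed ability of its not-yet-selected neighbours.
#' Each round the highest-scoring unselected node is picked (ties by node
#' identifier), its ability is set to 0 and it never votes again, and each
#' of its neighbours loses `f = 1/<k>` of its voting ability (clamped at 0),
#' where `<k>` is the mean degree.
#'
#' @param graph An undirected [igraph::graph].
#' @param p_total Number of spreaders to select.
#' @return A spreader tibble with columns `node`, `score` (voting score at
#'   selection time), `rank`.
#' @export
voterank_select <- function(graph, p_total) {
  n <- igraph::vcount(graph)
  p_total <- as.integer(p_total)
  stopifnot(p_total >= 1, p_total <= n)
  nodes <- node_names(graph)
  adj <- adjacency_index(graph)
  kbar <- mean_degree(graph)
  f <- if (kbar > 0) 1 / kbar else 0
  va <- rep(1, n)
  selected <- logical(n)
  picks <- integer(p_total)
  scores <- numeric(p_total)
  for (r in seq_len(p_total)) {
    vs <- vapply(seq_len(n), function(i) {
      if (selected[i]) return(-Inf)
      nb <- adj[[i]]
      nb <- nb[!selected[nb]]
      if (length(nb) == 0) 0 else sum(va[nb])
    }, numeric(1))
    cand <- which(!selected)
    best <- cand[order(-vs[cand], nodes[cand])][1]
    picks[r] <- best
    scores[r] <- vs[best]
    selected[best] <- TRUE
    va[best] <- 0
    nb <- adj[[best]]
    va[nb] <- pmax(0, va[nb] - f)
  }
  tibble::tibble(node = nodes[picks], score = scores,
                 rank = seq_len(p_total))
}

#' HybridRank seed selection
#'
#' Scores each node by `HC = ICC * EC`, the product of the improved coreness
#' centrality (sum of the k-shell indices of the node's neighbours) and the
#' eigenvector centrality (principal-eigenvector, max-normalised). Seeds are
#' taken greedily from the HC-descending list, removing each pick's
#' neighbours from the list to avoid adjacent seeds; if the list empties
#' before `p_total` picks, selection falls back to the highest-HC remaining
#' nodes regardless of adjacency.
#'
#' @inheritParams voterank_select
#' @return A spreader tibble (`node`, `score` = HC, `rank`).
#' @export
hybridrank_select <- function(graph, p_total) {
  n <- igraph::vcount(graph)
  p_total <- as.integer(p_total)
  stopifnot(p_total >= 1, p_total <= n)
  hc <- hybrid_centrality(graph)
  nodes <- hc$node
  adj <- adjacency_index(graph)
  ord <- order(-hc$score, nodes)
  in_list <- rep(TRUE, n)
  selected <- logical(n)
  picks <- integer(0)
  for (i in ord) {
    if (length(picks) == p_total) break
    if (!in_list[i]) next
    picks <- c(picks, i)
    selected[i] <- TRUE
    in_list[i] <- FALSE
    in_list[adj[[i]]] <- FALSE
  }
  if (length(picks) < p_total) {
    rest <- ord[!selected[ord]]
    picks <- c(picks, rest[seq_len(p_total - length(picks))])
  }
  tibble::tibble(node = nodes[picks], score = hc$score[picks],
                 rank = seq_along(picks))
}

#' @rdname hybridrank_select
#' @return `hybrid_centrality()`: a tibble `node`, `icc`, `ec`, `score`.
#' @export
hybrid_centrality <- function(graph) {
  ks <- kshell_index(graph)$ks
  adj <- adjacency_index(graph)
  icc <- unname(vapply(adj, function(nb) sum(ks[nb]), numeric(1)))
  ec <- eigenvector_centrality(graph)
  tibble::tibble(node = node_names(graph), icc = icc, ec = ec,
                 score = icc * ec)
}

# Principal-eigenvector centrality by power iteration on (A + I) (same
# eigenvector as A, but convergent on bipartite components), max-normalised
# per connected component, tolerance 1e-10.
eigenvector_centrality <- function(graph, tol = 1e-10, max_iter = 10000L) {
  n <- igraph::vcount(graph)
  comp <- igraph::components(graph)$membership
  adj <- adjacency_index(graph)
  ec <- numeric(n)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) {
      ec[idx] <- 1
      next
    }
    pos <- match(seq_len(n), idx)  # n -> position within component
    x <- rep(1, length(idx))
    for (it in seq_len(max_iter)) {
      xn <- vapply(seq_along(idx), function(j) {
        nb <- adj[[idx[j]]]
        x[j] + sum(x[pos[nb]])
      }, numeric(1))
      xn <- xn / max(xn)
      if (max(abs(xn - x)) < tol) {
        x <- xn
        break
      }
      x <- xn
    }
    ec[idx] <- x
  }
  ec
}

#' Indirect spreading strength (SC) scores
#'
#' Edge spreading strength for an edge `(i, j)`:
#' \deqn{c_{ij} = (1 + k_j^{out}) (1 + |D_{ij,2}|)^{2\alpha},}
#' where \eqn{k_j^{out}} counts the edges from `j` to nodes outside
#' \eqn{\delta_i \cup \{i\}} (the closed neighbourhood of `i`) and
#' \eqn{D_{ij,2}} is the set of length-2 paths from `i` to `j` (common
#' neighbours). The node score is \eqn{SC_i = \sum_{j \in \delta_i} c_{ij}}.
#' `alpha` tunes the weight of the indirect (2-path) term.
#'
#' @param graph An undirected [igraph::graph].
#' @param alpha Positive tuning exponent (default 1).
#' @return A tibble with columns `node`, `score`.
#' @export
sc_scores <- function(graph, alpha = 1) {
  stopifnot(alpha > 0)
  adj <- adjacency_index(graph)
  n <- igraph::vcount(graph)
  score <- vapply(seq_len(n), function(i) {
    nbi <- adj[[i]]
    if (length(nbi) == 0) return(0)
    closed_i <- c(i, nbi)
    sum(vapply(nbi, function(j) {
      nbj <- adj[[j]]
      k_out <- sum(!(nbj %in% closed_i))
      d2 <- sum(nbj %in% nbi)  # common neighbours = length-2 i..j paths
      (1 + k_out) * (1 + d2)^(2 * alpha)
    }, numeric(1)))
  }, numeric(1))
  tibble::tibble(node = node_names(graph), score = score)
}

#' Node information entropy
#'
#' \deqn{e_i = -\sum_{j \in \delta_i} \frac{k_j}{\sum_h k_h}
#'        \ln \frac{k_j}{\sum_h k_h},}
#' with the normalising sum taken over all nodes of the graph. Nodes with no
#' neighbours (or an edgeless graph) score 0.
#'
#' @param graph An undirected [igraph::graph].
#' @return A tibble with columns `node`, `score`.
#' @export
entropy_scores <- function(graph) {
  deg <- as.numeric(igraph::degree(graph))
  total <- sum(deg)
  adj <- adjacency_index(graph)
  score <- unname(vapply(adj, function(nb) {
    if (length(nb) == 0 || total == 0) return(0)
    p <- deg[nb] / total
    -sum(p * log(p))
  }, numeric(1)))
  tibble::tibble(node = node_names(graph), score = score)
}

#' Improved k-shell (IKS) seed selection
#'
#' Nodes are grouped by k-shell and sorted within each shell by information
#' entropy (descending, ties by node identifier). Selection cycles the
#' shells from the highest to the lowest, taking the current top node of
#' each non-exhausted shell, and repeats the sweep until `p_total` nodes are
#' selected. With `p_total = n` every node is selected exactly once.
#'
#' @inheritParams voterank_select
#' @return A spreader tibble (`node`, `score` = entropy, `ks`, `rank`).
#' @export
iks_select <- function(graph, p_total) {
  n <- igraph::vcount(graph)
  p_total <- as.integer(p_total)
  stopifnot(p_total >= 1, p_total <= n)
  tab <- kshell_index(graph) |>
    dplyr::inner_join(entropy_scores(graph), by = "node") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$node)
  shells <- sort(unique(tab$ks), decreasing = TRUE)
  queues <- lapply(shells, function(s) which(tab$ks == s))
  picks <- integer(0)
  ptr <- rep(1L, length(queues))
  while (length(picks) < p_total) {
    for (q in seq_along(queues)) {
      if (length(picks) == p_total) break
      if (ptr[q] > length(queues[[q]])) next  # shell exhausted: skip
      picks <- c(picks, queues[[q]][ptr[q]])
      ptr[q] <- ptr[q] + 1L
    }
  }
  tibble::tibble(node = tab$node[picks], score = tab$score[picks],
                 ks = tab$ks[picks], rank = seq_along(picks))
}

#' True spreading ability (TSA) scores
#'
#' Scores each node by its mean final spreading scope when used as the sole
#' seed of the SIR contact process, estimated over `config$runs` replicates.
#' This is the simulation-based "ideal" ranking; it is expensive (one SIR
#' ensemble per node) and intended for small graphs.
#'
#' @param graph An undirected [igraph::graph].
#' @param config An [sir_config()].
#' @return A tibble with columns `node`, `score`.
#' @export
tsa_scores <- function(graph, config) {
  nodes <- node_names(graph)
  score <- vapply(seq_along(nodes), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    fss_mean(graph, nodes[i], cfg)$fss_mean
  }, numeric(1))
  tibble::tibble(node = nodes, score = score)
}

# Internal: adjacency as a list of integer neighbour indices.
adjacency_index <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

#' Score or select nodes with a named ranking method
#'
#' A single dispatcher over all ranking strategies, used by the experiment
#' harness and the command-line interface. Score-type metrics (`"gksw"`,
#' `"deg"`, `"clo"`, `"bet"`, `"sc"`, `"tsa"`) return a full score table and
#' select the global top `p_total` (ties by node identifier); iterative
#' metrics (`"vr"`, `"hc"`, `"iks"`) run their own sequential selection.
#'
#' @param graph An undirected [igraph::graph].
#' @param metric One of `"gksw"`, `"deg"`, `"clo"`, `"bet"`, `"vr"`, `"hc"`,
#'   `"sc"`, `"iks"`, `"tsa"`.
#' @param radius Gravity radius (for `"gksw"`).
#' @param alpha SC tuning exponent.
#' @param sir An [sir_config()] (required for `"tsa"`).
#' @return `rank_nodes()`: a score tibble (`node`, `score`).
#' @export
rank_nodes <- function(graph, metric, radius = 3L, alpha = 1, sir = NULL) {
  switch(metric,
    gksw = gksw_scores(graph, radius = radius)[, c("node", "score")],
    deg = degree_scores(graph),
    clo = closeness_scores(graph),
    bet = betweenness_scores(graph),
    sc = sc_scores(graph, alpha = alpha),
    tsa = {
      if (is.null(sir)) abort("tsa ranking needs an sir_config")
      tsa_scores(graph, sir)
    },
    abort(paste0("not a score-type metric: ", metric))
  )
}

#' @rdname rank_nodes
#' @param p_total Number of nodes to select.
#' @return `select_top_nodes()`: a spreader tibble (`node`, `score`, `rank`).
#' @export
select_top_nodes <- function(graph, metric, p_total, radius = 3L, alpha = 1,
                             sir = NULL) {
  p_total <- as.integer(p_total)
  if (metric %in% c("vr", "hc", "iks")) {
    out <- switch(metric,
      vr = voterank_select(graph, p_total),
      hc = hybridrank_select(graph, p_total),
      iks = iks_select(graph, p_total)
    )
    return(out[, c("node", "score", "rank")])
  }
  scores <- rank_nodes(graph, metric, radius = radius, alpha = alpha,
                       sir = sir)
  scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$node) |>
    dplyr::slice_head(n = p_total) |>
    dplyr::mutate(rank = dplyr::row_number())
}
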
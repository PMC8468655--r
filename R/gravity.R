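#' k-shell (coreness) decomposition
#'
#' Shell indices from iterative degree pruning (the Batagelj–Zaversnik
#' algorithm, via [igraph::coreness()]). Isolated nodes get shell 0.
#'
#' @param graph An undirected [igraph::graph].
#' @return A tibble with columns `node` and `ks` (non-negative integer).
#' @examples
#' kshell_index(toy_fixtures()$k4_pendant)
#' @export
kshell_index <- function(graph) {
  tibble::tibble(
    node = node_names(graph),
    ks = as.integer(igraph::coreness(graph))
  )
}

#' Hop-bounded neighbourhood of a node
#'
#' Breadth-first distances from `node` to every other node within `radius`
#' hops; the node itself is excluded.
#'
#' @param graph An undirected [igraph::graph].
#' @param node A node identifier present in the graph.
#' @param radius Positive integer hop limit.
#' @return A tibble with columns `node` and `dist` (1 ... radius).
#' @export
neighborhood_within <- function(graph, node, radius = 3L) {
  stopifnot(radius >= 1)
  node <- check_nodes(graph, node)
  d <- igraph::distances(graph, v = node, algorithm = "unweighted")[1, ]
  keep <- is.finite(d) & d > 0 & d <= radius
  tibble::tibble(node = names(d)[keep], dist = as.numeric(d[keep]))
}

#' Gravity k-shell scores (the PBSI ranking metric)
#'
#' Scores each node `v` by
#' \deqn{GKSW(v) = \sum_{w \in \psi_r(v)} \frac{ks(v)\, ks(w)}{d_{vw}^2},}
#' where \eqn{\psi_r(v)} is the set of nodes within `radius` hops of `v`
#' (excluding `v` itself), `ks` is the k-shell index playing the role of
#' mass, and \eqn{d_{vw}} is the hop distance. Nodes beyond the radius
#' contribute nothing. Scores are computed globally, ignoring any community
#' structure; isolated nodes (empty neighbourhood or shell 0) score 0.
#'
#' @param graph An undirected [igraph::graph].
#' @param radius Positive integer hop limit (default 3).
#' @return A tibble with columns `node`, `ks`, `score`.
#' @examples
#' gksw_scores(toy_fixtures()$star5)
#' @export
gksw_scores <- function(graph, radius = 3L) {
  stopifnot(radius >= 1)
  ks_tbl <- kshell_index(graph)
  ks <- setNames(ks_tbl$ks, ks_tbl$node)
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(tibble::tibble(node = character(0), ks = integer(0),
                          score = numeric(0)))
  }
  d <- igraph::distances(graph, algorithm = "unweighted")
  score <- vapply(seq_len(n), function(i) {
    di <- d[i, ]
    keep <- is.finite(di) & di > 0 & di <= radius
    if (!any(keep)) return(0)
    sum(ks[i] * ks[keep] / di[keep]^2)
  }, numeric(1))
  tibble::tibble(node = ks_tbl$node, ks = ks_tbl$ks, score = score)
}
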
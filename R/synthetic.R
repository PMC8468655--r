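#' Planted-partition random graph with known community structure
#'
#' Stochastic block model with constant intra-block probability `p_in` and
#' inter-block probability `p_out` (via [igraph::sample_sbm()]), plus the
#' planted membership labels. With `p_in >> p_out` the planted blocks are
#' the ground-truth communities every pipeline stage can be checked
#' against.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_in,p_out Edge probabilities, `0 <= p_out <= p_in <= 1`; `p_in`
#'   may be a vector (one intra-block probability per block) to make some
#'   blocks denser than others.
#' @param seed RNG seed; a fixed seed gives a byte-identical graph.
#' @return A list with `graph` (nodes named `v001`, `v002`, ...) and
#'   `membership` (tibble `node`, `community` with labels `b1`, `b2`, ...).
#' @export
planted_partition <- function(block_sizes, p_in, p_out, seed = 1L) {
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in)
  n <- sum(block_sizes)
  k <- length(block_sizes)
  pref <- matrix(p_out, k, k)
  diag(pref) <- p_in
  g <- withr::with_seed(seed,
    igraph::sample_sbm(n, pref.matrix = pref, block.sizes = block_sizes))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  membership <- tibble::tibble(
    node = igraph::V(g)$name,
    community = paste0("b", rep(seq_len(k), block_sizes))
  )
  list(graph = g, membership = membership)
}

#' Preferential-attachment (scale-free) random graph
#'
#' Standard growth model ([igraph::sample_pa()]): nodes arrive one at a
#' time and attach `m_attach` edges preferentially to high-degree nodes.
#' The result is connected, simple, and heavy-tailed in degree — a fixture
#' for k-shell and epidemic-threshold behaviour.
#'
#' @param n Number of nodes (`n > m_attach`).
#' @param m_attach Edges added per new node.
#' @param seed RNG seed.
#' @return An undirected simple [igraph::graph] with named nodes.
#' @export
preferential_attachment <- function(n, m_attach = 1L, seed = 1L) {
  stopifnot(n > m_attach, m_attach >= 1)
  g <- withr::with_seed(seed,
    igraph::sample_pa(n, m = m_attach, directed = FALSE))
  igraph::V(g)$name <- sprintf("v%03d", seq_len(n))
  g
}

#' Deterministic toy graph collection
#'
#' Small hand-analysable graphs used throughout the tests and examples:
#' complete graphs `k2` ... `k5`, paths `path3`/`path4`/`path5` (nodes
#' `a`, `b`, ...), the 4-cycle `c4`, the star `star5` (center `a`, four
#' leaves), `k4_pendant` (K4 plus a pendant on one clique node),
#' `two_cliques_bridge` (two K5s joined by a single bridge edge), and
#' `two_triangles` (two disjoint K3s).
#'
#' @return A named list of [igraph::graph] objects.
#' @export
toy_fixtures <- function() {
  path_graph <- function(k) {
    graph_from_edges(letters[seq_len(k - 1)], letters[seq_len(k - 1) + 1])
  }
  complete <- function(k, labels = letters[seq_len(k)]) {
    idx <- utils::combn(k, 2)
    graph_from_edges(labels[idx[1, ]], labels[idx[2, ]])
  }
  star <- function(k) {  # center "a" plus k - 1 leaves
    graph_from_edges(rep("a", k - 1), letters[seq_len(k - 1) + 1])
  }
  k4p <- igraph::add_edges(
    igraph::add_vertices(complete(4), 1, name = "e"),
    c("a", "e"))
  bridge <- igraph::add_edges(
    igraph::disjoint_union(complete(5, paste0("l", 1:5)),
                           complete(5, paste0("r", 1:5))),
    c("l1", "r1"))
  list(
    k2 = complete(2), k3 = complete(3), k4 = complete(4), k5 = complete(5),
    path3 = path_graph(3), path4 = path_graph(4), path5 = path_graph(5),
    c4 = graph_from_edges(c("a", "b", "c", "d"), c("b", "c", "d", "a")),
    star5 = star(5),
    k4_pendant = k4p,
    two_cliques_bridge = bridge,
    two_triangles = igraph::disjoint_union(complete(3, paste0("x", 1:3)),
                                           complete(3, paste0("y", 1:3)))
  )
}
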
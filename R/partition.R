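#' Detect communities with multi-level modularity optimisation (Louvain)
#'
#' Thin, seeded wrapper around [igraph::cluster_louvain()]. For a fixed seed
#' the partition is deterministic; a ground-truth membership file (see
#' [read_membership()] and [partition_from_membership()]) always overrides
#' detection in the higher-level pipelines, so downstream results do not
#' depend on community-detection drift.
#'
#' @param graph An undirected [igraph::graph].
#' @param seed Integer RNG seed.
#' @param resolution Modularity resolution parameter (default 1).
#' @return A membership tibble with columns `node` and `community`
#'   (community labels are arbitrary opaque strings).
#' @export
detect_communities <- function(graph, seed = 1L, resolution = 1) {
  if (igraph::vcount(graph) == 0) abort("cannot partition an empty graph")
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(graph, resolution = resolution))
  tibble::tibble(
    node = node_names(graph),
    community = as.character(igraph::membership(cl))
  )
}

#' Build a partition from a membership table
#'
#' Validates that every node of the graph carries exactly one community
#' label. Nodes present in the membership but absent from the graph are
#' allowed (isolated nodes entering via the membership file are retained
#' upstream); nodes of the graph missing from the membership are an error.
#'
#' @param graph An undirected [igraph::graph].
#' @param membership A tibble with columns `node`, `community`.
#' @return A membership tibble restricted to the graph's nodes, in the
#'   graph's node order.
#' @export
partition_from_membership <- function(graph, membership) {
  nodes <- node_names(graph)
  membership <- dplyr::mutate(membership,
                              node = as.character(.data$node),
                              community = as.character(.data$community))
  missing <- setdiff(nodes, membership$node)
  if (length(missing) > 0) {
    abort(paste0("graph node(s) missing from membership: ",
                 paste(missing, collapse = ", ")))
  }
  dplyr::left_join(tibble::tibble(node = nodes), membership, by = "node")
}

#' Community sizes in a canonical order
#'
#' Summarises a membership tibble into one row per community with its size
#' and smallest member identifier, sorted by size (stable). Ties in size are
#' broken by the lexicographically smallest member identifier, the package's
#' universal tie rule.
#'
#' @param membership A tibble with columns `node`, `community`.
#' @param order `"ascending"` (smallest community first, the allocation
#'   order) or `"descending"`.
#' @return A tibble with columns `community`, `size`, `min_member`, ordered.
#' @export
community_sizes <- function(membership, order = c("ascending", "descending")) {
  order <- match.arg(order)
  sizes <- membership |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(size = dplyr::n(),
                     min_member = min(.data$node), .groups = "drop")
  if (order == "ascending") {
    dplyr::arrange(sizes, .data$size, .data$min_member)
  } else {
    dplyr::arrange(sizes, dplyr::desc(.data$size), .data$min_member)
  }
}

#' @rdname community_sizes
#' @export
sort_communities <- community_sizes

#' Suggested number of spreaders for a partitioned graph
#'
#' The number of communities is a natural starting point for the number of
#' seeds: picking the best spreader of each community already covers the
#' whole graph.
#'
#' @param membership A tibble with columns `node`, `community`.
#' @return Integer, the number of distinct communities.
#' @export
suggest_num_spreaders <- function(membership) {
  length(unique(membership$community))
}
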
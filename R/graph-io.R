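#' Read an undirected simple graph from an edge-list file
#'
#' Parses a whitespace- or tab-delimited edge list (one edge per line,
#' `#`-prefixed comment lines ignored). The graph is treated as undirected
#' and unweighted: self-loops are dropped, duplicate edges (in either
#' orientation) are collapsed, and any extra columns (e.g. weights) are
#' ignored with a warning. Node identifiers are kept as opaque strings in
#' order of first appearance, which makes iteration order deterministic.
#'
#' @param path Path to the edge-list file.
#' @param delimiter Optional single-character delimiter; by default any run
#'   of whitespace separates the two endpoint columns.
#' @return An undirected simple [igraph::graph] with a `name` vertex
#'   attribute.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# toy", "a b", "b c"), tf)
#' g <- read_edgelist(tf)
#' igraph::vcount(g)
#' @export
read_edgelist <- function(path, delimiter = NULL) {
  if (!file.exists(path)) {
    abort(paste0("edge-list file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    abort(paste0("edge-list file is empty (no edge lines): ", path))
  }
  split_one <- function(line) {
    if (is.null(delimiter)) {
      strsplit(trimws(line), "\\s+")[[1]]
    } else {
      strsplit(trimws(line), delimiter, fixed = TRUE)[[1]]
    }
  }
  tokens <- lapply(lines[idx], split_one)
  nt <- lengths(tokens)
  if (any(nt < 2)) {
    bad <- idx[which(nt < 2)[1]]
    abort(paste0("malformed edge line ", bad, " in ", path,
                 ": need at least two tokens"))
  }
  if (any(nt > 2)) {
    warn(paste0("extra columns in ", path,
                " ignored (graph treated as unweighted)"))
  }
  from <- vapply(tokens, `[[`, character(1), 1L)
  to <- vapply(tokens, `[[`, character(1), 2L)
  graph_from_edges(from, to)
}

# Build an undirected simple named graph preserving first-appearance order.
graph_from_edges <- function(from, to, extra_nodes = character(0)) {
  nodes <- unique(c(rbind(from, to), extra_nodes))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a graph as a two-column edge list
#'
#' @param graph An undirected [igraph::graph].
#' @param path Output file path.
#' @param delimiter Column separator (default tab).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path, delimiter = "\t") {
  el <- igraph::as_edgelist(graph, names = TRUE)
  writeLines(paste(el[, 1], el[, 2], sep = delimiter), path)
  invisible(path)
}

#' Read a node-to-community membership table
#'
#' Two-column (node, community label) whitespace/tab-delimited file with
#' optional `#` comments. Listing a node twice with conflicting labels is an
#' error; repeated consistent lines are collapsed.
#'
#' @param path Path to the membership file.
#' @return A tibble with columns `node` and `community` (both character).
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("membership file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(idx) == 0) {
    abort(paste0("membership file is empty: ", path))
  }
  tokens <- lapply(lines[idx], function(l) strsplit(trimws(l), "\\s+")[[1]])
  nt <- lengths(tokens)
  if (any(nt < 2)) {
    bad <- idx[which(nt < 2)[1]]
    abort(paste0("malformed membership line ", bad, " in ", path))
  }
  m <- tibble::tibble(
    node = vapply(tokens, `[[`, character(1), 1L),
    community = vapply(tokens, `[[`, character(1), 2L)
  )
  m <- dplyr::distinct(m)
  dup <- m$node[duplicated(m$node)]
  if (length(dup) > 0) {
    abort(paste0("node(s) listed with conflicting community labels: ",
                 paste(unique(dup), collapse = ", ")))
  }
  m
}

#' Write a membership table
#'
#' @param membership A tibble with columns `node` and `community`.
#' @param path Output file path.
#' @param delimiter Column separator (default tab).
#' @return `path`, invisibly.
#' @export
write_membership <- function(membership, path, delimiter = "\t") {
  writeLines(paste(membership$node, membership$community, sep = delimiter),
             path)
  invisible(path)
}

#' Node degrees
#'
#' @param graph An undirected [igraph::graph].
#' @return A tibble with columns `node` and `degree`.
#' @examples
#' g <- toy_fixtures()$star5
#' node_degrees(g)
#' @export
node_degrees <- function(graph) {
  tibble::tibble(
    node = igraph::V(graph)$name,
    degree = as.numeric(igraph::degree(graph))
  )
}

#' Mean degree of a graph, or from printed node/edge counts
#'
#' The mean degree of an undirected graph is `2m/n`. `mean_degree_from_counts()`
#' evaluates the same identity directly from node and edge counts, which is
#' useful when only a published summary of a network is available.
#'
#' @param graph An undirected [igraph::graph].
#' @return A single number, `2m/n`.
#' @export
mean_degree <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) abort("mean degree undefined for an empty graph")
  2 * igraph::ecount(graph) / n
}

#' @rdname mean_degree
#' @param n_nodes,n_edges Node and edge counts.
#' @export
mean_degree_from_counts <- function(n_nodes, n_edges) {
  stopifnot(n_nodes > 0, n_edges >= 0)
  2 * n_edges / n_nodes
}

# Internal: node names in deterministic (creation) order.
node_names <- function(graph) igraph::V(graph)$name

# Internal: check a node subset against the graph, return character vector.
check_nodes <- function(graph, nodes) {
  nodes <- as.character(nodes)
  missing <- setdiff(nodes, node_names(graph))
  if (length(missing) > 0) {
    abort(paste0("node(s) not in graph: ", paste(missing, collapse = ", ")))
  }
  nodes
}
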
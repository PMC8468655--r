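#' Distribute spreaders across communities proportionally to size
#'
#' Implements the community-proportional allocation rule. Communities are
#' processed from smallest to largest; with `Pr` spreaders still unallocated
#' and `n_u` nodes still unprocessed, the current community `c_u` receives
#' \deqn{p_{c_u} = \max\{1, \lfloor Pr \cdot |c_u| / n_u \rfloor\},}
#' after which `n_u` and `Pr` are decremented. Every community thus gets at
#' least one spreader, larger communities get proportionally more, and the
#' last (largest) community absorbs the remainder so that the counts sum
#' exactly to `p_total`.
#'
#' When `p_total` is smaller than the number of communities the rule cannot
#' cover every community; [allocate_few()] is dispatched instead, which gives
#' one spreader to each of the `p_total` largest communities.
#'
#' @param membership A tibble with columns `node`, `community`.
#' @param p_total Total number of spreaders to allocate (1 to the number of
#'   nodes).
#' @return A tibble with columns `community`, `size`, `n_spreaders`, in
#'   allocation (ascending size) order for the proportional branch and
#'   descending size order for the few-spreaders branch.
#' @examples
#' m <- tibble::tibble(node = letters[1:20],
#'                     community = rep(c("A", "B", "C"), c(3, 5, 12)))
#' allocate_spreaders(m, 5)
#' @export
allocate_spreaders <- function(membership, p_total) {
  p_total <- as.integer(p_total)
  n <- nrow(membership)
  if (p_total < 1) abort("p_total must be at least 1")
  if (p_total > n) {
    abort(paste0("cannot allocate ", p_total, " spreaders among ", n,
                 " nodes"))
  }
  sizes <- community_sizes(membership, order = "ascending")
  nc <- nrow(sizes)
  if (p_total < nc) {
    return(allocate_few(membership, p_total))
  }
  counts <- integer(nc)
  n_u <- n
  pr <- p_total
  for (u in seq_len(nc)) {
    s <- sizes$size[u]
    p <- max(1L, as.integer(floor(pr * s / n_u)))
    p <- min(p, s, pr)  # cap at community size; never allocate more than left
    counts[u] <- p
    n_u <- n_u - s
    pr <- pr - p
  }
  # Backward redistribution of any surplus left after capping (degenerate
  # near p_total == n); keeps the conservation invariant sum(p) == p_total.
  u <- nc
  while (pr > 0 && u >= 1) {
    spare <- sizes$size[u] - counts[u]
    add <- min(spare, pr)
    counts[u] <- counts[u] + add
    pr <- pr - add
    u <- u - 1
  }
  tibble::tibble(community = sizes$community, size = sizes$size,
                 n_spreaders = counts)
}

#' Allocate fewer spreaders than communities
#'
#' One spreader to each of the `p_total` largest communities (descending
#' size, ties by smallest member identifier); the rest get none.
#'
#' @inheritParams allocate_spreaders
#' @return Same shape as [allocate_spreaders()], descending size order.
#' @export
allocate_few <- function(membership, p_total) {
  p_total <- as.integer(p_total)
  sizes <- community_sizes(membership, order = "descending")
  nc <- nrow(sizes)
  if (p_total < 1 || p_total >= nc) {
    abort("allocate_few requires 1 <= p_total < number of communities")
  }
  tibble::tibble(community = sizes$community, size = sizes$size,
                 n_spreaders = rep(c(1L, 0L), c(p_total, nc - p_total)))
}

#' Select the top-ranked nodes of each community under an allocation plan
#'
#' Within each community nodes are sorted by score (descending, ties by node
#' identifier ascending) and the allocated number of top nodes is taken.
#'
#' @param membership A tibble with columns `node`, `community`.
#' @param scores A tibble with columns `node`, `score`.
#' @param plan An allocation plan from [allocate_spreaders()] or
#'   [allocate_few()].
#' @return A spreader-set tibble with columns `node`, `community`, `score`,
#'   `rank` (rank within community).
#' @export
select_spreaders <- function(membership, scores, plan) {
  short <- plan$n_spreaders > plan$size
  if (any(short)) {
    abort(paste0("allocation exceeds community size for: ",
                 paste(plan$community[short], collapse = ", ")))
  }
  scored <- membership |>
    dplyr::inner_join(scores[, c("node", "score")], by = "node") |>
    dplyr::inner_join(plan[, c("community", "n_spreaders")], by = "community")
  if (nrow(scored) < nrow(membership)) {
    abort("scores must cover every node of the partition")
  }
  out <- scored |>
    dplyr::arrange(dplyr::desc(.data$score), .data$node) |>
    dplyr::group_by(.data$community) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::filter(.data$rank <= .data$n_spreaders) |>
    dplyr::ungroup() |>
    dplyr::select("node", "community", "score", "rank")
  # present in the plan's community order, top ranks first
  ord <- match(out$community, plan$community)
  out[order(ord, out$rank), ]
}

#' End-to-end partition-based spreader identification
#'
#' The full pipeline: partition the graph (ground-truth membership if given,
#' otherwise seeded Louvain detection), rank all nodes with the gravity
#' k-shell score, allocate `p_total` spreaders across communities
#' proportionally to size, and pick the top-ranked nodes of each community.
#'
#' @param graph An undirected [igraph::graph].
#' @param p_total Number of spreaders; defaults to the number of communities.
#' @param membership Optional ground-truth membership tibble
#'   (`node`, `community`); overrides detection.
#' @param radius Hop limit of the gravity score (default 3).
#' @param seed Seed for community detection when `membership` is `NULL`.
#' @return A spreader-set tibble (`node`, `community`, `score`, `rank`).
#' @examples
#' gm <- planted_partition(c(10, 10), p_in = 0.8, p_out = 0.05, seed = 7)
#' pbsi_select(gm$graph, p_total = 2, membership = gm$membership)
#' @export
pbsi_select <- function(graph, p_total = NULL, membership = NULL,
                        radius = 3L, seed = 1L) {
  if (is.null(membership)) {
    membership <- detect_communities(graph, seed = seed)
  } else {
    membership <- partition_from_membership(graph, membership)
  }
  if (is.null(p_total)) p_total <- suggest_num_spreaders(membership)
  scores <- gksw_scores(graph, radius = radius)
  plan <- allocate_spreaders(membership, p_total)
  select_spreaders(membership, scores, plan)
}
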
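# Brute-force oracles, independent of the package's code paths: adjacency
# matrices, Floyd-Warshall distances, naive peeling, direct double loops.

# Erdos-Renyi graph with named nodes; caller controls the RNG seed.
random_graph <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(runif(length(up)) < p)
  a <- a + t(a)
  labels <- sprintf("n%02d", seq_len(n))
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = labels[idx[, 1]], to = labels[idx[, 2]]),
    directed = FALSE,
    vertices = data.frame(name = labels))
  g
}

adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# All-pairs shortest-path hop distances by Floyd-Warshall.
fw_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# k-shell index by naive repeated peeling.
oracle_kshell <- function(a) {
  n <- nrow(a)
  deg <- rowSums(a)
  alive <- rep(TRUE, n)
  ks <- integer(n)
  s <- 0L
  while (any(alive)) {
    repeat {
      victims <- which(alive & deg <= s)
      if (length(victims) == 0) break
      ks[victims] <- s
      alive[victims] <- FALSE
      deg <- deg - rowSums(a[, victims, drop = FALSE])
    }
    s <- s + 1L
  }
  ks
}

# Gravity k-shell score by a direct double loop over the distance matrix.
oracle_gksw <- function(a, radius = 3) {
  ks <- oracle_kshell(a)
  d <- fw_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(v) {
    s <- 0
    for (w in seq_len(n)) {
      if (w != v && is.finite(d[v, w]) && d[v, w] <= radius) {
        s <- s + ks[v] * ks[w] / d[v, w]^2
      }
    }
    s
  }, numeric(1))
}

# Closeness: 1 / sum of distances within the component; singleton -> 0.
oracle_closeness <- function(a) {
  d <- fw_distances(a)
  vapply(seq_len(nrow(a)), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) 0 else 1 / sum(dv)
  }, numeric(1))
}

# Shortest-path counts from every source, by dynamic programming over the
# distance matrix (independent of Brandes' algorithm).
path_counts <- function(a, d) {
  n <- nrow(a)
  np <- matrix(0, n, n)
  for (v in seq_len(n)) {
    np[v, v] <- 1
    ord <- order(d[v, ])
    for (w in ord) {
      if (w == v || !is.finite(d[v, w])) next
      pred <- which(a[w, ] > 0 & d[v, ] == d[v, w] - 1)
      np[v, w] <- sum(np[v, pred])
    }
  }
  np
}

# Betweenness, unordered-pair convention.
oracle_betweenness <- function(a) {
  d <- fw_distances(a)
  np <- path_counts(a, d)
  n <- nrow(a)
  bc <- numeric(n)
  for (v in seq_len(n - 1)) {
    for (w in seq((v + 1), n)) {
      if (!is.finite(d[v, w]) || np[v, w] == 0) next
      for (u in seq_len(n)) {
        if (u == v || u == w) next
        if (is.finite(d[v, u]) && is.finite(d[u, w]) &&
            d[v, u] + d[u, w] == d[v, w]) {
          bc[u] <- bc[u] + np[v, u] * np[u, w] / np[v, w]
        }
      }
    }
  }
  bc
}

# Mean pairwise distance among a node subset, disconnected pairs excluded.
oracle_ls <- function(a, idx) {
  d <- fw_distances(a)
  vals <- c()
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i < j) vals <- c(vals, d[idx[i], idx[j]])
    }
  }
  mean(vals[is.finite(vals)])
}

# Membership helper for toy graphs.
toy_membership <- function(g, labels) {
  tibble::tibble(node = igraph::V(g)$name, community = labels)
}
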
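toys <- toy_fixtures()

test_that("closeness matches hand sums and the component convention", {
  expect_equal(closeness_scores(toys$k2)$score, c(1, 1))
  p3 <- closeness_scores(toys$path3)
  expect_equal(setNames(p3$score, p3$node), c(a = 1 / 3, b = 1 / 2, c = 1 / 3))
  expect_equal(closeness_scores(toys$k5)$score, rep(1 / 4, 5))
  # disconnected: per-component sums, singleton scores 0
  g <- igraph::add_vertices(toys$k2, 1, name = "z")
  cs <- closeness_scores(g)
  expect_equal(setNames(cs$score, cs$node), c(a = 1, b = 1, z = 0))
})

test_that("betweenness matches pair-enumeration values", {
  expect_equal(betweenness_scores(toys$k3)$score, rep(0, 3))
  s <- betweenness_scores(toys$star5)
  expect_equal(s$score[s$node == "a"], 6)  # choose(4, 2) leaf pairs
  expect_equal(s$score[s$node != "a"], rep(0, 4))
  p4 <- betweenness_scores(toys$path4)
  expect_equal(setNames(p4$score, p4$node), c(a = 0, b = 2, c = 2, d = 0))
})

test_that("closeness and betweenness agree with oracles on random graphs", {
  set.seed(303)
  for (i in 1:25) {
    g <- random_graph(sample(4:8, 1), runif(1, 0.2, 0.6))
    a <- adj_matrix(g)
    expect_equal(closeness_scores(g)$score, oracle_closeness(a))
    expect_equal(betweenness_scores(g)$score, oracle_betweenness(a))
  }
})

test_that("voterank selects by voting score with ability weakening", {
  star4 <- graph_from_edges(rep("a", 3), c("b", "c", "d"))
  expect_equal(voterank_select(star4, 1)$node, "a")        # vs 3 beats 1
  expect_equal(voterank_select(star4, 2)$node, c("a", "b"))  # tie -> id order
  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("u", "v", "w")
  expect_equal(voterank_select(edgeless, 2)$node, c("u", "v"))
})

test_that("voting abilities stay in [0, 1] and totals never increase", {
  set.seed(8)
  g <- random_graph(20, 0.2)
  # instrumented re-run of the voting rounds
  adj <- lapply(igraph::as_adj_list(g), as.integer)
  f <- 1 / mean(igraph::degree(g))
  va <- rep(1, 20)
  sel <- voterank_select(g, 10)
  for (v in sel$node) {
    i <- match(v, igraph::V(g)$name)
    total_before <- sum(va)
    va[i] <- 0
    va[adj[[i]]] <- pmax(0, va[adj[[i]]] - f)
    expect_lte(sum(va), total_before)
    expect_true(all(va >= 0 & va <= 1))
  }
})

test_that("hybridrank avoids adjacent seeds and falls back when pruned out", {
  star4 <- graph_from_edges(rep("a", 3), c("b", "c", "d"))
  expect_equal(hybridrank_select(star4, 1)$node, "a")
  expect_equal(nrow(hybridrank_select(star4, 2)), 2)  # fallback pick
  two <- toys$two_triangles
  sel <- hybridrank_select(two, 2)
  expect_length(intersect(substr(sel$node, 1, 1), c("x", "y")), 2)
})

test_that("indirect spreading strength matches hand evaluation", {
  expect_equal(sc_scores(toys$k2)$score, c(1, 1))
  p3 <- sc_scores(toys$path3)
  expect_equal(setNames(p3$score, p3$node), c(a = 2, b = 2, c = 2))
  expect_equal(sc_scores(toys$k3)$score, rep(8, 3))
  # alpha only rescales the indirect factor
  expect_equal(sc_scores(toys$k3, alpha = 0.5)$score, rep(4, 3))
})

test_that("information entropy and IKS shell cycling behave as specified", {
  e <- entropy_scores(toys$c4)
  expect_equal(e$score, rep(log(2), 4))
  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("u", "v", "w")
  expect_equal(entropy_scores(edgeless)$score, rep(0, 3))
  # K4 + pendant: first pick from shell 3, second from shell 1
  sel <- iks_select(toys$k4_pendant, 2)
  expect_equal(sel$ks, c(3L, 1L))
  # P = n selects every node exactly once
  set.seed(99)
  g <- random_graph(12, 0.3)
  all_sel <- iks_select(g, 12)
  expect_setequal(all_sel$node, igraph::V(g)$name)
  expect_equal(nrow(all_sel), 12)
})

test_that("all select-type rankers return exactly p distinct nodes", {
  set.seed(55)
  g <- random_graph(14, 0.25)
  for (p in c(1, 5, 14)) {
    for (fn in list(voterank_select, hybridrank_select, iks_select)) {
      sel <- fn(g, p)
      expect_equal(nrow(sel), p)
      expect_false(any(duplicated(sel$node)))
    }
  }
})

test_that("true spreading ability reflects the contact process", {
  # beta = 0: no transmission, every node scores exactly 1
  cfg0 <- sir_config(beta = 0, runs = 5, seed = 1)
  expect_equal(tsa_scores(toys$k4, cfg0)$score, rep(1, 4))
  # star at beta = 1: center scores exactly 2 (one contact, then done);
  # a leaf scores 2 + 3/4 (center hits a susceptible leaf w.p. 3/4)
  cfg1 <- sir_config(beta = 1, runs = 3000, seed = 10)
  ts <- tsa_scores(toys$star5, cfg1)
  expect_equal(ts$score[ts$node == "a"], 2)
  leaf <- ts$score[ts$node == "b"]
  expect_lt(abs(leaf - 2.75), 3 * sqrt(0.75 * 0.25 / 3000))
})

test_that("rank/select dispatcher agrees with the individual rankers", {
  g <- toys$k4_pendant
  expect_equal(rank_nodes(g, "deg"), degree_scores(g))
  expect_equal(select_top_nodes(g, "vr", 2)$node,
               voterank_select(g, 2)$node)
  top <- select_top_nodes(g, "gksw", 2)
  s <- gksw_scores(g)
  expect_equal(top$node, s$node[order(-s$score, s$node)][1:2])
})
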
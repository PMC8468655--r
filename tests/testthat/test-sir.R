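toys <- toy_fixtures()

test_that("degenerate parameter settings give exact outcomes", {
  # beta = 0: nobody else is ever infected; with mu = 1 it ends in one step
  r <- sir_run(toys$k5, c("a", "b"), sir_config(beta = 0), seed = 4)
  expect_equal(r$fss, 2)
  expect_equal(r$steps, 1)
  # isolated seed: no neighbours to contact
  lone <- igraph::add_vertices(toys$k2, 1, name = "z")
  expect_equal(sir_run(lone, "z", sir_config(beta = 1), seed = 2)$fss, 1)
  # path centre at beta = 1, mu = 1: exactly one neighbour infected, which
  # then only faces the recovered centre -> fss = 2 in every run
  for (s in 1:25) {
    expect_equal(sir_run(toys$path3, "b", sir_config(beta = 1),
                         seed = s)$fss, 2)
  }
  expect_error(sir_run(toys$k2, character(0), sir_config(beta = 0.5)),
               "non-empty")
  expect_error(sir_run(toys$k2, "nope", sir_config(beta = 0.5)),
               "not in graph")
})

test_that("compartments are conserved and states move one way only", {
  set.seed(66)
  g <- preferential_attachment(40, 2, seed = 12)
  r <- sir_run(g, c("v001", "v010"), sir_config(beta = 0.4, mu = 0.5),
               seed = 77)
  traj <- tidy(r)
  n <- igraph::vcount(g)
  expect_true(all(traj$n_s + traj$n_i + traj$n_r == n))
  expect_true(all(diff(traj$n_r) >= 0))
  expect_true(all(diff(traj$n_s) <= 0))
  # fss identity: seeds + total newly infected = recovered at termination
  expect_equal(r$fss, r$n_seeds + sum(traj$new_infected))
  expect_equal(r$fss, traj$n_r[nrow(traj)])
  expect_equal(traj$ss, r$n_seeds + traj$new_infected)
  # mu = 1: infectious for exactly one step -> I(t) == newly infected
  r1 <- sir_run(g, "v001", sir_config(beta = 0.4, mu = 1), seed = 5)
  t1 <- tidy(r1)
  expect_true(all(t1$n_i == t1$new_infected))
})

test_that("ensemble means match analytic values on tiny graphs", {
  # K2 single seed: E[FSS] = 1 + beta
  est <- fss_mean(toys$k2, "a", sir_config(beta = 0.5, runs = 4000,
                                           seed = 13))
  expect_lt(abs(est$fss_mean - 1.5), 3 * est$fss_se)
  # beta = 0: mean exactly the seed count, zero variance
  est0 <- fss_mean(toys$k4, c("a", "c"), sir_config(beta = 0, runs = 50,
                                                    seed = 2))
  expect_equal(est0$fss_mean, 2)
  expect_equal(est0$fss_se, 0)
  # K3 at beta = 1, mu = 1: enumeration of the contact choices gives
  # FSS = 3 w.p. 1/2 (second node contacts the susceptible third) else 2
  est3 <- fss_mean(toys$k3, "a", sir_config(beta = 1, runs = 4000,
                                            seed = 17))
  expect_lt(abs(est3$fss_mean - 2.5), 3 * est3$fss_se)
})

test_that("mean spreading scope increases with the transmission rate", {
  g <- preferential_attachment(50, 2, seed = 21)
  lo <- fss_mean(g, "v001", sir_config(beta = 0.1, runs = 1500, seed = 3))
  hi <- fss_mean(g, "v001", sir_config(beta = 0.9, runs = 1500, seed = 3))
  expect_gt(hi$fss_mean - 3 * hi$fss_se, lo$fss_mean + 3 * lo$fss_se)
})

test_that("the all-neighbours contact variant transmits to every contact", {
  toys2 <- toy_fixtures()
  # star centre at beta = 1: single-contact infects exactly one leaf,
  # the all-neighbours rule infects all four
  single <- sir_run(toys2$star5, "a", sir_config(beta = 1), seed = 4)
  all_nb <- sir_run(toys2$star5, "a",
                    sir_config(beta = 1, contact = "all"), seed = 4)
  expect_equal(single$fss, 2)
  expect_equal(all_nb$fss, 5)
  # K3 at beta = 1: everyone is reached deterministically
  expect_equal(sir_run(toys2$k3, "a", sir_config(beta = 1, contact = "all"),
                       seed = 1)$fss, 3)
  # beta = 0 still spreads nothing
  expect_equal(sir_run(toys2$k3, "a", sir_config(beta = 0, contact = "all"),
                       seed = 1)$fss, 1)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  g <- preferential_attachment(30, 2, seed = 14)
  a <- sir_run(g, "v003", sir_config(beta = 0.3), seed = 123)
  b <- sir_run(g, "v003", sir_config(beta = 0.3), seed = 123)
  expect_identical(tidy(a), tidy(b))
  m1 <- fss_mean(g, "v003", sir_config(beta = 0.3, runs = 50, seed = 9))
  m2 <- fss_mean(g, "v003", sir_config(beta = 0.3, runs = 50, seed = 9))
  expect_identical(m1, m2)
})

test_that("epidemic threshold equals the degree-moment ratio", {
  expect_equal(epidemic_threshold(toys$k2), 1)
  expect_equal(epidemic_threshold(toys$k5), 1 / 4)  # 4-regular
  expect_equal(epidemic_threshold(toys$c4), 1 / 2)  # 2-regular
  expect_equal(epidemic_threshold(toys$star5), 0.4)  # 1.6 / 4
  edgeless <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(edgeless)$name <- c("u", "v")
  expect_error(epidemic_threshold(edgeless), "edgeless")
})

test_that("sir results have tidy and glance methods", {
  r <- sir_run(toys$k3, "a", sir_config(beta = 0.5), seed = 1)
  expect_s3_class(tidy(r), "tbl_df")
  g <- glance(r)
  expect_equal(g$fss, r$fss)
  expect_equal(g$n_seeds, 1)
})
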
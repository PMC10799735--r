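test_that("assortativity hits its exact closed-form fixtures", {
  # two disjoint same-label edges: perfect assortment
  g1 <- labelled_graph(cbind(c("a", "c"), c("b", "d")),
                       c(a = 1L, b = 1L, c = 0L, d = 0L))
  expect_equal(nominal_assortativity(g1), 1)
  # star with ego labelled 1 and all alters 0: perfect disassortment
  g2 <- labelled_graph(cbind("hub", c("x", "y", "z")),
                       c(hub = 1L, x = 0L, y = 0L, z = 0L))
  expect_equal(nominal_assortativity(g2), -1)
  # path A-A-B-B: mixing matrix by hand gives tr(e) = 2/3, sum a^2 = 1/2
  g3 <- labelled_graph(cbind(c("1", "2", "3"), c("2", "3", "4")),
                       c("1" = 1L, "2" = 1L, "3" = 0L, "4" = 0L))
  expect_equal(nominal_assortativity(g3), 1 / 3)
  # single-label network: coefficient undefined
  g4 <- labelled_graph(cbind("a", "b"), c(a = 1L, b = 1L))
  expect_error(nominal_assortativity(g4), "ERR_SINGLE_LABEL")
})

test_that("coefficient agrees with igraph on random labelled graphs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    g <- igraph::sample_gnp(n, 0.4)
    while (igraph::ecount(g) < 2) g <- igraph::sample_gnp(n, 0.5)
    labels <- sample(0:1, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0L, 1L)
    igraph::V(g)$label_value <- labels
    igraph::V(g)$name <- paste0("v", seq_len(n))
    r_ours <- tryCatch(nominal_assortativity(g), error = function(e) NA)
    r_ig <- igraph::assortativity_nominal(g, types = labels + 1)
    if (!is.na(r_ours) && is.finite(r_ig)) {
      expect_equal(r_ours, r_ig, tolerance = 1e-12)
    }
  }
})

test_that("coefficient is invariant to label naming and edge order", {
  edges <- cbind(c("a", "b", "c", "a"), c("b", "c", "d", "d"))
  labs <- c(a = 1L, b = 0L, c = 1L, d = 0L)
  g <- labelled_graph(edges, labs)
  r1 <- nominal_assortativity(g)
  g_sw <- labelled_graph(edges, 1L - labs)           # swap 0 <-> 1
  expect_equal(nominal_assortativity(g_sw), r1)
  g_re <- labelled_graph(edges[c(3, 1, 4, 2), ], labs)  # reorder edges
  expect_equal(nominal_assortativity(g_re), r1)
})

test_that("permutation test is deterministic, one-sided and add-one", {
  g <- labelled_graph(cbind(c("a", "c", "a"), c("b", "d", "c")),
                      c(a = 1L, b = 1L, c = 0L, d = 0L))
  r1 <- permutation_test(g, n_perm = 200, seed = 5)
  r2 <- permutation_test(g, n_perm = 200, seed = 5)
  expect_identical(r1$null_draws, r2$null_draws)
  expect_identical(r1$p_value, r2$p_value)
  expect_length(r1$null_draws, 200)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_equal(r1$p_value,
               (1 + sum(r1$null_draws >= r1$r_obs)) / 201)
  expect_error(permutation_test(g, n_perm = 0), "n_perm")
})

test_that("perfectly assorted cliques give small permutation p", {
  # two 6-cliques, one all-1 and one all-0, joined by nothing; only 2 of
  # the choose(12, 6) label assignments reach r = 1
  ones <- t(utils::combn(paste0("a", 1:6), 2))
  zeros <- t(utils::combn(paste0("b", 1:6), 2))
  labs <- c(stats::setNames(rep(1L, 6), paste0("a", 1:6)),
            stats::setNames(rep(0L, 6), paste0("b", 1:6)))
  g <- labelled_graph(rbind(ones, zeros), labs)
  res <- permutation_test(g, n_perm = 999, seed = 2)
  expect_equal(res$r_obs, 1)
  expect_lte(res$p_value, 0.01)
})

test_that("sampled null matches exhaustive enumeration on a small graph", {
  edges <- cbind(c("a", "a", "b", "c", "e"), c("b", "c", "d", "e", "f"))
  labs <- c(a = 1L, b = 1L, c = 0L, d = 1L, e = 0L, f = 0L)
  g <- labelled_graph(edges, labs)
  r_obs <- nominal_assortativity(g)
  exact <- exhaustive_null(g)
  exact <- exact[!is.na(exact)]
  p_exact <- mean(exact >= r_obs)
  res <- permutation_test(g, n_perm = 20000, seed = 3)
  p_mc <- mean(res$null_draws >= r_obs)
  se <- sqrt(p_exact * (1 - p_exact) / res$n_perm)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1e-9)
  # the null mean carries the small negative bias of random labelling
  expect_equal(mean(res$null_draws), mean(exact),
               tolerance = 5 * stats::sd(exact) / sqrt(res$n_perm) + 0.01)
  expect_lt(mean(exact), 0)
})

test_that("null summary follows the boxplot convention", {
  res <- structure(list(null_draws = rep(0.2, 50)), class = "assortment_result")
  s <- null_summary(res)
  expect_true(all(abs(s - 0.2) < 1e-12))
  res2 <- structure(list(null_draws = (1:1000) / 1000),
                    class = "assortment_result")
  s2 <- null_summary(res2)
  expect_equal(unname(s2["median"]), 0.5005)
  # whiskers clamp at observed extremes
  expect_gte(unname(s2["whisker_low"]), unname(s2["min"]))
  expect_lte(unname(s2["whisker_high"]), unname(s2["max"]))
})
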
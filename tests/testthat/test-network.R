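test_that("quantile discretisation bins equal-frequency states", {
  mat <- matrix(1:9, nrow = 1, dimnames = list("g1", sprintf("s%d", 1:9)))
  dm <- discretise_quantile(mat, levels = 3)
  expect_equal(unname(dm$values[1, ]), rep(0:2, each = 3))

  flat <- matrix(5, nrow = 1, ncol = 6,
                 dimnames = list("gc", sprintf("s%d", 1:6)))
  expect_warning(dmc <- discretise_quantile(flat, 3), "constant")
  expect_true(all(dmc$values == 0L))

  withr::with_seed(71, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      x <- matrix(rnorm(n), nrow = 1, dimnames = list("g", seq_len(n)))
      d <- discretise_quantile(x, 3)
      occ <- tabulate(d$values + 1L, nbins = 3)
      expect_lte(max(occ) - min(occ), 1L)
    }
  })
})

test_that("BDeu family scores match the direct Gamma-formula oracle", {
  withr::with_seed(72, {
    for (i in 1:10) {
      g <- random_dag(4, edge_prob = 0.5, seed = i)
      tr <- ground_truth_cpds(g, strength = 0.7, seed = i)
      dm <- sample_discrete_dataset(tr, 120, seed = i)
      nd <- sample(g$nodes, 1)
      expect_equal(bde_family_score(nd, g$parents[[nd]], dm),
                   oracle_family_score(nd, g$parents[[nd]], dm),
                   tolerance = 1e-12)
    }
  })
  # parentless binary node with counts (1, 1), ess = 1
  d2 <- discrete_matrix(matrix(c(0L, 1L), nrow = 1,
                               dimnames = list("A", c("s1", "s2"))), 2L)
  direct <- lgamma(1) - lgamma(1 + 2) +
    (lgamma(0.5 + 1) - lgamma(0.5)) * 2
  expect_equal(bde_family_score("A", character(0), d2), direct)
  # zero-sample data scores zero for every family
  d0 <- discrete_matrix(matrix(integer(0), nrow = 2, ncol = 0,
                               dimnames = list(c("A", "B"), NULL)), 3L)
  expect_equal(bde_family_score("A", "B", d0), 0)
  expect_error(bde_family_score("A", rep("B", 11), d0), "max_parents")
})

test_that("a spurious parent loses to the empty family at large n", {
  wins <- 0L
  for (seed in 1:60) {
    dm <- withr::with_seed(seed, {
      discrete_matrix(matrix(sample(0:2, 2 * 2000, replace = TRUE), nrow = 2,
                             dimnames = list(c("A", "B"), NULL)), 3L)
    })
    wins <- wins + (bde_family_score("B", character(0), dm) >
                      bde_family_score("B", "A", dm))
  }
  expect_gte(wins, 57L)  # >= 95% of replicates
})

test_that("network score is decomposable and equal across Markov-equivalent DAGs", {
  withr::with_seed(73, {
    for (i in 1:15) {
      g <- random_dag(4, edge_prob = 0.5, seed = 200 + i)
      tr <- ground_truth_cpds(g, strength = 0.6, seed = 200 + i)
      dm <- sample_discrete_dataset(tr, 80, seed = 200 + i)
      total <- bde_network_score(g, dm)
      parts <- sum(vapply(g$nodes, function(nd)
        oracle_family_score(nd, g$parents[[nd]], dm), numeric(1)))
      expect_equal(total, parts, tolerance = 1e-10)
      cov <- find_covered_edge(g)
      if (!is.null(cov)) {
        g2 <- reverse_edge(g, cov[1], cov[2])
        expect_equal(bde_network_score(g2, dm), total, tolerance = 1e-8)
      }
    }
  })
  # two-node score equivalence, explicitly
  dm2 <- withr::with_seed(74, discrete_matrix(
    matrix(sample(0:2, 300, replace = TRUE), nrow = 2,
           dimnames = list(c("A", "B"), NULL)), 3L))
  s_ab <- bde_network_score(dag(c("A", "B"), list(B = "A")), dm2)
  s_ba <- bde_network_score(dag(c("A", "B"), list(A = "B")), dm2)
  expect_lt(abs(s_ab - s_ba), 1e-8)
})

test_that("the exhaustive oracle enumerates the known DAG counts", {
  base <- matrix(sample(0:1, 20, replace = TRUE), nrow = 2,
                 dimnames = list(c("A", "B"), NULL))
  expect_equal(exhaustive_search_oracle(discrete_matrix(base, 2L))$n_dags, 3)
  base3 <- rbind(base, C = sample(0:1, 10, replace = TRUE))
  expect_equal(exhaustive_search_oracle(discrete_matrix(base3, 2L))$n_dags, 25)
  base4 <- rbind(base3, D = sample(0:1, 10, replace = TRUE))
  expect_equal(exhaustive_search_oracle(discrete_matrix(base4, 2L))$n_dags, 543)
  base6 <- rbind(base4, E = 0L, F = 0L)
  expect_error(exhaustive_search_oracle(discrete_matrix(base6, 2L)),
               "more than 5")
})

test_that("independent two-node data leave the empty graph optimal", {
  empty_best <- 0L
  for (seed in 1:40) {
    dm <- withr::with_seed(1000 + seed, discrete_matrix(
      matrix(sample(0:2, 2 * 5000, replace = TRUE), nrow = 2,
             dimnames = list(c("A", "B"), NULL)), 3L))
    res <- exhaustive_search_oracle(dm)
    empty_best <- empty_best +
      (nrow(stmgrn:::dag_edges(res$dag)) == 0L)
  }
  expect_gte(empty_best, 38L)  # >= 95%
})

test_that("annealing recovers a strong chain and is deterministic by seed", {
  chain <- dag(c("A", "B", "C"), list(B = "A", C = "B"))
  tr <- ground_truth_cpds(chain, strength = 0.9, seed = 81)
  dm <- sample_discrete_dataset(tr, 2000, seed = 81)
  optimum <- exhaustive_search_oracle(dm)$score
  hits <- 0L
  for (seed in 1:20) {
    res <- sa_search(dm, seed = seed)
    hits <- hits + (res$score >= optimum - 1e-9)
  }
  expect_gte(hits, 18L)

  r1 <- sa_search(dm, seed = 7)
  r2 <- sa_search(dm, seed = 7)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$dag, r2$dag)
  expect_identical(r1$score, r2$score)
})

test_that("near-zero temperature behaves as greedy hill climbing", {
  g <- random_dag(5, edge_prob = 0.5, seed = 82)
  tr <- ground_truth_cpds(g, strength = 0.8, seed = 82)
  dm <- sample_discrete_dataset(tr, 300, seed = 82)
  cold <- annealing_schedule(t_initial = 1e-8, t_reanneal = 1e-9,
                             proposal_budget = 20000, max_restarts = 0L)
  res <- sa_search(dm, schedule = cold, seed = 3)
  # with no thermal acceptance the search converges to a local optimum:
  # no single-edge modification of the result improves the score
  base_score <- bde_network_score(res$dag, dm)
  expect_equal(base_score, res$score, tolerance = 1e-9)
  nodes <- res$dag$nodes
  for (u in nodes) {
    for (v in setdiff(nodes, u)) {
      parents <- res$dag$parents
      if (u %in% parents[[v]]) {
        del <- parents
        del[[v]] <- setdiff(del[[v]], u)
        expect_lte(bde_network_score(dag(nodes, del), dm), base_score + 1e-9)
        rev_p <- del
        rev_p[[u]] <- union(rev_p[[u]], v)
        g_rev <- tryCatch(dag(nodes, rev_p), error = function(e) NULL)
        if (!is.null(g_rev)) {
          expect_lte(bde_network_score(g_rev, dm), base_score + 1e-9)
        }
      } else {
        add <- parents
        add[[v]] <- union(add[[v]], u)
        g_add <- tryCatch(dag(nodes, add), error = function(e) NULL)
        if (!is.null(g_add)) {
          expect_lte(bde_network_score(g_add, dm), base_score + 1e-9)
        }
      }
    }
  }
  expect_error(annealing_schedule(proposal_budget = 0))
})

test_that("consensus edge frequencies respect the inclusive threshold", {
  nodes <- c("A", "B", "C")
  with_edge <- dag(nodes, list(B = "A"))
  without <- dag(nodes)
  # edge present in 14/50 runs (28%) is excluded, 15/50 (30%) included
  dags14 <- c(rep(list(with_edge), 14), rep(list(without), 36))
  dags15 <- c(rep(list(with_edge), 15), rep(list(without), 35))
  expect_equal(nrow(consensus_network(dags14, 0.30)$edges), 0L)
  net15 <- consensus_network(dags15, 0.30)
  expect_equal(net15$edges$frequency, 0.30)

  # 50 identical DAGs give frequency one on every edge
  same <- consensus_network(rep(list(dag(nodes, list(B = "A", C = "B"))), 50))
  expect_true(all(same$edges$frequency == 1))

  # input order does not matter
  shuffled <- consensus_network(rev(dags15), 0.30)
  expect_equal(shuffled$edges, net15$edges)

  expect_error(consensus_network(list(with_edge, dag(c("A", "B")))),
               "node sets")
})

test_that("mutual edges are flagged as feedback with combined frequency", {
  nodes <- c("A", "B")
  ab <- dag(nodes, list(B = "A"))
  ba <- dag(nodes, list(A = "B"))
  none <- dag(nodes)
  dags <- c(rep(list(ab), 20), rep(list(ba), 18), rep(list(none), 12))
  net <- consensus_network(dags, threshold = 0.30)
  expect_true(all(net$edges$feedback))
  expect_equal(nrow(net$feedback_pairs), 1L)
  expect_equal(net$feedback_pairs$combined_frequency, 38 / 50)
})

test_that("node order is breadth-first distance from the root", {
  star <- consensus_network(rep(list(
    dag(c("R", "a", "b", "c"), list(a = "R", b = "R", c = "R"))), 2))
  expect_equal(unname(annotate_order(star, "R")), c(0L, 1L, 1L, 1L))

  chain <- consensus_network(rep(list(
    dag(c("R", "a", "b", "c"), list(a = "R", b = "a", c = "b"))), 2))
  expect_equal(unname(annotate_order(chain, "R")), c(0L, 1L, 2L, 3L))

  lonely <- consensus_network(rep(list(
    dag(c("R", "a", "x"), list(a = "R"))), 2))
  ord <- annotate_order(lonely, "R")
  expect_true(is.na(ord[["x"]]))
  expect_error(annotate_order(lonely, "missing"), "root")
})
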
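test_that("G2 statistic, degrees of freedom and sparse-table handling", {
  # perfectly associated 2x2 diagonal: G2 = 2 * 10 * ln 2
  co <- counts_cohort(rbind(c(5, 0), c(0, 5)))
  t <- g2_test(co, "a", "b")
  expect_equal(t$statistic, 20 * log(2), tolerance = 1e-12)
  expect_equal(t$df, 1L)

  # observed = expected everywhere -> G2 = 0
  co0 <- counts_cohort(rbind(c(4, 4), c(4, 4)))
  expect_equal(g2_test(co0, "a", "b")$statistic, 0, tolerance = 1e-12)

  # df counts only conditioning strata with observations
  df <- data.frame(x = factor(rep(c("0", "1"), 20)),
                   y = factor(rep(c("0", "1"), each = 20)),
                   z = factor(rep("z1", 40), levels = c("z1", "z2", "z3")))
  t3 <- g2_test(toy_cohort(df), "x", "y", "z")
  expect_equal(t3$df, 1L)   # (2-1)(2-1) x 1 nonempty stratum

  expect_error(g2_test(toy_cohort(df[0, ]), "x", "y"), "empty cohort")
  expect_error(g2_test(co, "a", "a"), "distinct")
})

test_that("G2 detects conditional independence on chain-generated data", {
  withr::with_seed(7, {
    co <- chain_cohort(2000)
    marg <- g2_test(co, "x", "y")
    cond <- g2_test(co, "x", "y", "w")
    expect_lt(marg$p_value, 0.05)   # x and y marginally dependent
    expect_gt(cond$p_value, 0.05)   # independent given the middle node
    # cross-check the conditional test against an independent exact test
    # on the same counts (Fisher within each stratum, combined minimum)
    for (wv in c("no", "yes")) {
      sub <- as.data.frame(co)[as.character(co$w) == wv, ]
      ft <- stats::fisher.test(table(sub$x, sub$y))
      expect_gt(ft$p.value, 0.05)
    }
  })
})

test_that("BDeu local score matches closed-form Gamma evaluation", {
  # binary child, one observation per state, ess = 1:
  # Gamma(1)/Gamma(3) * (Gamma(1.5)/Gamma(0.5))^2 = 1/8
  co <- toy_cohort(data.frame(a = factor(c("a1", "a2"))))
  expect_equal(bdeu_local(co, "a", ess = 1), log(1 / 8), tolerance = 1e-12)

  # empty cohort: all terms cancel
  co0 <- toy_cohort(data.frame(a = factor(character(0), levels = c("x", "y"))))
  expect_equal(bdeu_local(co0, "a", ess = 1), 0)

  expect_error(score_params(ess = 0), "ess")
  expect_error(score_params(alpha = 1), "alpha")
})

test_that("BDeu is score-equivalent and decomposable", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- sample(20:60, 1)
      co <- toy_cohort(data.frame(
        a = factor(sample(c("0", "1"), n, TRUE)),
        b = factor(sample(c("0", "1"), n, TRUE)),
        c = factor(sample(c("0", "1"), n, TRUE))))
      nodes <- c("a", "b", "c")
      # two-node equivalence: A->B and B->A score identically
      g_ab <- dag(nodes, rbind(c("a", "b")))
      g_ba <- dag(nodes, rbind(c("b", "a")))
      expect_equal(score_dag(g_ab, co), score_dag(g_ba, co),
                   tolerance = 1e-9)
      # covered-arc reversal: pa(c) = pa(b) + {b} -> reversing b-c
      # preserves the total score
      g1 <- dag(nodes, rbind(c("a", "b"), c("a", "c"), c("b", "c")))
      g2 <- dag(nodes, rbind(c("a", "b"), c("a", "c"), c("c", "b")))
      expect_equal(score_dag(g1, co), score_dag(g2, co), tolerance = 1e-9)
      # decomposability: empty DAG = sum of parentless locals
      expect_equal(score_dag(dag(nodes), co),
                   sum(vapply(nodes, function(v) bdeu_local(co, v),
                              numeric(1))), tolerance = 1e-12)
    }
  })
})

test_that("single-arc graph wins on a strongly dependent pair", {
  withr::with_seed(5, {
    x <- sample(c("0", "1"), 500, TRUE)
    y <- ifelse(runif(500) < 0.9, x, sample(c("0", "1"), 500, TRUE))
    co <- toy_cohort(data.frame(x = factor(x), y = factor(y)))
    s_empty <- score_dag(dag(c("x", "y")), co)
    s_xy <- score_dag(dag(c("x", "y"), rbind(c("x", "y"))), co)
    s_yx <- score_dag(dag(c("x", "y"), rbind(c("y", "x"))), co)
    expect_gt(s_xy, s_empty)
    expect_equal(s_xy, s_yx, tolerance = 1e-9)
    g <- hill_climb(co)
    expect_equal(nrow(g$arcs), 1L)
  })
})

test_that("mmpc finds correct candidate sets on simulated structures", {
  withr::with_seed(11, {
    # mutually independent variables -> empty candidate sets
    co_ind <- toy_cohort(data.frame(
      a = factor(sample(c("0", "1"), 1000, TRUE)),
      b = factor(sample(c("0", "1"), 1000, TRUE))))
    cpc <- mmpc(co_ind)
    expect_length(cpc$a, 0)
    expect_length(cpc$b, 0)

    # chain x -> w -> y: endpoints are separated by the middle node
    co_chain <- chain_cohort(2000)
    cpc2 <- mmpc(co_chain)
    expect_equal(cpc2$x, "w")
    expect_setequal(cpc2$w, c("x", "y"))
    expect_equal(cpc2$y, "w")
  })
})

test_that("constraints are respected by mmpc and hill_climb", {
  withr::with_seed(13, {
    x <- sample(c("0", "1"), 400, TRUE)
    y <- ifelse(runif(400) < 0.9, x, sample(c("0", "1"), 400, TRUE))
    co <- toy_cohort(data.frame(x = factor(x), y = factor(y)))
    # blacklisted in both directions: never a candidate, never an arc
    cs <- constraint_set(blacklist = rbind(c("x", "y"), c("y", "x")))
    cpc <- mmpc(co, constraints = cs)
    expect_length(cpc$x, 0)
    expect_length(cpc$y, 0)
    expect_equal(nrow(mmhc(co, constraints = cs)$arcs), 0L)
    # whitelisted arc always present, even against the data
    co_ind <- toy_cohort(data.frame(
      a = factor(sample(c("0", "1"), 300, TRUE)),
      b = factor(sample(c("0", "1"), 300, TRUE))))
    cs2 <- constraint_set(whitelist = rbind(c("a", "b")))
    g <- hill_climb(co_ind, constraints = cs2)
    expect_true(any(g$arcs[, 1] == "a" & g$arcs[, 2] == "b"))
    expect_error(constraint_set(whitelist = rbind(c("a", "b"), c("b", "a"))),
                 "cyclic")
  })
})

test_that("hill climbing respects 100 random blacklists", {
  withr::with_seed(17, {
    co <- modelled_cohort(generate_cohort(n = 300, seed = 91))
    vars <- names(co)
    for (i in 1:100) {
      pairs <- t(replicate(8, sample(vars, 2)))
      cs <- constraint_set(blacklist = pairs)
      g <- hill_climb(co, constraints = cs,
                      nodes = sample(vars, 6))
      for (j in seq_len(nrow(pairs))) {
        expect_false(any(g$arcs[, 1] == pairs[j, 1] &
                           g$arcs[, 2] == pairs[j, 2]))
      }
      expect_silent(topo_sort(g))  # acyclic by construction, checked
    }
  })
})

test_that("mmhc attains the exhaustive-enumeration optimum on 3 nodes", {
  withr::with_seed(23, {
    co <- chain_cohort(2000, p_flip = 0.1)
    g <- mmhc(co)
    scores <- vapply(all_dags_3(c("x", "w", "y")), score_dag, numeric(1),
                     cohort = co)
    expect_gte(score_dag(g, co) + 1e-9, max(scores))
    # recovered skeleton is the chain skeleton
    skel <- paste(pmin(g$arcs[, 1], g$arcs[, 2]),
                  pmax(g$arcs[, 1], g$arcs[, 2]))
    expect_setequal(skel, c("w x", "w y"))
  })
})

test_that("domain blacklist holds on the synthetic cohort and empty input errors", {
  co <- modelled_cohort(generate_cohort(n = 400, seed = 55))
  cs <- sics_constraints(names(co))
  g <- mmhc(co, constraints = cs)
  expect_false(any(g$arcs[, 2] %in% c("age", "gender")))
  expect_false(any(g$arcs[, 1] == "estimate"))
  expect_error(mmhc(co[0, ]), "empty cohort")
})
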
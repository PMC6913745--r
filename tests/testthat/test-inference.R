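two_node_net <- function() {
  lv <- list(a = c("0", "1"), b = c("0", "1"))
  bayes_net(dag(c("a", "b"), rbind(c("a", "b"))),
            list(a = make_cpt("a", character(0), lv, c(0.7, 0.3)),
                 b = make_cpt("b", "a", lv, c(0.8, 0.2, 0.1, 0.9))))
}

test_that("CPT fitting: empirical frequencies, priors, undefined rows", {
  co <- toy_cohort(data.frame(
    a = factor(c(rep("yes", 7), rep("no", 3)), c("no", "yes"))))
  bn <- fit_cpts(dag("a"), co, pseudocount = 0)
  expect_equal(unname(bn$cpts$a["yes"]), 0.7)

  # parent configuration never observed: uniform under Laplace, error at 0
  df <- data.frame(p = factor(rep("no", 10), c("no", "yes")),
                   c = factor(rep(c("no", "yes"), 5), c("no", "yes")))
  g <- dag(c("p", "c"), rbind(c("p", "c")))
  bn1 <- fit_cpts(g, toy_cohort(df), pseudocount = 1)
  expect_equal(unname(bn1$cpts$c[, "yes"]), c(0.5, 0.5))
  expect_error(fit_cpts(g, toy_cohort(df), pseudocount = 0), "undefined")
  expect_error(fit_cpts(g, toy_cohort(df), pseudocount = -1), ">= 0")
})

test_that("posterior matches Bayes rule and the enumeration oracle", {
  bn <- two_node_net()
  expect_equal(unname(posterior(bn, "a", list(b = "1"))["1"]), 27 / 41,
               tolerance = 1e-12)
  # empty evidence: marginal equals independent forward enumeration
  expect_equal(as.numeric(posterior(bn, "b")),
               as.numeric(enum_posterior(bn, "b")), tolerance = 1e-12)
  # zero-probability evidence is an inconsistency error
  lv <- list(a = c("0", "1"), b = c("0", "1"))
  det <- bayes_net(dag(c("a", "b"), rbind(c("a", "b"))),
                   list(a = make_cpt("a", character(0), lv, c(1, 0)),
                        b = make_cpt("b", "a", lv, c(1, 0, 0, 1))))
  expect_error(posterior(det, "a", list(b = "1")), "zero probability")
  expect_error(posterior(bn, "a", list(a = "1")), "target")
})

test_that("variable elimination equals full-joint enumeration on random nets", {
  withr::with_seed(101, {
    for (i in 1:50) {
      bn <- rand_binary_net(sample(3:8, 1))
      tgt <- sample(bn$dag$nodes, 1)
      pool <- setdiff(bn$dag$nodes, tgt)
      evn <- sample(pool, sample(0:length(pool), 1))
      ev <- stats::setNames(lapply(evn, function(v) sample(c("s1", "s2"), 1)),
                            evn)
      got <- posterior(bn, tgt, ev)
      expected <- enum_posterior(bn, tgt, ev)
      expect_lt(max(abs(got - expected)), 1e-9)
      expect_equal(sum(got), 1, tolerance = 1e-9)
      expect_true(all(got >= 0))
      # evidence probability agrees with the enumerated joint
      if (length(ev) > 0) {
        j <- enum_joint(bn)
        keep <- rep(TRUE, nrow(j))
        for (v in names(ev)) keep <- keep & j[[v]] == ev[[v]]
        expect_equal(evidence_probability(bn, ev), sum(j$p[keep]),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("query trees obey the law of total probability", {
  bn <- build_ground_truth()
  # empty order: single root carrying the marginal
  root_only <- query_tree(bn, "estimate")
  expect_equal(nrow(root_only), 1L)
  expect_equal(root_only$p_good, unname(posterior(bn, "estimate")["good"]))

  tree <- query_tree(bn, "estimate", c("ventilated", "noradrenaline", "dcrt_m"))
  expect_equal(nrow(tree), 1 + 2 + 4 + 8)
  pcols <- grep("^p_", names(tree), value = TRUE)
  for (pid in tree$id[tree$depth < 3]) {
    kids <- tree[tree$parent == pid, , drop = FALSE]
    expect_equal(sum(kids$branch_prob), 1, tolerance = 1e-9)
    parent_dist <- unlist(tree[tree$id == pid, pcols])
    mixed <- colSums(kids$branch_prob * as.matrix(kids[, pcols]))
    expect_lt(max(abs(mixed - parent_dist)), 1e-9)
  }
  # node joint probabilities are consistent down every path
  for (r in seq_len(nrow(tree))[-1]) {
    par <- tree[tree$id == tree$parent[r], ]
    expect_equal(tree$prob[r], par$prob * tree$branch_prob[r],
                 tolerance = 1e-12)
  }
  expect_error(query_tree(bn, "estimate", c("estimate")), "target")
})

test_that("ancestral sampling is seeded and matches exact marginals", {
  bn <- withr::with_seed(55, rand_binary_net(6))
  expect_equal(nrow(ancestral_sample(bn, 0, seed = 1)), 0L)
  s1 <- ancestral_sample(bn, 200, seed = 8)
  s2 <- ancestral_sample(bn, 200, seed = 8)
  expect_identical(as.data.frame(s1), as.data.frame(s2))

  n <- 50000
  s <- ancestral_sample(bn, n, seed = 12)
  for (v in bn$dag$nodes) {
    p <- unname(enum_posterior(bn, v)["s2"])   # independent oracle
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(s[[v]] == "s2") - p), 3 * se + 1e-12)
  }
})

test_that("sampling/fitting round trip recovers the generating CPTs", {
  bn <- build_ground_truth()
  s <- ancestral_sample(bn, 50000, seed = 9)
  refit <- fit_cpts(ground_truth_dag(), s, pseudocount = 1)
  err <- max(vapply(bn$dag$nodes, function(v) {
    max(abs(bn$cpts[[v]] - refit$cpts[[v]]))
  }, numeric(1)))
  expect_lt(err, 0.02)
})

test_that("prediction uses the Markov blanket and matches brute force", {
  bn <- build_ground_truth()
  expect_setequal(markov_blanket(bn$dag, "estimate"),
                  c("noradrenaline", "dcrt_m", "cardiac_index"))
  base <- list(noradrenaline = "yes", dcrt_m = "yes", cardiac_index = "low",
               ventilated = "yes", age = "lt65")
  alt <- base
  alt$ventilated <- "no"; alt$age <- "ge65"
  expect_equal(predict_estimate(bn, base), predict_estimate(bn, alt),
               tolerance = 1e-12)
  # vasopressor + hypoperfusion signs lower P(reasonable or good)
  marg <- posterior(bn, "estimate")
  pred <- predict_estimate(bn, list(noradrenaline = "yes", dcrt_m = "yes",
                                    cardiac_index = "low"))
  expect_lt(pred[["reasonable"]] + pred[["good"]],
            marg[["reasonable"]] + marg[["good"]])
  expect_error(predict_estimate(bn, list(noradrenaline = "yes")),
               "Markov blanket")

  toy <- withr::with_seed(77, rand_binary_net(6))
  rec <- stats::setNames(as.list(rep("s1", 5)), setdiff(toy$dag$nodes, "v3"))
  expect_equal(as.numeric(predict_estimate(toy, rec, target = "v3")),
               as.numeric(enum_posterior(toy, "v3", rec)), tolerance = 1e-9)
})

test_that("network JSON serialization round-trips", {
  bn <- build_ground_truth()
  path <- withr::local_tempfile(fileext = ".json")
  write_bn_json(bn, path)
  back <- read_bn_json(path)
  expect_setequal(back$dag$nodes, bn$dag$nodes)
  for (v in bn$dag$nodes) {
    expect_equal(back$cpts[[v]], bn$cpts[[v]], tolerance = 1e-12)
  }
  q1 <- posterior(bn, "estimate", list(ventilated = "yes"))
  q2 <- posterior(back, "estimate", list(ventilated = "yes"))
  expect_equal(q1, q2, tolerance = 1e-12)
})
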
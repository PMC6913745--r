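conf_row <- function(from, to, strength, direction) {
  data.frame(from = from, to = to, strength = strength,
             direction = direction, stringsAsFactors = FALSE)
}

test_that("significance threshold is the L1-optimal cutpoint", {
  # {1,1,1,0,0}: the threshold must select exactly the three strength-1 arcs
  s <- c(1, 1, 1, 0, 0)
  th <- significance_threshold(s)
  expect_equal(sum(s > th), 3L)
  # degenerate worlds
  expect_equal(sum(rep(1, 4) > significance_threshold(rep(1, 4))), 4L)
  expect_equal(sum(rep(0, 4) > significance_threshold(rep(0, 4))), 0L)
  expect_error(significance_threshold(numeric(0)), "empty")
  expect_error(significance_threshold(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("consensus keeps, directs and drops edges per the thresholds", {
  conf <- rbind(
    conf_row("lactate", "oliguria", 0.728, 0.803),   # retained, directed
    conf_row("ventilated", "high_rr", 0.994, 0.504), # retained, undirected
    conf_row("a", "b", 0.68, 0.9),                   # below 0.700 floor
    conf_row("c", "d", 0, NA),
    conf_row("e", "f", 0, NA))
  g <- build_consensus(conf)
  expect_equal(g$strength_threshold, 0.700)
  expect_equal(nrow(g$arcs), 1L)
  expect_equal(unname(g$arcs[1, ]), c("lactate", "oliguria"))
  expect_equal(nrow(g$undirected), 1L)
  expect_false(any(g$arcs[, 1] == "a"))
  # direction exactly at 0.666 counts as directed
  g2 <- build_consensus(rbind(conf_row("p", "q", 0.9, 0.666),
                              conf_row("r", "s", 0, NA),
                              conf_row("t", "u", 0, NA)))
  expect_equal(nrow(g2$arcs), 1L)
  expect_equal(nrow(g2$undirected), 0L)
  # a majority orientation below the threshold leaves the edge undirected,
  # and the minority orientation can also win when >= threshold
  g3 <- build_consensus(rbind(conf_row("p", "q", 0.9, 0.60),
                              conf_row("r", "s", 0, NA)))
  expect_equal(nrow(g3$undirected), 1L)
  # directed cycle among retained arcs is an error, not silently fixed
  cyc <- rbind(conf_row("a", "b", 1, 1), conf_row("b", "c", 1, 1),
               conf_row("c", "a", 1, 1))
  expect_error(build_consensus(cyc), "cycle")
})

test_that("raising the strength floor never adds an edge", {
  withr::with_seed(41, {
    for (i in 1:20) {
      k <- 12
      conf <- conf_row(paste0("n", 1:k), paste0("m", 1:k),
                       round(runif(k), 3),
                       round(runif(k, 0.5, 1), 3))
      floors <- sort(runif(3, 0.4, 0.99))
      prev <- NULL
      for (fl in rev(floors)) {   # decreasing floor
        g <- build_consensus(conf, strength_floor = fl)
        edges <- nrow(g$arcs) + nrow(g$undirected)
        if (!is.null(prev)) expect_gte(edges, prev)
        prev <- edges
      }
    }
  })
})

test_that("expert orientation completes the consensus graph", {
  conf <- rbind(conf_row("high_rr", "ventilated", 0.994, 0.504),
                conf_row("noradrenaline", "ventilated", 1, 0.957),
                conf_row("x", "y", 0, NA))
  g <- build_consensus(conf)
  expect_equal(nrow(g$undirected), 1L)
  out <- orient_undirected(g, sics_expert_orientations())
  expect_s3_class(out, "dag")
  expect_true(any(out$arcs[, 1] == "high_rr" & out$arcs[, 2] == "ventilated"))
  # no undirected edges: graph passes through unchanged
  g2 <- build_consensus(conf[-1, ])
  expect_identical(orient_undirected(g2)$arcs, g2$arcs)
  # missing orientation and cycle-inducing orientation are errors
  expect_error(orient_undirected(g, NULL), "no expert orientation")
  cyc <- build_consensus(rbind(conf_row("a", "b", 1, 1),
                               conf_row("b", "c", 1, 1),
                               conf_row("a", "c", 1, 0.5)))
  expect_error(orient_undirected(cyc, rbind(c("c", "a"))), "cycle")
})

test_that("bootstrap confidence: determinism, copy-pair certainty, noise floor", {
  withr::with_seed(3, {
    x <- sample(c("0", "1"), 150, TRUE)
    co_copy <- toy_cohort(data.frame(x = factor(x), y = factor(x)))
  })
  c1 <- bootstrap_confidence(co_copy, replicates = 30, seed = 10)
  c2 <- bootstrap_confidence(co_copy, replicates = 30, seed = 10)
  expect_identical(c1, c2)   # seeded reproducibility
  expect_equal(c1$strength, 1)   # deterministic copy: arc in every replicate

  withr::with_seed(19, {
    co_ind <- toy_cohort(data.frame(
      a = factor(sample(c("0", "1"), 2000, TRUE)),
      b = factor(sample(c("0", "1"), 2000, TRUE))))
  })
  ci <- bootstrap_confidence(co_ind, replicates = 50, seed = 4)
  expect_lt(ci$strength, 0.25)   # only sampling noise

  expect_error(bootstrap_confidence(co_copy, replicates = 0), "replicates")
})

test_that("confidence tables have consistent direction pairs and round-trip", {
  co <- modelled_cohort(generate_cohort(n = 250, seed = 77))
  vars <- c("noradrenaline", "estimate", "dcrt_m", "ventilated", "high_rr")
  sub <- as_cohort(as.data.frame(co)[vars], attr(co, "specs")[vars])
  conf <- bootstrap_confidence(sub, replicates = 25, seed = 6,
                               constraints = sics_constraints(vars),
                               nodes = vars)
  # every unordered pair reported exactly once
  expect_equal(nrow(conf), choose(length(vars), 2))
  # direction convention: reported orientation is the majority one, and
  # the two orientations sum to 1 (the complement is implicit)
  pos <- conf$strength > 0
  expect_true(all(conf$direction[pos] >= 0.5 & conf$direction[pos] <= 1))
  expect_true(all(is.na(conf$direction[!pos])))
  expect_true(all(conf$strength >= 0 & conf$strength <= 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_confidence_csv(conf, path)
  back <- read_confidence_csv(path)
  expect_equal(back$strength, conf$strength)
  expect_equal(back$direction, conf$direction)
})
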
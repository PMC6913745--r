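test_that("dichotomization rules", {
  expect_equal(dichotomize_estimate(c("poor", "moderate")), c("low", "low"))
  expect_equal(dichotomize_estimate(c("reasonable", "good")),
               c("high", "high"))
  expect_error(dichotomize_estimate("fine"), "unknown estimate state")
  expect_equal(dichotomize_ci(c(2.2, 2.21, 1.0)), c("low", "high", "low"))
  expect_error(dichotomize_ci(-1), "positive")
})

test_that("cross-tabulation counts cells correctly", {
  t0 <- crosstab(character(0), character(0))
  expect_equal(unlist(unclass(t0)), c(tp = 0, fp = 0, fn = 0, tn = 0))
  t1 <- crosstab(rep("low", 4), rep("low", 4))
  expect_equal(t1$fp + t1$fn, 0)
  # 4 hand-built records: (low,low), (low,high), (high,low), (high,high)
  t2 <- crosstab(c("low", "low", "high", "high"),
                 c("low", "high", "low", "high"))
  expect_equal(unlist(unclass(t2)), c(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_error(crosstab("low", c("low", "high")), "length")
  expect_error(crosstab("low", NA_character_), "missing")
  expect_error(two_by_two(-1, 0, 0, 0), "non-negative")
})

test_that("accuracy metrics reproduce hand arithmetic and handle degeneracy", {
  m <- dx_metrics(two_by_two(8, 2, 2, 8))
  get <- function(m, k, f = "estimate") m[[f]][m$metric == k]
  expect_equal(get(m, "sensitivity"), 0.8)
  expect_equal(get(m, "specificity"), 0.8)
  expect_equal(get(m, "lr_pos"), 4.0)
  expect_equal(get(m, "ppv"), 0.8)

  perfect <- dx_metrics(two_by_two(10, 0, 0, 10))
  expect_equal(get(perfect, "sensitivity"), 1)
  expect_equal(get(perfect, "specificity"), 1)
  expect_equal(get(perfect, "accuracy"), 1)
  expect_equal(get(perfect, "lr_pos"), Inf)   # undefined CI, infinite LR
  expect_true(is.na(get(perfect, "lr_pos", "ci_low")))
})

test_that("LR identities and Wilson interval behaviour on random tables", {
  withr::with_seed(61, {
    for (i in 1:50) {
      cells <- sample(1:200, 4)
      t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
      m <- dx_metrics(t)
      get <- function(k, f = "estimate") m[[f]][m$metric == k]
      sens <- get("sensitivity"); spec <- get("specificity")
      expect_equal(get("lr_pos"), sens / (1 - spec), tolerance = 1e-12)
      expect_equal(get("lr_neg"), (1 - sens) / spec, tolerance = 1e-12)
      # Wilson CI contains the point estimate
      for (k in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
        expect_gte(get(k), get(k, "ci_low"))
        expect_lte(get(k), get(k, "ci_high"))
      }
      # CI narrows when all counts scale up tenfold
      m10 <- dx_metrics(two_by_two(cells[1] * 10, cells[2] * 10,
                                   cells[3] * 10, cells[4] * 10))
      w <- m$ci_high[m$metric == "sensitivity"] -
        m$ci_low[m$metric == "sensitivity"]
      w10 <- m10$ci_high[m10$metric == "sensitivity"] -
        m10$ci_low[m10$metric == "sensitivity"]
      expect_lt(w10, w)
    }
  })
})

test_that("the overall published table reconstructs uniquely", {
  t <- reconstruct_overall_table()
  expect_equal(unlist(unclass(t)), c(tp = 85, fp = 98, fn = 198, tn = 402))
  # impossible printed LR+ -> no table
  expect_error(
    reconstruct_overall_table(printed = list(sensitivity = 30,
                                             specificity = 80,
                                             lr_pos = 9.99)),
    "no table")
  # accuracy alone is under-determined
  expect_error(reconstruct_overall_table(printed = list(accuracy = 62)),
               "under-determined")
  expect_error(reconstruct_overall_table(low_margin = 0), "positive")
})

test_that("AUROC follows the rank statistic with tie correction", {
  # pair counting: both positive-negative pairs correctly ordered
  expect_equal(auroc(c(0.9, 0.8, 0.4), c("low", "high", "high")), 1.0)
  expect_equal(auroc(c(0.4, 0.8), c("low", "high")), 0)
  expect_equal(auroc(c(0.5, 0.5), c("low", "high")), 0.5)  # tie -> one half
  expect_true(is.na(auroc(c(0.1, 0.2), c("low", "low"))))
  withr::with_seed(71, {   # null behaviour on shuffled labels
    a <- auroc(runif(2000), sample(c("low", "high"), 2000, TRUE))
    expect_lt(abs(a - 0.5), 0.05)
  })
})

test_that("cross-validation partitions once and scores predictions", {
  withr::with_seed(81, {
    x <- sample(c("no", "yes"), 200, TRUE)
    co <- toy_cohort(data.frame(
      x = factor(x, c("no", "yes")),
      estimate = factor(ifelse(x == "yes", "poor", "good"),
                        c("poor", "moderate", "reasonable", "good"))))
  })
  df <- as.data.frame(co)
  df$cardiac_index <- factor(ifelse(df$x == "yes", "low", "high"),
                             c("low", "high"))
  specs <- c(attr(co, "specs"),
             list(cardiac_index = variable_spec("cardiac_index",
                                                c("low", "high"), "outcome")))
  co2 <- as_cohort(df, specs)
  g <- dag(c("x", "estimate"), rbind(c("x", "estimate")))
  cv <- cross_validate(co2, g, folds = 10, seed = 5)
  # fold partition is a permutation of the records
  expect_equal(sort(cv$predictions$row), 1:200)
  expect_equal(sum(cv$fold_sizes), 200L)
  expect_true(all(cv$fold_sizes == 20L))
  expect_identical(cross_validate(co2, g, folds = 10, seed = 5)$predictions,
                   cv$predictions)
  # perfectly informative relation -> AUROC 1
  expect_equal(cv$auroc, 1.0)
  expect_error(cross_validate(co2, g, folds = 1), "folds")
  # single outcome class -> AUROC flagged undefined
  df3 <- df
  df3$cardiac_index <- factor(rep("low", 200), c("low", "high"))
  cv3 <- cross_validate(as_cohort(df3, specs), g, folds = 5, seed = 5)
  expect_true(is.na(cv3$auroc))
})
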
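#' Dichotomization of estimates and cardiac index
#'
#' `dichotomize_estimate()` groups the four-level cardiac-function
#' estimate: poor/moderate become `"low"`, reasonable/good become
#' `"high"`. `dichotomize_ci()` dichotomizes a cardiac index in L/min/m2
#' at the conventional 2.2 cutoff (inclusive: 2.2 itself is `"low"`).
#'
#' @param state character vector of estimate levels.
#' @param value positive numeric cardiac index values.
#' @param cutoff cardiac-index cutoff (default 2.2 L/min/m2).
#' @return character vector of `"low"`/`"high"` (`NA` passed through for
#'   the cardiac index).
#' @export
dichotomize_estimate <- function(state) {
  state <- as.character(state)
  out <- ifelse(state %in% c("poor", "moderate"), "low",
                ifelse(state %in% c("reasonable", "good"), "high",
                       NA_character_))
  bad <- which(!is.na(state) & is.na(out))
  if (length(bad) > 0) {
    stop("unknown estimate state: ", state[bad[1]])
  }
  out
}

#' @rdname dichotomize_estimate
#' @export
dichotomize_ci <- function(value, cutoff = 2.2) {
  value <- as.numeric(value)
  if (any(!is.na(value) & value <= 0)) {
    stop("cardiac index must be positive")
  }
  ifelse(is.na(value), NA_character_, ifelse(value <= cutoff, "low", "high"))
}

#' 2x2 contingency table of predictions versus cardiac index
#'
#' Cross-tabulates dichotomized predictions against dichotomized truth.
#' `"low"` is the positive class: `tp` counts records predicted low with a
#' truly low cardiac index.
#'
#' @param pred,truth equal-length vectors of `"low"`/`"high"`; `truth`
#'   must be non-missing.
#' @param tp,fp,fn,tn cell counts (direct constructor).
#' @return object of class `two_by_two` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
crosstab <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth)) stop("length mismatch")
  if (anyNA(truth)) stop("truth contains missing values")
  ok <- c("low", "high")
  if (!all(pred %in% ok) || !all(truth %in% ok)) {
    stop("values must be 'low' or 'high'")
  }
  two_by_two(tp = sum(pred == "low" & truth == "low"),
             fp = sum(pred == "low" & truth == "high"),
             fn = sum(pred == "high" & truth == "low"),
             tn = sum(pred == "high" & truth == "high"))
}

#' @rdname crosstab
#' @export
two_by_two <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(estimate = c("low", "high"),
                              cardiac_index = c("low", "high")))
  print(m)
  invisible(x)
}

wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(center - half, center + half)
}

#' Diagnostic accuracy metrics with 95% confidence intervals
#'
#' Sensitivity, specificity, predictive values and overall accuracy with
#' Wilson score intervals; positive and negative likelihood ratios with
#' log-method intervals, e.g.
#' `exp(ln LR+ +- z sqrt(1/tp - 1/(tp+fn) + 1/fp - 1/(fp+tn)))`.
#' Metrics with a zero denominator are flagged `NA` (an infinite LR is
#' reported as `Inf` with an undefined CI).
#'
#' @param t a [two_by_two()].
#' @param conf confidence level.
#' @return object of class `dx_metrics`: data frame with columns `metric`,
#'   `estimate`, `ci_low`, `ci_high`; the raw cells are kept in attribute
#'   `"cells"`.
#' @export
dx_metrics <- function(t, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tp <- t$tp; fp <- t$fp; fn <- t$fn; tn <- t$tn
  n <- tp + fp + fn + tn
  prop <- function(x, d) if (d == 0) NA_real_ else x / d
  sens <- prop(tp, tp + fn)
  spec <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp)
  npv <- prop(tn, tn + fn)
  acc <- prop(tp + tn, n)
  lr_pos <- if (is.na(sens) || is.na(spec)) NA_real_
            else if (spec == 1) Inf else sens / (1 - spec)
  lr_neg <- if (is.na(sens) || is.na(spec)) NA_real_
            else if (spec == 0) Inf else (1 - sens) / spec
  lr_ci <- function(lr, a, b, c, d) {
    # a/b and c/d are the two proportions whose ratio is the LR
    if (!is.finite(lr) || lr <= 0 || a == 0 || c == 0) {
      return(c(NA_real_, NA_real_))
    }
    se <- sqrt(1 / a - 1 / b + 1 / c - 1 / d)
    exp(log(lr) + c(-1, 1) * z * se)
  }
  rows <- rbind(
    data.frame(metric = "sensitivity", estimate = sens,
               ci_low = wilson_ci(tp, tp + fn, conf)[1],
               ci_high = wilson_ci(tp, tp + fn, conf)[2]),
    data.frame(metric = "specificity", estimate = spec,
               ci_low = wilson_ci(tn, tn + fp, conf)[1],
               ci_high = wilson_ci(tn, tn + fp, conf)[2]),
    data.frame(metric = "ppv", estimate = ppv,
               ci_low = wilson_ci(tp, tp + fp, conf)[1],
               ci_high = wilson_ci(tp, tp + fp, conf)[2]),
    data.frame(metric = "npv", estimate = npv,
               ci_low = wilson_ci(tn, tn + fn, conf)[1],
               ci_high = wilson_ci(tn, tn + fn, conf)[2]),
    data.frame(metric = "accuracy", estimate = acc,
               ci_low = wilson_ci(tp + tn, n, conf)[1],
               ci_high = wilson_ci(tp + tn, n, conf)[2]),
    data.frame(metric = "lr_pos", estimate = lr_pos,
               ci_low = lr_ci(lr_pos, tp, tp + fn, fp, fp + tn)[1],
               ci_high = lr_ci(lr_pos, tp, tp + fn, fp, fp + tn)[2]),
    data.frame(metric = "lr_neg", estimate = lr_neg,
               ci_low = lr_ci(lr_neg, fn, tp + fn, tn, fp + tn)[1],
               ci_high = lr_ci(lr_neg, fn, tp + fn, tn, fp + tn)[2]))
  structure(rows, cells = t, class = c("dx_metrics", "data.frame"))
}

#' @rdname dx_metrics
#' @param x a `dx_metrics` object.
#' @param path output CSV path (a JSON sidecar `<path>.json` stores the
#'   raw cells).
#' @export
write_metrics_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  cells <- attr(x, "cells")
  jsonlite::write_json(list(tp = cells$tp, fp = cells$fp, fn = cells$fn,
                            tn = cells$tn),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# round half away from zero, the convention used for printed values
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Reconstruct the published overall 2x2 table from printed summaries
#'
#' Exhaustive search over all integer tables with the given dichotomized
#' estimate margins (low = tp + fp, high = fn + tn) for the unique table
#' whose computed metrics round — half away from zero, at the printed
#' precision — to every supplied printed value. Percent metrics are
#' matched at whole percents, likelihood ratios and their CI bounds at two
#' decimals. Errors when no table or more than one table qualifies.
#'
#' @param low_margin,high_margin number of records with a low / high
#'   dichotomized estimate (published overall margins: 183 and 600).
#' @param printed named list of printed values to match; any of
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` (percents),
#'   `lr_pos`, `lr_neg`, and `lr_pos_ci`, `lr_neg_ci` (length-2 bounds).
#'   Defaults to the published overall column.
#' @param conf confidence level for the CI bounds.
#' @return the unique [two_by_two()].
#' @export
reconstruct_overall_table <- function(
    low_margin = 183, high_margin = 600,
    printed = list(sensitivity = 30, specificity = 80, ppv = 46, npv = 67,
                   accuracy = 62, lr_pos = 1.53, lr_neg = 0.87,
                   lr_pos_ci = c(1.19, 1.97), lr_neg_ci = c(0.80, 0.95)),
    conf = 0.95) {
  if (low_margin <= 0 || high_margin <= 0) stop("margins must be positive")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tp <- rep(0:low_margin, times = high_margin + 1)
  tn <- rep(0:high_margin, each = low_margin + 1)
  fp <- low_margin - tp
  fn <- high_margin - tn
  n <- low_margin + high_margin
  ok <- rep(TRUE, length(tp))
  pct <- function(x) round_half_up(100 * x)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  match_val <- function(computed, key, digits) {
    if (is.null(printed[[key]])) return()
    ok <<- ok & !is.na(computed) &
      round_half_up(computed, digits) == printed[[key]]
  }
  match_val(pct(sens), "sensitivity", 0)
  match_val(pct(spec), "specificity", 0)
  match_val(pct(tp / (tp + fp)), "ppv", 0)
  match_val(pct(tn / (tn + fn)), "npv", 0)
  match_val(pct((tp + tn) / n), "accuracy", 0)
  lr_pos <- sens / (1 - spec)
  lr_neg <- (1 - sens) / spec
  match_val(lr_pos, "lr_pos", 2)
  match_val(lr_neg, "lr_neg", 2)
  if (!is.null(printed$lr_pos_ci)) {
    se <- suppressWarnings(sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn)))
    lo <- exp(log(lr_pos) - z * se)
    hi <- exp(log(lr_pos) + z * se)
    ok <- ok & is.finite(lo) & is.finite(hi) &
      round_half_up(lo, 2) == printed$lr_pos_ci[1] &
      round_half_up(hi, 2) == printed$lr_pos_ci[2]
  }
  if (!is.null(printed$lr_neg_ci)) {
    se <- suppressWarnings(sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn)))
    lo <- exp(log(lr_neg) - z * se)
    hi <- exp(log(lr_neg) + z * se)
    ok <- ok & is.finite(lo) & is.finite(hi) &
      round_half_up(lo, 2) == printed$lr_neg_ci[1] &
      round_half_up(hi, 2) == printed$lr_neg_ci[2]
  }
  hits <- which(ok)
  if (length(hits) == 0) {
    stop("reconstruction error: no table matches the printed values")
  }
  if (length(hits) > 1) {
    stop("reconstruction error: ", length(hits),
         " tables match; constraints under-determined")
  }
  two_by_two(tp = tp[hits], fp = fp[hits], fn = fn[hits], tn = tn[hits])
}

#' Area under the ROC curve by the rank statistic
#'
#' Mann-Whitney formulation with midrank tie correction: the probability
#' that a randomly chosen positive outscores a randomly chosen negative
#' (ties count one half).
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels vector of class labels.
#' @param positive label of the positive class (default `"low"`, a low
#'   cardiac index).
#' @return AUROC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auroc <- function(scores, labels, positive = "low") {
  pos <- labels == positive
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated prediction of the estimate
#'
#' Partitions the cohort once into `folds` test folds (each record held
#' out exactly once), refits the CPTs of a fixed network structure on the
#' training folds, and predicts the held-out records' estimate
#' distribution from their clinical variables. The predicted probability
#' of a *low* (poor/moderate) estimate is scored against the dichotomized
#' cardiac index on the subset with a validated measurement: AUROC by the
#' rank statistic, plus sensitivity and specificity of the dichotomized
#' prediction.
#'
#' @param cohort a `cohort` containing the structure's nodes and the
#'   outcome column.
#' @param dag fixed network structure (consensus DAG over the modelled
#'   variables, outcome excluded).
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold permutation.
#' @param pseudocount CPT pseudocount used when refitting.
#' @param target estimate variable name.
#' @param outcome cardiac-index variable name.
#' @param threshold probability threshold classifying a record as a
#'   predicted low estimate.
#' @return list with `predictions` (data frame: `row`, `fold`, `p_low`,
#'   `pred`), `auroc`, `sensitivity`, `specificity`, `n_validated`,
#'   `fold_sizes`.
#' @export
cross_validate <- function(cohort, dag, folds = 10, seed = 1,
                           pseudocount = 1, target = "estimate",
                           outcome = "cardiac_index", threshold = 0.5) {
  if (folds < 2) stop("folds must be >= 2")
  if (!outcome %in% names(cohort)) stop("cohort lacks the outcome column")
  n <- nrow(cohort)
  if (n < folds) stop("more folds than records")
  assign_folds <- function() {
    sample(rep(seq_len(folds), length.out = n))
  }
  fold_id <- if (is.null(seed)) assign_folds() else {
    withr::with_seed(seed, assign_folds())
  }
  evidence_vars <- setdiff(dag$nodes, target)
  p_low <- numeric(n)
  for (f in seq_len(folds)) {
    test <- which(fold_id == f)
    train <- cohort[-test, dag$nodes, drop = FALSE]
    attr(train, "specs") <- cohort_specs(cohort)[dag$nodes]
    class(train) <- class(cohort)
    bn <- fit_cpts(dag, train, pseudocount)
    # predictions depend only on the Markov blanket of the target, so
    # query each distinct blanket configuration once
    mb <- markov_blanket(dag, target)
    key <- do.call(paste, c(lapply(mb, function(v) cohort[[v]][test]),
                            sep = "\r"))
    for (k in unique(key)) {
      rows <- test[key == k]
      ev <- stats::setNames(
        lapply(mb, function(v) as.character(cohort[[v]][rows[1]])), mb)
      d <- posterior(bn, target, ev)
      p_low[rows] <- unname(d[["poor"]] + d[["moderate"]])
    }
  }
  pred <- ifelse(p_low >= threshold, "low", "high")
  predictions <- data.frame(row = seq_len(n), fold = fold_id,
                            p_low = p_low, pred = pred,
                            stringsAsFactors = FALSE)
  valid <- !is.na(cohort[[outcome]])
  truth <- as.character(cohort[[outcome]][valid])
  auc <- auroc(p_low[valid], truth, positive = "low")
  t <- crosstab(pred[valid], truth)
  m <- dx_metrics(t)
  list(predictions = predictions, auroc = auc,
       sensitivity = m$estimate[m$metric == "sensitivity"],
       specificity = m$estimate[m$metric == "specificity"],
       n_validated = sum(valid),
       fold_sizes = as.integer(table(fold_id)))
}
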
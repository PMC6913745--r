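#' Variable specifications
#'
#' A `variable_spec` declares one modelled variable: its name, its ordered
#' set of discrete states, and its role in the analysis. Exactly one
#' variable per cohort carries the role `"estimate"` (the examiner's
#' four-level cardiac-function estimate) and at most one carries the role
#' `"outcome"` (the dichotomized cardiac index, the only variable allowed
#' to be missing).
#'
#' @param name variable name (a valid column name).
#' @param states character vector of >= 2 unique state labels, in order.
#' @param role one of `"clinical"`, `"estimate"`, `"outcome"`.
#' @return object of class `variable_spec`.
#' @export
variable_spec <- function(name, states,
                          role = c("clinical", "estimate", "outcome")) {
  role <- match.arg(role)
  states <- as.character(states)
  if (length(states) < 2) stop("a variable needs at least 2 states")
  if (anyDuplicated(states)) stop("duplicate state labels in ", name)
  if (role == "estimate" &&
      !identical(states, c("poor", "moderate", "reasonable", "good"))) {
    stop("the estimate variable uses states poor/moderate/reasonable/good")
  }
  if (role == "outcome" && !identical(states, c("low", "high"))) {
    stop("the outcome variable uses states low/high")
  }
  structure(list(name = name, states = states, role = role),
            class = "variable_spec")
}

#' Default variable set of the cardiac-function cohort
#'
#' The 14 discretized clinical variables, the 4-level estimate, and the
#' optional dichotomized cardiac index. Binary clinical abnormalities use
#' states `no`/`yes` (second state = abnormal/present).
#'
#' @param include_outcome include the `cardiac_index` outcome variable.
#' @return named list of [variable_spec()] objects.
#' @export
default_variable_specs <- function(include_outcome = TRUE) {
  yn <- c("no", "yes")
  specs <- list(
    variable_spec("age", c("lt65", "ge65")),
    variable_spec("gender", c("female", "male")),
    variable_spec("cold_temperature", yn),
    variable_spec("irregular_rhythm", yn),
    variable_spec("tachycardia", yn),
    variable_spec("high_rr", yn),
    variable_spec("low_sbp", yn),
    variable_spec("low_dbp", yn),
    variable_spec("low_map", yn),
    variable_spec("elevated_lactate", yn),
    variable_spec("oliguria", yn),
    variable_spec("noradrenaline", yn),
    variable_spec("ventilated", yn),
    variable_spec("dcrt_m", yn),
    variable_spec("estimate", c("poor", "moderate", "reasonable", "good"),
                  role = "estimate")
  )
  if (include_outcome) {
    specs <- c(specs, list(
      variable_spec("cardiac_index", c("low", "high"), role = "outcome")))
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

validate_specs <- function(specs) {
  roles <- vapply(specs, `[[`, "", "role")
  if (sum(roles == "estimate") > 1) {
    stop("at most one variable may have role 'estimate'")
  }
  if (sum(roles == "outcome") > 1) {
    stop("at most one variable may have role 'outcome'")
  }
  invisible(specs)
}

#' Cohorts of discretized patient records
#'
#' A `cohort` is a data frame with one row per patient and one factor
#' column per declared variable; factor levels are the declared states.
#' Missing values (`NA`) are permitted only in the outcome column
#' (cardiac index unavailable, e.g. when ultrasound views could not be
#' validated); clinical predictors are complete-case.
#'
#' @param df data frame of state labels (character or factor).
#' @param specs named list of [variable_spec()]; defaults to the package's
#'   variable set restricted to `df`'s columns.
#' @return a `cohort` (data frame subclass with a `specs` attribute).
#' @export
as_cohort <- function(df, specs = NULL) {
  if (is.null(specs)) {
    all_specs <- default_variable_specs()
    missing <- setdiff(names(df), names(all_specs))
    if (length(missing) > 0) {
      stop("no default spec for column(s): ", paste(missing, collapse = ", "))
    }
    specs <- all_specs[names(df)]
  }
  validate_specs(specs)
  if (!setequal(names(df), names(specs))) {
    stop("cohort columns must match the variable specs; missing: ",
         paste(setdiff(names(specs), names(df)), collapse = ", "))
  }
  df <- df[names(specs)]
  for (v in names(specs)) {
    spec <- specs[[v]]
    col <- as.character(df[[v]])
    bad <- !is.na(col) & !(col %in% spec$states)
    if (any(bad)) {
      stop(sprintf("undeclared state '%s' in variable '%s' (row %d)",
                   col[which(bad)[1]], v, which(bad)[1]))
    }
    if (anyNA(col) && spec$role != "outcome") {
      stop(sprintf("missing value in non-outcome variable '%s' (row %d)",
                   v, which(is.na(col))[1]))
    }
    df[[v]] <- factor(col, levels = spec$states)
  }
  structure(df, specs = specs, class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x), "patients,", ncol(x), "variables\n")
  NextMethod()
}

cohort_specs <- function(x) attr(x, "specs")

# integer-coded view used by counting routines: 1-based codes, one column
# per variable, plus the per-variable level counts.
cohort_codes <- function(x, vars = names(x)) {
  codes <- matrix(0L, nrow = nrow(x), ncol = length(vars),
                  dimnames = list(NULL, vars))
  for (v in vars) codes[, v] <- as.integer(x[[v]])
  nlev <- vapply(vars, function(v) nlevels(x[[v]]), integer(1))
  levels <- lapply(stats::setNames(vars, vars), function(v) levels(x[[v]]))
  list(codes = codes, nlev = nlev, levels = levels, vars = vars)
}

#' Read and write cohort CSV files
#'
#' The file format is UTF-8 CSV with a header row of variable names and one
#' row per patient; an empty cell encodes a missing outcome value.
#'
#' @param path CSV file path.
#' @param specs named list of [variable_spec()]; defaults to the package's
#'   variable set restricted to the file's columns.
#' @param x a cohort.
#' @return `read_cohort` returns a `cohort`; `write_cohort` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path, specs = NULL) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!is.null(specs)) {
    missing <- setdiff(names(specs), names(df))
    if (length(missing) > 0) {
      stop("cohort file lacks declared column(s): ",
           paste(missing, collapse = ", "))
    }
    df <- df[names(specs)]
  }
  df[df == ""] <- NA
  as_cohort(df, specs)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  out <- as.data.frame(lapply(x, as.character),
                       stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Discretization rules for raw bedside measurements
#'
#' Rules map raw (numeric or categorical) measurements to the declared
#' discrete states. Threshold rules follow the convention that a value
#' exactly equal to a cutoff falls in the *lower* bin: for a `gt` rule
#' ("abnormal if > cutoff") the cutoff itself is normal; `ge` and `le`
#' rules are provided for the two protocol definitions that are inclusive
#' (age >= 65, cardiac index <= 2.2).
#'
#' @param var target variable name.
#' @param type `"threshold"`, `"map"` or `"any_of"`.
#' @param column raw column consumed (threshold/map rules).
#' @param op for threshold rules: `"gt"`, `"ge"`, `"lt"` or `"le"` — the
#'   comparison that yields the *abnormal* (second) state.
#' @param cutoff numeric cutoff.
#' @param mapping named character vector raw value -> state (map rules).
#' @param conditions for `any_of`: list of sub-conditions, each a list with
#'   `column`, `op` and `value`; the abnormal state is assigned when any
#'   condition holds. `op` may also be `"ne"` (categorical not-equal).
#' @param states two output states, `c(normal, abnormal)`; taken from the
#'   variable spec when omitted.
#' @return a `discretization_rule`.
#' @export
discretization_rule <- function(var, type = c("threshold", "map", "any_of"),
                                column = var, op = "gt", cutoff = NULL,
                                mapping = NULL, conditions = NULL,
                                states = NULL) {
  type <- match.arg(type)
  structure(list(var = var, type = type, column = column, op = op,
                 cutoff = cutoff, mapping = mapping,
                 conditions = conditions, states = states),
            class = "discretization_rule")
}

#' Default discretization rules
#'
#' Shipped conventions for the protocolized bedside examination (editable
#' configuration, not hard-coded constants): tachycardia HR > 100/min; high
#' respiratory rate > 22/min; low SBP < 90 mmHg; low DBP < 60 mmHg; low MAP
#' < 70 mmHg; elevated lactate > 2.0 mmol/L; oliguria < 0.5 mL/kg/h;
#' delayed capillary refill or mottling (dCRT-M) = CRT > 4.5 s at any of
#' knee/sternum/finger OR mottling beyond "none"; high age >= 65 y; cardiac
#' index low when <= 2.2 L/min/m2. Categorical variables map yes/no
#' verbatim.
#'
#' @return named list of [discretization_rule()] objects, keyed by output
#'   variable.
#' @export
default_rules <- function() {
  yn <- c(no = "no", yes = "yes")
  rules <- list(
    discretization_rule("age", "threshold", column = "age_years",
                        op = "ge", cutoff = 65),
    discretization_rule("gender", "map", column = "gender",
                        mapping = c(female = "female", male = "male")),
    discretization_rule("cold_temperature", "map", column = "cold_temperature",
                        mapping = yn),
    discretization_rule("irregular_rhythm", "map", column = "irregular_rhythm",
                        mapping = yn),
    discretization_rule("tachycardia", "threshold", column = "heart_rate",
                        op = "gt", cutoff = 100),
    discretization_rule("high_rr", "threshold", column = "respiratory_rate",
                        op = "gt", cutoff = 22),
    discretization_rule("low_sbp", "threshold", column = "sbp",
                        op = "lt", cutoff = 90),
    discretization_rule("low_dbp", "threshold", column = "dbp",
                        op = "lt", cutoff = 60),
    discretization_rule("low_map", "threshold", column = "map",
                        op = "lt", cutoff = 70),
    discretization_rule("elevated_lactate", "threshold", column = "lactate",
                        op = "gt", cutoff = 2.0),
    discretization_rule("oliguria", "threshold", column = "urine_output",
                        op = "lt", cutoff = 0.5),
    discretization_rule("noradrenaline", "map", column = "noradrenaline",
                        mapping = yn),
    discretization_rule("ventilated", "map", column = "ventilated",
                        mapping = yn),
    discretization_rule("dcrt_m", "any_of", conditions = list(
      list(column = "crt_knee", op = "gt", value = 4.5),
      list(column = "crt_sternum", op = "gt", value = 4.5),
      list(column = "crt_finger", op = "gt", value = 4.5),
      list(column = "mottling", op = "ne", value = "none"))),
    discretization_rule("estimate", "map", column = "estimate",
                        mapping = c(poor = "poor", moderate = "moderate",
                                    reasonable = "reasonable", good = "good")),
    discretization_rule("cardiac_index", "threshold", column = "cardiac_index",
                        op = "le", cutoff = 2.2,
                        states = c("high", "low"))
  )
  stats::setNames(rules, vapply(rules, `[[`, "", "var"))
}

apply_condition <- function(values, op, ref, column) {
  if (op %in% c("gt", "ge", "lt", "le")) {
    v <- suppressWarnings(as.numeric(values))
    if (anyNA(v) & !all(is.na(values))) {
      bad <- which(is.na(v) & !is.na(values))[1]
      if (!is.na(bad)) {
        stop(sprintf("non-numeric value '%s' in raw column '%s'",
                     values[bad], column))
      }
    }
    switch(op, gt = v > ref, ge = v >= ref, lt = v < ref, le = v <= ref)
  } else if (op == "ne") {
    as.character(values) != ref
  } else {
    stop("unknown comparison op: ", op)
  }
}

#' Discretize raw measurements into a cohort
#'
#' Applies a rule set to a raw table of bedside measurements and returns a
#' [as_cohort()] cohort. Deterministic; boundary values fall in the lower
#' bin (see [discretization_rule()]).
#'
#' @param raw data frame of raw measurements; must contain every column a
#'   rule consumes.
#' @param rules named list of rules, defaults to [default_rules()]
#'   restricted to the target variables in `specs`.
#' @param specs variable specs of the output cohort; defaults to the
#'   package set restricted to `names(rules)`.
#' @return a `cohort`.
#' @export
discretize <- function(raw, rules = NULL, specs = NULL) {
  if (is.null(rules)) rules <- default_rules()
  if (is.null(specs)) specs <- default_variable_specs()[names(rules)]
  rules <- rules[names(specs)]
  if (anyNA(names(rules))) {
    stop("no rule for variable(s): ",
         paste(setdiff(names(specs), names(default_rules())), collapse = ", "))
  }
  out <- list()
  for (v in names(rules)) {
    rule <- rules[[v]]
    states <- rule$states %||% specs[[v]]$states
    if (rule$type == "threshold") {
      if (!rule$column %in% names(raw)) {
        stop("raw table lacks column '", rule$column, "'")
      }
      vals <- raw[[rule$column]]
      miss_ok <- specs[[v]]$role == "outcome"
      abn <- apply_condition(vals, rule$op, rule$cutoff, rule$column)
      res <- ifelse(abn, states[2], states[1])
      if (miss_ok) res[is.na(vals)] <- NA
      else if (anyNA(res)) {
        stop(sprintf("missing raw value for '%s' (row %d)",
                     v, which(is.na(res))[1]))
      }
      out[[v]] <- res
    } else if (rule$type == "map") {
      if (!rule$column %in% names(raw)) {
        stop("raw table lacks column '", rule$column, "'")
      }
      vals <- as.character(raw[[rule$column]])
      res <- unname(rule$mapping[vals])
      bad <- which(is.na(res) & !is.na(vals))
      if (length(bad) > 0) {
        stop(sprintf("value '%s' in raw column '%s' outside rule range (row %d)",
                     vals[bad[1]], rule$column, bad[1]))
      }
      out[[v]] <- res
    } else { # any_of
      hits <- rep(FALSE, nrow(raw))
      for (cond in rule$conditions) {
        if (!cond$column %in% names(raw)) {
          stop("raw table lacks column '", cond$column, "'")
        }
        h <- apply_condition(raw[[cond$column]], cond$op, cond$value,
                             cond$column)
        if (anyNA(h)) {
          stop(sprintf("missing raw value in '%s' for composite '%s'",
                       cond$column, v))
        }
        hits <- hits | h
      }
      out[[v]] <- ifelse(hits, states[2], states[1])
    }
  }
  as_cohort(as.data.frame(out, stringsAsFactors = FALSE), specs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cramer's V association between two discrete variables
#'
#' `V = sqrt(chi2 / (n * min(r - 1, c - 1)))` with the Pearson chi-squared
#' statistic on the observed `a` x `b` contingency table (states with zero
#' observed margin are dropped, making V invariant to unobserved declared
#' states). Symmetric in its arguments and bounded in `[0, 1]`.
#'
#' @param cohort a `cohort` (or data frame of factors).
#' @param a,b variable names.
#' @return numeric association strength in `[0, 1]`.
#' @export
cramers_v <- function(cohort, a, b) {
  if (!all(c(a, b) %in% names(cohort))) stop("unknown variable name")
  tab <- table(cohort[[a]], cohort[[b]])
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  if (n < 1) stop("empty cohort")
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("association undefined: a variable has a single observed state")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  sqrt(chi2 / (n * min(nrow(tab) - 1, ncol(tab) - 1)))
}
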
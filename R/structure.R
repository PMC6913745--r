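# Contingency counts over a set of columns of an integer-coded cohort
# (see cohort_codes); returns an array with one dimension per variable,
# first variable fastest. Zero columns -> total count.
joint_counts <- function(cc, cols) {
  if (length(cols) == 0) return(nrow(cc$codes))
  nlev <- cc$nlev[cols]
  idx <- cc$codes[, cols[1]]
  stride <- nlev[[1]]
  for (j in seq_along(cols)[-1]) {
    idx <- idx + (cc$codes[, cols[j]] - 1L) * stride
    stride <- stride * nlev[[j]]
  }
  array(tabulate(idx, nbins = prod(nlev)), dim = nlev)
}

#' Structure-learning parameters
#'
#' @param ess equivalent sample size of the BDeu prior (> 0); default 1.
#' @param alpha significance level of the G2 conditional-independence
#'   tests in the constraint phase; default 0.05.
#' @param max_sx largest conditioning-set size examined by [mmpc()].
#' @return object of class `score_params`.
#' @export
score_params <- function(ess = 1, alpha = 0.05, max_sx = 3) {
  if (ess <= 0) stop("ess must be > 0")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(ess = ess, alpha = alpha, max_sx = as.integer(max_sx)),
            class = "score_params")
}

#' G2 conditional-independence test
#'
#' Log-likelihood-ratio test of `x` independent of `y` given the variables
#' in `z`: `G2 = 2 * sum O * ln(O / E)` over the `x` by `y` table within
#' each configuration of `z` (empty cells contribute 0). Degrees of
#' freedom are `(r_x - 1) (r_y - 1)` times the number of `z`
#' configurations with a nonzero total; the p-value is the upper
#' chi-squared tail.
#'
#' @param cohort a `cohort`.
#' @param x,y variable names (`x != y`).
#' @param z character vector of conditioning variables (may be empty).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
g2_test <- function(cohort, x, y, z = character(0)) {
  if (x == y || x %in% z || y %in% z) {
    stop("x, y and z must be distinct variables")
  }
  cc <- cohort_codes(cohort, c(x, y, z))
  if (nrow(cc$codes) == 0) stop("empty cohort")
  g2_test_codes(cc, 1L, 2L, seq_along(z) + 2L)
}

# core test on pre-coded data; x, y, z are column indices into cc$codes.
g2_test_codes <- function(cc, x, y, z) {
  cols <- colnames(cc$codes)[c(x, y, z)]
  counts <- joint_counts(cc, cols)
  rx <- cc$nlev[[cols[1]]]
  ry <- cc$nlev[[cols[2]]]
  q <- length(counts) / (rx * ry)
  n3 <- array(counts, c(rx, ry, q))
  tz <- colSums(matrix(n3, rx * ry, q))
  rowx <- colSums(aperm(n3, c(2, 1, 3)))            # rx x q
  coly <- colSums(n3)                               # ry x q
  e <- array(0, dim(n3))
  nz <- which(tz > 0)
  for (s in nz) e[, , s] <- outer(rowx[, s], coly[, s]) / tz[s]
  pos <- n3 > 0
  stat <- 2 * sum(n3[pos] * log(n3[pos] / e[pos]))
  df <- (rx - 1) * (ry - 1) * length(nz)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' BDeu local score
#'
#' Log marginal likelihood contribution of one node given a parent set
#' under the Bayesian-Dirichlet equivalent uniform prior:
#' `sum_j [lgamma(a_j) - lgamma(a_j + N_j) +
#'  sum_k (lgamma(a_jk + N_jk) - lgamma(a_jk))]` with `a_j = ess / q` and
#' `a_jk = ess / (r q)` over `r` child states and `q` parent
#' configurations. Decomposable and identical across Markov-equivalent
#' structures.
#'
#' @param cohort a `cohort`.
#' @param child child variable name.
#' @param parents character vector of parent names (may be empty).
#' @param ess equivalent sample size (> 0).
#' @return finite numeric log score.
#' @export
bdeu_local <- function(cohort, child, parents = character(0), ess = 1) {
  cc <- cohort_codes(cohort, c(child, parents))
  bdeu_local_codes(cc, child, parents, ess)
}

bdeu_local_codes <- function(cc, child, parents, ess) {
  counts <- joint_counts(cc, c(child, parents))
  r <- cc$nlev[[child]]
  m <- matrix(counts, nrow = r)
  q <- ncol(m)
  aj <- ess / q
  ajk <- ess / (r * q)
  nj <- colSums(m)
  sum(lgamma(aj) - lgamma(aj + nj)) + sum(lgamma(ajk + m) - lgamma(ajk))
}

#' Total BDeu score of a DAG
#'
#' Sum of [bdeu_local()] terms over all nodes; decomposable, so changing
#' one node's parent set changes only that node's term.
#'
#' @param dag a [dag()] whose nodes are cohort variables.
#' @param cohort a `cohort`.
#' @param ess equivalent sample size.
#' @return numeric log score.
#' @export
score_dag <- function(dag, cohort, ess = 1) {
  cc <- cohort_codes(cohort, dag$nodes)
  sum(vapply(dag$nodes, function(v) {
    bdeu_local_codes(cc, v, dag_parents(dag, v), ess)
  }, numeric(1)))
}

#' Max-Min Parents-Children candidate sets
#'
#' Constraint phase of the Max-Min Hill-Climbing learner. For each target
#' the candidate parent-children set grows by repeatedly admitting the
#' variable whose *minimum* association with the target — the largest G2
#' p-value over all subsets (up to `max_sx`) of the current candidate set —
#' is strongest, until no remaining variable is dependent at level
#' `alpha`; a backward pass removes members that are conditionally
#' independent of the target given some subset of the others. The
#' symmetry correction keeps `x` in `cpc(t)` only when `t` is in
#' `cpc(x)`. Pairs blacklisted in both directions are never candidates;
#' whitelisted arcs are always included.
#'
#' @param cohort a nonempty `cohort`.
#' @param params a [score_params()].
#' @param constraints a [constraint_set()].
#' @param nodes variables to analyse (defaults to all cohort columns).
#' @return named list: candidate parent-children set per node.
#' @export
mmpc <- function(cohort, params = score_params(),
                 constraints = constraint_set(), nodes = names(cohort)) {
  if (nrow(cohort) == 0) stop("empty cohort")
  cc <- cohort_codes(cohort, nodes)
  cache <- new.env(parent = emptyenv())
  pval <- function(x, t, s) {
    key <- paste(c(sort(c(x, t)), "|", sort(s)), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    p <- g2_test_codes(cc, match(x, nodes), match(t, nodes),
                       match(s, nodes))$p_value
    cache[[key]] <- p
    p
  }
  subsets_of <- function(set, kmax) {
    out <- list(character(0))
    for (k in seq_len(min(length(set), kmax))) {
      cmb <- utils::combn(set, k, simplify = FALSE)
      out <- c(out, cmb)
    }
    out
  }
  max_pval <- function(x, t, cpc) {
    m <- 0
    for (s in subsets_of(cpc, params$max_sx)) {
      p <- pval(x, t, s)
      if (p > m) m <- p
      if (m > params$alpha) break   # already independent for some subset
    }
    m
  }
  cpc <- stats::setNames(vector("list", length(nodes)), nodes)
  for (t in nodes) {
    forced <- nodes[vapply(nodes, function(x) {
      x != t && (whitelisted(constraints, x, t) ||
                 whitelisted(constraints, t, x))
    }, TRUE)]
    pool <- setdiff(nodes, c(t, forced))
    pool <- pool[!vapply(pool, function(x) {
      blacklisted(constraints, x, t) && blacklisted(constraints, t, x)
    }, TRUE)]
    set <- forced
    repeat {
      if (length(pool) == 0) break
      mp <- vapply(pool, max_pval, numeric(1), t = t, cpc = set)
      drop <- pool[mp > params$alpha]
      pool <- setdiff(pool, drop)
      if (length(pool) == 0) break
      mp <- mp[pool]
      best <- pool[which.min(mp)]
      set <- c(set, best)
      pool <- setdiff(pool, best)
    }
    # backward: shrink members now separable given the final set
    for (x in setdiff(set, forced)) {
      others <- setdiff(set, x)
      if (max_pval(x, t, others) > params$alpha) set <- setdiff(set, x)
    }
    cpc[[t]] <- sort(set)
  }
  for (t in nodes) {   # symmetry correction
    keep <- vapply(cpc[[t]], function(x) {
      t %in% cpc[[x]] ||
        whitelisted(constraints, x, t) || whitelisted(constraints, t, x)
    }, TRUE)
    cpc[[t]] <- cpc[[t]][keep]
  }
  cpc
}

#' Greedy hill climbing under the BDeu score
#'
#' Score-based search over DAG space starting from the whitelist-only
#' graph. Each step applies the single arc addition, deletion or reversal
#' with the largest strictly positive BDeu gain among moves that preserve
#' acyclicity, respect the blacklist, never delete or reverse whitelisted
#' arcs, and (when a candidate restriction map from [mmpc()] is supplied)
#' only add arcs between candidate neighbours. Ties break on the first
#' move in a fixed lexicographic enumeration (sorted node names; additions
#' before deletions before reversals), so the search is deterministic.
#'
#' @param cohort a nonempty `cohort`.
#' @param constraints a [constraint_set()].
#' @param candidates optional named list (node -> allowed neighbours).
#' @param params a [score_params()].
#' @param nodes variables to model (defaults to all cohort columns).
#' @param max_iter safety cap on greedy steps.
#' @return a [dag()], a local optimum of the BDeu score.
#' @export
hill_climb <- function(cohort, constraints = constraint_set(),
                       candidates = NULL, params = score_params(),
                       nodes = names(cohort), max_iter = 1000L) {
  if (nrow(cohort) == 0) stop("empty cohort")
  nodes <- sort(nodes)
  cc <- cohort_codes(cohort, nodes)
  cache <- new.env(parent = emptyenv())
  lscore <- function(child, parents) {
    key <- paste(c(child, sort(parents)), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    s <- bdeu_local_codes(cc, child, parents, params$ess)
    cache[[key]] <- s
    s
  }
  wl <- constraints$whitelist
  wl <- wl[wl[, 1] %in% nodes & wl[, 2] %in% nodes, , drop = FALSE]
  pa <- stats::setNames(lapply(nodes, function(v) {
    sort(wl[wl[, 2] == v, 1])
  }), nodes)
  if (is.null(try_topo_sort(list(nodes = nodes, arcs = wl)))) {
    stop("whitelist is cyclic")
  }
  cur <- vapply(nodes, function(v) lscore(v, pa[[v]]), numeric(1))
  may_add <- function(x, y) {
    if (blacklisted(constraints, x, y)) return(FALSE)
    if (!is.null(candidates) && !whitelisted(constraints, x, y) &&
        !(x %in% candidates[[y]])) {
      return(FALSE)
    }
    TRUE
  }
  arcs_of <- function(pa) {
    do.call(rbind, c(list(matrix(character(0), ncol = 2)),
                     lapply(nodes, function(v) {
                       if (length(pa[[v]])) cbind(pa[[v]], v)
                     })))
  }
  for (iter in seq_len(max_iter)) {
    arcs <- arcs_of(pa)
    ch <- children_list(nodes, arcs)
    best_gain <- 0
    best <- NULL
    for (x in nodes) for (y in nodes) {
      if (x == y) next
      if (x %in% pa[[y]]) next
      if (y %in% pa[[x]]) next   # would be a reversal, handled below
      if (!may_add(x, y)) next
      if (reachable(ch, y, x)) next
      gain <- lscore(y, c(pa[[y]], x)) - cur[[y]]
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(op = "add", x = x, y = y)
      }
    }
    for (x in nodes) for (y in nodes) {
      if (!(x %in% pa[[y]])) next
      if (whitelisted(constraints, x, y)) next
      gain <- lscore(y, setdiff(pa[[y]], x)) - cur[[y]]
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(op = "delete", x = x, y = y)
      }
    }
    for (x in nodes) for (y in nodes) {
      if (!(x %in% pa[[y]])) next
      if (whitelisted(constraints, x, y)) next
      if (blacklisted(constraints, y, x)) next
      if (!is.null(candidates) && !(y %in% candidates[[x]])) next
      ch2 <- children_list(nodes, arcs[!(arcs[, 1] == x & arcs[, 2] == y), ,
                                       drop = FALSE])
      if (reachable(ch2, x, y)) next
      gain <- (lscore(y, setdiff(pa[[y]], x)) - cur[[y]]) +
        (lscore(x, c(pa[[x]], y)) - cur[[x]])
      if (gain > best_gain + 1e-12) {
        best_gain <- gain
        best <- list(op = "reverse", x = x, y = y)
      }
    }
    if (is.null(best)) break
    if (best$op == "add") {
      pa[[best$y]] <- sort(c(pa[[best$y]], best$x))
    } else if (best$op == "delete") {
      pa[[best$y]] <- setdiff(pa[[best$y]], best$x)
    } else {
      pa[[best$y]] <- setdiff(pa[[best$y]], best$x)
      pa[[best$x]] <- sort(c(pa[[best$x]], best$y))
      cur[[best$x]] <- lscore(best$x, pa[[best$x]])
    }
    cur[[best$y]] <- lscore(best$y, pa[[best$y]])
  }
  dag(nodes, arcs_of(pa))
}

#' Max-Min Hill-Climbing structure learning
#'
#' Hybrid learner: [mmpc()] restricts the neighbourhood of each node via
#' G2 conditional-independence tests, then [hill_climb()] searches the
#' restricted DAG space for the BDeu optimum under the black/whitelists.
#'
#' @inheritParams hill_climb
#' @return a [dag()].
#' @export
mmhc <- function(cohort, params = score_params(),
                 constraints = constraint_set(), nodes = names(cohort)) {
  cand <- mmpc(cohort, params, constraints, nodes)
  hill_climb(cohort, constraints, candidates = cand, params = params,
             nodes = nodes)
}
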
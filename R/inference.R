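# Internal factor algebra backing exact inference. A factor is a
# flat-vector potential over a set of discrete variables, column-major with
# vars[1] fastest, mirroring R array layout.

new_factor <- function(vars, levels, vals) {
  dim <- vapply(levels, length, integer(1))
  stopifnot(length(vals) == prod(dim))
  list(vars = vars, dim = dim, levels = levels, vals = as.numeric(vals))
}

cpt_factor <- function(prob) {
  dn <- dimnames(prob)
  new_factor(names(dn), dn, as.vector(prob))
}

f_reduce <- function(f, var, state) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  k <- match(state, f$levels[[pos]])
  if (is.na(k)) stop(sprintf("unknown state '%s' for variable '%s'",
                             state, var))
  idx <- as.list(rep(TRUE, length(f$vars)))
  a <- array(f$vals, f$dim)
  sliced <- do.call(`[`, c(list(a), replace(idx, pos, k), drop = FALSE))
  keep <- setdiff(seq_along(f$vars), pos)
  new_factor(f$vars[keep], f$levels[keep], as.vector(sliced))
}

f_marginalize <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  keep <- setdiff(seq_along(f$vars), pos)
  a <- array(f$vals, f$dim)
  p <- aperm(a, c(pos, keep))
  vals <- colSums(matrix(p, f$dim[pos], prod(f$dim[keep])))
  new_factor(f$vars[keep], f$levels[keep], vals)
}

f_product <- function(f1, f2) {
  vars <- c(f1$vars, setdiff(f2$vars, f1$vars))
  levels <- c(f1$levels, f2$levels[setdiff(f2$vars, f1$vars)])
  dim <- vapply(levels, length, integer(1))
  n <- prod(dim)
  cells <- seq_len(n) - 1L
  strides <- c(1, cumprod(dim))[seq_along(dim)]
  coord <- function(k) (cells %/% strides[k]) %% dim[k]
  lin_index <- function(f) {
    if (length(f$vars) == 0) return(rep(1L, n))
    idx <- rep(1, n)
    fs <- c(1, cumprod(f$dim))[seq_along(f$dim)]
    for (j in seq_along(f$vars)) {
      idx <- idx + coord(match(f$vars[j], vars)) * fs[j]
    }
    idx
  }
  new_factor(vars, levels, f1$vals[lin_index(f1)] * f2$vals[lin_index(f2)])
}

# Sum-product variable elimination with a min-width greedy order.
# Returns an unnormalized factor over `keep`.
ve_eliminate <- function(factors, keep) {
  elim <- setdiff(unique(unlist(lapply(factors, `[[`, "vars"))), keep)
  while (length(elim) > 0) {
    width <- vapply(elim, function(v) {
      involved <- factors[vapply(factors, function(f) v %in% f$vars, TRUE)]
      prod(vapply(unique(unlist(lapply(involved, `[[`, "vars"))), function(u) {
        for (f in involved) if (u %in% f$vars) {
          return(f$dim[[match(u, f$vars)]])
        }
      }, numeric(1)))
    }, numeric(1))
    v <- elim[which.min(width)]
    hit <- vapply(factors, function(f) v %in% f$vars, TRUE)
    prod_f <- Reduce(f_product, factors[hit])
    factors <- c(factors[!hit], list(f_marginalize(prod_f, v)))
    elim <- setdiff(elim, v)
  }
  Reduce(f_product, factors)
}

reduce_all <- function(factors, evidence) {
  for (v in names(evidence)) {
    factors <- lapply(factors, f_reduce, var = v, state = evidence[[v]])
  }
  factors
}

#' Conditional probability tables and Bayesian networks
#'
#' A CPT is stored as a probability array whose first dimension is the
#' child variable and remaining dimensions are its parents; `dimnames` are
#' fully named (variable names) and every column (child distribution given
#' one parent configuration) sums to 1. `bayes_net()` bundles a [dag()]
#' with one CPT per node and validates that each CPT's parents equal the
#' node's graph parents.
#'
#' @param child,parents variable names.
#' @param levels named list of state labels covering child and parents.
#' @param prob numeric array/matrix of probabilities, child states varying
#'   fastest (an `r x q` matrix of `q` parent configurations in
#'   column-major parent order is accepted).
#' @return `make_cpt()` returns a probability array; `bayes_net()` an
#'   object of class `bayes_net` with elements `dag` and `cpts`.
#' @export
make_cpt <- function(child, parents, levels, prob) {
  dims <- c(length(levels[[child]]),
            vapply(levels[parents], length, integer(1)))
  prob <- array(as.numeric(prob), dim = dims,
                dimnames = stats::setNames(c(levels[child], levels[parents]),
                                           c(child, parents)))
  check_cpt(prob, child)
  prob
}

check_cpt <- function(prob, child) {
  if (any(prob < 0)) stop("negative probability in CPT of ", child)
  m <- matrix(prob, nrow = dim(prob)[1])
  sums <- colSums(m)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("CPT rows of ", child, " do not sum to 1")
  }
  invisible(prob)
}

#' @param dag a [dag()].
#' @param cpts named list of CPT arrays (one per node).
#' @rdname make_cpt
#' @export
bayes_net <- function(dag, cpts) {
  if (!setequal(names(cpts), dag$nodes)) {
    stop("need exactly one CPT per node")
  }
  for (node in dag$nodes) {
    dn <- names(dimnames(cpts[[node]]))
    if (dn[1] != node) stop("first CPT dimension of ", node, " must be itself")
    if (!setequal(dn[-1], dag_parents(dag, node))) {
      stop("CPT parents of ", node, " do not match the DAG")
    }
    check_cpt(cpts[[node]], node)
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes]), class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  cat("bayes_net:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$arcs), "arcs\n")
  invisible(x)
}

bn_levels <- function(bn) {
  lapply(bn$cpts, function(p) dimnames(p)[[1]])
}

check_evidence <- function(bn, evidence, target = NULL) {
  evidence <- as.list(evidence)
  if (length(evidence) == 0) return(evidence)
  lv <- bn_levels(bn)
  for (v in names(evidence)) {
    if (!v %in% bn$dag$nodes) stop("evidence variable not in network: ", v)
    if (!evidence[[v]] %in% lv[[v]]) {
      stop(sprintf("invalid state '%s' for evidence variable '%s'",
                   evidence[[v]], v))
    }
  }
  if (!is.null(target) && target %in% names(evidence)) {
    stop("target variable may not appear in the evidence")
  }
  evidence
}

#' Fit conditional probability tables on a fixed structure
#'
#' Maximum-posterior CPT estimation with a Dirichlet pseudocount: each row
#' is `(N_jk + pseudocount) / (N_j + r * pseudocount)` where `r` is the
#' number of child states. The default pseudocount of 1 (Laplace) keeps all
#' probabilities strictly positive, as exact belief propagation requires.
#'
#' @param dag a [dag()] whose nodes are cohort variables.
#' @param cohort a `cohort`, complete on the DAG's nodes.
#' @param pseudocount nonnegative Dirichlet pseudocount per CPT cell.
#' @return a [bayes_net()].
#' @export
fit_cpts <- function(dag, cohort, pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  cc <- cohort_codes(cohort, dag$nodes)
  if (anyNA(cc$codes)) stop("cohort must be complete on the network's nodes")
  cpts <- list()
  for (node in dag$nodes) {
    parents <- dag_parents(dag, node)
    counts <- joint_counts(cc, c(node, parents))
    r <- cc$nlev[[node]]
    m <- matrix(counts, nrow = r)
    nj <- colSums(m)
    if (pseudocount == 0 && any(nj == 0)) {
      stop("unobserved parent configuration for '", node,
           "' with pseudocount 0: CPT row undefined")
    }
    prob <- sweep(m + pseudocount, 2, nj + r * pseudocount, "/")
    cpts[[node]] <- make_cpt(node, parents, cc$levels, prob)
  }
  bayes_net(dag, cpts)
}

#' Exact conditional queries by variable elimination
#'
#' `posterior()` computes the exact conditional distribution of `target`
#' given the evidence by sum-product variable elimination over the
#' network's factorized joint; `evidence_probability()` returns the exact
#' joint probability of an evidence assignment; `joint_marginal()` the
#' exact joint distribution of a small set of variables.
#'
#' @param bn a [bayes_net()].
#' @param target target variable name.
#' @param evidence named list/vector `variable = state`; must have positive
#'   probability.
#' @return `posterior()`: named probability vector over the target's
#'   states, summing to 1.
#' @export
posterior <- function(bn, target, evidence = list()) {
  if (!target %in% bn$dag$nodes) stop("unknown target variable: ", target)
  evidence <- check_evidence(bn, evidence, target)
  factors <- reduce_all(lapply(bn$cpts, cpt_factor), evidence)
  res <- ve_eliminate(factors, target)
  z <- sum(res$vals)
  if (!is.finite(z) || z <= 0) {
    stop("evidence has zero probability under the network")
  }
  stats::setNames(res$vals / z, res$levels[[match(target, res$vars)]])
}

#' @rdname posterior
#' @export
evidence_probability <- function(bn, evidence) {
  evidence <- check_evidence(bn, evidence)
  if (length(evidence) == 0) return(1)
  factors <- reduce_all(lapply(bn$cpts, cpt_factor), evidence)
  sum(ve_eliminate(factors, character(0))$vals)
}

#' @param vars variable names (joint marginal).
#' @rdname posterior
#' @export
joint_marginal <- function(bn, vars) {
  factors <- lapply(bn$cpts, cpt_factor)
  res <- ve_eliminate(factors, vars)
  a <- array(res$vals / sum(res$vals), res$dim,
             dimnames = stats::setNames(res$levels, res$vars))
  if (length(vars) > 1) aperm(a, vars) else a
}

#' Sequential conditional-probability query trees
#'
#' Enumerates every state path over an ordered list of evidence variables
#' and records, at each node, the accumulated evidence, its exact joint
#' probability, the branch probability given the parent's evidence, and
#' the conditional distribution of the target — the tree-diagram view of
#' how the estimate distribution shifts as bedside information accrues.
#'
#' @param bn a [bayes_net()].
#' @param target target variable.
#' @param vars ordered character vector of evidence variables (may be
#'   empty; must not contain the target).
#' @return a `query_tree`: data frame with columns `id`, `parent`, `depth`,
#'   `var`, `state`, `evidence`, `prob` (joint probability of the
#'   accumulated evidence), `branch_prob`, and one `p_<state>` column per
#'   target state.
#' @export
query_tree <- function(bn, target, vars = character(0)) {
  if (target %in% vars) stop("target may not be part of the evidence order")
  if (!all(vars %in% bn$dag$nodes)) stop("unknown evidence variable")
  lv <- bn_levels(bn)
  tstates <- lv[[target]]
  rows <- list()
  nid <- 0L
  expand <- function(ev, parent_id, depth, var, state, prob, branch) {
    nid <<- nid + 1L
    id <- nid
    dist <- posterior(bn, target, ev)
    row <- data.frame(id = id, parent = parent_id, depth = depth,
                      var = var, state = state,
                      evidence = paste(names(ev), unlist(ev), sep = "=",
                                       collapse = ";"),
                      prob = prob, branch_prob = branch,
                      stringsAsFactors = FALSE)
    for (s in tstates) row[[paste0("p_", s)]] <- unname(dist[s])
    rows[[id]] <<- row
    if (depth < length(vars)) {
      v <- vars[depth + 1]
      bp <- posterior(bn, v, ev)
      for (s in lv[[v]]) {
        if (bp[s] <= 0) next  # impossible branch: no subtree
        expand(c(ev, stats::setNames(list(s), v)), id, depth + 1L,
               v, s, prob * unname(bp[s]), unname(bp[s]))
      }
    }
  }
  expand(list(), 0L, 0L, "", "", 1, 1)
  out <- do.call(rbind, rows)
  structure(out, target = target, vars = vars, states = tstates,
            class = c("query_tree", "data.frame"))
}

#' @rdname query_tree
#' @param tree a `query_tree`.
#' @param path output CSV path.
#' @export
write_query_tree_csv <- function(tree, path) {
  utils::write.csv(as.data.frame(tree), path, row.names = FALSE)
  invisible(path)
}

#' Ancestral sampling from a Bayesian network
#'
#' Draws i.i.d. records by sampling each node given its parents in
#' topological order. Reproducible for a fixed seed.
#'
#' @param bn a [bayes_net()].
#' @param n number of records (>= 0).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a `cohort` with one factor column per network node.
#' @export
ancestral_sample <- function(bn, n, seed = NULL) {
  draw <- function() {
    ord <- topo_sort(bn$dag)
    lv <- bn_levels(bn)
    codes <- matrix(0L, nrow = n, ncol = length(ord),
                    dimnames = list(NULL, ord))
    for (node in ord) {
      prob <- bn$cpts[[node]]
      parents <- names(dimnames(prob))[-1]
      r <- dim(prob)[1]
      q <- prod(dim(prob)) / r
      pm <- matrix(prob, nrow = r)
      cdf <- apply(pm, 2, cumsum)           # r x q
      if (length(parents) == 0) {
        cfg <- rep(1L, n)
      } else {
        pd <- vapply(parents, function(p) length(lv[[p]]), integer(1))
        strides <- c(1, cumprod(pd))[seq_along(pd)]
        cfg <- rep(1L, n)
        for (j in seq_along(parents)) {
          cfg <- cfg + (codes[, parents[j]] - 1L) * as.integer(strides[j])
        }
      }
      u <- stats::runif(n)
      cmp <- matrix(cdf[, cfg], nrow = r)   # r x n
      codes[, node] <- 1L + colSums(cmp < rep(u, each = r))
    }
    df <- as.data.frame(lapply(stats::setNames(ord, ord), function(v) {
      factor(lv[[v]][codes[, v]], levels = lv[[v]])
    }), check.names = FALSE)
    as_cohort(df, specs_from_levels(lv[ord]))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

specs_from_levels <- function(levels) {
  specs <- lapply(names(levels), function(v) {
    role <- if (v == "estimate" &&
                identical(levels[[v]],
                          c("poor", "moderate", "reasonable", "good"))) {
      "estimate"
    } else if (v == "cardiac_index" &&
               identical(levels[[v]], c("low", "high"))) {
      "outcome"
    } else "clinical"
    variable_spec(v, levels[[v]], role)
  })
  stats::setNames(specs, names(levels))
}

#' Predict the estimate for one patient record
#'
#' Returns the exact posterior distribution of the target given a patient
#' record. Because the record covers (at least) the target's Markov
#' blanket, the prediction is invariant to any variable outside the
#' blanket.
#'
#' @param bn a [bayes_net()].
#' @param record named list/vector of observed states; must cover the
#'   Markov blanket of `target`. Entries for unknown variables or `NA`
#'   values are ignored.
#' @param target predicted variable, default `"estimate"`.
#' @return named probability vector over the target's states.
#' @export
predict_estimate <- function(bn, record, target = "estimate") {
  record <- as.list(record)
  record <- record[!vapply(record, function(x) is.null(x) || is.na(x), TRUE)]
  record <- record[intersect(names(record), setdiff(bn$dag$nodes, target))]
  mb <- markov_blanket(bn$dag, target)
  if (!all(mb %in% names(record))) {
    stop("record must cover the Markov blanket of '", target, "': missing ",
         paste(setdiff(mb, names(record)), collapse = ", "))
  }
  posterior(bn, target, record)
}

#' Round-trip JSON serialization of a Bayesian network
#'
#' Stores nodes (in topological order), arcs, state lists and flattened CPT
#' values; `read_bn_json()` reconstructs an identical network.
#'
#' @param bn a [bayes_net()].
#' @param path file path.
#' @export
write_bn_json <- function(bn, path) {
  ord <- topo_sort(bn$dag)
  nodes <- lapply(ord, function(v) {
    prob <- bn$cpts[[v]]
    list(name = v,
         parents = I(names(dimnames(prob))[-1]),
         states = I(dimnames(prob)[[1]]),
         parent_states = lapply(dimnames(prob)[-1], I),
         prob = I(as.vector(prob)))
  })
  jsonlite::write_json(list(nodes = nodes), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_bn_json
#' @export
read_bn_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cpts <- list()
  arcs <- NULL
  for (nd in doc$nodes) {
    parents <- as.character(unlist(nd$parents))
    levels <- c(stats::setNames(list(as.character(nd$states)), nd$name),
                lapply(nd$parent_states, as.character))
    cpts[[nd$name]] <- make_cpt(nd$name, parents, levels,
                                as.numeric(unlist(nd$prob)))
    if (length(parents) > 0) arcs <- rbind(arcs, cbind(parents, nd$name))
  }
  bayes_net(dag(names(cpts), arcs), cpts)
}
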
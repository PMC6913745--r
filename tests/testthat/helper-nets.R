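# shared fixtures: toy cohorts, random networks, and an independent
# brute-force inference oracle (full-joint enumeration via expand.grid and
# direct CPT lookups -- no shared code with the variable-elimination path).

toy_cohort <- function(df) {
  df <- as.data.frame(lapply(df, function(x) {
    if (is.factor(x)) x else factor(x)
  }), stringsAsFactors = FALSE)
  specs <- stats::setNames(lapply(names(df), function(v) {
    variable_spec(v, levels(df[[v]]))
  }), names(df))
  as_cohort(df, specs)
}

# cohort from explicit 2x2 counts of two binary variables
counts_cohort <- function(counts, a = "a", b = "b",
                          states_a = c("a1", "a2"), states_b = c("b1", "b2")) {
  rows <- NULL
  for (i in 1:2) for (j in 1:2) {
    k <- counts[i, j]
    if (k > 0) {
      rows <- rbind(rows, data.frame(x = rep(states_a[i], k),
                                     y = rep(states_b[j], k)))
    }
  }
  names(rows) <- c(a, b)
  rows[[a]] <- factor(rows[[a]], levels = states_a)
  rows[[b]] <- factor(rows[[b]], levels = states_b)
  toy_cohort(rows)
}

# random binary network with ~40% arc density and interior probabilities
rand_binary_net <- function(k) {
  nodes <- paste0("v", seq_len(k))
  arcs <- NULL
  if (k >= 2) {
    for (i in 2:k) for (j in 1:(i - 1)) {
      if (stats::runif(1) < 0.4) arcs <- rbind(arcs, c(nodes[j], nodes[i]))
    }
  }
  g <- dag(nodes, arcs)
  lv <- lapply(stats::setNames(nodes, nodes), function(v) c("s1", "s2"))
  cpts <- lapply(stats::setNames(nodes, nodes), function(v) {
    pa <- dag_parents(g, v)
    q <- 2^length(pa)
    p <- matrix(stats::runif(2 * q) + 0.05, 2)
    p <- sweep(p, 2, colSums(p), "/")
    make_cpt(v, pa, lv, p)
  })
  bayes_net(g, cpts)
}

# independent oracle: full-joint enumeration by direct CPT lookup
enum_joint <- function(bn) {
  lv <- lapply(bn$cpts, function(p) dimnames(p)[[1]])
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  w <- rep(1, nrow(grid))
  for (node in bn$dag$nodes) {
    cpt <- bn$cpts[[node]]
    vars <- names(dimnames(cpt))
    for (r in seq_len(nrow(grid))) {
      idx <- as.list(unlist(grid[r, vars, drop = FALSE]))
      w[r] <- w[r] * do.call(`[`, c(list(cpt), idx))
    }
  }
  cbind(grid, p = w)
}

enum_posterior <- function(bn, target, evidence = list()) {
  j <- enum_joint(bn)
  keep <- rep(TRUE, nrow(j))
  for (v in names(evidence)) keep <- keep & j[[v]] == evidence[[v]]
  j <- j[keep, , drop = FALSE]
  tapply(j$p, factor(j[[target]], levels = dimnames(bn$cpts[[target]])[[1]]),
         sum) / sum(j$p)
}

# simulated chain x -> w -> y with strong links
chain_cohort <- function(n, p_flip = 0.15) {
  x <- sample(c("no", "yes"), n, replace = TRUE)
  w <- ifelse(stats::runif(n) < p_flip, sample(c("no", "yes"), n, TRUE), x)
  y <- ifelse(stats::runif(n) < p_flip, sample(c("no", "yes"), n, TRUE), w)
  toy_cohort(data.frame(x = factor(x, c("no", "yes")),
                        w = factor(w, c("no", "yes")),
                        y = factor(y, c("no", "yes"))))
}

# all 25 DAGs on 3 labelled nodes, for exhaustive-score oracles
all_dags_3 <- function(nodes) {
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s1 in 0:2) for (s2 in 0:2) for (s3 in 0:2) {
    arcs <- NULL
    for (k in 1:3) {
      s <- c(s1, s2, s3)[k]
      if (s == 1) arcs <- rbind(arcs, nodes[pairs[[k]]])
      if (s == 2) arcs <- rbind(arcs, nodes[rev(pairs[[k]])])
    }
    g <- tryCatch(dag(nodes, arcs), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1]] <- g
  }
  out
}

modelled_cohort <- function(cohort) {
  vars <- setdiff(names(cohort), "cardiac_index")
  as_cohort(as.data.frame(cohort)[vars],
            attr(cohort, "specs")[vars])
}
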
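#' Bootstrap arc confidence
#'
#' Nonparametric bootstrap model averaging: `replicates` resamples of the
#' cohort (rows drawn with replacement) are each passed through [mmhc()],
#' and every unordered node pair receives a *strength* — the fraction of
#' replicate DAGs containing the pair in either orientation — and a
#' *direction* coefficient — among replicates containing the pair, the
#' fraction oriented `from -> to` (conditional convention). All unordered
#' pairs are reported, absent ones with strength 0, so the strength
#' universe is well defined for [significance_threshold()].
#'
#' @param cohort a nonempty `cohort`.
#' @param replicates number of bootstrap resamples (>= 1); the study-scale
#'   value is 2000, desk-scale runs use fewer.
#' @param seed integer seed for reproducible resampling.
#' @param params a [score_params()].
#' @param constraints a [constraint_set()].
#' @param nodes variables to model (defaults to all cohort columns).
#' @return an `arc_confidence` data frame with columns `from`, `to`,
#'   `strength`, `direction`, rows ordered so `direction >= 0.5`
#'   (`direction` is `NA` for pairs never observed).
#' @export
bootstrap_confidence <- function(cohort, replicates = 200, seed = 1,
                                 params = score_params(),
                                 constraints = constraint_set(),
                                 nodes = names(cohort)) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (nrow(cohort) == 0) stop("empty cohort")
  nodes <- sort(nodes)
  k <- length(nodes)
  pres <- matrix(0, k, k, dimnames = list(nodes, nodes))  # oriented counts
  run <- function() {
    n <- nrow(cohort)
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- cohort[idx, , drop = FALSE]
      attr(boot, "specs") <- attr(cohort, "specs")
      class(boot) <- class(cohort)
      g <- tryCatch(mmhc(boot, params, constraints, nodes),
                    error = function(e) {
                      stop("structure learning failed in bootstrap replicate ",
                           r, ": ", conditionMessage(e))
                    })
      for (i in seq_len(nrow(g$arcs))) {
        pres[g$arcs[i, 1], g$arcs[i, 2]] <<- pres[g$arcs[i, 1],
                                                  g$arcs[i, 2]] + 1
      }
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    a <- nodes[i]; b <- nodes[j]
    nab <- pres[a, b]; nba <- pres[b, a]
    strength <- (nab + nba) / replicates
    if (nab + nba == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        from = a, to = b, strength = 0, direction = NA_real_,
        stringsAsFactors = FALSE)
    } else {
      dir_ab <- nab / (nab + nba)
      if (dir_ab >= 0.5) {
        rows[[length(rows) + 1]] <- data.frame(
          from = a, to = b, strength = strength, direction = dir_ab,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          from = b, to = a, strength = strength, direction = 1 - dir_ab,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  structure(out, replicates = replicates,
            class = c("arc_confidence", "data.frame"))
}

#' Data-driven significance threshold for arc strengths
#'
#' L1-optimal cutpoint on the empirical distribution of bootstrap arc
#' strengths: with `Fhat` the empirical CDF of the strengths over `[0, 1)`,
#' the constant level `t*` minimizing the integral of `|Fhat(x) - t|` is
#' the length-weighted median of `Fhat`'s step values, and the returned
#' threshold is the generalized empirical quantile
#' `inf{ x : Fhat(x) >= t* }`. Arcs *strictly above* the returned value
#' count as significant.
#'
#' @param strengths numeric vector of strengths in `[0, 1]` (nonempty).
#' @return threshold in `[0, 1]`.
#' @export
significance_threshold <- function(strengths) {
  if (length(strengths) == 0) stop("empty strength list")
  if (any(strengths < 0 | strengths > 1)) stop("strengths must be in [0, 1]")
  s <- sort(unique(strengths))
  # step heights of Fhat and interval lengths over [0, 1)
  knots <- unique(c(0, s[s < 1], 1))
  lengths <- diff(knots)
  heights <- vapply(knots[-length(knots)], function(x) mean(strengths <= x),
                    numeric(1))
  ord <- order(heights)
  cum <- cumsum(lengths[ord])
  tstar <- heights[ord][which(cum >= sum(lengths) / 2)[1]]
  cand <- c(0, s)
  fhat <- vapply(cand, function(x) mean(strengths <= x), numeric(1))
  cand[which(fhat >= tstar)[1]]
}

#' Thresholded consensus graph
#'
#' Builds the consensus (model-averaged) graph from a bootstrap confidence
#' table. The effective strength threshold is the larger of the
#' data-driven [significance_threshold()] and the configured floor
#' (default 0.700); edges strictly above it are retained. A retained edge
#' is directed toward the orientation whose direction coefficient is at
#' least `direction_threshold` (default 0.666) and left undirected
#' otherwise. A cycle among the retained directed arcs is reported as an
#' error, never silently repaired.
#'
#' @param confidences an `arc_confidence` table ([bootstrap_confidence()]).
#' @param strength_floor minimum significance threshold for arc strength.
#' @param direction_threshold directionality threshold.
#' @param nodes node universe (defaults to the confidence table's
#'   endpoints).
#' @return a `consensus_graph`: list with `nodes`, `arcs` (directed,
#'   two-column matrix), `undirected` (two-column matrix), `strength_threshold`
#'   (effective), `direction_threshold`, and the retained rows in `table`.
#' @export
build_consensus <- function(confidences, strength_floor = 0.700,
                            direction_threshold = 0.666, nodes = NULL) {
  stopifnot(all(c("from", "to", "strength") %in% names(confidences)))
  if (is.null(nodes)) {
    nodes <- sort(unique(c(confidences$from, confidences$to)))
  }
  eff <- max(significance_threshold(confidences$strength), strength_floor)
  keep <- confidences[confidences$strength > eff, , drop = FALSE]
  arcs <- NULL
  undirected <- NULL
  for (i in seq_len(nrow(keep))) {
    d <- keep$direction[i]
    if (!is.na(d) && d >= direction_threshold) {
      arcs <- rbind(arcs, c(keep$from[i], keep$to[i]))
    } else if (!is.na(d) && 1 - d >= direction_threshold) {
      arcs <- rbind(arcs, c(keep$to[i], keep$from[i]))
    } else {
      undirected <- rbind(undirected, c(keep$from[i], keep$to[i]))
    }
  }
  arcs <- as_arc_matrix(arcs)
  undirected <- as_arc_matrix(undirected)
  if (is.null(try_topo_sort(list(nodes = nodes, arcs = arcs)))) {
    stop("retained directed arcs form a cycle; consensus graph invalid")
  }
  structure(list(nodes = nodes, arcs = arcs, undirected = undirected,
                 strength_threshold = eff,
                 direction_threshold = direction_threshold,
                 table = keep),
            class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat("consensus_graph:", length(x$nodes), "nodes,", nrow(x$arcs),
      "directed arcs,", nrow(x$undirected), "undirected edge(s)\n")
  cat("effective strength threshold:", format(x$strength_threshold),
      "| direction threshold:", format(x$direction_threshold), "\n")
  invisible(x)
}

#' Orient undirected consensus edges by expert knowledge
#'
#' Converts a consensus graph into a fully directed [dag()] by applying an
#' expert orientation to every undirected edge (as done for the mechanical
#' ventilation / high respiratory rate edge, oriented from respiratory
#' rate to ventilation). Directed arcs are never altered.
#'
#' @param graph a `consensus_graph`.
#' @param expert_orientations list/two-column matrix of directed pairs
#'   `(from, to)`, one per undirected edge.
#' @return a [dag()].
#' @export
orient_undirected <- function(graph, expert_orientations = NULL) {
  expert <- as_arc_matrix(expert_orientations)
  arcs <- graph$arcs
  for (i in seq_len(nrow(graph$undirected))) {
    a <- graph$undirected[i, 1]; b <- graph$undirected[i, 2]
    hit <- (expert[, 1] == a & expert[, 2] == b) |
      (expert[, 1] == b & expert[, 2] == a)
    if (!any(hit)) {
      stop(sprintf("undirected edge %s - %s has no expert orientation", a, b))
    }
    arcs <- rbind(arcs, expert[which(hit)[1], ])
  }
  if (is.null(try_topo_sort(list(nodes = graph$nodes, arcs = arcs)))) {
    stop("expert orientation induces a directed cycle")
  }
  dag(graph$nodes, arcs)
}

#' Read/write bootstrap confidence tables and consensus graphs
#'
#' The confidence table CSV has columns `from,to,strength,direction`; the
#' consensus arc-list CSV has columns `from,to,directed` plus a JSON
#' sidecar recording the thresholds.
#'
#' @param x an `arc_confidence` table or `consensus_graph`.
#' @param path CSV file path (the consensus writer also writes
#'   `<path>.json`).
#' @export
write_confidence_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_confidence_csv
#' @export
read_confidence_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "strength", "direction") %in% names(df)))
  structure(df, class = c("arc_confidence", "data.frame"))
}

#' @rdname write_confidence_csv
#' @export
write_consensus_csv <- function(x, path) {
  df <- rbind(
    data.frame(from = x$arcs[, 1], to = x$arcs[, 2],
               directed = rep(TRUE, nrow(x$arcs))),
    data.frame(from = x$undirected[, 1], to = x$undirected[, 2],
               directed = rep(FALSE, nrow(x$undirected))))
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(strength_threshold = x$strength_threshold,
                            direction_threshold = x$direction_threshold,
                            nodes = x$nodes),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
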
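#' Directed acyclic graphs over named variables
#'
#' A `dag` is a minimal container for a directed acyclic graph: a character
#' vector of node names and an arc list (ordered `from`/`to` pairs). All
#' structure-learning and inference functions in the package operate on this
#' class. Construction validates acyclicity, so a `dag` object can always be
#' topologically sorted.
#'
#' @param nodes character vector of unique node names.
#' @param arcs two-column character matrix or data frame of `(from, to)`
#'   pairs; may have zero rows. Self-loops and duplicated ordered pairs are
#'   rejected, as is any directed cycle.
#' @return An object of class `dag` with elements `nodes` and `arcs`
#'   (two-column character matrix).
#' @examples
#' g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
#' topo_sort(g)
#' @export
dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  arcs <- as_arc_matrix(arcs)
  if (nrow(arcs) > 0) {
    if (!all(arcs %in% nodes)) {
      stop("arc endpoints must be declared nodes: ",
           paste(setdiff(unique(as.vector(arcs)), nodes), collapse = ", "))
    }
    if (any(arcs[, 1] == arcs[, 2])) stop("self-loops are not allowed")
    key <- paste(arcs[, 1], arcs[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicated arcs")
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "dag")
  if (is.null(try_topo_sort(g))) stop("arcs contain a directed cycle")
  g
}

as_arc_matrix <- function(arcs) {
  if (is.null(arcs) || NROW(arcs) == 0) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("from", "to"))))
  }
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs)
  if (is.vector(arcs) && length(arcs) == 2) arcs <- matrix(arcs, ncol = 2)
  arcs <- matrix(as.character(arcs), ncol = 2,
                 dimnames = list(NULL, c("from", "to")))
  arcs
}

#' @export
print.dag <- function(x, ...) {
  cat("dag:", length(x$nodes), "nodes,", nrow(x$arcs), "arcs\n")
  if (nrow(x$arcs) > 0) {
    cat(paste0("  ", x$arcs[, 1], " -> ", x$arcs[, 2]), sep = "\n")
  }
  invisible(x)
}

# Kahn's algorithm; NULL when a cycle exists.
try_topo_sort <- function(g) {
  nodes <- g$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(factor(g$arcs[, 2], levels = nodes))
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  arcs <- g$arcs
  while (length(avail) > 0) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    out <- arcs[arcs[, 1] == v, 2]
    arcs <- arcs[arcs[, 1] != v, , drop = FALSE]
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) != length(nodes)) NULL else order
}

#' Topological ordering of a DAG
#'
#' @param g a [dag()].
#' @return character vector of node names, parents before children.
#' @export
topo_sort <- function(g) {
  out <- try_topo_sort(g)
  if (is.null(out)) stop("graph is cyclic")
  out
}

#' Parents, children and Markov blanket
#'
#' @param g a [dag()].
#' @param node node name.
#' @return character vector of node names.
#' @export
dag_parents <- function(g, node) {
  sort(unique(g$arcs[g$arcs[, 2] == node, 1]))
}

#' @rdname dag_parents
#' @export
dag_children <- function(g, node) {
  sort(unique(g$arcs[g$arcs[, 1] == node, 2]))
}

#' @rdname dag_parents
#' @export
markov_blanket <- function(g, node) {
  ch <- dag_children(g, node)
  coparents <- unlist(lapply(ch, function(c) dag_parents(g, c)))
  sort(setdiff(unique(c(dag_parents(g, node), ch, coparents)), node))
}

# TRUE when `to` is reachable from `from` following arcs given as a
# named list of children.
reachable <- function(children, from, to) {
  seen <- from
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    if (to %in% nxt) return(TRUE)
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
  }
  FALSE
}

children_list <- function(nodes, arcs) {
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(arcs))) {
    out[[arcs[i, 1]]] <- c(out[[arcs[i, 1]]], arcs[i, 2])
  }
  out
}

#' Black- and whitelist constraints for structure learning
#'
#' Constraint sets restrict the search space of [hill_climb()] / [mmhc()]:
#' blacklisted ordered arcs never appear in a learned graph, whitelisted
#' arcs always do (and are never deleted or reversed).
#'
#' @param blacklist,whitelist two-column matrices/data frames of ordered
#'   `(from, to)` pairs, or `NULL`.
#' @return object of class `constraint_set`.
#' @export
constraint_set <- function(blacklist = NULL, whitelist = NULL) {
  blacklist <- as_arc_matrix(blacklist)
  whitelist <- as_arc_matrix(whitelist)
  bk <- paste(blacklist[, 1], blacklist[, 2], sep = "\r")
  wk <- paste(whitelist[, 1], whitelist[, 2], sep = "\r")
  if (length(intersect(bk, wk)) > 0) {
    stop("whitelist and blacklist overlap")
  }
  if (nrow(whitelist) > 0) {
    nodes <- unique(as.vector(whitelist))
    if (is.null(try_topo_sort(list(nodes = nodes, arcs = whitelist)))) {
      stop("whitelist is cyclic")
    }
  }
  structure(list(blacklist = blacklist, whitelist = whitelist),
            class = "constraint_set")
}

blacklisted <- function(constraints, from, to) {
  b <- constraints$blacklist
  any(b[, 1] == from & b[, 2] == to)
}

whitelisted <- function(constraints, from, to) {
  w <- constraints$whitelist
  any(w[, 1] == from & w[, 2] == to)
}

#' Domain constraints for the cardiac-function network
#'
#' Encodes the prior knowledge used when learning the clinician-estimate
#' network: `age` and `gender` are exogenous, so every arc pointing into
#' them is forbidden, and the `estimate` cannot influence any clinical
#' variable, so every arc leaving it is forbidden.
#'
#' @param nodes node names of the modelled variables (must contain
#'   `estimate`; `age`/`gender` constraints are added when those nodes are
#'   present).
#' @param estimate name of the estimate node.
#' @return a [constraint_set()].
#' @export
sics_constraints <- function(nodes, estimate = "estimate") {
  bl <- NULL
  for (root in intersect(c("age", "gender"), nodes)) {
    bl <- rbind(bl, cbind(setdiff(nodes, root), root))
  }
  if (estimate %in% nodes) {
    bl <- rbind(bl, cbind(estimate, setdiff(nodes, estimate)))
  }
  bl <- unique(bl)
  constraint_set(blacklist = bl)
}

#' Read and write arc lists as CSV
#'
#' Arc-list files have columns `from,to` (plus any extra columns, which are
#' preserved on read).
#'
#' @param g a [dag()].
#' @param path file path.
#' @param nodes node universe when reading (defaults to the arcs' own
#'   endpoints).
#' @return `write_dag_csv` returns `path` invisibly; `read_dag_csv` returns
#'   a [dag()].
#' @export
write_dag_csv <- function(g, path) {
  utils::write.csv(as.data.frame(g$arcs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dag_csv
#' @export
read_dag_csv <- function(path, nodes = NULL) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("from", "to") %in% names(df))) {
    stop("arc-list file needs 'from' and 'to' columns")
  }
  arcs <- as.matrix(df[, c("from", "to")])
  if (is.null(nodes)) nodes <- sort(unique(as.vector(arcs)))
  dag(nodes, arcs)
}

#' Serialize a DAG (with optional learning metadata) to JSON
#'
#' @param g a [dag()].
#' @param path file path.
#' @param meta optional named list stored alongside nodes and arcs.
#' @return `path`, invisibly (writer); a [dag()] (reader).
#' @export
write_dag_json <- function(g, path, meta = NULL) {
  doc <- list(nodes = g$nodes,
              arcs = as.data.frame(g$arcs, stringsAsFactors = FALSE))
  if (!is.null(meta)) doc$meta <- meta
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_dag_json
#' @export
read_dag_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  arcs <- if (NROW(doc$arcs) > 0) as.matrix(doc$arcs) else NULL
  dag(doc$nodes, arcs)
}
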
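#' Construct a directed acyclic graph over named nodes
#'
#' @param nodes Character vector of unique node ids.
#' @param parents Named list mapping a node to its parent nodes; nodes
#'   absent from the list have no parents.
#' @param max_parents Maximum in-degree (default 10, the search cap).
#' @return An object of class `dag` with `nodes` and a complete
#'   `parents` list.
#' @export
dag <- function(nodes, parents = list(), max_parents = 10L) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node ids")
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (nd in nodes) full[[nd]] <- character(0)
  for (nd in names(parents)) {
    if (!nd %in% nodes) stop("parent set for unknown node ", nd)
    ps <- as.character(parents[[nd]])
    if (!all(ps %in% nodes)) stop("unknown parent of ", nd)
    if (nd %in% ps) stop("self-loop at ", nd)
    if (length(ps) > max_parents) {
      stop("node ", nd, " exceeds max_parents = ", max_parents)
    }
    full[[nd]] <- ps
  }
  out <- structure(list(nodes = nodes, parents = full), class = "dag")
  if (!is_acyclic(out)) stop("graph contains a directed cycle")
  out
}

is_acyclic <- function(dag) {
  el <- dag_edges(dag)
  if (nrow(el) == 0L) return(TRUE)
  g <- igraph::graph_from_data_frame(el, directed = TRUE,
                                     vertices = dag$nodes)
  igraph::is_dag(g)
}

dag_edges <- function(dag) {
  rows <- lapply(dag$nodes, function(nd) {
    ps <- dag$parents[[nd]]
    if (length(ps) == 0L) return(NULL)
    data.frame(parent = ps, child = nd, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(parent = character(0), child = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

dag_from_adjacency <- function(adj, nodes) {
  parents <- lapply(seq_along(nodes), function(j) nodes[adj[, j] == 1L])
  names(parents) <- nodes
  dag(nodes, parents, max_parents = length(nodes))
}

dag_to_adjacency <- function(dag) {
  n <- length(dag$nodes)
  adj <- matrix(0L, n, n, dimnames = list(dag$nodes, dag$nodes))
  el <- dag_edges(dag)
  if (nrow(el) > 0L) adj[cbind(el$parent, el$child)] <- 1L
  adj
}

data_for_cpp <- function(data) {
  stopifnot(inherits(data, "discrete_matrix"))
  list(values = t(data$values), levels = unname(data$levels))
}

#' BDeu family log score
#'
#' Bayesian Dirichlet equivalent uniform marginal log-likelihood of one
#' child node given a candidate parent set: with `q` parent
#' configurations, `r` child states and hyperparameters
#' `a_jk = ess / (q r)`, the score is
#' `sum_j [ lnG(a_j) - lnG(a_j + N_j) + sum_k lnG(a_jk + N_jk) -
#' lnG(a_jk) ]` over the data counts `N`. Decomposable and equal on
#' Markov-equivalent structures.
#'
#' @param child Child node id.
#' @param parents Character vector of parent ids (excluding the child).
#' @param data A `discrete_matrix`.
#' @param ess Equivalent sample size (> 0; default 1).
#' @param max_parents In-degree cap (error above it).
#' @return Log score (0 for zero-sample data).
#' @export
bde_family_score <- function(child, parents, data, ess = 1,
                             max_parents = 10L) {
  stopifnot(inherits(data, "discrete_matrix"), ess > 0)
  if (child %in% parents) stop("child cannot be its own parent")
  if (length(parents) > max_parents) {
    stop("parent set exceeds max_parents = ", max_parents)
  }
  ci <- match(child, data$genes)
  pi <- match(parents, data$genes)
  if (is.na(ci) || anyNA(pi)) stop("unknown node id")
  d <- data_for_cpp(data)
  .cpp_bde_family_score(d$values, d$levels, ci - 1L,
                        as.integer(pi - 1L), ess)
}

#' BDeu network log score
#'
#' Sum of [bde_family_score()] over all nodes of a DAG
#' (decomposability). Cyclic input is an error.
#'
#' @param dag A `dag`.
#' @param data A `discrete_matrix` covering all nodes.
#' @param ess Equivalent sample size.
#' @return Log score.
#' @export
bde_network_score <- function(dag, data, ess = 1) {
  stopifnot(inherits(dag, "dag"))
  if (!is_acyclic(dag)) stop("graph contains a directed cycle")
  sum(vapply(dag$nodes, function(nd) {
    bde_family_score(nd, dag$parents[[nd]], data, ess = ess,
                     max_parents = length(dag$nodes))
  }, numeric(1)))
}
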
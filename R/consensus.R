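#' Edge-frequency consensus over repeated structure searches
#'
#' Each directed edge's frequency is its number of occurrences across
#' the input DAGs divided by the number of DAGs; edges at or above the
#' threshold are retained (the inclusive reading of a "30%" cut-off, so
#' an edge in exactly 30% of runs is kept). Node pairs retained in both
#' directions are flagged as feedback pairs, for which the combined
#' frequency of the two directions is reported.
#'
#' @param dags List of `dag` objects over a common node set.
#' @param threshold Frequency threshold in (0, 1]; default 0.30.
#' @return An object of class `consensus_network`: `nodes`, `edges`
#'   (parent, child, frequency, feedback), `feedback_pairs` (node_a,
#'   node_b, combined_frequency), `threshold`, `n_dags`.
#' @export
consensus_network <- function(dags, threshold = 0.30) {
  stopifnot(length(dags) >= 1L, threshold > 0, threshold <= 1)
  nodes <- dags[[1L]]$nodes
  for (d in dags) {
    if (!setequal(d$nodes, nodes)) stop("DAGs cover different node sets")
  }
  all_edges <- do.call(rbind, lapply(dags, dag_edges))
  if (is.null(all_edges) || nrow(all_edges) == 0L) {
    return(new_consensus_network(nodes,
                                 data.frame(parent = character(0),
                                            child = character(0),
                                            frequency = numeric(0)),
                                 threshold, n_dags = length(dags)))
  }
  key <- paste(all_edges$parent, all_edges$child, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  freq <- data.frame(
    parent = vapply(parts, `[`, character(1), 1L),
    child = vapply(parts, `[`, character(1), 2L),
    frequency = as.numeric(counts) / length(dags),
    stringsAsFactors = FALSE
  )
  keep <- freq[freq$frequency >= threshold, , drop = FALSE]
  new_consensus_network(nodes, keep, threshold, n_dags = length(dags))
}

new_consensus_network <- function(nodes, edges, threshold, n_dags = NA_integer_) {
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  fwd <- paste(edges$parent, edges$child, sep = "\r")
  rev <- paste(edges$child, edges$parent, sep = "\r")
  edges$feedback <- rev %in% fwd
  fb <- edges[edges$feedback & edges$parent < edges$child, , drop = FALSE]
  feedback_pairs <- data.frame(
    node_a = fb$parent, node_b = fb$child,
    combined_frequency = fb$frequency +
      edges$frequency[match(paste(fb$child, fb$parent, sep = "\r"), fwd)],
    stringsAsFactors = FALSE
  )
  structure(list(nodes = nodes, edges = edges,
                 feedback_pairs = feedback_pairs,
                 threshold = threshold, n_dags = n_dags),
            class = "consensus_network")
}

#' Order nodes by distance from a root regulator
#'
#' Breadth-first distance over the undirected skeleton of the retained
#' consensus edges: the root (STM in the study design) is order 0,
#' its direct neighbours order 1, their neighbours order 2, and so on.
#' Nodes with no path to the root are marked unreachable (`NA`).
#'
#' @param network A `consensus_network`.
#' @param root Root node id (must be present).
#' @return Named integer vector of orders; `NA` = unreachable.
#' @export
annotate_order <- function(network, root) {
  stopifnot(inherits(network, "consensus_network"))
  if (!root %in% network$nodes) stop("root node absent from network")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("parent", "child")], directed = FALSE,
    vertices = network$nodes)
  d <- igraph::distances(g, v = root, mode = "all")[1L, ]
  out <- stats::setNames(suppressWarnings(as.integer(d)), network$nodes)
  out[is.infinite(d)] <- NA_integer_
  out[network$nodes]
}

#' @export
print.consensus_network <- function(x, ...) {
  cat("Consensus network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges at threshold", x$threshold, "\n")
  if (nrow(x$feedback_pairs) > 0L) {
    cat("Feedback pairs:", nrow(x$feedback_pairs), "\n")
  }
  invisible(x)
}
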
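#' Export a consensus network as SIF plus an edge-attribute table
#'
#' Writes one line per directed edge (`parent <tab> relation <tab>
#' child`) in Cytoscape's simple-interaction format, and a sidecar
#' tab-delimited attribute table carrying per-edge frequency and the
#' feedback flag.
#'
#' @param network A `consensus_network` (see [consensus_network()]).
#' @param path Output SIF path.
#' @param attr_path Output path of the attribute table; defaults to
#'   `path` with an `_edges.tsv` suffix.
#' @param relation Relation label written in the SIF second column.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path,
                      attr_path = paste0(sub("\\.sif$", "", path), "_edges.tsv"),
                      relation = "regulates") {
  stopifnot(inherits(network, "consensus_network"))
  edges <- network$edges
  sif <- if (nrow(edges) > 0L) {
    sprintf("%s\t%s\t%s", edges$parent, relation, edges$child)
  } else character(0)
  writeLines(sif, path)
  attrs <- data.frame(parent = edges$parent, child = edges$child,
                      frequency = edges$frequency, feedback = edges$feedback,
                      stringsAsFactors = FALSE)
  utils::write.table(attrs, attr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Re-import a SIF / attribute-table pair
#'
#' Round-trip counterpart of [write_sif()]; reconstructs the edge table
#' (and, with it, the feedback pairing) from the exported files.
#'
#' @param path SIF path.
#' @param attr_path Attribute-table path (default as in [write_sif()]).
#' @param threshold Frequency threshold recorded on the rebuilt object.
#' @return A `consensus_network`.
#' @export
read_sif <- function(path,
                     attr_path = paste0(sub("\\.sif$", "", path), "_edges.tsv"),
                     threshold = NA_real_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  attrs <- utils::read.table(attr_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE,
                             colClasses = c(parent = "character",
                                            child = "character"))
  if (length(lines) != nrow(attrs)) {
    stop("SIF and attribute table disagree on edge count")
  }
  if (nrow(attrs) > 0L) {
    parts <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
    if (!all(parts[, 1L] == attrs$parent & parts[, 3L] == attrs$child)) {
      stop("SIF and attribute table list different edges")
    }
  }
  nodes <- sort(unique(c(attrs$parent, attrs$child)))
  new_consensus_network(nodes = nodes,
                        edges = attrs[, c("parent", "child", "frequency")],
                        threshold = threshold)
}
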